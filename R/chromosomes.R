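#' Chromosome identifiers in canonical order
#'
#' The sixteen budding-yeast chromosomes, as Roman numerals `I` through
#' `XVI`. This is the canonical column order of every karyotype in the
#' package.
#'
#' @return Character vector of length 16.
#' @export
chromosome_ids <- function() {
  as.character(utils::as.roman(1:16))
}

#' Reference chromosome length table
#'
#' Lengths in base pairs of the 16 nuclear chromosomes of
#' *Saccharomyces cerevisiae*, taken from the S288C reference assembly
#' (R64). These lengths weight copy numbers when computing apparent
#' ploidy (total DNA content relative to the haploid genome). A
#' user-supplied table with the same two columns can be used anywhere
#' this one is accepted.
#'
#' @return A data frame with columns `chromosome` (Roman numeral) and
#'   `length_bp` (positive integer), one row per chromosome in canonical
#'   order.
#' @seealso [apparent_ploidy()]
#' @export
#' @examples
#' tab <- yeast_chromosomes()
#' sum(tab$length_bp) # ~12.07 Mb haploid genome
yeast_chromosomes <- function() {
  data.frame(
    chromosome = chromosome_ids(),
    length_bp = c(
      230218L, 813184L, 316620L, 1531933L,
      576874L, 270161L, 1090940L, 562643L,
      439888L, 745751L, 666816L, 1078177L,
      924431L, 784333L, 1091291L, 948066L
    ),
    stringsAsFactors = FALSE
  )
}

#' Normalize chromosome labels to canonical Roman numerals
#'
#' Accepts Roman numerals in any case (`"iv"`, `"IV"`), Arabic numbers
#' (`"4"`, `4`), and an optional `"chr"`/`"Chr"` prefix, and returns the
#' canonical `I`..`XVI` label.
#'
#' @param x Character or numeric vector of chromosome labels.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' normalize_chromosome(c("chrIV", "iv", "4", "XVI"))
normalize_chromosome <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr][._ ]?", "", x)
  out <- character(length(x))
  is_num <- grepl("^[0-9]+$", x)
  out[is_num] <- as.character(utils::as.roman(as.integer(x[is_num])))
  rom <- suppressWarnings(utils::as.roman(toupper(x[!is_num])))
  out[!is_num] <- as.character(rom)
  bad <- is.na(out) | !(out %in% chromosome_ids())
  if (any(bad)) {
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Validate a chromosome length table
#'
#' @param table Data frame with columns `chromosome` and `length_bp`.
#' @return The table, rows reordered to canonical chromosome order and
#'   labels normalized.
#' @export
validate_chromosome_table <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("chromosome", "length_bp") %in% names(table))) {
    stop("chromosome table must have columns 'chromosome' and 'length_bp'")
  }
  chrom <- normalize_chromosome(table$chromosome)
  if (anyDuplicated(chrom)) stop("duplicated chromosome identifiers")
  if (!setequal(chrom, chromosome_ids())) {
    stop("chromosome table must cover exactly chromosomes I-XVI; missing: ",
         paste(setdiff(chromosome_ids(), chrom), collapse = ", "))
  }
  if (any(!is.finite(table$length_bp)) || any(table$length_bp <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  table$chromosome <- chrom
  table[match(chromosome_ids(), chrom), , drop = FALSE]
}
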