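#' Construct and validate a karyotype
#'
#' A karyotype is a vector of 16 non-negative integer whole-chromosome
#' copy numbers, one per yeast chromosome in canonical order `I`..`XVI`.
#' Copy number 0 represents nullisomy, which is lethal: a live cell has
#' all copy numbers >= 1.
#'
#' @param copy_numbers Numeric vector of length 16 of non-negative
#'   integers. If named, names are normalized (see
#'   [normalize_chromosome()]) and used to reorder into canonical order.
#' @param require_live If `TRUE` (default), reject karyotypes containing
#'   a zero copy number.
#' @return Named integer vector of length 16, names `I`..`XVI`.
#' @export
#' @examples
#' as_karyotype(rep(1, 16))
#' k <- as_karyotype(c(rep(1, 3), 2, rep(1, 12))) # disomic for ChrIV
as_karyotype <- function(copy_numbers, require_live = TRUE) {
  k <- copy_numbers
  if (length(k) != 16L) {
    stop("a karyotype must have exactly 16 copy numbers, got ", length(k))
  }
  if (any(!is.finite(k)) || any(k < 0) || any(k != round(k))) {
    stop("copy numbers must be non-negative integers")
  }
  if (require_live && any(k == 0)) {
    stop("karyotype contains a nullisomic chromosome (copy number 0)")
  }
  k <- as.integer(round(k))
  if (!is.null(names(copy_numbers)) && !all(names(copy_numbers) == "")) {
    nm <- normalize_chromosome(names(copy_numbers))
    if (anyDuplicated(nm)) stop("duplicated chromosome names in karyotype")
    k <- k[match(chromosome_ids(), nm)]
  }
  names(k) <- chromosome_ids()
  k
}

#' Apparent ploidy of a karyotype
#'
#' Total DNA content relative to the haploid genome: the length-weighted
#' mean copy number sum(c_i * L_i) / sum(L_i), where L_i are the
#' chromosome lengths in base pairs. This is the quantity a flow
#' cytometer reports when a G1 peak is scaled to a haploid control. A
#' `"count"` method (mean copy number, total chromosomes / 16) is also
#' exposed since the two only differ through length weighting.
#'
#' @param karyotype Copy-number vector, see [as_karyotype()].
#' @param table Chromosome length table, default [yeast_chromosomes()].
#' @param method `"length"` (default, length-weighted) or `"count"`
#'   (unweighted mean copy number).
#' @return A single number; 1 for a haploid, 2 for a diploid.
#' @export
#' @examples
#' apparent_ploidy(rep(1, 16)) # 1
#' k <- rep(1, 16); k[4] <- 2  # one extra ChrIV
#' apparent_ploidy(k)          # ~1.13: ChrIV is the largest chromosome
apparent_ploidy <- function(karyotype, table = yeast_chromosomes(),
                            method = c("length", "count")) {
  k <- as_karyotype(karyotype, require_live = FALSE)
  method <- match.arg(method)
  if (method == "count") return(mean(k))
  table <- validate_chromosome_table(table)
  len <- table$length_bp[match(names(k), table$chromosome)]
  sum(k * len) / sum(len)
}

#' Basal ploidy (modal copy number)
#'
#' The integer copy number occurring most frequently in the karyotype.
#' When two copy numbers tie for the mode (e.g. eight chromosomes at 1
#' and eight at 2) the basal ploidy is undefined and `NA` is returned;
#' such strains cannot be assigned per-chromosome aneuploidy calls.
#'
#' @inheritParams apparent_ploidy
#' @return Integer scalar, or `NA_integer_` on a tie.
#' @export
#' @examples
#' basal_ploidy(c(rep(1, 7), rep(2, 9)))  # 2
#' basal_ploidy(c(rep(1, 8), rep(2, 8)))  # NA (tie)
basal_ploidy <- function(karyotype) {
  k <- as_karyotype(karyotype)
  counts <- table(k)
  top <- counts[counts == max(counts)]
  if (length(top) > 1L) return(NA_integer_)
  as.integer(names(top))
}

#' Aneuploid chromosomes of a karyotype
#'
#' Chromosomes whose copy number deviates (gain or loss alike) from the
#' basal ploidy. Errors when the basal ploidy is undefined, signalling
#' that the strain must be excluded from single-chromosome analyses.
#'
#' @inheritParams apparent_ploidy
#' @return Character vector of chromosome identifiers (possibly empty).
#' @export
#' @examples
#' k <- rep(2, 16); k[6] <- 1 # ChrVI monosomy on a diploid base
#' aneuploid_chromosomes(k)   # "VI"
aneuploid_chromosomes <- function(karyotype) {
  k <- as_karyotype(karyotype)
  bp <- basal_ploidy(k)
  if (is.na(bp)) {
    stop("basal ploidy undefined (modal copy number tie); ",
         "strain cannot be assigned aneuploid chromosomes")
  }
  names(k)[k != bp]
}

#' Copy-number ratio between two chromosomes
#'
#' For strains with copy numbers in \{1, 2\} the ratio is 0.5, 1 or 2;
#' a pair with ratio different from 1 is called imbalanced.
#'
#' @inheritParams apparent_ploidy
#' @param chrom_a,chrom_b Chromosome identifiers (numerator,
#'   denominator); any label accepted by [normalize_chromosome()].
#' @return The ratio `c_a / c_b`.
#' @export
imbalance_ratio <- function(karyotype, chrom_a, chrom_b) {
  k <- as_karyotype(karyotype)
  a <- normalize_chromosome(chrom_a)
  b <- normalize_chromosome(chrom_b)
  if (k[a] == 0 || k[b] == 0) stop("copy numbers must be >= 1 for a ratio")
  unname(k[a] / k[b])
}

#' Per-strain aneuploidy metrics
#'
#' All the derived karyotype summaries used in genome-level association
#' analyses: apparent ploidy, basal ploidy, number of aneuploid
#' chromosomes, megabases in aneuploidy (each aneuploid chromosome's
#' full length counted once, gains and losses alike), total chromosome
#' count and total genome size in megabases.
#'
#' @inheritParams apparent_ploidy
#' @return A one-row data frame with columns `apparent_ploidy`,
#'   `basal_ploidy`, `n_aneuploid_chromosomes`, `mb_aneuploid`,
#'   `total_chromosomes`, `total_mb`. The aneuploidy counts are `NA`
#'   when basal ploidy is undefined.
#' @export
aneuploidy_metrics <- function(karyotype, table = yeast_chromosomes()) {
  k <- as_karyotype(karyotype)
  table <- validate_chromosome_table(table)
  len <- table$length_bp[match(names(k), table$chromosome)]
  bp <- basal_ploidy(k)
  if (is.na(bp)) {
    n_aneu <- NA_integer_
    mb_aneu <- NA_real_
  } else {
    aneu <- k != bp
    n_aneu <- sum(aneu)
    mb_aneu <- sum(len[aneu]) / 1e6
  }
  data.frame(
    apparent_ploidy = apparent_ploidy(k, table),
    basal_ploidy = bp,
    n_aneuploid_chromosomes = n_aneu,
    mb_aneuploid = mb_aneu,
    total_chromosomes = sum(k),
    total_mb = sum(k * len) / 1e6
  )
}
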