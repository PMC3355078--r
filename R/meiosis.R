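#' Random spore karyotype from triploid meiosis
#'
#' In meiosis I of a homozygous triploid, each chromosome's three
#' homologs segregate 2:1, so each of the 16 chromosomes of a resulting
#' spore independently carries 1 or 2 copies with probability 1/2.
#'
#' @param n Number of spores to draw (default 1).
#' @return For `n = 1`, a karyotype vector; otherwise an `n x 16`
#'   integer matrix, one spore per row.
#' @export
#' @examples
#' set.seed(7)
#' random_spore()
random_spore <- function(n = 1L) {
  m <- matrix(1L + stats::rbinom(n * 16L, 1L, 0.5), nrow = n, ncol = 16L)
  colnames(m) <- chromosome_ids()
  if (n == 1L) as_karyotype(m[1L, ]) else m
}

#' Exact apparent-ploidy distribution over all triploid-meiosis spores
#'
#' Enumerates all 2^16 = 65,536 equally likely spore karyotypes (each
#' chromosome 1 or 2) and returns their apparent ploidies. This exact
#' enumeration backs one-sample comparisons and serves as a check on
#' Monte-Carlo output.
#'
#' @param table Chromosome length table.
#' @return Numeric vector of length 65,536 of apparent ploidies (one
#'   per karyotype, equally likely).
#' @export
enumerate_spore_ploidies <- function(table = yeast_chromosomes()) {
  table <- validate_chromosome_table(table)
  len <- table$length_bp
  idx <- 0:(2L^16L - 1L)
  total <- sum(len)
  ploidy <- rep(1, length(idx))
  for (j in 1:16) {
    bit <- idx %/% (2L^(j - 1L)) %% 2L
    ploidy <- ploidy + bit * (len[j] / total)
  }
  ploidy
}

#' Simulated apparent-ploidy distribution of random spores
#'
#' Repeatedly draws batches of random triploid-meiosis spores, computes
#' each batch's apparent ploidies and histogram, and summarizes bin
#' counts across replicates (mean and standard deviation), mirroring
#' the way expected spore-ploidy histograms with simulation error bars
#' are constructed. The pooled ploidies are kept for empirical-CDF
#' comparisons.
#'
#' @param n_spores Spores per replicate (default 41, a typical number
#'   of viable spores scored in one experiment).
#' @param n_replicates Number of replicates (default 10,000).
#' @param bin_edges Histogram bin edges on the apparent-ploidy axis
#'   (default width 0.1 on \[1, 2\]).
#' @param table Chromosome length table.
#' @return Object of class `spore_ploidy_distribution`: list with
#'   `bins` (data frame: bin edges, mean and sd of counts per
#'   replicate), `pooled` (all simulated ploidies), and the settings.
#' @export
#' @examples
#' set.seed(1)
#' d <- spore_ploidy_distribution(n_replicates = 100)
#' d$bins
spore_ploidy_distribution <- function(n_spores = 41L,
                                      n_replicates = 10000L,
                                      bin_edges = seq(1, 2, by = 0.1),
                                      table = yeast_chromosomes()) {
  if (n_spores < 1 || n_replicates < 1) stop("counts must be positive")
  table <- validate_chromosome_table(table)
  len <- table$length_bp
  total_n <- n_spores * n_replicates
  spores <- matrix(stats::rbinom(total_n * 16L, 1L, 0.5),
                   nrow = total_n, ncol = 16L)
  ploidy <- 1 + as.vector(spores %*% (len / sum(len)))
  rep_id <- rep(seq_len(n_replicates), each = n_spores)
  nb <- length(bin_edges) - 1L
  bin <- findInterval(ploidy, bin_edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  in_range <- bin >= 1L & bin <= nb
  counts <- matrix(0L, nrow = n_replicates, ncol = nb)
  tab <- table(factor(rep_id[in_range], levels = seq_len(n_replicates)),
               factor(bin[in_range], levels = seq_len(nb)))
  counts[] <- as.integer(tab)
  bins <- data.frame(
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1],
    mean_count = colMeans(counts),
    sd_count = apply(counts, 2, stats::sd)
  )
  structure(list(bins = bins, pooled = ploidy, n_spores = n_spores,
                 n_replicates = n_replicates, bin_edges = bin_edges),
            class = "spore_ploidy_distribution")
}

#' @export
print.spore_ploidy_distribution <- function(x, ...) {
  cat(sprintf(
    "Apparent-ploidy distribution: %d replicates x %d spores\n",
    x$n_replicates, x$n_spores))
  print(x$bins)
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of observed and expected ploidies
#'
#' Two-sample KS test between observed apparent ploidies and an
#' expected sample (typically a large pool of simulated spore ploidies,
#' or the exact enumeration from [enumerate_spore_ploidies()]). Used to
#' ask whether the viable strains' ploidy distribution deviates from
#' the one random meiotic segregation predicts.
#'
#' @param observed Numeric vector of observed apparent ploidies.
#' @param expected Numeric vector representing the expected
#'   distribution.
#' @return List with `statistic` (the KS D) and `p.value`.
#' @export
ks_compare <- function(observed, expected) {
  if (length(observed) == 0) stop("observed sample is empty")
  if (length(expected) == 0) stop("expected sample is empty")
  kt <- suppressWarnings(stats::ks.test(observed, expected))
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
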