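#' Fisher's exact test on a contingency table
#'
#' Two-sided exact test of association between categorical variables.
#' For 2x2 tables the two-sided p-value follows the minimum-likelihood
#' convention: the sum of probabilities of all tables (with the
#' observed margins) no more probable than the observed one. Larger
#' tables are tested exactly by network enumeration when feasible, else
#' by Monte-Carlo with a fixed number of replicates (set a seed for
#' reproducibility).
#'
#' @param table Matrix of non-negative integer counts (r x c, at least
#'   one positive entry).
#' @param simulate_threshold Total-count threshold above which r x c
#'   tables fall back to Monte-Carlo p-values (default 2000).
#' @param B Monte-Carlo replicates for the fallback (default 1e5).
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact(matrix(c(18, 0, 26, 11), nrow = 2)) # ~0.01
fisher_exact <- function(table, simulate_threshold = 2000, B = 1e5) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must contain non-negative integer counts")
  }
  if (sum(table) == 0) stop("contingency table has no observations")
  if (nrow(table) == 2L && ncol(table) == 2L) {
    return(stats::fisher.test(table)$p.value)
  }
  simulate <- sum(table) > simulate_threshold
  stats::fisher.test(table, simulate.p.value = simulate, B = B,
                     workspace = 2e7)$p.value
}

#' Hypergeometric enrichment (upper tail)
#'
#' Probability of observing at least `hits_in_selection` marked items
#' when drawing `selection_size` items without replacement from a
#' population of `population_size` containing `hits_total` marked ones:
#' `P(X >= observed)` under the hypergeometric null.
#'
#' @param hits_in_selection Observed marked items in the selection.
#' @param selection_size Size of the selection (draw).
#' @param hits_total Total marked items in the population.
#' @param population_size Total population size.
#' @return Upper-tail p-value; 1 when `hits_in_selection` is 0.
#' @export
#' @examples
#' # chance of drawing 0 of 18 marked strains in 11 draws from 55
#' 1 - hypergeometric_enrichment(1, 11, 18, 55) # P(X = 0)
hypergeometric_enrichment <- function(hits_in_selection, selection_size,
                                      hits_total, population_size) {
  x <- c(hits_in_selection, selection_size, hits_total, population_size)
  if (any(x < 0) || any(x != round(x))) {
    stop("all counts must be non-negative integers")
  }
  if (hits_in_selection > min(selection_size, hits_total) ||
      selection_size > population_size || hits_total > population_size) {
    stop("inconsistent counts for a hypergeometric test")
  }
  stats::phyper(hits_in_selection - 1, hits_total,
                population_size - hits_total, selection_size,
                lower.tail = FALSE)
}

#' Pairwise chromosome-imbalance scan
#'
#' For every unordered pair of the 16 chromosomes, tests whether
#' strains carrying that pair in copy-number imbalance (ratio 0.5 or 2,
#' i.e. not 1) are enriched for the unstable CIN group, using the
#' upper-tail hypergeometric test ([hypergeometric_enrichment()]).
#' Two groupings are supported: `"hu-vs-rest"` treats HU strains as
#' unstable (S+MU as the stable pool) and `"s-vs-rest"` treats MU+HU
#' as unstable.
#'
#' @param karyotypes Strain x 16 integer matrix of copy numbers.
#' @param cin_classes Character vector of per-strain classes
#'   (`"S"`, `"MU"`, `"HU"`).
#' @param grouping `"hu-vs-rest"` (default) or `"s-vs-rest"`.
#' @param adjust If `TRUE`, append a Benjamini-Hochberg adjusted copy
#'   of the matrix as attribute `"bh"` (off by default; raw p-values
#'   are the primary output).
#' @return A 16 x 16 symmetric matrix of p-values with `NA` on the
#'   diagonal and chromosome identifiers as dimnames.
#' @export
pairwise_imbalance_scan <- function(karyotypes, cin_classes,
                                    grouping = c("hu-vs-rest",
                                                 "s-vs-rest"),
                                    adjust = FALSE) {
  grouping <- match.arg(grouping)
  m <- as.matrix(karyotypes)
  if (ncol(m) != 16L) stop("karyotype matrix must have 16 columns")
  if (nrow(m) != length(cin_classes)) {
    stop("one CIN class per strain required")
  }
  if (!all(cin_classes %in% c("S", "MU", "HU"))) {
    stop("CIN classes must be S, MU or HU")
  }
  unstable <- if (grouping == "hu-vs-rest") {
    cin_classes == "HU"
  } else {
    cin_classes != "S"
  }
  if (sum(unstable) < 2 || sum(!unstable) < 2) {
    stop("need at least 2 strains per CIN group")
  }
  n <- nrow(m)
  k <- sum(unstable)
  p <- matrix(NA_real_, 16, 16,
              dimnames = list(chromosome_ids(), chromosome_ids()))
  for (a in 1:15) {
    for (b in (a + 1):16) {
      imbalanced <- m[, a] != m[, b]
      draw <- sum(imbalanced)
      hits <- sum(imbalanced & unstable)
      pv <- if (draw == 0) 1 else {
        hypergeometric_enrichment(hits, draw, k, n)
      }
      p[a, b] <- pv
      p[b, a] <- pv
    }
  }
  if (adjust) {
    up <- p[upper.tri(p)]
    bh <- p
    bh[upper.tri(bh)] <- stats::p.adjust(up, method = "BH")
    bh[lower.tri(bh)] <- t(bh)[lower.tri(bh)]
    attr(p, "bh") <- bh
  }
  p
}

#' Welch's two-sample t-test
#'
#' Two-sided unpaired t-test with Welch-Satterthwaite degrees of
#' freedom, the standard comparison of group means when variances may
#' differ (e.g. growth rates of stable vs highly unstable strains).
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2; at
#'   least one group with positive variance).
#' @return List with `statistic`, `df` and `p.value`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(statistic = 0, df = NA_real_, p.value = 1))
    }
    stop("both groups are constant; t-test undefined")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Growth rate from timed cell counts
#'
#' Least-squares slope of log2(cell count) against time: the number of
#' population doublings (generations) per hour, as estimated by
#' regressing absolute counts measured at successive sampling times.
#'
#' @param cell_counts Positive cell counts.
#' @param times Sampling times in hours (same length, >= 2 distinct).
#' @return Growth rate in generations per hour.
#' @export
#' @examples
#' growth_rate(c(1e6, 2e6, 4e6), c(0, 1, 2)) # 1 doubling per hour
growth_rate <- function(cell_counts, times) {
  if (length(cell_counts) != length(times) || length(times) < 2) {
    stop("need matched counts and times at >= 2 time points")
  }
  if (any(!is.finite(cell_counts)) || any(cell_counts <= 0)) {
    stop("cell counts must be positive")
  }
  unname(stats::coef(stats::lm(log2(cell_counts) ~ times))[2])
}

#' Peak-normalized Gaussian kernel density
#'
#' Gaussian kernel density estimate rescaled so its maximum equals 1,
#' then multiplied by `class_weight` — the construction used to overlay
#' per-class distributions scaled to the relative proportion of strains
#' in each class.
#'
#' @param values Numeric vector (length >= 1).
#' @param class_weight Proportion to scale the peak to (default 1).
#' @param bw Kernel bandwidth; the default `"nrd0"` (Silverman's rule)
#'   requires >= 2 distinct values — pass a number for degenerate
#'   inputs.
#' @param n Number of grid points (default 512).
#' @return Data frame with columns `x` and `y`; `max(y)` equals
#'   `class_weight`.
#' @export
density_profile <- function(values, class_weight = 1, bw = "nrd0",
                            n = 512) {
  if (length(values) == 0) stop("empty input")
  if (length(values) == 1 && !is.numeric(bw)) {
    bw <- 1  # Silverman's rule undefined for a single point
  }
  d <- stats::density(values, bw = bw, n = n)
  data.frame(x = d$x, y = d$y / max(d$y) * class_weight)
}

#' Per-chromosome gene-set enrichment counts
#'
#' Observed versus expected chromosome distribution of a gene list,
#' under the null that list membership is uniform across the genome:
#' expected count on a chromosome = list size x (genes on chromosome /
#' total genes). An exact binomial upper-tail p-value per chromosome is
#' included.
#'
#' @param gene_to_chromosome Named character vector mapping gene name
#'   to chromosome identifier.
#' @param gene_list Character vector of genes of interest; genes
#'   missing from the mapping are reported, not silently dropped.
#' @param table Chromosome length table (fixes the chromosome set).
#' @return Data frame per chromosome: `observed`, `expected`, `ratio`,
#'   `p_binomial`; attribute `"unmapped"` lists genes without a
#'   mapping.
#' @export
chromosome_gene_enrichment <- function(gene_to_chromosome, gene_list,
                                       table = yeast_chromosomes()) {
  table <- validate_chromosome_table(table)
  chrom <- normalize_chromosome(gene_to_chromosome)
  names(chrom) <- names(gene_to_chromosome)
  unmapped <- setdiff(gene_list, names(chrom))
  hits <- intersect(gene_list, names(chrom))
  genes_per_chr <- table(factor(chrom, levels = table$chromosome))
  obs <- table(factor(chrom[hits], levels = table$chromosome))
  total <- length(chrom)
  expected <- length(hits) * as.numeric(genes_per_chr) / total
  pb <- vapply(seq_len(16L), function(i) {
    stats::pbinom(as.numeric(obs[i]) - 1, length(hits),
                  as.numeric(genes_per_chr[i]) / total,
                  lower.tail = FALSE)
  }, 0)
  out <- data.frame(
    chromosome = table$chromosome,
    observed = as.integer(obs),
    expected = expected,
    ratio = ifelse(expected > 0, as.numeric(obs) / expected, NA_real_),
    p_binomial = pb,
    stringsAsFactors = FALSE
  )
  attr(out, "unmapped") <- unmapped
  out
}

#' Percentage of viable spores
#'
#' Viable spores as a percentage of the number expected from the
#' dissected tetrads (four spores each).
#'
#' @param n_viable Number of spores that formed colonies.
#' @param n_expected Number of spores expected (tetrads x 4).
#' @return Percentage (0-100).
#' @export
#' @examples
#' viability_percent(52, 116) # ~45
viability_percent <- function(n_viable, n_expected) {
  if (n_expected <= 0 || n_viable < 0 || n_viable > n_expected) {
    stop("need 0 <= n_viable <= n_expected with n_expected > 0")
  }
  100 * n_viable / n_expected
}
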