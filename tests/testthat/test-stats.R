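test_that("Fisher exact test matches the enumeration oracle on 2x2 tables", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1)
  # zero margin: no evidence either way
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 7), 2)), 1)
  set.seed(19)
  for (i in 1:40) {
    tab <- matrix(stats::rpois(4, sample(1:10, 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("the MAD2:MAD1 stability table is significant at p = 0.01", {
  # 18 unstable strains at ratio 0.5, none stable; 26 unstable and 11
  # stable at other ratios
  tab <- matrix(c(18, 0, 26, 11), nrow = 2)
  p <- fisher_exact(tab)
  expect_equal(round(p, 2), 0.01)
})

test_that("r x c Fisher tables are accepted", {
  tab <- matrix(c(4, 1, 0, 2, 3, 1, 0, 2, 5), 3)
  p <- fisher_exact(tab)
  expect_true(p >= 0 && p <= 1)
})

test_that("hypergeometric enrichment matches the direct product formula", {
  # P(X = 0) drawing 11 from 55 with 18 marked: prod (37-i)/(55-i)
  p0 <- prod((37 - 0:10) / (55 - 0:10))
  expect_equal(1 - hypergeometric_enrichment(1, 11, 18, 55), p0,
               tolerance = 1e-12)
  expect_equal(round(p0, 4), 0.0071)
  # P(X >= 0) is always 1; selection = population forces all hits
  expect_equal(hypergeometric_enrichment(0, 11, 18, 55), 1)
  expect_equal(hypergeometric_enrichment(18, 55, 18, 55), 1)
  expect_error(hypergeometric_enrichment(12, 11, 18, 55), "inconsistent")
  # monotone non-increasing in the number of hits
  ps <- vapply(0:11, hypergeometric_enrichment, 0,
               selection_size = 11, hits_total = 18,
               population_size = 55)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("pairwise imbalance scan flags a planted pair", {
  set.seed(33)
  n <- 30
  kar <- matrix(1L + stats::rbinom(n * 16, 1, 0.5), n, 16)
  classes <- rep(c("S", "MU", "HU"), each = 10)
  # plant: all HU strains imbalanced for (VII, X), everyone else balanced
  kar[, 10] <- kar[, 7]
  hu <- classes == "HU"
  kar[hu, 7] <- 1L
  kar[hu, 10] <- 2L
  p <- pairwise_imbalance_scan(kar, classes, grouping = "hu-vs-rest")
  expect_equal(dim(p), c(16L, 16L))
  expect_true(all(is.na(diag(p))))
  expect_equal(p, t(p))
  off <- p
  diag(off) <- NA
  best_pair <- sort(which(off == min(off, na.rm = TRUE),
                          arr.ind = TRUE)[1, ])
  expect_equal(unname(best_pair), c(7L, 10L))
  # a pair balanced in every strain carries no signal
  kar2 <- kar
  kar2[, 2] <- kar2[, 1]
  p2 <- pairwise_imbalance_scan(kar2, classes)
  expect_equal(p2[1, 2], 1)
})

test_that("Welch t-test matches a permutation oracle in its decisions", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_lt(welch_t(stats::rnorm(30, 0), stats::rnorm(30, 5))$p.value,
            1e-6)
  set.seed(27)
  agree <- 0
  n_draws <- 40
  for (i in seq_len(n_draws)) {
    shift <- sample(c(0, 2.5), 1)
    a <- stats::rnorm(6)
    b <- stats::rnorm(6, shift)
    p_w <- welch_t(a, b)$p.value
    p_perm <- oracle_permutation_p(a, b)
    if ((p_w < 0.05) == (p_perm < 0.05)) agree <- agree + 1
  }
  expect_gte(agree / n_draws, 0.95)
})

test_that("growth rate is the log2 regression slope", {
  expect_equal(growth_rate(c(1e6, 2e6, 4e6), c(0, 1, 2)), 1)
  expect_equal(growth_rate(c(5e5, 5e5, 5e5), c(0, 5, 10)), 0)
  expect_error(growth_rate(c(0, 10), c(0, 1)), "positive")
  set.seed(13)
  true_rate <- 0.5
  reps <- vapply(1:50, function(i) {
    t <- c(0, 10, 20)
    counts <- 1e4 * 2^(true_rate * t) * exp(stats::rnorm(3, 0, 0.1))
    growth_rate(counts, t)
  }, 0)
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - true_rate), 2 * se + 0.01)
})

test_that("density profiles peak at the class weight", {
  d <- density_profile(c(1, 1.2, 1.4, 2), class_weight = 0.3)
  expect_equal(max(d$y), 0.3)
  d1 <- density_profile(1.5, class_weight = 0.25)
  expect_equal(max(d1$y), 0.25)
  expect_equal(d1$x[which.max(d1$y)], 1.5, tolerance = 0.02)
  # symmetric bimodal input gives a symmetric curve
  x <- c(stats::rnorm(200, -2, 0.3), stats::rnorm(200, 2, 0.3))
  x <- c(x, -x) # enforce exact symmetry
  ds <- density_profile(x)
  mid <- mean(ds$x)
  expect_lt(abs(mid), 0.05)
  expect_error(density_profile(numeric(0)), "empty")
})

test_that("gene-set chromosome enrichment finds planted signal", {
  set.seed(3)
  genes <- paste0("g", 1:800)
  chrom <- sample(chromosome_ids(), 800, replace = TRUE)
  names(chrom) <- genes
  # full list: observed equals expected exactly
  full <- chromosome_gene_enrichment(chrom, genes)
  expect_equal(full$observed, round(full$expected))
  expect_equal(sum(full$observed), 800L)
  # empty list: all zero
  empty <- chromosome_gene_enrichment(chrom, character(0))
  expect_true(all(empty$observed == 0))
  # plant enrichment on ChrV
  on_v <- names(chrom)[chrom == "V"]
  listed <- c(on_v[1:20], sample(setdiff(genes, on_v), 10))
  res <- chromosome_gene_enrichment(chrom, listed)
  expect_equal(res$chromosome[which.max(res$ratio)], "V")
  # unmapped genes reported
  res2 <- chromosome_gene_enrichment(chrom, c("g1", "nope"))
  expect_equal(attr(res2, "unmapped"), "nope")
})

test_that("spore viability percentage", {
  expect_equal(round(viability_percent(52, 116)), 45)
  expect_error(viability_percent(10, 5))
})
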