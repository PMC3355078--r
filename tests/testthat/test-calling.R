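test_that("FACS apparent ploidy is the G1 peak ratio to the haploid control", {
  expect_equal(apparent_ploidy_from_facs(100, 100), 1)
  expect_equal(apparent_ploidy_from_facs(200, 100), 2)
  expect_equal(apparent_ploidy_from_facs(210, 100), 2.1)
  expect_error(apparent_ploidy_from_facs(-1, 100), "positive")
  expect_error(apparent_ploidy_from_facs(100, 0), "positive")
})

test_that("relative quantification follows efficiency^(deltaCt)", {
  expect_equal(relative_ratio_from_ct(20, 20), 1)
  expect_equal(relative_ratio_from_ct(21, 20), 0.5)
  expect_equal(relative_ratio_from_ct(19, 20), 2)
  # sub-perfect efficiency
  expect_equal(relative_ratio_from_ct(19, 20, efficiency = 1.9), 1.9)
  expect_error(relative_ratio_from_ct(19, 20, efficiency = 1), "efficiency")
  # double normalization composes multiplicatively
  expect_equal(ddct_ratio(19, 20, 20, 20), 2)
  expect_equal(ddct_ratio(19, 20, 19, 20), 1)
})

test_that("delta-delta-Ct round trip recovers a 2:1 copy ratio exactly", {
  k <- rep(1, 16)
  k[c(4, 9)] <- 2
  set.seed(3)
  ct <- generate_ct_table(k, noise_sd = 0)
  stoich <- stoichiometry_from_ct(ct, calibrator = "calibrator")
  ratios <- stats::setNames(stoich$ratio, stoich$probe_id)[chromosome_ids()]
  expect_equal(unname(ratios), as.numeric(k))
  expect_equal(unname(ratios["IV"] / ratios["I"]), 2)
  # with an endogenous control probe everything rescales to that probe
  stoich2 <- stoichiometry_from_ct(ct, calibrator = "calibrator",
                                   reference_probe = "IV")
  r2 <- stats::setNames(stoich2$ratio, stoich2$probe_id)[chromosome_ids()]
  expect_equal(unname(r2), as.numeric(k) / 2)
})

test_that("integer calling recovers noise-free karyotypes at any global scale", {
  set.seed(21)
  for (i in 1:25) {
    k <- 1L + stats::rbinom(16, 1, 0.5)
    scale <- stats::runif(1, 0.2, 5)
    cl <- call_karyotype(k / scale, apparent_ploidy(k))
    expect_equal(cl$verdict, "ok")
    expect_equal(unname(cl$karyotype), as.integer(k))
    expect_false(any(cl$flags))
  }
})

test_that("a half-integer population ratio is flagged heterogeneous", {
  k <- rep(1, 16)
  r <- as.numeric(k)
  r[5] <- 1.5 # chromosome V at mixed copy number in the population
  cl <- call_karyotype(r, apparent_ploidy(k))
  expect_equal(cl$verdict, "ok")
  expect_true(cl$flags["V"])
  expect_false(any(cl$flags[-5]))
})

test_that("irreconcilable ploidy yields a too-heterogeneous verdict", {
  # ratios say haploid, FACS says 2.0 with a tolerance that cannot bridge
  cl <- call_karyotype(rep(1, 16), 1.55, ploidy_tol = 0.05)
  expect_equal(cl$verdict, "too_heterogeneous")
  expect_null(cl$karyotype)
})

test_that("ploidy stability compares strain CV to the haploid control", {
  set.seed(9)
  control <- generate_facs_peaks(1, cv = 0.02, n = 12)
  expect_equal(classify_ploidy_stability(rep(100, 12), control)$verdict,
               "stable")
  # peaks at triple the control CV
  noisy <- generate_facs_peaks(1.4, cv = 0.06, n = 12)
  expect_equal(classify_ploidy_stability(noisy, control)$verdict,
               "unstable")
  # one colony at twice the ploidy of the rest
  mixed <- c(rep(100, 11), 200)
  expect_equal(classify_ploidy_stability(mixed, control)$verdict,
               "unstable")
  # verdict invariant to a common rescaling of every peak
  expect_equal(classify_ploidy_stability(noisy * 7.3, control * 7.3)$verdict,
               classify_ploidy_stability(noisy, control)$verdict)
  expect_error(classify_ploidy_stability(rep(100, 11), control), "12")
  expect_equal(classify_ploidy_stability(rep(100, 12), control,
                                         force_unstable = TRUE)$verdict,
               "unstable")
})

test_that("MAD2:MAD1 ratios map to the nearest admissible class", {
  expect_equal(mad_ratio_class(0.52)$class, 0.5)
  expect_true(mad_ratio_class(0.52)$is_half)
  expect_equal(mad_ratio_class(1.0)$class, 1)
  expect_false(mad_ratio_class(1.0)$is_half)
  expect_equal(mad_ratio_class(1.9)$class, 2)
  expect_error(mad_ratio_class(-1), "positive")
  # strains built with ChrX:ChrVII = 1:2 all land in class 0.5
  set.seed(14)
  for (i in 1:10) {
    measured <- 0.5 * exp(stats::rnorm(1, 0, 0.05))
    expect_true(mad_ratio_class(measured)$is_half)
  }
})
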