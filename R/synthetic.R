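#' Configuration for a synthetic strain collection
#'
#' Bundles the generator settings with defaults mirroring the study
#' design they emulate: spores from triploid meiosis grown for ~20
#' divisions, 11 randomly picked colonies per strain, qPCR in technical
#' triplicates, and a haploid control processed in parallel.
#'
#' @param n_strains Number of strains to generate.
#' @param rates Set of true per-chromosome mis-segregation rates from
#'   which each strain's rate is drawn uniformly (default
#'   `c(0, 1e-4, 5e-4, 1e-3)`).
#' @param generations Divisions before the population is sampled
#'   (default 20).
#' @param n_colonies Colonies sampled per strain (default 11).
#' @param population_cap Downsampling cap for the growing population
#'   (default 100,000).
#' @param ct_noise_sd Gaussian noise SD on Ct values, in cycles
#'   (default 0.15).
#' @param facs_cv Coefficient of variation of simulated G1 peak
#'   positions (default 0.02).
#' @param viability_filter If `TRUE`, spores with apparent ploidy in
#'   \[1.4, 1.6\] are discarded with probability
#'   `viability_depletion`, emulating reduced viability near ploidy
#'   1.5.
#' @param viability_depletion Depletion probability for the filter
#'   (default 0.8).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_strains = 50L,
                             rates = c(0, 1e-4, 5e-4, 1e-3),
                             generations = 20L,
                             n_colonies = 11L,
                             population_cap = 1e5,
                             ct_noise_sd = 0.15,
                             facs_cv = 0.02,
                             viability_filter = FALSE,
                             viability_depletion = 0.8) {
  stopifnot(n_strains >= 1, all(rates >= 0), all(rates <= 1),
            generations >= 1, n_colonies >= 1, population_cap >= 1,
            ct_noise_sd >= 0, facs_cv >= 0,
            viability_depletion >= 0, viability_depletion <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic strain collection with known ground truth
#'
#' For each strain: draws a seed karyotype from triploid meiosis
#' (optionally through a viability filter depleting ploidies near
#' 1.5), evolves a colony from it under the strain's true
#' mis-segregation rate ([simulate_colony] semantics, nullisomic
#' daughters dying, population capped), samples `n_colonies` cells
#' uniformly from the final live population as colony karyotypes, and
#' records the ground truth: the strain's true rate and the number of
#' distinct founding deviation events among the sampled colonies
#' (lineages are tracked, so every sampled deviant is attributed to
#' the event that first took its lineage off the seed karyotype).
#' Extinct populations are redrawn and logged.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_collection` with `strains` (data
#'   frame: `strain_id`, `true_rate`, `n_true_root_events`,
#'   `true_class`, `seed_ploidy`, `redrawn`), `karyotype_matrices`
#'   (per strain: (1 + n_colonies) x 16 matrix, population/seed row
#'   first), and `seed_karyotypes`.
#' @export
#' @examples
#' set.seed(1)
#' coll <- generate_strain_collection(
#'   synthetic_config(n_strains = 2, population_cap = 500,
#'                    generations = 10))
#' coll$strains
generate_strain_collection <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_strains
  strains <- vector("list", n)
  mats <- vector("list", n)
  seeds <- vector("list", n)
  for (i in seq_len(n)) {
    rate <- sample(config$rates, 1L)
    redrawn <- 0L
    repeat {
      seed <- random_spore()
      if (config$viability_filter) {
        ap <- apparent_ploidy(seed)
        if (ap >= 1.4 && ap <= 1.6 &&
            stats::runif(1) < config$viability_depletion) next
      }
      res <- simulate_colony(seed, rate, config$generations,
                             cap = config$population_cap, track = TRUE)
      if (!res$extinct) break
      redrawn <- redrawn + 1L
    }
    pick <- sample.int(nrow(res$population), config$n_colonies,
                       replace = nrow(res$population) < config$n_colonies)
    colonies <- res$population[pick, , drop = FALSE]
    ids <- res$ids[pick]
    # a sampled cell may have reverted to the seed karyotype; only
    # karyotypically deviant colonies witness a root event
    deviant <- rowSums(colonies != matrix(seed, length(pick), 16L,
                                          byrow = TRUE)) > 0L
    n_events <- length(unique(ids[deviant & ids > 0L]))
    mat <- rbind(seed, colonies)
    rownames(mat) <- c("population", paste0("colony", seq_len(config$n_colonies)))
    colnames(mat) <- chromosome_ids()
    strains[[i]] <- data.frame(
      strain_id = sprintf("s%03d", i),
      true_rate = rate,
      n_true_root_events = n_events,
      true_class = cin_class(n_events),
      seed_ploidy = apparent_ploidy(seed),
      redrawn = redrawn,
      stringsAsFactors = FALSE
    )
    mats[[i]] <- mat
    seeds[[i]] <- seed
  }
  out <- list(strains = do.call(rbind, strains),
              karyotype_matrices = mats,
              seed_karyotypes = seeds,
              config = config)
  names(out$karyotype_matrices) <- out$strains$strain_id
  names(out$seed_karyotypes) <- out$strains$strain_id
  class(out) <- "synthetic_collection"
  out
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat(sprintf("Synthetic collection: %d strains, generations %d\n",
              nrow(x$strains), x$config$generations))
  print(table(rate = x$strains$true_rate, class = x$strains$true_class))
  invisible(x)
}

#' Synthetic qPCR Ct table for a known karyotype
#'
#' Ct values constructed so that noise-free relative quantification
#' recovers the chromosome copy ratios exactly: for a probe on
#' chromosome i, `Ct = base_ct - log_E(c_i)` plus Gaussian noise per
#' technical replicate, and the calibrator sample carries one copy of
#' every chromosome (`Ct = base_ct`). With efficiency 2, a 2:1 copy
#' ratio therefore sits exactly one cycle earlier before noise.
#'
#' @param karyotype True copy-number vector.
#' @param noise_sd Gaussian noise SD on the sample's technical
#'   replicates, in cycles (default 0.15).
#' @param efficiency Amplification efficiency (default 2).
#' @param n_replicates Technical replicates per probe (default 3).
#' @param base_ct Calibrator Ct level (default 20).
#' @param calibrator_noise_sd Noise SD on the calibrator's replicates
#'   (default 0: the calibrator is the scaling anchor, so measurement
#'   noise is modelled on the sample side).
#' @param sample_id,calibrator_id Sample labels.
#' @return Data frame `sample_id`, `probe_id`, `replicate`, `ct`
#'   containing both the sample and the calibrator.
#' @export
generate_ct_table <- function(karyotype, noise_sd = 0.15,
                              efficiency = 2, n_replicates = 3L,
                              base_ct = 20,
                              calibrator_noise_sd = 0,
                              sample_id = "sample",
                              calibrator_id = "calibrator") {
  k <- as_karyotype(karyotype)
  if (noise_sd < 0 || calibrator_noise_sd < 0) {
    stop("noise SDs must be >= 0")
  }
  probes <- chromosome_ids()
  true_ct <- base_ct - log(k, base = efficiency)
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      probe_id = probes, stringsAsFactors = FALSE)
  samp <- data.frame(sample_id = sample_id,
                     probe_id = rows$probe_id,
                     replicate = rows$replicate,
                     ct = true_ct[rows$probe_id] +
                       stats::rnorm(nrow(rows), 0, noise_sd))
  cal <- data.frame(sample_id = calibrator_id,
                    probe_id = rows$probe_id,
                    replicate = rows$replicate,
                    ct = base_ct +
                      stats::rnorm(nrow(rows), 0, calibrator_noise_sd))
  rbind(samp, cal)
}

#' Synthetic FACS G1 peak positions
#'
#' Peak positions with mean proportional to apparent ploidy and the
#' requested coefficient of variation (Gaussian multiplicative noise,
#' truncated to stay positive).
#'
#' @param apparent_ploidy True apparent ploidy of the sample.
#' @param cv Coefficient of variation of the peaks (default 0.02).
#' @param n Number of peaks (default 12: spore + 11 colonies).
#' @param scale Fluorescence units per ploidy unit (default 100).
#' @return Numeric vector of `n` positive peak positions.
#' @export
generate_facs_peaks <- function(apparent_ploidy, cv = 0.02, n = 12L,
                                scale = 100) {
  if (cv < 0) stop("cv must be >= 0")
  mu <- apparent_ploidy * scale
  pmax(stats::rnorm(n, mu, cv * mu), mu * 1e-3)
}
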