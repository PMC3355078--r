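#' Simulate one cell division with chromosome mis-segregation
#'
#' Each of the 16 chromosomes mis-segregates independently with
#' probability `rate`. In the default `"single"` mode one homolog's
#' sister-chromatid pair goes to the wrong pole, so a uniformly chosen
#' daughter receives `c + 1` copies and the other `c - 1`; in `"all"`
#' mode every duplicated copy goes to one daughter (`2c` / `0`). Either
#' way copies are conserved: the daughters' copy numbers sum to twice
#' the parent's. At most one mis-segregation event occurs per
#' chromosome per division. A daughter losing all copies of any
#' chromosome (nullisomy) is dead and is discarded by the population
#' simulator.
#'
#' @param karyotype Parent karyotype (all copy numbers >= 1).
#' @param rate Mis-segregation probability per chromosome per division.
#' @param mode `"single"` (default) or `"all"`, see Details.
#' @return List with integer karyotype vectors `daughter1` and
#'   `daughter2` (either may contain zeros, i.e. be dead).
#' @export
#' @examples
#' set.seed(1)
#' divide_cell(rep(2, 16), rate = 1) # every chromosome splits 3/1
divide_cell <- function(karyotype, rate, mode = c("single", "all")) {
  mode <- match.arg(mode)
  k <- as_karyotype(karyotype)
  if (!is.finite(rate) || rate < 0 || rate > 1) {
    stop("rate must be a probability in [0, 1]")
  }
  ev <- stats::rbinom(16L, 1L, rate)
  dir <- sample(c(-1L, 1L), 16L, replace = TRUE)
  step <- if (mode == "single") ev * dir else ev * dir * k
  d1 <- k + step
  d2 <- k - step
  list(daughter1 = as_karyotype(d1, require_live = FALSE),
       daughter2 = as_karyotype(d2, require_live = FALSE))
}

# One colony growing from a single seed cell. Sparse event placement:
# the number of mis-segregation events among the n*16 chromosome slots
# is Binomial(n*16, rate) and positions are uniform without
# replacement, which is distributionally identical to independent
# per-slot Bernoulli draws but much cheaper at realistic rates.
# Returns the final population matrix plus, when track = TRUE, the
# founding-event id of each cell's lineage (0 = lineage never deviated
# from the seed karyotype; a fresh id is assigned whenever a daughter
# of a seed-karyotype lineage first deviates).
simulate_colony <- function(seed_karyotype, rate, generations,
                            cap = 1e5, mode = c("single", "all"),
                            track = FALSE) {
  mode <- match.arg(mode)
  seed <- as_karyotype(seed_karyotype)
  pop <- matrix(seed, nrow = 1L, ncol = 16L, byrow = TRUE)
  ids <- 0L
  next_id <- 1L
  for (g in seq_len(generations)) {
    n <- nrow(pop)
    nev <- stats::rbinom(1L, n * 16L, rate)
    d1 <- pop
    d2 <- pop
    touched <- integer(0)
    if (nev > 0L) {
      pos <- sample.int(n * 16L, nev)
      row <- (pos - 1L) %% n + 1L
      col <- (pos - 1L) %/% n + 1L
      dir <- sample(c(-1L, 1L), nev, replace = TRUE)
      idx <- cbind(row, col)
      step <- if (mode == "single") dir else dir * pop[idx]
      d1[idx] <- d1[idx] + step
      d2[idx] <- d2[idx] - step
      touched <- unique(row)
    }
    kids <- rbind(d1, d2)
    kid_ids <- c(ids, ids)
    # deaths and lineage bookkeeping only possible among touched rows
    if (length(touched) > 0L) {
      check <- c(touched, touched + n)
      dead <- check[rowSums(kids[check, , drop = FALSE] < 1L) > 0L]
      if (track) {
        fresh <- check[kid_ids[check] == 0L &
                         rowSums(kids[check, , drop = FALSE] !=
                                   matrix(seed, length(check), 16L,
                                          byrow = TRUE)) > 0L]
        fresh <- setdiff(fresh, dead)
        if (length(fresh) > 0L) {
          kid_ids[fresh] <- seq.int(next_id, length.out = length(fresh))
          next_id <- next_id + length(fresh)
        }
      }
      if (length(dead) > 0L) {
        keep <- setdiff(seq_len(2L * n), dead)
        kids <- kids[keep, , drop = FALSE]
        kid_ids <- kid_ids[keep]
      }
    }
    if (nrow(kids) == 0L) {
      return(list(population = kids, ids = integer(0), extinct = TRUE,
                  seed = seed))
    }
    if (nrow(kids) > cap) {
      keep <- sample.int(nrow(kids), cap)
      kids <- kids[keep, , drop = FALSE]
      kid_ids <- kid_ids[keep]
    }
    pop <- kids
    ids <- kid_ids
  }
  colnames(pop) <- chromosome_ids()
  list(population = pop, ids = ids, extinct = FALSE, seed = seed)
}

#' Simulate karyotype divergence under chromosome mis-segregation
#'
#' Branching-population simulation of a colony growing from one seed
#' cell. Every generation each live cell divides (see [divide_cell()]);
#' daughters that lost all copies of any chromosome are discarded as
#' dead; whenever the colony exceeds `cap` cells it is downsampled
#' uniformly without replacement to `cap` to bound the computation.
#' After `generations` divisions the fraction of live cells whose
#' karyotype differs from the seed is recorded, per replicate.
#'
#' @param seed_karyotype Founding karyotype; default a random
#'   triploid-meiosis spore (each chromosome 1 or 2 with probability
#'   1/2, see [random_spore()]), drawn once and shared by all
#'   replicates.
#' @param rate Per-chromosome per-division mis-segregation probability.
#' @param generations Number of divisions to simulate.
#' @param cap Population size at which downsampling kicks in
#'   (default 100,000).
#' @param replicates Number of independent simulations (default 30).
#' @param mode Mis-segregation granularity, see [divide_cell()].
#' @return Object of class `missegregation_sim`: list with
#'   `deviant_fraction` (per non-extinct replicate), `extinct` (count),
#'   `summary` (median, quartiles), and the call parameters.
#' @export
#' @examples
#' set.seed(42)
#' sim <- simulate_missegregation(rate = 1e-3, generations = 10,
#'                                cap = 2000, replicates = 5)
#' sim$summary
simulate_missegregation <- function(rate, generations,
                                    seed_karyotype = random_spore(),
                                    cap = 1e5, replicates = 30,
                                    mode = c("single", "all")) {
  mode <- match.arg(mode)
  if (generations < 1) stop("generations must be >= 1")
  if (cap < 1) stop("cap must be >= 1")
  seed <- as_karyotype(seed_karyotype)
  frac <- rep(NA_real_, replicates)
  extinct <- 0L
  for (r in seq_len(replicates)) {
    res <- simulate_colony(seed, rate, generations, cap, mode)
    if (res$extinct) {
      extinct <- extinct + 1L
    } else {
      dev <- rowSums(res$population !=
                       matrix(seed, nrow(res$population), 16L,
                              byrow = TRUE)) > 0L
      frac[r] <- mean(dev)
    }
  }
  frac <- frac[!is.na(frac)]
  qs <- if (length(frac) > 0) {
    stats::quantile(frac, c(0.25, 0.5, 0.75), names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  structure(list(
    deviant_fraction = frac,
    extinct = extinct,
    summary = data.frame(q1 = qs[1], median = qs[2], q3 = qs[3],
                         n_replicates = length(frac)),
    rate = rate, generations = generations, cap = cap,
    seed_karyotype = seed, mode = mode
  ), class = "missegregation_sim")
}

#' @export
print.missegregation_sim <- function(x, ...) {
  cat("Chromosome mis-segregation simulation\n")
  cat(sprintf("  rate %.2g /chromosome/division, %d generations, cap %d\n",
              x$rate, x$generations, as.integer(x$cap)))
  cat(sprintf("  %d replicates (%d extinct)\n",
              length(x$deviant_fraction) + x$extinct, x$extinct))
  cat(sprintf("  deviant fraction: median %.3f [IQR %.3f-%.3f]\n",
              x$summary$median, x$summary$q1, x$summary$q3))
  invisible(x)
}
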