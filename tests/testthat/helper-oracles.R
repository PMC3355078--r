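# Independent oracles used by the test suite. Each is a deliberately
# naive implementation kept separate from the package's algorithms.

# --- exhaustive Steiner-tree search over the full state product space ---
# Terminals: rows of `obs` (distinct karyotype vectors restricted to
# varying loci). Candidate Steiner vertices: every combination of the
# observed per-locus states. The minimum is found by brute force over
# all Steiner subsets (size <= #terminals - 2), taking the MST of each
# augmented vertex set under Hamming distance.
oracle_steiner_cost <- function(obs) {
  obs <- unique(obs)
  m <- nrow(obs)
  if (m == 1) return(0L)
  varying <- which(apply(obs, 2, function(v) length(unique(v))) > 1)
  ov <- obs[, varying, drop = FALSE]
  states <- lapply(seq_along(varying), function(j) sort(unique(ov[, j])))
  cand <- as.matrix(expand.grid(states))
  hamming <- function(a, b) sum(a != b)
  dist_all <- function(vs) {
    n <- nrow(vs)
    d <- matrix(0L, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      d[i, j] <- hamming(vs[i, ], vs[j, ])
    }
    d
  }
  mst_cost <- function(d) {
    n <- nrow(d)
    if (n == 1) return(0)
    in_tree <- c(TRUE, rep(FALSE, n - 1))
    best <- d[1, ]
    total <- 0
    for (s in seq_len(n - 1)) {
      v <- which(!in_tree)[which.min(best[!in_tree])]
      total <- total + best[v]
      in_tree[v] <- TRUE
      best <- pmin(best, d[v, ])
    }
    total
  }
  okeys <- apply(ov, 1, paste, collapse = ",")
  ckeys <- apply(cand, 1, paste, collapse = ",")
  extra_pool <- which(!(ckeys %in% okeys))
  best <- mst_cost(dist_all(ov))
  max_extra <- m - 2
  if (max_extra >= 1 && length(extra_pool) > 0) {
    for (k in seq_len(max_extra)) {
      if (length(extra_pool) < k) break
      combs <- utils::combn(extra_pool, k)
      for (ci in seq_len(ncol(combs))) {
        vs <- rbind(ov, cand[combs[, ci], , drop = FALSE])
        best <- min(best, mst_cost(dist_all(vs)))
      }
    }
  }
  best
}

# --- two-sided Fisher p for a 2x2 table by direct enumeration -----------
# All tables with the observed margins; sum the probabilities of those
# no more likely than the observed table (minimum-likelihood rule).
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- exact deviant fraction after 2 generations -------------------------
# Full enumeration of the 2-generation division tree (3 divisions, 4
# potential leaves) for a population seeded by one cell. Per
# chromosome, all 27 combinations of (no event / event favoring
# daughter 1 / daughter 2) across the three divisions are enumerated;
# the resulting distribution over per-leaf outcomes (dead / deviant /
# matching) is then convolved across the 16 independent chromosomes,
# and E[deviant / live | live > 0] is accumulated.
oracle_deviant_fraction_g2 <- function(seed, p) {
  stopifnot(length(seed) == 16)
  outcomes <- expand.grid(e1 = 1:3, e2 = 1:3, e3 = 1:3)
  probs_ev <- c(1 - p, p / 2, p / 2)
  # per chromosome value v: status of 4 leaves
  leaf_status <- function(v, e1, e2, e3) {
    step <- function(c, e) {
      if (e == 1) c(c, c) else if (e == 2) c(c + 1, c - 1) else c(c - 1, c + 1)
    }
    g1 <- step(v, e1)            # two gen-1 cells
    l12 <- step(g1[1], e2)       # leaves 1,2
    l34 <- step(g1[2], e3)       # leaves 3,4
    leaves <- c(l12, l34)
    anc <- rep(g1, each = 2)
    status <- ifelse(anc <= 0 | leaves <= 0, 0L,       # dead
                     ifelse(leaves != v, 2L, 1L))      # deviant / match
    status
  }
  # distribution over the 4-leaf status pattern for one chromosome
  chrom_patterns <- function(v) {
    pat <- list()
    for (i in seq_len(nrow(outcomes))) {
      st <- leaf_status(v, outcomes$e1[i], outcomes$e2[i], outcomes$e3[i])
      key <- paste(st, collapse = "")
      pr <- probs_ev[outcomes$e1[i]] * probs_ev[outcomes$e2[i]] *
        probs_ev[outcomes$e3[i]]
      pat[[key]] <- (if (is.null(pat[[key]])) 0 else pat[[key]]) + pr
    }
    pat
  }
  # convolve across chromosomes: combined leaf status in {0 dead,
  # 1 match-so-far, 2 deviant}; dead dominates, deviant beats match
  combine <- function(s1, s2) {
    ifelse(s1 == 0 | s2 == 0, 0L, pmax(s1, s2))
  }
  keys_to_mat <- function(keys) {
    do.call(rbind, lapply(strsplit(keys, ""), as.integer))
  }
  dist <- stats::setNames(1, paste(rep(1L, 4), collapse = ""))
  for (j in 1:16) {
    pat <- chrom_patterns(seed[j])
    newdist <- list()
    dm <- keys_to_mat(names(dist))
    pm <- keys_to_mat(names(pat))
    for (a in seq_along(dist)) {
      for (b in seq_along(pat)) {
        comb <- combine(dm[a, ], pm[b, ])
        key <- paste(comb, collapse = "")
        add <- dist[[a]] * pat[[b]]
        newdist[[key]] <- (if (is.null(newdist[[key]])) 0 else newdist[[key]]) + add
      }
    }
    dist <- unlist(newdist)
  }
  dm <- keys_to_mat(names(dist))
  live <- rowSums(dm > 0)
  deviant <- rowSums(dm == 2)
  ok <- live > 0
  # expectation of deviant/live conditional on survival
  sum(dist[ok] * deviant[ok] / live[ok]) / sum(dist[ok])
}

# --- permutation test for a difference in means --------------------------
oracle_permutation_p <- function(a, b, n_perm = 2000) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}
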