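#' Modal karyotype across colonies
#'
#' Per chromosome, the most common copy number across a set of colony
#' karyotypes; used to infer a population's founding karyotype
#' indirectly when the population sample itself is too noisy. Ties are
#' resolved toward the population-sample evidence when supplied,
#' otherwise left unresolved (`NA` with a flag).
#'
#' @param colonies Integer matrix of colony karyotypes (rows =
#'   colonies, 16 columns), or a list of karyotype vectors.
#' @param population Optional karyotype used to break per-chromosome
#'   ties.
#' @return List with `karyotype` (may contain `NA` at unresolved
#'   ties), `ties` (chromosomes that tied) and `resolved` (logical).
#' @export
infer_modal_karyotype <- function(colonies, population = NULL) {
  if (is.list(colonies)) colonies <- do.call(rbind, colonies)
  if (ncol(colonies) != 16L) stop("colony karyotypes must have 16 columns")
  if (nrow(colonies) < 1L) stop("need at least one colony karyotype")
  modal <- integer(16L)
  tied <- logical(16L)
  for (j in 1:16) {
    counts <- table(colonies[, j])
    top <- counts[counts == max(counts)]
    if (length(top) == 1L) {
      modal[j] <- as.integer(names(top))
    } else {
      tied[j] <- TRUE
      cands <- as.integer(names(top))
      if (!is.null(population) && population[j] %in% cands) {
        modal[j] <- population[j]
      } else {
        modal[j] <- NA_integer_
      }
    }
  }
  names(modal) <- chromosome_ids()
  list(karyotype = modal, ties = chromosome_ids()[tied],
       resolved = !anyNA(modal))
}

# ---- internal machinery -------------------------------------------------

hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (j in seq_len(ncol(m))) {
    d <- d + outer(m[, j], m[, j], "!=")
  }
  storage.mode(d) <- "integer"
  d
}

row_keys <- function(m) apply(m, 1, paste, collapse = ",")

# majority-vector (median) closure of a set of state vectors; ties at a
# locus resolved toward the first member of the triple
median_closure <- function(m, max_vectors = 64L, max_rounds = 4L) {
  keys <- row_keys(m)
  for (round in seq_len(max_rounds)) {
    n <- nrow(m)
    if (n < 3L || n >= max_vectors) break
    added <- FALSE
    combs <- utils::combn(n, 3L)
    for (ci in seq_len(ncol(combs))) {
      tri <- m[combs[, ci], , drop = FALSE]
      med <- apply(tri, 2, function(v) {
        tv <- table(v)
        if (max(tv) >= 2L) as.integer(names(tv)[which.max(tv)]) else v[1L]
      })
      key <- paste(med, collapse = ",")
      if (!(key %in% keys)) {
        m <- rbind(m, med)
        keys <- c(keys, key)
        added <- TRUE
        if (nrow(m) >= max_vectors) break
      }
    }
    if (!added) break
  }
  m
}

# Exact minimum Steiner tree (Dreyfus-Wagner) over candidate vertices
# `cand` with terminals `term` (indices into cand), metric = Hamming.
# Returns list(edges = 2-col matrix of cand indices, cost).
steiner_dw <- function(d, term) {
  m <- length(term)
  n <- nrow(d)
  if (m == 1L) return(list(edges = matrix(integer(0), 0, 2), cost = 0L))
  if (m == 2L) {
    return(list(edges = matrix(term, 1, 2), cost = d[term[1], term[2]]))
  }
  others <- term[-m]
  t_last <- term[m]
  nS <- 2L^(m - 1L) - 1L
  f <- matrix(Inf, nS, n)
  for (i in seq_len(m - 1L)) f[bitwShiftL(1L, i - 1L), ] <- d[others[i], ]
  popcount <- function(x) sum(bitwAnd(bitwShiftR(x, 0:30), 1L))
  masks <- seq_len(nS)
  ord <- masks[order(vapply(masks, popcount, 0))]
  g_of <- function(S) {
    g <- rep(Inf, n)
    lowbit <- bitwAnd(S, -S)
    S1 <- bitwAnd(S - 1L, S)  # submask iteration
    while (S1 > 0L) {
      if (bitwAnd(S1, lowbit) == lowbit) {
        S2 <- S - S1
        g <- pmin(g, f[S1, ] + f[S2, ])
      }
      S1 <- bitwAnd(S1 - 1L, S)
    }
    g
  }
  for (S in ord) {
    if (popcount(S) < 2L) next
    g <- g_of(S)
    f[S, ] <- apply(g + d, 2, min)  # (g + d)[u, v] = g[u] + d[u, v]
  }
  full <- nS
  cost <- f[full, t_last]

  edges <- matrix(integer(0), 0, 2)
  add_edge <- function(a, b) {
    if (a != b) edges <<- rbind(edges, c(a, b))
  }
  reconstruct <- function(S, v) {
    if (popcount(S) == 1L) {
      t <- others[which(bitwShiftL(1L, seq_len(m - 1L) - 1L) == S)]
      add_edge(t, v)
      return(invisible())
    }
    g <- g_of(S)
    u <- which.min(g + d[, v])
    add_edge(u, v)
    # find the split achieving g[u]
    lowbit <- bitwAnd(S, -S)
    S1 <- bitwAnd(S - 1L, S)
    while (S1 > 0L) {
      if (bitwAnd(S1, lowbit) == lowbit) {
        S2 <- S - S1
        if (f[S1, u] + f[S2, u] == g[u]) {
          reconstruct(S1, u)
          reconstruct(S2, u)
          return(invisible())
        }
      }
      S1 <- bitwAnd(S1 - 1L, S)
    }
    stop("internal error: no achieving split found")
  }
  reconstruct(full, t_last)
  list(edges = edges, cost = cost)
}

# MST over a set of vertices given a distance matrix; returns edges +
# cost (Prim's algorithm).
mst_edges <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(list(edges = matrix(integer(0), 0, 2), cost = 0))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1, ]
  parent <- rep(1L, n)
  edges <- matrix(integer(0), 0, 2)
  cost <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    in_tree[v] <- TRUE
    cost <- cost + best[v]
    edges <- rbind(edges, c(parent[v], v))
    upd <- !in_tree & d[v, ] < best
    best[upd] <- d[v, upd]
    parent[upd] <- v
  }
  list(edges = edges, cost = cost)
}

# remove Steiner leaves and contract degree-2 Steiner vertices
prune_steiner <- function(edges, keep) {
  repeat {
    if (nrow(edges) == 0L) break
    verts <- unique(as.vector(edges))
    deg <- tabulate(as.vector(edges), nbins = max(verts))
    leaf <- setdiff(verts[deg[verts] == 1L], keep)
    if (length(leaf) > 0L) {
      drop <- edges[, 1] %in% leaf | edges[, 2] %in% leaf
      edges <- edges[!drop, , drop = FALSE]
      next
    }
    mid <- setdiff(verts[deg[verts] == 2L], keep)
    if (length(mid) == 0L) break
    u <- mid[1L]
    inc <- which(edges[, 1] == u | edges[, 2] == u)
    nb <- setdiff(as.vector(edges[inc, ]), u)
    edges <- edges[-inc, , drop = FALSE]
    if (length(nb) == 2L && nb[1] != nb[2]) {
      edges <- rbind(edges, nb)
    }
  }
  edges
}

#' Reconstruct a parsimony karyotype network
#'
#' Collapses the input samples into distinct karyotypes (nodes, with
#' observation frequencies) and connects them by the network that
#' minimizes the total number of per-chromosome copy-number changes
#' across the whole map, in the spirit of haplotype-network
#' reconstruction with chromosomes as loci and copy numbers as alleles.
#' Unobserved intermediate ("median") karyotypes are inserted when they
#' reduce the total change count; they appear as frequency-0 nodes.
#'
#' The optimum is found by exact minimum-Steiner-tree search
#' (Dreyfus-Wagner dynamic programming) over the space of candidate
#' karyotypes formed by all combinations of the observed per-chromosome
#' states, whenever that space and the number of distinct karyotypes
#' are small enough (the case for 12-sample instances with modest
#' divergence); otherwise candidates are restricted to the
#' median-vector closure of the observed karyotypes, and for very many
#' distinct karyotypes a greedy median-joining refinement of the
#' minimum spanning tree is used (`exact = FALSE` in the result).
#'
#' With `enumerate_ties = TRUE` all co-optimal networks (over the
#' median-closure candidate pool) are enumerated, since distinct
#' co-optimal topologies can differ in how many events touch the
#' founding karyotype.
#'
#' @param karyotypes Integer matrix of samples x 16 chromosomes
#'   (typically 12 rows: 1 population sample + 11 colonies).
#' @param root_row Row index of the population (founding) sample
#'   (default 1).
#' @param enumerate_ties Enumerate all co-optimal networks instead of
#'   returning a single optimum.
#' @param max_candidates Cap on the exact candidate-space size before
#'   falling back to the median closure (default 512).
#' @return A `karyotype_network` (or, with `enumerate_ties = TRUE`, a
#'   `karyotype_network_set`, a list of them with a `$cost`
#'   attribute). A network has `karyotypes` (node x 16 matrix),
#'   `frequency`, `observed`, `root` (node index), `edges` (data frame
#'   `from`, `to`, `label`, `n_changes`, oriented away from the root),
#'   `total_cost` and `exact`.
#' @export
#' @examples
#' m <- matrix(rep(c(rep(1, 8), rep(2, 8)), 12), nrow = 12, byrow = TRUE)
#' m[12, 1] <- 2 # one colony gained ChrI
#' net <- build_network(m)
#' net$edges
build_network <- function(karyotypes, root_row = 1L,
                          enumerate_ties = FALSE,
                          max_candidates = 512L) {
  m <- as.matrix(karyotypes)
  if (ncol(m) != 16L) stop("karyotype matrix must have 16 columns")
  storage.mode(m) <- "integer"
  keys <- row_keys(m)
  uk <- unique(keys)
  obs <- m[match(uk, keys), , drop = FALSE]
  freq <- as.integer(table(factor(keys, levels = uk)))
  root_key <- keys[root_row]
  root_node <- match(root_key, uk)
  n_obs <- nrow(obs)

  if (n_obs == 1L) {
    net <- new_karyotype_network(obs, freq, root_node,
                                 matrix(integer(0), 0, 2), 0L, TRUE)
    if (enumerate_ties) {
      return(structure(list(net), cost = 0L,
                       class = "karyotype_network_set"))
    }
    return(net)
  }

  varying <- which(apply(obs, 2, function(v) length(unique(v))) > 1L)
  states <- lapply(varying, function(j) sort(unique(obs[, j])))
  prod_size <- prod(vapply(states, length, 0))
  ov <- obs[, varying, drop = FALSE]

  use_exact_space <- prod_size <= max_candidates && n_obs <= 10L &&
    prod_size^2 * 2^(n_obs - 1L) <= 2e8
  if (use_exact_space) {
    cand <- as.matrix(expand.grid(states))
    storage.mode(cand) <- "integer"
  } else {
    cand <- median_closure(ov)
  }
  # ensure observed vectors are present and note their indices
  ckeys <- row_keys(cand)
  okeys <- row_keys(ov)
  missing <- !(okeys %in% ckeys)
  if (any(missing)) {
    cand <- rbind(cand, ov[missing, , drop = FALSE])
    ckeys <- c(ckeys, okeys[missing])
  }
  term <- match(okeys, ckeys)
  d <- hamming_matrix(cand)

  exact <- use_exact_space
  if (n_obs <= 10L) {
    sol <- steiner_dw(d, term)
  } else {
    sol <- greedy_median_joining(d, term, cand)
    exact <- FALSE
  }

  edges <- prune_steiner(sol$edges, keep = term)
  net <- assemble_network(cand, varying, obs, freq, root_node, term,
                          edges, sol$cost, exact)
  if (!enumerate_ties) return(net)

  # Steiner-point pool for tie enumeration: median closure of observed
  pool_vec <- median_closure(ov)
  pool <- setdiff(match(row_keys(pool_vec), ckeys), c(term, NA))
  nets <- enumerate_cooptimal(d, term, pool, cand, varying, obs, freq,
                              root_node, sol$cost, exact)
  if (length(nets) == 0L) nets <- list(net)
  structure(nets, cost = sol$cost, class = "karyotype_network_set")
}

# greedy fallback for many distinct karyotypes: MST over observed,
# then repeatedly add the candidate vertex that most reduces MST cost
greedy_median_joining <- function(d, term, cand) {
  current <- term
  best <- mst_edges(d[current, current, drop = FALSE])
  repeat {
    pool <- setdiff(seq_len(nrow(cand)), current)
    improved <- FALSE
    best_gain <- 0
    best_v <- NA_integer_
    for (v in pool) {
      vs <- c(current, v)
      trial <- mst_edges(d[vs, vs, drop = FALSE])
      gain <- best$cost - trial$cost
      if (gain > best_gain) {
        best_gain <- gain
        best_v <- v
        improved <- TRUE
      }
    }
    if (!improved) break
    current <- c(current, best_v)
    best <- mst_edges(d[current, current, drop = FALSE])
  }
  list(edges = matrix(current[best$edges], ncol = 2), cost = best$cost)
}

new_karyotype_network <- function(karyotypes, frequency, root, edges,
                                  cost, exact) {
  rownames(karyotypes) <- NULL
  colnames(karyotypes) <- chromosome_ids()
  structure(list(karyotypes = karyotypes, frequency = frequency,
                 observed = frequency > 0L, root = root,
                 edges = orient_edges(karyotypes, root, edges),
                 total_cost = as.integer(round(cost)), exact = exact),
            class = "karyotype_network")
}

# orient tree edges away from the root and label chromosome changes
orient_edges <- function(karyotypes, root, edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(from = integer(0), to = integer(0),
                      label = character(0), n_changes = integer(0)))
  }
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  parent <- rep(NA_integer_, nrow(karyotypes))
  order_out <- integer(0)
  queue <- root
  seen <- root
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (w in adj[[as.character(v)]]) {
      if (!(w %in% seen)) {
        parent[w] <- v
        seen <- c(seen, w)
        queue <- c(queue, w)
      }
    }
  }
  children <- which(!is.na(parent))
  lab <- character(length(children))
  nch <- integer(length(children))
  for (i in seq_along(children)) {
    ch <- children[i]
    pa <- parent[ch]
    diff <- which(karyotypes[ch, ] != karyotypes[pa, ])
    sign <- ifelse(karyotypes[ch, diff] > karyotypes[pa, diff], "+", "-")
    lab[i] <- paste0(sign, chromosome_ids()[diff], collapse = ",")
    nch[i] <- length(diff)
  }
  ord <- order(match(parent[children], order_out), children)
  data.frame(from = parent[children][ord], to = children[ord],
             label = lab[ord], n_changes = nch[ord],
             stringsAsFactors = FALSE)
}

assemble_network <- function(cand, varying, obs, freq, root_node, term,
                             edges, cost, exact) {
  used <- sort(unique(c(term, as.vector(edges))))
  # node karyotypes: full 16-chromosome vectors
  base <- obs[1L, ]
  kmat <- matrix(rep(base, length(used)), ncol = 16L, byrow = TRUE)
  kmat[, varying] <- cand[used, , drop = FALSE]
  node_freq <- integer(length(used))
  node_freq[match(term, used)] <- freq
  remap <- match(edges, used)
  redges <- matrix(remap, ncol = 2)
  root_idx <- match(term[root_node], used)
  new_karyotype_network(kmat, node_freq, root_idx, redges, cost, exact)
}

# enumerate all spanning trees of the complete graph on `vs` (indices
# into d) with total cost exactly `target`; returns list of edge
# matrices (in vs-index space)
opt_spanning_trees <- function(d, target, max_nodes = 2e5) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  ne <- length(w)
  found <- list()
  visits <- 0L
  find_root <- function(comp, x) {
    while (comp[x] != x) x <- comp[x]
    x
  }
  recurse <- function(i, comp, chosen, cost) {
    visits <<- visits + 1L
    if (visits > max_nodes) return(invisible())
    k <- nrow(chosen)
    if (k == n - 1L) {
      if (cost == target) found[[length(found) + 1L]] <<- chosen
      return(invisible())
    }
    if (i > ne) return(invisible())
    remaining_needed <- n - 1L - k
    if (ne - i + 1L < remaining_needed) return(invisible())
    # lower bound: cheapest remaining edges
    if (cost + sum(w[i:(i + remaining_needed - 1L)]) > target) {
      return(invisible())
    }
    a <- find_root(comp, pairs[i, 1])
    b <- find_root(comp, pairs[i, 2])
    if (a != b) {
      comp2 <- comp
      comp2[a] <- b
      recurse(i + 1L, comp2, rbind(chosen, pairs[i, ]), cost + w[i])
    }
    recurse(i + 1L, comp, chosen, cost)
  }
  recurse(1L, seq_len(n), matrix(integer(0), 0, 2), 0)
  found
}

enumerate_cooptimal <- function(d, term, pool, cand, varying, obs, freq,
                                root_node, cost, exact) {
  m <- length(term)
  if (length(pool) > 48L) pool <- pool[seq_len(48L)]
  max_extra <- max(0L, min(m - 2L, 3L))
  subsets <- list(integer(0))
  for (k in seq_len(max_extra)) {
    if (length(pool) >= k) {
      cmb <- utils::combn(pool, k)
      subsets <- c(subsets, lapply(seq_len(ncol(cmb)),
                                   function(i) cmb[, i]))
    }
  }
  seen <- character(0)
  nets <- list()
  for (S in subsets) {
    vs <- c(term, S)
    dsub <- d[vs, vs, drop = FALSE]
    if (mst_edges(dsub)$cost != cost) next
    trees <- opt_spanning_trees(dsub, cost)
    for (tr in trees) {
      ge <- matrix(vs[tr], ncol = 2)
      ge <- prune_steiner(ge, keep = term)
      used_key <- paste(sort(apply(cbind(pmin(ge[, 1], ge[, 2]),
                                         pmax(ge[, 1], ge[, 2])),
                                   1, paste, collapse = "-")),
                        collapse = ";")
      if (used_key %in% seen) next
      seen <- c(seen, used_key)
      nets[[length(nets) + 1L]] <-
        assemble_network(cand, varying, obs, freq, root_node, term,
                         ge, cost, exact)
    }
  }
  nets
}

#' @export
print.karyotype_network <- function(x, ...) {
  cat(sprintf(
    "Karyotype network: %d nodes (%d observed), %d edges, total cost %d%s\n",
    nrow(x$karyotypes), sum(x$observed), nrow(x$edges), x$total_cost,
    if (isFALSE(x$exact)) " (heuristic)" else ""))
  if (nrow(x$edges) > 0) print(x$edges)
  invisible(x)
}

#' @export
print.karyotype_network_set <- function(x, ...) {
  cat(sprintf("%d co-optimal karyotype network(s), total cost %d\n",
              length(x), attr(x, "cost")))
  invisible(x)
}

#' Count root-linked CIN events and classify instability
#'
#' Counts the network edges incident to the founding (population)
#' karyotype node. Each such edge is one chromosome-instability event
#' regardless of how many chromosomes changed along it (multiple
#' simultaneous changes are scored conservatively as a single event);
#' karyotype changes hanging off a deviant node are attributed to that
#' deviant, not to the founder. Classification: 0 events = stable
#' (`"S"`), 1 = mildly unstable (`"MU"`), 2 or more = highly unstable
#' (`"HU"`).
#'
#' @param network A `karyotype_network`, or a `karyotype_network_set`
#'   of co-optimal networks.
#' @return For a single network, a list with `n_root_events` and
#'   `cin_class`. For a set, a data frame with one row per co-optimal
#'   network plus attributes `consensus` (`TRUE` if all networks agree
#'   on the class) and `cin_class` (the agreed or first class).
#' @export
count_root_events <- function(network) {
  if (inherits(network, "karyotype_network_set")) {
    per <- lapply(network, count_root_events)
    df <- data.frame(
      network = seq_along(per),
      n_root_events = vapply(per, `[[`, 0L, "n_root_events"),
      cin_class = vapply(per, `[[`, "", "cin_class")
    )
    attr(df, "consensus") <- length(unique(df$cin_class)) == 1L
    attr(df, "cin_class") <- df$cin_class[1L]
    return(df)
  }
  if (!inherits(network, "karyotype_network")) {
    stop("expected a karyotype_network")
  }
  if (is.na(network$root)) stop("network has no root node")
  n <- sum(network$edges$from == network$root |
             network$edges$to == network$root)
  list(n_root_events = n, cin_class = cin_class(n))
}

#' CIN class from a root-linked event count
#'
#' @param n_events Non-negative integer count of events linked to the
#'   founding karyotype.
#' @return `"S"` (0 events), `"MU"` (1) or `"HU"` (>= 2).
#' @export
cin_class <- function(n_events) {
  if (any(n_events < 0)) stop("event counts must be non-negative")
  ifelse(n_events == 0L, "S", ifelse(n_events == 1L, "MU", "HU"))
}
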