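make_matrix <- function(root, deviants, n_rows = 12) {
  # root + deviants stacked, root repeated to fill n_rows
  extra <- n_rows - 1 - length(deviants)
  do.call(rbind, c(list(root), rep(list(root), extra), deviants))
}

test_that("modal karyotype inference recovers the founder", {
  root <- c(rep(1L, 8), rep(2L, 8))
  colonies <- do.call(rbind, rep(list(root), 11))
  expect_equal(unname(infer_modal_karyotype(colonies)$karyotype),
               root)
  # 9 vs 2 split at ChrXII (root copy number 2)
  colonies2 <- colonies
  colonies2[1:2, 12] <- 1L
  expect_equal(unname(infer_modal_karyotype(colonies2)$karyotype)[12], 2L)
  # even split resolved by the population sample
  colonies3 <- colonies
  colonies3[1:5, 12] <- 1L
  colonies3 <- colonies3[1:10, ]
  res <- infer_modal_karyotype(colonies3)
  expect_false(res$resolved)
  expect_equal(res$ties, "XII")
  res2 <- infer_modal_karyotype(colonies3, population = root)
  expect_true(res2$resolved)
  expect_equal(unname(res2$karyotype)[12], 2L)
})

test_that("identical samples collapse to a single-node network", {
  root <- c(rep(1L, 8), rep(2L, 8))
  m <- make_matrix(root, list())
  net <- build_network(m)
  expect_equal(nrow(net$karyotypes), 1L)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$frequency, 12L)
  ev <- count_root_events(net)
  expect_equal(ev$n_root_events, 0L)
  expect_equal(ev$cin_class, "S")
})

test_that("a single deviant colony yields one labelled edge", {
  root <- c(rep(1L, 8), rep(2L, 8))
  dev <- root
  dev[16] <- 1L # loss of one ChrXVI copy
  net <- build_network(make_matrix(root, list(dev)))
  expect_equal(nrow(net$karyotypes), 2L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$label, "-XVI")
  expect_equal(net$total_cost, 1L)
  expect_equal(count_root_events(net)$cin_class, "MU")
})

test_that("multi-chromosome edges count as a single event", {
  root <- rep(1L, 16)
  dev <- root
  dev[c(7, 10)] <- c(2L, 2L)
  dev2 <- root
  dev2[10] <- 2L
  # dev reachable via dev2: root -(+X)- dev2 -(+VII)- dev, cost 2
  net <- build_network(make_matrix(root, list(dev, dev2)))
  expect_equal(net$total_cost, 2L)
  ev <- count_root_events(net)
  expect_equal(ev$n_root_events, 1L)
  expect_equal(ev$cin_class, "MU")
  # without the intermediate, the direct jump is one two-chromosome edge
  net2 <- build_network(make_matrix(root, list(dev)))
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$n_changes, 2L)
  expect_setequal(strsplit(net2$edges$label, ",")[[1]],
                  c("+VII", "+X"))
  expect_equal(count_root_events(net2)$n_root_events, 1L)
})

test_that("independent deviants plus a secondary change classify HU", {
  root <- rep(1L, 16)
  d1 <- root; d1[2] <- 2L
  d2 <- root; d2[5] <- 2L
  d3 <- d1;   d3[9] <- 2L # secondary event off d1
  net <- build_network(make_matrix(root, list(d1, d2, d3)))
  expect_equal(net$total_cost, 3L)
  ev <- count_root_events(net)
  expect_equal(ev$n_root_events, 2L)
  expect_equal(ev$cin_class, "HU")
})

test_that("chain topology is preferred when it is more parsimonious", {
  root <- rep(1L, 16)
  a <- root; a[1] <- 2L
  b <- a;    b[2] <- 2L # b is two steps from root, one from a
  net <- build_network(rbind(root, root, a, b))
  expect_equal(net$total_cost, 2L)
  # root-a-b chain: only one edge at the root
  expect_equal(count_root_events(net)$n_root_events, 1L)
})

test_that("median nodes are inserted when they reduce total cost", {
  # three observed karyotypes pairwise 2 apart: star around the
  # (unobserved) center costs 3, any MST over observed costs 4
  center <- rep(1L, 16)
  m1 <- center; m1[c(1, 2)] <- 2L
  m2 <- center; m2[c(1, 3)] <- 2L
  m3 <- center; m3[c(2, 3)] <- 2L
  net <- build_network(rbind(m1, m1, m2, m3), root_row = 1)
  expect_equal(net$total_cost, 3L)
  expect_equal(nrow(net$karyotypes), 4L)
  expect_equal(sum(!net$observed), 1L)
  expect_equal(net$frequency[!net$observed], 0L)
})

test_that("network cost equals the exhaustive Steiner oracle on small instances", {
  set.seed(55)
  cases <- c(lapply(1:15, function(i) {
    list(n_distinct = sample(2:5, 1), n_vary = sample(2:6, 1))
  }), lapply(1:3, function(i) {
    # wider instances kept small in distinct karyotypes so the
    # brute-force oracle stays tractable
    list(n_distinct = 3L, n_vary = 8L)
  }))
  for (trial in seq_along(cases)) {
    n_distinct <- cases[[trial]]$n_distinct
    n_vary <- cases[[trial]]$n_vary
    base <- rep(1L, 16)
    obs <- unique(do.call(rbind, lapply(seq_len(n_distinct), function(i) {
      k <- base
      k[seq_len(n_vary)] <- 1L + stats::rbinom(n_vary, 1, 0.5)
      k
    })))
    net <- build_network(obs, root_row = 1)
    expect_true(net$exact)
    expect_equal(net$total_cost, oracle_steiner_cost(obs),
                 info = sprintf("trial %d", trial))
  }
})

test_that("cost is invariant to row and chromosome permutations and duplicates", {
  set.seed(66)
  root <- c(rep(1L, 8), rep(2L, 8))
  d1 <- root; d1[3] <- 2L
  d2 <- root; d2[c(5, 11)] <- c(2L, 1L)
  m <- make_matrix(root, list(d1, d2))
  net <- build_network(m)
  labels0 <- sort(net$edges$label[net$edges$from == net$root |
                                    net$edges$to == net$root])
  for (i in 1:5) {
    rows <- sample(nrow(m))
    mp <- m[rows, ]
    netp <- build_network(mp, root_row = which(rows == 1)[1])
    expect_equal(netp$total_cost, net$total_cost)
    labs <- sort(netp$edges$label[netp$edges$from == netp$root |
                                    netp$edges$to == netp$root])
    expect_equal(labs, labels0)
  }
  # an added duplicate row changes frequencies only
  net_dup <- build_network(rbind(m, d1), root_row = 1)
  expect_equal(net_dup$total_cost, net$total_cost)
  expect_equal(nrow(net_dup$karyotypes), nrow(net$karyotypes))
  expect_equal(sum(net_dup$frequency), sum(net$frequency) + 1L)
})

test_that("co-optimal networks are enumerated and classified per solution", {
  # square in the hypercube: root, +I, +II, +I+II. Four spanning trees
  # of unit edges achieve the optimal cost 3, and they disagree on how
  # many events touch the root (1 for the chains, 2 for the forks).
  root <- rep(1L, 16)
  a <- root; a[1] <- 2L
  b <- root; b[2] <- 2L
  ab <- root; ab[c(1, 2)] <- 2L
  nets <- build_network(rbind(root, a, b, ab), enumerate_ties = TRUE)
  expect_s3_class(nets, "karyotype_network_set")
  expect_equal(length(nets), 4L)
  costs <- vapply(nets, function(n) n$total_cost, 0L)
  expect_true(all(costs == attr(nets, "cost")))
  cls <- count_root_events(nets)
  expect_setequal(unique(cls$cin_class), c("MU", "HU"))
  expect_false(attr(cls, "consensus"))
})

test_that("event counting needs a rooted network", {
  expect_error(count_root_events(structure(list(), class = "lm")),
               "karyotype_network")
})
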