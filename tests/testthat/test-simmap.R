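test_that("node marginals reproduce forced and symmetric cases", {
  tr <- newick_tree("((A:1,B:1):1,C:2);")
  Q0 <- build_q(c("a", "b"), "ER", values = 1e-10)
  M <- node_marginals(tr, c(A = "a", B = "a", C = "a"), Q0)
  expect_equal(unname(M["a", ]), rep(1, 5), tolerance = 1e-6)

  tr2 <- newick_tree("(A:1,B:1);")
  Qs <- build_q(c("a", "b"), "ER", values = 0.4)
  M2 <- node_marginals(tr2, c(A = "a", B = "b"), Qs)
  expect_equal(unname(M2[, 3]), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("node marginals equal brute-force Bayes on 5-tip instances", {
  set.seed(31)
  for (i in 1:10) {
    inst <- random_instance(ntip = 5, k = 2)
    M <- node_marginals(inst$tree, inst$x, inst$Q)
    oracle <- enum_posterior(inst$tree, inst$states, inst$x, inst$Q,
                             c(0.5, 0.5))
    ntip <- 5
    expect_equal(unname(M[, (ntip + 1):ncol(M)]),
                 unname(oracle$node_marginals), tolerance = 1e-8)
  }
})

test_that("histories: zero-rate homogeneous data give zero transitions", {
  tr <- newick_tree("((A:1,B:1):1,C:2);")
  Q0 <- build_q(c("a", "b"), "ER", values = 0)
  hs <- sample_histories(tr, c(A = "a", B = "a", C = "a"), Q0, nsim = 5,
                         seed = 1)
  expect_true(all(vapply(hs, function(h) nrow(h$events), 0L) == 0))
})

test_that("histories are reproducible and structurally sound", {
  tr <- sim_tree(30, 90, seed = 9)
  Q <- build_q(c("a", "b"), "ARD", values = c(0.01, 0.04))
  st <- sim_trait(tr, Q, seed = 2)
  h1 <- sample_histories(tr, st$data, Q, nsim = 3, seed = 11)
  h2 <- sample_histories(tr, st$data, Q, nsim = 3, seed = 11)
  expect_identical(h1, h2)
  for (h in h1) {
    m <- history_maps(h)
    # dwell durations sum to branch lengths
    expect_equal(unname(vapply(m, sum, 0)), h$tree$edge.length,
                 tolerance = 1e-9)
    # consecutive segments differ in state
    expect_true(all(vapply(m, function(x)
      all(names(x)[-1] != names(x)[-length(x)]) || length(x) == 1, TRUE)))
    # first/last segments agree with sampled node states
    for (e in seq_len(nrow(h$tree$edge))) {
      expect_equal(names(m[[e]])[1],
                   unname(h$states[h$tree$edge[e, 1]]))
      expect_equal(names(m[[e]])[length(m[[e]])],
                   unname(h$states[h$tree$edge[e, 2]]))
    }
  }
})

test_that("endpoint-conditioned path sampler matches the analytic event probability", {
  # one long branch (t = 1) with both endpoints effectively pinned to 'a';
  # under 2-state ER with rate 1: P(>=1 change | a -> a)
  #   = 1 - exp(-q t) / P_aa(t),  P_aa(t) = 1/2 + exp(-2 q t)/2
  tr <- newick_tree("(A:1,B:0.0000001);")
  Q <- build_q(c("a", "b"), "ER", values = 1)
  n <- 40000
  hs <- sample_histories(tr, c(A = "a", B = "a"), Q, nsim = n, seed = 13)
  edgeA <- which(ape::reorder.phylo(tr, "postorder")$edge[, 2] ==
                   which(tr$tip.label == "A"))
  root_a <- vapply(hs, function(h) unname(h$states[3]) == "a", TRUE)
  has_ev <- vapply(hs, function(h)
    any(h$events[, "edge"] == edgeA), TRUE)
  frac <- mean(has_ev[root_a])
  paa <- 0.5 + 0.5 * exp(-2)
  expect_gt(mean(root_a), 0.99)
  analytic <- 1 - exp(-1) / paa
  mc_se <- sqrt(analytic * (1 - analytic) / sum(root_a))
  expect_lt(abs(frac - analytic), 3 * mc_se)
})

test_that("histories never contain constraint-forbidden transitions", {
  tr <- sim_tree(80, 90, seed = 10)
  cs <- constraint_set(rbind(c("MH", "AU"), c("MH", "PMH")))
  Q <- build_q(c("AU", "PMH", "MH"), "ARD", cs,
               values = c(0.02, 0.01, 0.02, 0.02))
  st <- sim_trait(tr, Q, root_state = "AU", seed = 3)
  # truth histories respect the absorbing state
  ev <- st$truth$history$events
  mh <- 3
  expect_false(any(ev[, "from"] == mh))
  hs <- sample_histories(tr, st$data, Q, nsim = 200, seed = 4)
  for (h in hs)
    expect_false(any(h$events[, "from"] == mh))
})

test_that("summaries bin events by age and summarize counts", {
  tr <- sim_tree(40, 90, seed = 12)
  Q <- build_q(c("a", "b"), "ARD", values = c(0.01, 0.03))
  st <- sim_trait(tr, Q, seed = 5)
  hs <- sample_histories(tr, st$data, Q, nsim = 50, seed = 6)
  sm <- summarize_histories(hs)
  expect_equal(dim(sm$counts), c(50, 2, 2))
  expect_true(all(sm$count_summary$q5 <= sm$count_summary$median))
  expect_true(all(sm$count_summary$median <= sm$count_summary$q95))
  expect_equal(unname(colSums(sm$node_freq)),
               rep(1, ncol(sm$node_freq)), tolerance = 1e-9)
  # total binned events equal total events (all ages within the bins)
  expect_equal(sum(sm$bin_counts) * 50,
               sum(vapply(hs, function(h) nrow(h$events), 0L)),
               tolerance = 1e-9)
  expect_error(summarize_histories(hs, bins = c(10, 5, 0)),
               "increasing")
})

test_that("expected state occupancy is conserved across histories", {
  tr <- sim_tree(30, 90, seed = 14)
  Q <- build_q(c("a", "b"), "ER", values = 0.02)
  st <- sim_trait(tr, Q, seed = 7)
  hs <- sample_histories(tr, st$data, Q, nsim = 20, seed = 8)
  total_len <- sum(tr$edge.length)
  for (h in hs) {
    dwell <- tapply(unlist(history_maps(h)),
                    names(unlist(history_maps(h))), sum)
    expect_equal(sum(dwell), total_len, tolerance = 1e-8)
  }
})

test_that("origin counts are as defined, including re-entry", {
  tr <- sim_tree(50, 90, seed = 15)
  Q0 <- build_q(c("a", "b"), "ER", values = 0)
  hs0 <- sample_histories(tr, stats::setNames(rep("a", 50),
                                              tr$tip.label),
                          Q0, nsim = 3, seed = 1)
  oc0 <- count_origins(hs0, "b")
  expect_equal(unique(oc0$counts), 0L)
  # hand-built history: two separate entries into state b
  h <- hs0[[1]]
  h$events <- rbind(c(edge = 1, time = 0.1, from = 1, to = 2),
                    c(edge = 2, time = 0.1, from = 1, to = 2),
                    c(edge = 3, time = 0.1, from = 2, to = 1))
  oc1 <- count_origins(list(h), "b")
  expect_equal(oc1$counts, 2L)
  expect_error(count_origins(hs0, "z"), "not in state space")
})

test_that("SIMMAP export writes one annotated tree per history", {
  tr <- sim_tree(8, 10, seed = 16)
  Q <- build_q(c("a", "b"), "ER", values = 0.1)
  st <- sim_trait(tr, Q, seed = 9)
  hs <- sample_histories(tr, st$data, Q, nsim = 2, seed = 10)
  tf <- tempfile(fileext = ".nwk")
  write_simmap(hs, tf)
  lines <- readLines(tf)
  expect_length(lines, 2)
  expect_match(lines[1], "\\{a,|\\{b,")
  # phytools parses the format and agrees on total dwell times
  rt <- phytools::read.simmap(text = lines[1], format = "phylip")
  expect_equal(sort(unname(vapply(rt$maps, sum, 0))),
               sort(unname(vapply(history_maps(hs[[1]]), sum, 0))),
               tolerance = 1e-6)
})
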