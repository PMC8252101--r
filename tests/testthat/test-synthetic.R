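test_that("simulated trees honour size, age and seed contracts", {
  tr <- sim_tree(2, root_age = 90, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(attr(tr, "height"), 90, tolerance = 1e-9)

  t1 <- sim_tree(40, 90, seed = 2)
  t2 <- sim_tree(40, 90, seed = 2)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  t3 <- sim_tree(519, 90, seed = 3)
  expect_equal(length(t3$tip.label), 519)
  d <- ape::node.depth.edgelength(t3)[1:519]
  expect_lt(max(abs(d - 90)), 1e-6)
  expect_error(sim_tree(1), "n_tips")
  expect_error(sim_tree(5, birth = 0.1, death = 0.2), "birth > death")
})

test_that("zero-rate and absorbing simulations behave as forced", {
  tr <- sim_tree(20, 90, seed = 4)
  Q0 <- build_q(c("a", "b"), "ER", values = 0)
  st <- sim_trait(tr, Q0, root_state = "b", seed = 1)
  expect_true(all(unlist(st$data$tips) == "b"))
  expect_equal(nrow(st$truth$history$events), 0)

  cs <- constraint_set(rbind(c("MH", "AU")))
  Qa <- build_q(c("AU", "MH"), "ARD", cs, values = 0.03)
  st2 <- sim_trait(tr, Qa, root_state = "AU", seed = 2)
  expect_false(any(st2$truth$history$events[, "from"] == 2))
})

test_that("high-rate simulation approaches the stationary distribution", {
  tr <- balanced_tree(512, height = 90)
  Q <- build_q(c("a", "b", "c"), "ER", values = 0.5)
  st <- sim_trait(tr, Q, root_state = "a", seed = 3)
  freq <- table(factor(unlist(st$data$tips), c("a", "b", "c"))) / 512
  se <- sqrt((1 / 3) * (2 / 3) / 512)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})

test_that("ground truth is internally consistent with the emitted history", {
  tr <- sim_tree(60, 90, seed = 5)
  Q <- build_q(c("a", "b"), "ARD", values = c(0.02, 0.05))
  st <- sim_trait(tr, Q, seed = 4)
  h <- st$truth$history
  # recounting transitions from the history reproduces the recorded counts
  C <- matrix(0L, 2, 2)
  for (i in seq_len(nrow(h$events)))
    C[h$events[i, "from"], h$events[i, "to"]] <-
      C[h$events[i, "from"], h$events[i, "to"]] + 1L
  expect_equal(unname(st$truth$counts), C)
  # tip states match the history's terminal states
  expect_equal(unlist(st$data$tips),
               h$states[seq_along(tr$tip.label)], ignore_attr = TRUE)
})

test_that("refitting the generating model recovers rates better with more tips", {
  err_at <- function(n, seed) {
    tr <- sim_tree(n, 90, seed = seed)
    st <- sim_trait(tr, build_q(c("a", "b"), "ER", values = 0.03),
                    seed = seed)
    f <- fit_mk(tr, st$data, model = "ER", starts = 3, seed = seed)
    abs(log(unname(coef(f))) - log(0.03))
  }
  e100 <- mean(vapply(1:4, function(s) err_at(100, s), 0))
  e500 <- mean(vapply(1:4, function(s) err_at(500, s), 0))
  expect_lt(e500, e100 + 0.1)
  expect_lt(e500, 0.5)
})

test_that("orchid-like bundles hit the target frequencies and reproduce", {
  b <- suppressWarnings(sim_orchid_like(101))
  expect_equal(length(b$tree$tip.label), 519)
  expect_lt(abs(b$realized[["mh"]] - 37 / 519), 0.2 * 37 / 519 + 1e-9)
  expect_lt(abs(b$realized[["r"]] - 454 / 519), 0.2 * 454 / 519 + 1e-9)
  expect_gt(b$truth$mh_origins, 0)
  # strict coding of the emitted trophic table gives 27 PMH, relaxed 69
  ts <- trophic_dataset(b$trophic, "strict")
  tl <- trophic_dataset(b$trophic, "relaxed")
  expect_equal(sum(unlist(ts$tips) == "PMH"), 27)
  expect_equal(sum(unlist(tl$tips) == "PMH"), 69)
  b2 <- suppressWarnings(sim_orchid_like(101))
  expect_identical(ape::write.tree(b$tree), ape::write.tree(b2$tree))
  expect_identical(b$fungal$presence, b2$fungal$presence)
  expect_identical(b$coupled, b2$coupled)
})

test_that("bundles round-trip through coding and likelihood without error", {
  b <- suppressWarnings(sim_orchid_like(102, n_tips = 150))
  d <- tempfile()
  write_bundle(b, d)
  pres <- read_presence_tsv(file.path(d, "presence.tsv"))
  filt <- filter_families(pres)
  assoc <- suppressWarnings(association_dataset(filt,
                                                coding = "collapsed"))
  tro <- utils::read.delim(file.path(d, "trophic.tsv"))
  troph <- trophic_dataset(tro, "strict")
  coupled <- suppressWarnings(couple_dataset(troph, assoc))
  tree <- read_tree(file.path(d, "tree.nwk"))
  al <- align_tree_and_traits(tree, coupled)
  ll <- mk_loglik(al$tree, al$data,
                  build_q(coupled_states(), "ER", values = 0.01))
  expect_true(is.finite(ll))
  # coded association reflects the true coupled state for R-only species
  truth <- unlist(b$coupled$tips)
  r_only <- names(truth)[truth == "AU-R"]
  got <- unlist(assoc$tips[r_only])
  expect_true(mean(got == "R") > 0.95)
})

test_that("dependent-pair simulation controls the cross-trait rate ratio", {
  tr <- sim_tree(400, 90, seed = 44)
  dep <- sim_dependent_pair(tr, "dependent", effect_size = 10, seed = 45)
  expect_gt(dep$truth$rate_ratio, 3)
  inds <- vapply(1:6, function(s)
    sim_dependent_pair(tr, "independent", seed = s)$truth$rate_ratio, 0)
  inds <- inds[is.finite(inds) & inds > 0]
  # centred near 1 over replicates
  expect_lt(abs(mean(log(inds))), 0.8)
  expect_error(sim_dependent_pair(tr, "dependent", effect_size = 0),
               "effect_size")
  d1 <- sim_dependent_pair(tr, "dependent", seed = 46)
  d2 <- sim_dependent_pair(tr, "dependent", seed = 46)
  expect_identical(d1$traitA, d2$traitA)
  expect_identical(d1$truth$history$events, d2$truth$history$events)
})
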