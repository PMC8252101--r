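small_cfg <- function(seed, iters = 12000, burnin = 2000, thin = 10)
  mcmc_config(iterations = iters, burnin = burnin, thinning = thin,
              seed = seed)

test_that("MultiState MCMC recovers a known rate and is bit-reproducible", {
  tr <- sim_tree(200, 90, seed = 21)
  st <- sim_trait(tr, build_q(c("a", "b"), "ER", values = 0.05), seed = 4)
  m <- mcmc_multistate(tr, st$data, model = "ER", config = small_cfg(5))
  post_mean <- mean(m$samples)
  expect_gte(post_mean, 0.025)   # within +/-50% of the true 0.05
  expect_lte(post_mean, 0.075)
  expect_gt(m$acceptance, 0.05)
  expect_lt(m$acceptance, 0.95)
  m2 <- mcmc_multistate(tr, st$data, model = "ER", config = small_cfg(5))
  expect_identical(m, m2)
})

test_that("flat data pull the posterior rate below the prior mean", {
  tr <- sim_tree(100, 90, seed = 22)
  x <- stats::setNames(rep("a", 100), tr$tip.label)
  m <- mcmc_multistate(tr, trait_dataset(x, c("a", "b")), model = "ER",
                       config = small_cfg(6, iters = 6000, burnin = 1000))
  # prior mean 10 per unit height; change-free data concentrate far below
  expect_lt(mean(m$samples) * 90, 10)
})

test_that("two chains mix: Gelman-Rubin below 1.1", {
  tr <- sim_tree(120, 90, seed = 23)
  st <- sim_trait(tr, build_q(c("a", "b"), "ER", values = 0.02), seed = 4)
  ch <- lapply(c(31, 32), function(s)
    mcmc_multistate(tr, st$data, model = "ER", config = small_cfg(s)))
  expect_lt(max(gelman_rubin(ch)), 1.1)
})

test_that("MCMC under a flat prior tracks the likelihood profile", {
  # coarse check of sampler correctness: posterior density on a rate grid
  # is proportional to the likelihood when the prior is (nearly) flat
  tr <- sim_tree(80, 90, seed = 24)
  st <- sim_trait(tr, build_q(c("a", "b"), "ER", values = 0.03), seed = 5)
  m <- mcmc_multistate(tr, st$data, model = "ER",
                       config = mcmc_config(iterations = 42000,
                                            burnin = 2000, thinning = 5,
                                            seed = 7,
                                            prior = list(
                                              family = "uniform",
                                              max = 100)))
  r <- as.numeric(m$samples) * 90   # rates per unit height
  qs <- stats::quantile(r, c(0.25, 0.75))
  grid <- seq(qs[1], qs[2], length.out = 9)
  ll <- vapply(grid / 90, function(q)
    mk_loglik(tr, st$data, build_q(c("a", "b"), "ER", values = q)), 0)
  dens <- stats::density(r, from = qs[1], to = qs[2], n = 9)$y
  # log-density and log-likelihood should differ by ~constant
  resid <- (log(dens) - ll) - mean(log(dens) - ll)
  expect_lt(max(abs(resid)), 0.35)
})

test_that("reversible jump finds the single-class model under ER truth", {
  tr <- sim_tree(150, 90, seed = 61)
  st <- sim_trait(tr, build_q(c("a", "b"), "ER", values = 0.03), seed = 8)
  rj <- rj_mcmc(tr, st$data, model = "ARD", config = small_cfg(3))
  expect_equal(names(rj$partitions)[1], "11")
  expect_gt(rj$partitions[["11"]], 0.5)
  expect_lt(max(rj$zero_prob), 0.5)
})

test_that("reversible jump places a truly zero rate in the zero bin", {
  tr <- sim_tree(150, 90, seed = 62)
  cs <- constraint_set(rbind(c("b", "a")))
  st <- sim_trait(tr, build_q(c("a", "b"), "ARD", cs, values = 0.02),
                  root_state = "a", seed = 9)
  rj <- rj_mcmc(tr, st$data, model = "ARD", config = small_cfg(4))
  expect_gte(rj$zero_prob[["b->a"]], 0.5)
  # averaged rates near the fixed-model posterior when one partition rules
  m <- mcmc_multistate(tr, st$data, model = "ARD", config = small_cfg(5))
  keep <- rj$samples[, "a->b"] > 0
  expect_equal(mean(rj$samples[keep, "a->b"]),
               mean(m$samples[, "a->b"]), tolerance = 0.5)
})

test_that("stepping stone is exact with no free parameters and flags one stone", {
  tr <- sim_tree(20, 90, seed = 31)
  x <- stats::setNames(sample(c("a", "b"), 20, TRUE), tr$tip.label)
  cs <- constraint_set(c("a->b", "b->a"))
  ss <- stepping_stone(tr, trait_dataset(x, c("a", "b")), model = "ARD",
                       constraints = cs, stones = 10, iters = 100,
                       seed = 1)
  expect_match(ss$flags, "exact")
  expect_equal(ss$log_ml,
               mk_loglik(tr, trait_dataset(x, c("a", "b")),
                         build_q(c("a", "b"), "ARD", cs,
                                 values = numeric(0))))
  st <- sim_trait(tr, build_q(c("a", "b"), "ER", values = 0.02), seed = 4)
  ss1 <- stepping_stone(tr, st$data, model = "ER", stones = 1,
                        iters = 200, burnin = 50, reps = 1, seed = 2)
  expect_match(paste(ss1$flags, collapse = " "), "single stone")
})

test_that("stepping stone matches direct quadrature within 0.1 nats", {
  tr <- sim_tree(20, 90, seed = 31)
  st <- sim_trait(tr, build_q(c("a", "b"), "ER", values = 0.02), seed = 4)
  h <- 90
  llf <- function(r) vapply(r, function(ri)
    mk_loglik(tr, st$data, build_q(c("a", "b"), "ER",
                                   values = ri / h)), 0)
  shift <- -10
  quad <- log(stats::integrate(function(r)
    exp(llf(r) + stats::dexp(r, 0.1, log = TRUE) - shift),
    0, Inf, rel.tol = 1e-9)$value) + shift
  ss <- stepping_stone(tr, st$data, model = "ER", stones = 24,
                       iters = 1200, burnin = 200, reps = 3, seed = 2)
  expect_lt(abs(ss$log_ml - quad), 0.1)
  expect_lt(diff(range(ss$replicates)), 0.5)
})

test_that("bayes_factor follows the 2-delta-logML convention", {
  expect_equal(bayes_factor(-10, -10), 0)
  expect_equal(bayes_factor(-9, -10), 2)
  expect_equal(bayes_factor(-13, -10), -6)
})

test_that("discrete test validates its inputs", {
  tr <- sim_tree(30, 90, seed = 33)
  a <- stats::setNames(sample(c("0", "1"), 30, TRUE), tr$tip.label)
  b_const <- stats::setNames(rep("0", 30), tr$tip.label)
  expect_error(discrete_correlation_test(tr, a, b_const), "degenerate")
  tri <- stats::setNames(sample(c("0", "1", "2"), 30, TRUE),
                         tr$tip.label)
  expect_error(discrete_correlation_test(tr, a, tri),
               "binary|state space")
})

test_that("discrete test separates dependent from independent evolution", {
  tr <- sim_tree(300, 90, seed = 34)
  dep <- sim_dependent_pair(tr, "dependent", seed = 35)
  ind <- sim_dependent_pair(tr, "independent", seed = 36)
  ss_args <- list(stones = 12, iters = 400, burnin = 120, reps = 1,
                  seed = 7)
  bf_dep <- do.call(discrete_correlation_test,
                    c(list(tr, dep$traitA, dep$traitB), ss_args))
  bf_ind <- do.call(discrete_correlation_test,
                    c(list(tr, ind$traitA, ind$traitB), ss_args))
  expect_gt(bf_dep$bayes_factor, bf_ind$bayes_factor)
  expect_lt(bf_ind$bayes_factor, 2)
})
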