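# Stepping-stone marginal likelihoods over a Beta-quantile power ladder,
# Bayes factors, and Pagel's Discrete correlated-evolution test.

#' Stepping-stone log marginal likelihood
#'
#' Integrates the likelihood against the rate prior along a ladder of power
#' posteriors with Beta-quantile spacing `beta_j = (j/stones)^(1/theta)`.
#' Each rung's expectation is estimated from MH samples at the previous
#' power (independent prior draws at power 0). The analysis is run in
#' replicate and the replicate log marginal likelihoods are averaged.
#'
#' A model with no free parameters needs no integration: the exact
#' log-likelihood is returned.
#'
#' @inheritParams mcmc_multistate
#' @param stones number of ladder rungs (>= 2 for a real ladder; a single
#'   stone degenerates to the high-variance prior-arithmetic-mean regime
#'   and is flagged).
#' @param iters post-burn-in samples per stone.
#' @param burnin burn-in iterations per stone (chains warm-start from the
#'   previous rung).
#' @param theta Beta-spacing parameter (default 0.4, concentrating rungs
#'   near the prior).
#' @param reps number of replicate runs averaged.
#' @param prior rate prior as in [mcmc_config()].
#' @param proposal_scale log-multiplier proposal sd.
#' @param seed integer seed; replicate r uses seed + r.
#' @return Object of class `marginal_lik`: `log_ml` (replicate mean),
#'   `replicates`, `stones`, `betas`, `flags`.
#' @export
stepping_stone <- function(tree, data, model = c("ARD", "ER", "SYM",
                                                 "custom"),
                           constraints = NULL, root = "equal",
                           stones = 100, iters = 10000, burnin = 1000,
                           theta = 0.4, reps = 3,
                           prior = list(family = "exponential", mean = 10),
                           proposal_scale = 0.5, seed = 1,
                           scale_tree = TRUE) {
  model <- match.arg(model)
  bs <- bayes_setup(tree, data, model, constraints, root, scale_tree)
  flags <- character(0)
  if (bs$p == 0) {
    ll <- bs$ll_of(numeric(0))
    return(structure(list(log_ml = ll, replicates = ll, stones = 0L,
                          betas = 1, theta = theta,
                          flags = "exact (no free parameters)"),
                     class = "marginal_lik"))
  }
  if (stones < 2)
    flags <- c(flags,
               "single stone: prior-arithmetic-mean regime (high variance)")
  pf <- prior_fns(prior)
  betas <- (seq(0, stones) / stones)^(1 / theta)
  one_rep <- function(rep_seed) with_seed(rep_seed, {
    r <- pf$draw(bs$p)
    ll <- bs$ll_of(r)
    tries <- 0
    while (!is.finite(ll) && tries < 100) {
      r <- pf$draw(bs$p); ll <- bs$ll_of(r); tries <- tries + 1
    }
    if (!is.finite(ll)) stop("no finite-likelihood start from the prior")
    sc <- proposal_scale
    log_ml <- 0
    for (j in seq_len(stones)) {
      b_prev <- betas[j]; b_next <- betas[j + 1]
      lls <- numeric(iters)
      nit <- burnin + iters
      for (it in seq_len(nit)) {
        if (b_prev == 0) {
          # power 0 is the prior itself: independent draws
          r2 <- pf$draw(bs$p)
          ll2 <- bs$ll_of(r2)
          if (is.finite(ll2)) { r <- r2; ll <- ll2 }
        } else {
          jdx <- if (bs$p == 1) 1L else sample.int(bs$p, 1)
          r2 <- r
          r2[jdx] <- r[jdx] * exp(sc * stats::rnorm(1))
          ll2 <- bs$ll_of(r2)
          a <- (b_prev * ll2 + pf$logd(r2) + log(r2[jdx])) -
            (b_prev * ll + pf$logd(r) + log(r[jdx]))
          if (is.finite(ll2) && log(stats::runif(1)) < a) {
            r <- r2; ll <- ll2
          }
        }
        if (it > burnin) lls[it - burnin] <- ll
      }
      d <- (b_next - b_prev) * lls
      m <- max(d)
      contrib <- m + log(mean(exp(d - m)))
      if (!is.finite(contrib))
        stop("non-finite stepping-stone contribution at stone ", j,
             " (beta ", signif(b_prev, 4), " -> ", signif(b_next, 4), ")")
      log_ml <- log_ml + contrib
    }
    log_ml
  })
  repv <- vapply(seq_len(reps), function(r) one_rep(seed + r), 0)
  structure(list(log_ml = mean(repv), replicates = repv,
                 stones = stones, betas = betas, theta = theta,
                 flags = flags),
            class = "marginal_lik")
}

#' @export
print.marginal_lik <- function(x, ...) {
  cat("Stepping-stone log marginal likelihood:",
      format(x$log_ml, digits = 8), "\n")
  if (length(x$replicates) > 1)
    cat("  replicates:", paste(format(x$replicates, digits = 8),
                               collapse = ", "),
        " (spread ", format(diff(range(x$replicates)), digits = 3), ")\n")
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Bayes factor (log scale, BayesTraits convention)
#'
#' `2 * (log ML_alt - log ML_null)`.
#'
#' @param log_ml_alt,log_ml_null log marginal likelihoods (numbers or
#'   `marginal_lik` objects).
#' @export
bayes_factor <- function(log_ml_alt, log_ml_null) {
  g <- function(x) if (inherits(x, "marginal_lik")) x$log_ml else x
  2 * (g(log_ml_alt) - g(log_ml_null))
}

discrete_joint_states <- function() c("00", "01", "10", "11")

# constraint sets of Pagel's Discrete construction; double transitions
# (both traits changing at once) are forbidden in both models
discrete_constraints <- function(dependent) {
  doubles <- c("00->11", "11->00", "01->10", "10->01")
  if (dependent) return(constraint_set(doubles))
  constraint_set(doubles, equal = list(
    c("00->10", "01->11"),   # A gains, regardless of B
    c("10->00", "11->01"),   # A loses
    c("00->01", "10->11"),   # B gains
    c("01->00", "11->10")))  # B loses
}

#' Pagel's Discrete test for correlated evolution of two binary traits
#'
#' Fits the Independent model (4 rates: each trait evolves regardless of
#' the other, embedded in the joint 4-state chain) and the Dependent model
#' (8 rates) with double transitions forbidden in both, estimates each
#' model's marginal likelihood by [stepping_stone()], and reports the Bayes
#' factor `2 * (log ML_dep - log ML_ind)`.
#'
#' @param tree a `phylo`.
#' @param traitA,traitB binary [trait_dataset()]s (states "0"/"1") or named
#'   vectors, on a shared species set.
#' @param ... passed to [stepping_stone()] (stones, iters, reps, prior,
#'   seed, ...).
#' @return Object of class `discrete_test`: `log_ml_independent`,
#'   `log_ml_dependent`, `bayes_factor`.
#' @export
discrete_correlation_test <- function(tree, traitA, traitB, ...) {
  traitA <- as_trait_dataset(traitA, c("0", "1"))
  traitB <- as_trait_dataset(traitB, c("0", "1"))
  for (tr in list(A = traitA, B = traitB)) {
    if (!setequal(tr$states, c("0", "1")))
      stop("traits must be binary with states '0' and '1'")
    obs <- unlist(tr$tips[lengths(tr$tips) == 1])
    if (length(unique(obs)) < 2)
      stop("degenerate data: a trait is constant across species")
  }
  sp <- intersect(names(traitA$tips), names(traitB$tips))
  if (length(sp) < 3) stop("too few shared species")
  joint <- stats::setNames(paste0(
    vapply(traitA$tips[sp], `[`, "", 1),
    vapply(traitB$tips[sp], `[`, "", 1)), sp)
  data <- trait_dataset(joint, discrete_joint_states())
  al <- align_tree_and_traits(tree, data)
  ind <- stepping_stone(al$tree, al$data, model = "custom",
                        constraints = discrete_constraints(FALSE), ...)
  dep <- stepping_stone(al$tree, al$data, model = "custom",
                        constraints = discrete_constraints(TRUE), ...)
  structure(list(log_ml_independent = ind$log_ml,
                 log_ml_dependent = dep$log_ml,
                 bayes_factor = bayes_factor(dep, ind),
                 independent = ind, dependent = dep),
            class = "discrete_test")
}

#' @export
print.discrete_test <- function(x, ...) {
  cat("Pagel's Discrete correlated-evolution test\n")
  cat("  log ML independent:", format(x$log_ml_independent, digits = 8),
      "\n  log ML dependent:  ", format(x$log_ml_dependent, digits = 8),
      "\n  Bayes factor (2 dlogML):", format(x$bayes_factor, digits = 5),
      "\n")
  invisible(x)
}
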