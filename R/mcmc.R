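# Bayesian MultiState machinery: Metropolis-Hastings over transition rates
# (log-scale multiplier proposals), reversible-jump model averaging over
# rate-equality classes with a zero bin, and convergence diagnostics.
#
# Following common practice for rate MCMC on dated trees, the samplers work
# internally on a tree rescaled to unit height (rates per tree-height), so a
# prior with mean 10 covers realistic per-Myr rates whatever the time scale;
# reported rates are converted back to events per Myr.

#' MCMC configuration
#'
#' @param iterations total iterations (default 1 010 000).
#' @param burnin burn-in iterations discarded (default 10 000); the proposal
#'   scale is auto-tuned to 20-40% acceptance during burn-in, then frozen.
#' @param thinning keep every `thinning`-th post-burn-in sample.
#' @param seed integer seed; traces are bit-identical given (seed, config).
#' @param prior rate prior: `list(family = "exponential", mean = 10)` or
#'   `list(family = "uniform", max = 100)`.
#' @param proposal_scale initial log-scale multiplier sd.
#' @param chains number of chains (run via [gelman_rubin()]).
#' @export
mcmc_config <- function(iterations = 1010000, burnin = 10000,
                        thinning = 1000, seed = 1,
                        prior = list(family = "exponential", mean = 10),
                        proposal_scale = 0.5, chains = 1) {
  if (burnin >= iterations) stop("burnin must be < iterations")
  if ((iterations - burnin) %% thinning != 0)
    thinning <- max(1, thinning)
  stopifnot(prior$family %in% c("exponential", "uniform"))
  structure(list(iterations = iterations, burnin = burnin,
                 thinning = thinning, seed = seed, prior = prior,
                 proposal_scale = proposal_scale, chains = chains),
            class = "mcmc_config")
}

prior_fns <- function(prior) {
  if (prior$family == "exponential") {
    m <- if (is.null(prior$mean)) 10 else prior$mean
    list(logd = function(r) sum(stats::dexp(r, 1 / m, log = TRUE)),
         draw = function(n) stats::rexp(n, 1 / m))
  } else {
    mx <- if (is.null(prior$max)) 100 else prior$max
    list(logd = function(r) if (all(r <= mx)) -length(r) * log(mx) else -Inf,
         draw = function(n) stats::runif(n, 0, mx))
  }
}

# shared setup for the samplers; optionally rescales tree to unit height
bayes_setup <- function(tree, data, model, constraints, root, scale_tree) {
  data <- as_trait_dataset(data)
  k <- length(data$states)
  tree <- validate_tree(tree)
  height <- tree_height(tree)
  scale <- if (scale_tree) height else 1
  if (scale_tree) tree$edge.length <- tree$edge.length / height
  idx <- param_index(data$states, model, constraints)
  env <- mk_env(tree, data)
  rootp <- as_root_prior(root)
  q_of <- function(rates) {
    Q <- matrix(0, k, k)
    Q[idx > 0] <- rates[idx[idx > 0]]
    diag(Q) <- -rowSums(Q)
    Q
  }
  ll_q <- if (rootp$kind == "stationary") {
    function(Q) {
      rp <- tryCatch(resolve_root(rootp, as_q_matrix(Q, data$states), k),
                     error = function(e) NULL)
      if (is.null(rp)) return(-Inf)
      mk_ll(env, Q, rp$weights, rp$fitzjohn)
    }
  } else {
    rp0 <- resolve_root(rootp, NULL, k)
    function(Q) mk_ll(env, Q, rp0$weights, rp0$fitzjohn)
  }
  ll_of <- function(rates) ll_q(q_of(rates))
  list(env = env, idx = idx, p = n_params(idx), k = k, states = data$states,
       scale = scale, ll_of = ll_of, ll_q = ll_q, q_of = q_of)
}

#' MultiState MCMC over transition rates
#'
#' Metropolis-Hastings sampler for the posterior of the free rates of a
#' (possibly constrained) Mk model: one rate per iteration receives a
#' symmetric log-normal multiplier proposal; the scale is tuned to 20-40%
#' acceptance during burn-in and then frozen.
#'
#' @inheritParams fit_mk
#' @param config an [mcmc_config()].
#' @param scale_tree work on the unit-height tree internally (recommended;
#'   reported rates are always events/Myr).
#' @return Object of class `mk_mcmc`: `samples` (matrix, events/Myr),
#'   `loglik`, `logprior`, `acceptance`, `config`.
#' @export
mcmc_multistate <- function(tree, data, model = c("ARD", "ER", "SYM",
                                                  "custom"),
                            constraints = NULL, root = "equal",
                            config = mcmc_config(), scale_tree = TRUE) {
  model <- match.arg(model)
  bs <- bayes_setup(tree, data, model, constraints, root, scale_tree)
  if (bs$p == 0) stop("model has no free parameters to sample")
  pf <- prior_fns(config$prior)
  nkeep <- (config$iterations - config$burnin) %/% config$thinning
  with_seed(config$seed, {
    r <- pf$draw(bs$p)
    ll <- bs$ll_of(r)
    tries <- 0
    while (!is.finite(ll) && tries < 100) {
      r <- pf$draw(bs$p); ll <- bs$ll_of(r); tries <- tries + 1
    }
    if (!is.finite(ll)) stop("could not find a finite-likelihood start")
    lp <- pf$logd(r)
    sc <- config$proposal_scale
    samples <- matrix(NA_real_, nkeep, bs$p)
    llv <- lpv <- numeric(nkeep)
    acc <- 0L; acc_win <- 0L; kept <- 0L
    for (it in seq_len(config$iterations)) {
      j <- if (bs$p == 1) 1L else sample.int(bs$p, 1)
      r2 <- r
      r2[j] <- r[j] * exp(sc * stats::rnorm(1))
      ll2 <- bs$ll_of(r2)
      lp2 <- pf$logd(r2)
      # Jacobian of the log-scale walk: + log(r2/r)
      a <- (ll2 + lp2 + log(r2[j])) - (ll + lp + log(r[j]))
      if (is.finite(ll2) && log(stats::runif(1)) < a) {
        r <- r2; ll <- ll2; lp <- lp2
        acc_win <- acc_win + 1L
        if (it > config$burnin) acc <- acc + 1L
      }
      if (it <= config$burnin && it %% 200 == 0) {
        rate <- acc_win / 200
        if (rate < 0.2) sc <- sc * 0.8
        if (rate > 0.4) sc <- sc * 1.25
        acc_win <- 0L
      }
      if (it > config$burnin &&
          (it - config$burnin) %% config$thinning == 0) {
        kept <- kept + 1L
        samples[kept, ] <- r
        llv[kept] <- ll; lpv[kept] <- lp
      }
    }
    accept <- acc / (config$iterations - config$burnin)
    if (accept == 0)
      warning("zero post-burn-in acceptance; decrease proposal_scale")
    colnames(samples) <- param_names(bs$idx)
    structure(list(samples = samples / bs$scale, loglik = llv,
                   logprior = lpv, acceptance = accept,
                   proposal_scale = sc, config = config,
                   states = bs$states, index = bs$idx,
                   time_scale = bs$scale),
              class = "mk_mcmc")
  })
}

#' @export
print.mk_mcmc <- function(x, ...) {
  cat("MultiState MCMC:", nrow(x$samples), "retained samples,",
      ncol(x$samples), "rate parameter(s), acceptance",
      sprintf("%.2f", x$acceptance), "\n")
  print(round(rbind(mean = colMeans(x$samples),
                    sd = apply(x$samples, 2, stats::sd)), 5))
  invisible(x)
}

#' @export
summary.mk_mcmc <- function(object, ...) {
  q <- t(apply(object$samples, 2, stats::quantile,
               c(0.05, 0.5, 0.95)))
  data.frame(mean = colMeans(object$samples),
             sd = apply(object$samples, 2, stats::sd), q)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' @param chains list of `mk_mcmc` objects (same model, different seeds).
#' @return Named vector of R-hat values, one per rate parameter.
#' @export
gelman_rubin <- function(chains) {
  stopifnot(length(chains) >= 2)
  mats <- lapply(chains, function(x)
    if (inherits(x, "mk_mcmc")) x$samples else as.matrix(x))
  n <- min(vapply(mats, nrow, 0L))
  mats <- lapply(mats, function(m) m[seq_len(n), , drop = FALSE])
  m <- length(mats)
  vapply(seq_len(ncol(mats[[1]])), function(j) {
    means <- vapply(mats, function(x) mean(x[, j]), 0)
    vars <- vapply(mats, function(x) stats::var(x[, j]), 0)
    B <- n * stats::var(means)
    W <- mean(vars)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0) -> rhat
  stats::setNames(rhat, colnames(mats[[1]]))
}

#' Posterior node-state reconstruction from an MCMC trace
#'
#' Averages the marginal ancestral-state posteriors over retained rate
#' samples (per-sample reconstruction, then trace average).
#'
#' @param trace an `mk_mcmc` object.
#' @param tree,data,root as supplied to the sampler.
#' @param every use every `every`-th retained sample.
#' @return k x (ntip + nnode) matrix of averaged posteriors.
#' @export
mcmc_node_posterior <- function(trace, tree, data, root = "equal",
                                every = 10) {
  use <- seq(1, nrow(trace$samples), by = every)
  data <- as_trait_dataset(data)
  k <- length(trace$states)
  acc <- NULL
  for (i in use) {
    Q <- matrix(0, k, k, dimnames = list(trace$states, trace$states))
    Q[trace$index > 0] <- trace$samples[i, ][trace$index[trace$index > 0]]
    diag(Q) <- -rowSums(Q)
    M <- node_marginals(tree, data, Q, root)
    acc <- if (is.null(acc)) M else acc + M
  }
  acc / length(use)
}

#' Reversible-jump MCMC over rate-equality classes
#'
#' Model-averaging sampler in which every allowed off-diagonal cell is
#' assigned either to the zero bin (rate exactly 0) or to one of a set of
#' shared-rate classes. Cell reassignments are Metropolis moves on a
#' saturated parameter space (rates for all potential classes are carried
#' and refreshed from the prior when unused), which makes the
#' trans-dimensional sweep a standard fixed-dimension MH step; the prior is
#' uniform over assignment vectors.
#'
#' @inheritParams mcmc_multistate
#' @return Object of class `mk_rjmcmc`: per-sample cell rates and
#'   assignments, visited partitions with posterior probabilities, and the
#'   per-cell posterior probability of lying in the zero bin.
#' @export
rj_mcmc <- function(tree, data, model = c("ARD", "ER", "SYM", "custom"),
                    constraints = NULL, root = "equal",
                    config = mcmc_config(), scale_tree = TRUE) {
  model <- match.arg(model)
  bs <- bayes_setup(tree, data, model, constraints, root, scale_tree)
  ncell <- bs$p
  if (ncell == 0) stop("no free cells to average over")
  # bypass the model's parameter sharing: every cell is its own coordinate
  cell_ids <- which(bs$idx > 0)
  cell_names <- cell_labels(bs$states)[cell_ids]
  k <- bs$k
  q_cells <- function(cell_rates) {
    Q <- matrix(0, k, k)
    Q[cell_ids] <- cell_rates
    diag(Q) <- -rowSums(Q)
    Q
  }
  ll_cells <- function(cell_rates) bs$ll_q(q_cells(cell_rates))
  pf <- prior_fns(config$prior)
  nkeep <- (config$iterations - config$burnin) %/% config$thinning
  with_seed(config$seed, {
    z <- rep(1L, ncell)             # all cells share one class
    rates <- pf$draw(ncell)          # saturated class-rate vector
    cur <- function() { r <- ifelse(z == 0, 0, rates[pmax(z, 1)]); r }
    ll <- ll_cells(cur())
    sc <- config$proposal_scale
    zs <- matrix(NA_integer_, nkeep, ncell)
    rs <- matrix(NA_real_, nkeep, ncell)
    llv <- numeric(nkeep)
    kept <- 0L; acc <- 0L; acc_win <- 0L; nprop <- 0L
    for (it in seq_len(config$iterations)) {
      if (stats::runif(1) < 0.5) {
        cidx <- sample.int(ncell, 1)
        if (cidx %in% z) {          # used class: MH multiplier move
          old <- rates[cidx]
          new <- old * exp(sc * stats::rnorm(1))
          rates[cidx] <- new
          ll2 <- ll_cells(cur())
          a <- (ll2 + pf$logd(new) + log(new)) -
            (ll + pf$logd(old) + log(old))
          nprop <- nprop + 1L
          if (is.finite(ll2) && log(stats::runif(1)) < a) {
            ll <- ll2
            if (it > config$burnin) acc <- acc + 1L
            acc_win <- acc_win + 1L
          } else rates[cidx] <- old
        } else {                    # unused class: Gibbs refresh from prior
          rates[cidx] <- pf$draw(1)
        }
      } else {                      # reassign one cell
        j <- sample.int(ncell, 1)
        choices <- setdiff(0:ncell, z[j])
        znew <- z; znew[j] <- if (length(choices) == 1) choices
          else sample(choices, 1)
        rnew <- ifelse(znew == 0, 0, rates[pmax(znew, 1)])
        ll2 <- ll_cells(rnew)
        if (is.finite(ll2) && log(stats::runif(1)) < (ll2 - ll)) {
          z <- znew; ll <- ll2
        }
      }
      if (it <= config$burnin && it %% 200 == 0) {
        rate <- if (nprop > 0) acc_win / nprop else 0.3
        if (rate < 0.2) sc <- sc * 0.8
        if (rate > 0.4) sc <- sc * 1.25
        acc_win <- 0L; nprop <- 0L
      }
      if (it > config$burnin &&
          (it - config$burnin) %% config$thinning == 0) {
        kept <- kept + 1L
        zs[kept, ] <- z
        rs[kept, ] <- cur()
        llv[kept] <- ll
      }
    }
    colnames(zs) <- colnames(rs) <- cell_names
    partition <- apply(zs, 1, function(zz) {
      # canonical labels in order of first appearance; 0 stays 0
      out <- integer(length(zz)); nxt <- 0L
      seen <- integer(0)
      for (i in seq_along(zz)) {
        if (zz[i] == 0) { out[i] <- 0L; next }
        pos <- match(zz[i], seen)
        if (is.na(pos)) { seen <- c(seen, zz[i]); pos <- length(seen) }
        out[i] <- pos
      }
      paste(out, collapse = "")
    })
    ptab <- sort(table(partition) / kept, decreasing = TRUE)
    structure(list(samples = rs / bs$scale, assignments = zs,
                   loglik = llv, partitions = ptab,
                   zero_prob = colMeans(zs == 0),
                   config = config, cells = cell_names,
                   time_scale = bs$scale),
              class = "mk_rjmcmc")
  })
}

#' @export
print.mk_rjmcmc <- function(x, ...) {
  cat("Reversible-jump MCMC:", nrow(x$samples), "retained samples over",
      length(x$cells), "cells\n")
  cat("Top partitions (canonical labels; 0 = zero bin):\n")
  print(utils::head(round(x$partitions, 3), 5))
  cat("Zero-bin inclusion per cell:\n")
  print(round(x$zero_prob, 3))
  invisible(x)
}
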