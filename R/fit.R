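# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

param_names <- function(idx) {
  lab <- cell_labels(rownames(idx))
  vapply(seq_len(n_params(idx)), function(p) {
    cells <- lab[idx == p]
    if (length(cells) == 1) cells else paste0(cells[1], " (+",
                                              length(cells) - 1, ")")
  }, "")
}

#' Fit a continuous-time Markov (Mk) model to a discrete character
#'
#' Maximum-likelihood fit of a (possibly constrained) k-state CTMC on a
#' dated tree by multi-start bounded quasi-Newton optimisation of the
#' pruning log-likelihood over log-rates.
#'
#' @param tree a `phylo` object (branch lengths in Myr).
#' @param data a [trait_dataset()] or named state vector; ambiguous tips
#'   allowed.
#' @param model `"ER"`, `"SYM"`, `"ARD"` or `"custom"`.
#' @param constraints optional [constraint_set()].
#' @param root a [root_prior()] or its kind; default equal weights.
#' @param starts number of optimisation starts (first is a heuristic start
#'   at one expected event per tree height; the rest are drawn log-uniform).
#' @param seed optional integer seed for the start draws.
#' @param lambda optional fixed Pagel's lambda in `[0, 1]` applied to the
#'   tree before fitting (use [fit_lambda()] to estimate it).
#' @param init optional vector (or list of vectors) of starting rates.
#' @param lower,upper rate bounds, events per Myr.
#' @return Object of class `mk_fit` with elements `rates`, `Q`, `loglik`,
#'   `k_params`, `converged`, and supporting metadata. Methods: `print`,
#'   `summary`, `coef`, `logLik` (so `BIC()` works), `predict` (marginal
#'   ancestral states), `simulate`, `plot`.
#' @export
fit_mk <- function(tree, data, model = c("ARD", "ER", "SYM", "custom"),
                   constraints = NULL, root = "equal", starts = 10,
                   seed = NULL, lambda = NULL, init = NULL,
                   lower = 1e-8, upper = 1e3) {
  model <- match.arg(model)
  data <- as_trait_dataset(data)
  k <- length(data$states)
  if (k < 2) stop("degenerate state space: need at least 2 states")
  tree <- validate_tree(tree)
  if (!is.null(lambda)) tree <- lambda_transform(tree, lambda)
  idx <- param_index(data$states, model, constraints)
  p <- n_params(idx)
  env <- mk_env(tree, data)
  rootp <- as_root_prior(root)
  height <- tree_height(tree)

  q_of <- function(rates) {
    Q <- matrix(0, k, k, dimnames = list(data$states, data$states))
    Q[idx > 0] <- rates[idx[idx > 0]]
    diag(Q) <- -rowSums(Q)
    Q
  }
  ll_of <- if (rootp$kind == "stationary") {
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

  if (p == 0) {
    Q <- q_of(numeric(0))
    ll <- ll_of(Q)
    fit <- list(rates = numeric(0), Q = as_q_matrix(Q), loglik = ll,
                k_params = 0L, converged = is.finite(ll), index = idx,
                states = data$states, root = rootp, ntip = env$ntip,
                height = height, lambda = lambda, env = env,
                n_starts = 0L, n_failed = 0L)
    class(fit) <- "mk_fit"
    return(fit)
  }

  obj <- function(logr) {
    ll <- ll_of(q_of(exp(logr)))
    if (!is.finite(ll)) 1e10 else -ll
  }

  start_list <- with_seed(seed, {
    s <- list(log(rep(1 / height, p)))
    if (starts > 1)
      for (i in seq_len(starts - 1))
        s[[i + 1]] <- stats::runif(p, log(0.01 / height), log(10 / height))
    s
  })
  if (!is.null(init)) {
    if (!is.list(init)) init <- list(init)
    start_list <- c(lapply(init, function(v) log(pmin(pmax(v, lower),
                                                      upper))), start_list)
  }

  best <- NULL; n_fail <- 0L
  for (s0 in start_list) {
    res <- tryCatch(
      stats::nlminb(s0, obj, lower = log(lower), upper = log(upper),
                    control = list(iter.max = 500, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective) ||
        res$objective >= 1e9) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best))
    stop("all ", length(start_list), " optimisation starts failed ",
         "(likelihood may be identically zero under these constraints)")

  rates <- stats::setNames(exp(best$par), param_names(idx))
  Q <- as_q_matrix(q_of(rates))
  attr(Q, "index") <- idx
  attr(Q, "constraints") <- constraints
  fit <- list(rates = rates, Q = Q, loglik = -best$objective,
              k_params = p, converged = best$convergence == 0,
              index = idx, states = data$states, root = rootp,
              ntip = env$ntip, height = height, lambda = lambda,
              env = env, n_starts = length(start_list), n_failed = n_fail)
  class(fit) <- "mk_fit"
  fit
}

#' @export
print.mk_fit <- function(x, digits = 4, ...) {
  cat("Mk model fit: ", length(x$states), " states (",
      paste(x$states, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$lambda)) cat("  fixed Pagel's lambda:", x$lambda, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " free parameters:", x$k_params,
      " BIC:", format(bic(x$loglik, x$k_params, x$ntip), digits = 8), "\n")
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  if (length(x$rates)) {
    cat("  rates (events/Myr):\n")
    print(round(x$rates, digits))
  }
  invisible(x)
}

#' @export
summary.mk_fit <- function(object, ...) {
  print(object)
  cat("\nGenerator Q:\n")
  print(round(unclass(object$Q), 5))
  invisible(object)
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$ntip,
            class = "logLik")
}

#' @export
predict.mk_fit <- function(object, type = c("marginal"), ...) {
  type <- match.arg(type)
  node_marginals(object$env$tree,
                 trait_env_dataset(object),
                 object$Q, object$root)
}

trait_env_dataset <- function(fit) {
  tips <- apply(fit$env$tipL, 2, function(col)
    fit$states[col > 0], simplify = FALSE)
  trait_dataset(tips, fit$states)
}

#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i)
    sim_trait(object$env$tree, object$Q,
              root_state = resolve_root(object$root, object$Q,
                                        length(object$states))$weights)))
}

#' @export
plot.mk_fit <- function(x, ...) {
  marg <- predict(x)
  tr <- x$env$tree
  ape::plot.phylo(tr, show.tip.label = length(tr$tip.label) <= 60,
                  no.margin = TRUE, ...)
  ape::nodelabels(pie = t(marg[, (length(tr$tip.label) + 1):
                                   (length(tr$tip.label) + tr$Nnode),
                               drop = FALSE]),
                  cex = 0.4)
  invisible(x)
}

#' Bayesian information criterion
#'
#' `-2 log L + k ln(n)` with `n` the number of tip species.
#'
#' @param loglik log-likelihood.
#' @param k_params free-parameter count.
#' @param n number of species (tips).
#' @export
bic <- function(loglik, k_params, n) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  -2 * loglik + k_params * log(n)
}

#' Estimate Pagel's lambda for a discrete character
#'
#' Joint maximum likelihood over lambda and the transition rates: the
#' profile likelihood over lambda in `[0, 1]` is maximised by golden-section
#' search, refitting the rates at each lambda (warm-started). Likelihoods at
#' the boundaries lambda = 0 (no phylogenetic signal: star-like tree) and
#' lambda = 1 (untransformed tree) are reported for signal assessment.
#'
#' @inheritParams fit_mk
#' @param starts optimisation starts for the boundary fits (interior fits
#'   warm-start from neighbours).
#' @param tol absolute tolerance on lambda.
#' @return Object of class `lambda_fit`: `lambda`, `loglik` (at the
#'   estimate), `loglik0`, `loglik1`, `fit` (the `mk_fit` at the estimate),
#'   `flat` (TRUE when the likelihood is constant in lambda, e.g. a 2-tip
#'   tree), and the evaluated `profile`.
#' @export
fit_lambda <- function(tree, data, model = c("ER", "SYM", "ARD", "custom"),
                       constraints = NULL, root = "equal", starts = 5,
                       seed = NULL, tol = 1e-3) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  if (!is_ultrametric_tree(tree))
    stop("Pagel's lambda requires an ultrametric tree")
  prof <- new.env()
  prof$pts <- list()
  eval_at <- function(lam, init = NULL, ns = starts) {
    key <- sprintf("%.10f", lam)
    if (!is.null(prof$pts[[key]])) return(prof$pts[[key]])
    f <- fit_mk(tree, data, model, constraints, root, starts = ns,
                seed = seed, lambda = lam, init = init)
    prof$pts[[key]] <- f
    f
  }
  f1 <- eval_at(1)
  f0 <- eval_at(0, init = list(f1$rates))
  warm <- function(...) {
    rs <- lapply(list(...), function(f) f$rates)
    rs[lengths(rs) > 0]
  }
  # golden-section search maximising the profile log-likelihood
  gr <- (sqrt(5) - 1) / 2
  a <- 0; b <- 1
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  fx1 <- eval_at(x1, init = warm(f0, f1), ns = 2)
  fx2 <- eval_at(x2, init = warm(f0, f1), ns = 2)
  while (b - a > tol) {
    if (fx1$loglik >= fx2$loglik) {
      b <- x2; x2 <- x1; fx2 <- fx1
      x1 <- b - gr * (b - a)
      fx1 <- eval_at(x1, init = warm(fx2), ns = 2)
    } else {
      a <- x1; x1 <- x2; fx1 <- fx2
      x2 <- a + gr * (b - a)
      fx2 <- eval_at(x2, init = warm(fx1), ns = 2)
    }
  }
  fits <- prof$pts
  lls <- vapply(fits, function(f) f$loglik, 0)
  lams <- as.numeric(names(fits))
  best <- which.max(lls)
  flat <- diff(range(lls[is.finite(lls)])) < 1e-6
  lambda_hat <- if (flat) 1 else lams[best]
  out <- list(lambda = lambda_hat, loglik = lls[best],
              loglik0 = f0$loglik, loglik1 = f1$loglik,
              fit = fits[[best]], flat = flat,
              profile = data.frame(lambda = lams, loglik = lls)[
                order(lams), ])
  class(out) <- "lambda_fit"
  out
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda (discrete character)\n")
  cat("  lambda-hat:", format(x$lambda, digits = 4),
      if (x$flat) "(likelihood flat in lambda)" else "", "\n")
  cat("  logL at lambda-hat:", format(x$loglik, digits = 8), "\n")
  cat("  logL at lambda = 1:", format(x$loglik1, digits = 8),
      "  lambda = 0:", format(x$loglik0, digits = 8), "\n")
  invisible(x)
}
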