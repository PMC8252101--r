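#' Root prior for discrete-trait likelihoods
#'
#' @param kind `"equal"` (default, the common MultiState convention),
#'   `"stationary"` (requires an irreducible Q), `"fitzjohn"` (weights
#'   proportional to the root partials), or `"fixed"`.
#' @param weights simplex of length k when `kind = "fixed"`.
#' @return Object of class `root_prior`.
#' @export
root_prior <- function(kind = c("equal", "stationary", "fitzjohn", "fixed"),
                       weights = NULL) {
  kind <- match.arg(kind)
  if (kind == "fixed") {
    if (is.null(weights) || any(weights < 0) ||
        abs(sum(weights) - 1) > 1e-8)
      stop("fixed root prior needs nonnegative weights summing to 1")
  }
  structure(list(kind = kind, weights = weights), class = "root_prior")
}

as_root_prior <- function(root) {
  if (inherits(root, "root_prior")) return(root)
  if (is.character(root)) return(root_prior(root))
  if (is.numeric(root)) return(root_prior("fixed", root / sum(root)))
  stop("cannot interpret root prior")
}

resolve_root <- function(root, Q, k) {
  root <- as_root_prior(root)
  w <- switch(root$kind,
    equal = rep(1 / k, k),
    stationary = as.numeric(stationary_dist(Q)),
    fixed = root$weights,
    fitzjohn = rep(1 / k, k))  # placeholder, flag handled separately
  list(weights = w, fitzjohn = root$kind == "fitzjohn")
}

# Precompute everything the C++ core needs for repeated likelihood calls on
# one (tree, data) pair: postorder edge matrix, lengths, tip partials.
mk_env <- function(tree, data) {
  data <- as_trait_dataset(data)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree_po,
       edge = tree_po$edge,
       elen = tree_po$edge.length,
       ntip = length(tree_po$tip.label),
       nnode = tree_po$Nnode,
       states = data$states,
       tipL = tip_partials(data, tree_po))
}

mk_ll <- function(env, Q, rootw, fitzjohn = FALSE) {
  mk_loglik_cpp(env$edge, env$elen, env$ntip, env$nnode, env$tipL,
                unclass(Q), rootw, fitzjohn)
}

#' Pruning log-likelihood of a discrete character on a tree
#'
#' Felsenstein's pruning algorithm with per-node rescaling; polytomies and
#' ambiguous tips (partial vectors) are supported. Data that are impossible
#' under the constraints yield `-Inf` with a warning rather than an error,
#' so constrained models can reject impossible histories gracefully.
#'
#' @param tree a `phylo` object.
#' @param data a [trait_dataset()] or named state vector.
#' @param Q a [build_q()] rate matrix (or plain generator matrix).
#' @param root a [root_prior()], its kind as a string, or fixed weights.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, data, Q, root = "equal") {
  if (!inherits(data, "trait_dataset") && !is.null(rownames(Q)))
    data <- trait_dataset(data, state_space = rownames(Q))
  data <- as_trait_dataset(data)
  Q <- as_q_matrix(Q, data$states)
  if (!identical(rownames(Q), data$states))
    Q <- Q[data$states, data$states]
  env <- mk_env(tree, data)
  rp <- resolve_root(root, Q, length(data$states))
  ll <- mk_ll(env, Q, rp$weights, rp$fitzjohn)
  if (!is.finite(ll) && ll < 0)
    warning("data have zero likelihood under this Q (impossible under ",
            "the constraints); returning -Inf")
  ll
}
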