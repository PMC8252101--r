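# Independent oracles: exhaustive enumeration over ancestral assignments
# (transition kernels via Matrix::expm, independent of the package's
# spectral kernel), and small fixture builders.

enum_posterior <- function(tree, states, x, Q, rootp) {
  tree <- ape::reorder.phylo(tree, "postorder")
  k <- length(states)
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(unclass(Q) * tree$edge.length[e])))
  tipsets <- if (is.list(x)) x[tree$tip.label]
  else lapply(x[tree$tip.label], identity)
  tip_opts <- lapply(tipsets, function(s) match(s, states))
  combs <- as.matrix(expand.grid(c(tip_opts, rep(list(1:k), nn))))
  lik <- apply(combs, 1, function(st) {
    p <- rootp[st[ntip + 1]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    p
  })
  tot <- sum(lik)
  marg <- vapply(seq_len(nn), function(j)
    vapply(seq_len(k), function(s)
      sum(lik[combs[, ntip + j] == s]), 0) / tot, numeric(k))
  list(loglik = log(tot), node_marginals = marg)
}

enum_loglik <- function(tree, states, x, Q,
                        rootp = rep(1 / length(states), length(states)))
  enum_posterior(tree, states, x, Q, rootp)$loglik

random_instance <- function(ntip = NULL, k = NULL) {
  if (is.null(ntip)) ntip <- sample(2:6, 1)
  if (is.null(k)) k <- sample(2:3, 1)
  tree <- validate_tree(ape::rtree(ntip))
  states <- letters[seq_len(k)]
  x <- stats::setNames(sample(states, ntip, replace = TRUE),
                       tree$tip.label)
  vals <- stats::runif(k * (k - 1), 0.05, 1.5)
  Q <- build_q(states, "ARD", values = vals)
  list(tree = tree, states = states, x = x, Q = Q)
}

newick_tree <- function(txt) {
  tf <- tempfile(fileext = ".nwk")
  writeLines(txt, tf)
  read_tree(tf)
}

balanced_tree <- function(n, height = 90) {
  tr <- ape::stree(n, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height / d
  validate_tree(tr)
}
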