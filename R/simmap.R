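# Stochastic character mapping: joint node-state sampling plus
# endpoint-conditioned path sampling by uniformization, with marginal
# ancestral-state posteriors as the analytic reference.

simmap_details <- function(tree, data, Q, root) {
  if (!inherits(data, "trait_dataset") && !is.null(rownames(Q)))
    data <- trait_dataset(data, state_space = rownames(Q))
  data <- as_trait_dataset(data)
  Q <- as_q_matrix(Q, data$states)
  env <- mk_env(tree, data)
  rp <- resolve_root(root, Q, length(data$states))
  det <- mk_pruning_cpp(env$edge, env$elen, env$ntip, env$nnode, env$tipL,
                        unclass(Q), rp$weights, rp$fitzjohn, TRUE)
  if (!is.finite(det$loglik))
    stop("data have zero likelihood under this Q; cannot map histories")
  rootw <- if (rp$fitzjohn) {
    d <- det$D[, env$ntip + 1]; d / sum(d)
  } else rp$weights
  list(env = env, Q = Q, det = det, rootw = rootw)
}

#' Marginal ancestral-state posteriors at every node
#'
#' For each node, the marginal posterior over states given the tip data and
#' the rate matrix, by the standard inside-outside (up-pass/down-pass)
#' recursion on the pruning partials.
#'
#' @param tree a `phylo` object.
#' @param data a [trait_dataset()] or named state vector.
#' @param Q a rate matrix.
#' @param root a [root_prior()] or its kind.
#' @return k x (ntip + nnode) matrix of posteriors; columns are node
#'   numbers (ape convention: tips first, root = ntip + 1).
#' @export
node_marginals <- function(tree, data, Q, root = "equal") {
  sd <- simmap_details(tree, data, Q, root)
  env <- sd$env; det <- sd$det
  k <- nrow(env$tipL); ntot <- env$ntip + env$nnode
  ne <- nrow(env$edge)
  # per-edge child contribution v_e = P_e D_child
  V <- matrix(0, k, ne)
  for (e in seq_len(ne))
    V[, e] <- det$P[, , e] %*% det$D[, env$edge[e, 2]]
  S <- matrix(0, k, ntot)
  S[, env$ntip + 1] <- sd$rootw
  child_edges <- split(seq_len(ne), env$edge[, 1])
  for (e in rev(seq_len(ne))) {  # preorder
    p <- env$edge[e, 1]; ch <- env$edge[e, 2]
    sibs <- setdiff(child_edges[[as.character(p)]], e)
    W <- S[, p]
    for (e2 in sibs) W <- W * V[, e2]
    s <- crossprod(det$P[, , e], W)[, 1]
    tot <- sum(s)
    S[, ch] <- if (tot > 0) s / tot else s
  }
  M <- det$D * S
  cs <- colSums(M)
  cs[cs == 0] <- 1
  M <- sweep(M, 2, cs, "/")
  dimnames(M) <- list(rownames(env$tipL), seq_len(ntot))
  M
}

# lazily-extended powers of the uniformized jump matrix
make_rpow <- function(R) {
  e <- new.env()
  e$pow <- list(diag(nrow(R)))
  function(n) {  # returns R^n
    while (length(e$pow) < n + 1)
      e$pow[[length(e$pow) + 1]] <- e$pow[[length(e$pow)]] %*% R
    e$pow[[n + 1]]
  }
}

# endpoint-conditioned CTMC path on one branch by uniformization.
# Returns integer state sequence and event times in (0, t).
sample_path_unif <- function(a, b, t, Q, mu, R, rpow, pab) {
  k <- nrow(Q)
  if (mu <= 0 || t == 0) {
    if (a != b) stop("impossible endpoint pair under a zero-rate chain")
    return(list(states = a, times = numeric(0)))
  }
  mt <- mu * t
  u <- stats::runif(1) * pab
  n <- -1L
  acc <- 0
  cap <- max(50, ceiling(mt + 10 * sqrt(mt) + 20))
  lpois <- -mt
  repeat {
    n <- n + 1L
    w <- exp(lpois + n * log(mt) - lgamma(n + 1)) * rpow(n)[a, b]
    acc <- acc + w
    if (acc >= u || n >= cap) break
  }
  if (n == 0) return(list(states = a, times = numeric(0)))
  times <- sort(stats::runif(n)) * t
  states <- integer(n + 1)
  states[1] <- a; states[n + 1] <- b
  if (n > 1) {
    for (m in 1:(n - 1)) {
      pr <- R[states[m], ] * rpow(n - m)[, b]
      states[m + 1] <- sample.int(k, 1, prob = pr)
    }
  }
  # drop virtual (self) jumps
  keep <- c(TRUE, states[-1] != states[-(n + 1)])
  list(states = states[keep], times = times[keep[-1]])
}

#' Sample complete character histories (stochastic character mapping)
#'
#' Node states are drawn from their joint conditional distribution by a
#' down-pass over the pruning partials; branch paths are then drawn
#' endpoint-conditioned by uniformization (exact, robust on long branches
#' and rare endpoint pairs).
#'
#' @inheritParams node_marginals
#' @param nsim number of histories.
#' @param seed optional integer seed (identical seeds reproduce identical
#'   histories).
#' @return List of `simmap_history` objects. Each carries the (postorder)
#'   tree, sampled `states` at every node, and an `events` matrix (edge,
#'   time offset from the parent end, from, to, as state indices); per-edge
#'   dwell maps are reconstructed on demand by [history_maps()].
#' @export
sample_histories <- function(tree, data, Q, root = "equal", nsim = 1,
                             seed = NULL) {
  stopifnot(nsim >= 1)
  sd <- simmap_details(tree, data, Q, root)
  env <- sd$env; det <- sd$det
  states <- rownames(env$tipL)
  raw <- with_seed(seed,
    simmap_sample_cpp(env$edge, env$elen, env$ntip, env$nnode, det$D,
                      det$P, sd$rootw, unclass(sd$Q), nsim))
  lapply(raw, function(r)
    structure(list(tree = env$tree,
                   states = stats::setNames(states[r$states],
                                            seq_along(r$states)),
                   maps = NULL,
                   events = r$events,
                   state_space = states),
              class = "simmap_history"))
}

#' Per-edge dwell maps of a character history
#'
#' Named duration vectors (state labels, parent end first) for every edge,
#' reconstructed from the event list when not stored.
#'
#' @param h a `simmap_history`.
#' @return List over edges of named numeric dwell-duration vectors.
#' @export
history_maps <- function(h) {
  if (!is.null(h$maps)) return(h$maps)
  tr <- h$tree
  ne <- nrow(tr$edge)
  sidx <- match(h$states, h$state_space)
  maps <- vector("list", ne)
  evedge <- h$events[, "edge"]
  for (e in seq_len(ne)) {
    rows <- which(evedge == e)
    tlen <- tr$edge.length[e]
    if (length(rows) == 0) {
      maps[[e]] <- stats::setNames(tlen,
                                   h$state_space[sidx[tr$edge[e, 1]]])
    } else {
      rows <- rows[order(h$events[rows, "time"])]
      bounds <- c(0, h$events[rows, "time"], tlen)
      labs <- h$state_space[c(h$events[rows, "from"],
                              h$events[rows[length(rows)], "to"])]
      maps[[e]] <- stats::setNames(diff(bounds), labs)
    }
  }
  maps
}

#' @export
print.simmap_history <- function(x, ...) {
  cat("Stochastic character map:", length(x$tree$tip.label), "tips,",
      nrow(x$events), "transition event(s)\n")
  invisible(x)
}

history_count_matrix <- function(h) {
  k <- length(h$state_space)
  C <- matrix(0L, k, k, dimnames = list(h$state_space, h$state_space))
  if (nrow(h$events))
    for (i in seq_len(nrow(h$events)))
      C[h$events[i, "from"], h$events[i, "to"]] <-
        C[h$events[i, "from"], h$events[i, "to"]] + 1L
  C
}

history_event_ages <- function(h) {
  # ages (Ma before present) of each event
  if (nrow(h$events) == 0) return(numeric(0))
  depth <- ape::node.depth.edgelength(h$tree)
  height <- max(depth[seq_along(h$tree$tip.label)])
  page <- height - depth[h$tree$edge[h$events[, "edge"], 1]]
  page - h$events[, "time"]
}

#' Summarize sampled character histories
#'
#' Transition-count posteriors, node-state frequencies, and transition
#' counts through geological time.
#'
#' @param histories list of `simmap_history` objects.
#' @param bins time-bin edges in Ma (ascending); default 10-Myr bins from
#'   the present back past the root age.
#' @return Object of class `simmap_summary`: `counts` (per-history count
#'   array), `count_summary` (mean, median and 90% credible interval per
#'   transition type), `node_freq` (state frequencies per node across
#'   histories), `bin_counts` (mean transitions per type per bin),
#'   `bins`.
#' @export
summarize_histories <- function(histories, bins = NULL) {
  if (length(histories) == 0) stop("no histories supplied")
  h1 <- histories[[1]]
  k <- length(h1$state_space)
  depth <- ape::node.depth.edgelength(h1$tree)
  height <- max(depth[seq_along(h1$tree$tip.label)])
  if (is.null(bins)) bins <- seq(0, 10 * ceiling(height / 10), by = 10)
  if (any(diff(bins) <= 0)) stop("bin edges must be strictly increasing")
  nh <- length(histories)
  counts <- array(0L, c(nh, k, k),
                  dimnames = list(NULL, h1$state_space, h1$state_space))
  nbin <- length(bins) - 1
  binc <- array(0, c(k, k, nbin))
  ntot <- length(h1$tree$tip.label) + h1$tree$Nnode
  freq <- matrix(0, k, ntot, dimnames = list(h1$state_space, seq_len(ntot)))
  for (i in seq_len(nh)) {
    h <- histories[[i]]
    counts[i, , ] <- history_count_matrix(h)
    si <- match(h$states, h1$state_space)
    freq[cbind(si, seq_len(ntot))] <- freq[cbind(si, seq_len(ntot))] + 1
    ages <- history_event_ages(h)
    if (length(ages)) {
      bi <- findInterval(ages, bins, rightmost.closed = TRUE)
      ok <- bi >= 1 & bi <= nbin
      if (any(ok)) {
        idx <- cbind(h$events[ok, "from"], h$events[ok, "to"], bi[ok])
        for (r in seq_len(nrow(idx)))
          binc[idx[r, 1], idx[r, 2], idx[r, 3]] <-
            binc[idx[r, 1], idx[r, 2], idx[r, 3]] + 1
      }
    }
  }
  freq <- freq / nh
  pairs <- which(matrix(TRUE, k, k) & !diag(k), arr.ind = TRUE)
  cs <- data.frame(
    from = h1$state_space[pairs[, 1]], to = h1$state_space[pairs[, 2]],
    mean = apply(counts, c(2, 3), mean)[pairs],
    median = apply(counts, c(2, 3), stats::median)[pairs],
    q5 = apply(counts, c(2, 3), stats::quantile, 0.05)[pairs],
    q95 = apply(counts, c(2, 3), stats::quantile, 0.95)[pairs])
  structure(list(counts = counts, count_summary = cs, node_freq = freq,
                 bin_counts = binc / nh, bins = bins, n = nh),
            class = "simmap_summary")
}

#' @export
print.simmap_summary <- function(x, ...) {
  cat("Summary of", x$n, "stochastic character maps\n")
  cs <- x$count_summary
  print(cs[cs$mean > 0 | cs$q95 > 0, ], row.names = FALSE, digits = 3)
  invisible(x)
}

#' Distribution of the number of origins of a state
#'
#' Counts, per history, the transitions entering the target state (or any
#' state of a target set) from outside it. A lineage re-entering the target
#' after an allowed exit counts as a new origin.
#'
#' @param histories list of `simmap_history` objects (or a single one).
#' @param target_state state label(s) defining the target set.
#' @return Object of class `origin_counts`: per-history `counts`, `median`,
#'   `map` (posterior mode), and the 5-95% interval `q5`, `q95`.
#' @export
count_origins <- function(histories, target_state) {
  if (inherits(histories, "simmap_history")) histories <- list(histories)
  ss <- histories[[1]]$state_space
  tgt <- match(target_state, ss)
  if (anyNA(tgt)) stop("target state not in state space: ",
                       paste(target_state[is.na(tgt)], collapse = ", "))
  counts <- vapply(histories, function(h) {
    if (nrow(h$events) == 0) return(0L)
    sum(!(h$events[, "from"] %in% tgt) & h$events[, "to"] %in% tgt)
  }, integer(1))
  tab <- table(counts)
  structure(list(counts = counts,
                 median = stats::median(counts),
                 map = as.integer(names(tab)[which.max(tab)]),
                 q5 = unname(stats::quantile(counts, 0.05, type = 1)),
                 q95 = unname(stats::quantile(counts, 0.95, type = 1)),
                 target = target_state),
            class = "origin_counts")
}

#' @export
print.origin_counts <- function(x, ...) {
  cat("Origins of {", paste(x$target, collapse = ", "), "}: median ",
      x$median, ", MAP ", x$map, ", 5-95% interval [", x$q5, ", ",
      x$q95, "] over ", length(x$counts), " histories\n", sep = "")
  invisible(x)
}

#' Export histories in SIMMAP-annotated Newick
#'
#' Branches carry their piecewise-constant state path as
#' `:{state,duration:state,duration}` comments, parent end first.
#'
#' @param histories a `simmap_history` or list of them.
#' @param path output file (one tree per line).
#' @export
write_simmap <- function(histories, path) {
  if (inherits(histories, "simmap_history")) histories <- list(histories)
  lines <- vapply(histories, function(h) {
    tr <- h$tree
    h$maps <- history_maps(h)
    ntip <- length(tr$tip.label)
    edge_of <- integer(ntip + tr$Nnode)
    edge_of[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
    kids <- split(tr$edge[, 2], tr$edge[, 1])
    rec <- function(node) {
      lab <- if (node <= ntip) tr$tip.label[node] else ""
      inner <- if (node > ntip)
        paste0("(", paste(vapply(kids[[as.character(node)]], rec, ""),
                          collapse = ","), ")")
      else ""
      ann <- ""
      if (edge_of[node] > 0) {
        m <- h$maps[[edge_of[node]]]
        ann <- paste0(":{", paste(sprintf("%s,%.10g", names(m), m),
                                  collapse = ":"), "}")
      }
      paste0(inner, lab, ann)
    }
    paste0(rec(ntip + 1), ";")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
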