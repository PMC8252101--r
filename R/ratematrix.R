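#' Constraints on a CTMC rate matrix
#'
#' A constraint set lists forbidden ordered transitions (their rates are
#' fixed to exactly zero) and equality classes of off-diagonal cells that
#' share one free parameter. Cells are written `"FROM->TO"`.
#'
#' @param forbidden two-column matrix/data.frame of (from, to) state labels,
#'   or a character vector of `"FROM->TO"` cells, or `NULL`.
#' @param equal list of character vectors of `"FROM->TO"` cells; the cells
#'   of one vector share a parameter.
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(forbidden = NULL, equal = NULL) {
  fb <- character(0)
  if (!is.null(forbidden)) {
    if (is.matrix(forbidden) || is.data.frame(forbidden)) {
      fb <- paste0(as.character(forbidden[, 1]), "->",
                   as.character(forbidden[, 2]))
    } else fb <- as.character(forbidden)
  }
  eq <- lapply(if (is.null(equal)) list() else equal, as.character)
  overlap <- intersect(fb, unlist(eq))
  if (length(overlap))
    stop("cells both forbidden and in an equality class: ",
         paste(overlap, collapse = ", "))
  structure(list(forbidden = unique(fb), equal = eq),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("Constraint set:", length(x$forbidden), "forbidden cell(s),",
      length(x$equal), "equality class(es)\n")
  if (length(x$forbidden)) cat("  forbidden:",
                               paste(x$forbidden, collapse = ", "), "\n")
  invisible(x)
}

#' Read a constraint file
#'
#' One forbidden transition per line as `from_state<TAB>to_state`; lines
#' starting with `=` declare an equality class of whitespace-separated
#' `FROM->TO` cells; `#` starts a comment.
#'
#' @param path file path.
#' @return A [constraint_set()].
#' @export
read_constraints <- function(path) {
  if (!file.exists(path)) stop("constraint file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fb <- character(0); eq <- list()
  for (ln in lines) {
    if (startsWith(ln, "=")) {
      cells <- strsplit(trimws(sub("^=", "", ln)), "[[:space:]]+")[[1]]
      if (length(cells) < 2) stop("equality class needs >= 2 cells: ", ln)
      eq[[length(eq) + 1]] <- cells
    } else {
      parts <- strsplit(ln, "\t")[[1]]
      if (length(parts) != 2)
        stop("expected 'from<TAB>to', got: ", ln)
      fb <- c(fb, paste0(parts[1], "->", parts[2]))
    }
  }
  constraint_set(fb, eq)
}

cell_labels <- function(states) {
  k <- length(states)
  outer(states, states, function(a, b) paste0(a, "->", b))
}

# Integer k x k matrix: 0 on diagonal and forbidden cells, parameter index
# 1..p elsewhere (shared indices for equality classes and for ER/SYM).
param_index <- function(states, model = c("ARD", "ER", "SYM", "custom"),
                        constraints = NULL) {
  model <- match.arg(model)
  k <- length(states)
  if (k < 2) stop("degenerate state space (fewer than 2 states)")
  if (anyDuplicated(states)) stop("duplicate state labels")
  lab <- cell_labels(states)
  idx <- matrix(0L, k, k, dimnames = list(states, states))
  off <- which(row(idx) != col(idx))
  base <- switch(model,
    ER = { idx[off] <- 1L; idx },
    SYM = { m <- matrix(0L, k, k); c <- 0L
            for (i in 1:(k - 1)) for (j in (i + 1):k) {
              c <- c + 1L; m[i, j] <- c; m[j, i] <- c }
            dimnames(m) <- list(states, states); m },
    { idx[off] <- seq_along(off); idx }  # ARD and custom start saturated
  )
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_set"))
    all_cells <- lab[off]
    unknown <- setdiff(c(constraints$forbidden, unlist(constraints$equal)),
                       all_cells)
    if (length(unknown))
      stop("constraint references unknown or diagonal cell(s): ",
           paste(unknown, collapse = ", "))
    for (cell in constraints$forbidden) base[lab == cell] <- 0L
    for (cls in constraints$equal) {
      ids <- unique(base[match(cls, lab)])
      ids <- ids[ids != 0]
      if (length(ids) == 0) next
      keep <- ids[1]
      base[base %in% ids] <- keep
    }
  }
  # renumber contiguously
  ids <- sort(unique(base[base > 0]))
  base[] <- match(base, ids, nomatch = 0L) * (base > 0)
  storage.mode(base) <- "integer"
  base
}

#' Build a constrained CTMC rate matrix
#'
#' Constructs the generator Q over a state space under a named model
#' (`ER` one rate, `SYM` symmetric, `ARD` all rates different, `custom`
#' same as ARD before constraints) plus an optional [constraint_set()].
#' Forbidden cells are exactly zero; equality-class cells share one free
#' parameter; the diagonal is the negative row sum.
#'
#' @param states ordered state labels.
#' @param model `"ER"`, `"SYM"`, `"ARD"` or `"custom"`.
#' @param constraints optional [constraint_set()].
#' @param values vector of free-parameter values (events per Myr), length
#'   [n_params()]; recycled if length 1.
#' @return Object of class `rate_matrix`: the k x k generator with
#'   attributes `index` (parameter map), `states`, `constraints`.
#' @export
build_q <- function(states, model = c("ARD", "ER", "SYM", "custom"),
                    constraints = NULL, values = NULL) {
  model <- match.arg(model)
  idx <- param_index(states, model, constraints)
  p <- max(idx)
  if (is.null(values)) values <- rep(0.1, p)
  if (length(values) == 1 && p > 1) values <- rep(values, p)
  if (length(values) != p)
    stop("expected ", p, " parameter value(s), got ", length(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop("rates must be finite and nonnegative")
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  Q[idx > 0] <- values[idx[idx > 0]]
  diag(Q) <- -rowSums(Q)
  structure(Q, index = idx, states = states, constraints = constraints,
            class = c("rate_matrix", "matrix"))
}

#' Number of free parameters of a rate matrix or parameter map
#' @param x a `rate_matrix` or an integer index matrix.
#' @export
n_params <- function(x) {
  idx <- if (inherits(x, "rate_matrix")) attr(x, "index") else x
  max(0L, max(idx))
}

#' @export
print.rate_matrix <- function(x, digits = 4, ...) {
  cat("Rate matrix (", nrow(x), " states, ", n_params(x),
      " free parameters)\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

as_q_matrix <- function(Q, states = NULL) {
  if (inherits(Q, "rate_matrix")) return(Q)
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  if (is.null(rownames(Q)))
    rownames(Q) <- colnames(Q) <-
      if (!is.null(states)) states else as.character(seq_len(nrow(Q)))
  if (max(abs(rowSums(Q))) > 1e-8) stop("Q rows must sum to 0")
  structure(Q, states = rownames(Q), class = c("rate_matrix", "matrix"))
}

#' Transition probabilities P(t) = exp(Qt)
#'
#' @param Q a generator matrix (rows sum to zero).
#' @param t nonnegative duration (Myr).
#' @return Row-stochastic matrix.
#' @export
transition_probs <- function(Q, t) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("t must be a single nonnegative number")
  Q <- as_q_matrix(Q)
  P <- expm_q_cpp(unclass(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

# reachability closure over the off-diagonal support
q_irreducible <- function(Q) {
  k <- nrow(Q)
  A <- (unclass(Q) > 0) | diag(k)
  R <- A
  for (i in seq_len(k)) R <- (R %*% A) > 0 | R
  all(R)
}

#' Stationary distribution of an irreducible generator
#'
#' Solves pi Q = 0 with pi on the simplex. Reducible chains (e.g. with an
#' absorbing mycoheterotrophic state) have no unique stationary law; an
#' error directs the caller to an equal or fixed root prior instead.
#'
#' @param Q a generator matrix.
#' @return Numeric simplex named by states.
#' @export
stationary_dist <- function(Q) {
  Q <- as_q_matrix(Q)
  if (!q_irreducible(Q))
    stop("Q is reducible (e.g. an absorbing state); stationary ",
         "distribution undefined - use an equal or fixed root prior")
  k <- nrow(Q)
  A <- rbind(t(unclass(Q)), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi[pi < 0 & pi > -1e-12] <- 0
  if (any(pi < 0)) stop("negative stationary weight; Q invalid")
  stats::setNames(pi / sum(pi), rownames(Q))
}
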