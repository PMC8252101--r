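#' Read and validate a dated phylogeny
#'
#' Reads a rooted, dated tree in Newick or NEXUS format (branch lengths in
#' Myr), validates its structure and annotates it with node ages and an
#' ultrametricity flag. Polytomies are preserved.
#'
#' @param path path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @param ultra_tol relative ultrametricity tolerance, as a fraction of tree
#'   height. Dated empirical trees carry rounding noise, so the default is
#'   permissive (`1e-6`).
#' @return An object of class `phylo` with attributes `height` (root age,
#'   Myr), `node_depth` (root-to-node path lengths), `node_age` (Myr before
#'   present) and `ultrametric` (logical).
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2):0;", tf)
#' tr <- read_tree(tf)
#' attr(tr, "ultrametric")
#' @export
read_tree <- function(path, format = c("newick", "nexus"), ultra_tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- tryCatch(
    if (format == "newick") ape::read.tree(path) else ape::read.nexus(path),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tr)) stop("failed to parse ", format, " file '", path, "'")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) == 0) stop("no trees in file '", path, "'")
    tr <- tr[[1]]
  }
  validate_tree(tr, ultra_tol = ultra_tol)
}

#' Validate a phylogeny and annotate ages
#'
#' Checks the invariants required by all downstream analyses: single root,
#' unique tip labels, branch lengths present and nonnegative. Stores node
#' depths, node ages (Myr before present, root age = tree height) and the
#' outcome of the ultrametricity check as attributes.
#'
#' @param tree an object of class `phylo`.
#' @inheritParams read_tree
#' @return The annotated tree.
#' @export
validate_tree <- function(tree, ultra_tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and nonnegative")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least 2 tips")
  # exactly one root: every node but one has one parent
  parents <- tabulate(tree$edge[, 2], nbins = ntip + tree$Nnode)
  if (any(parents > 1)) stop("node with more than one parent")
  if (sum(parents == 0) != 1) stop("tree must have exactly one root")
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ntip)])
  ultra <- if (height == 0) TRUE else
    all(abs(depth[seq_len(ntip)] - height) <= ultra_tol * height)
  attr(tree, "height") <- height
  attr(tree, "node_depth") <- depth
  attr(tree, "node_age") <- height - depth
  attr(tree, "ultrametric") <- ultra
  tree
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param path output file path (UTF-8).
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

tree_height <- function(tree) {
  h <- attr(tree, "height")
  if (is.null(h)) h <- max(ape::node.depth.edgelength(tree)[
    seq_len(length(tree$tip.label))])
  h
}

is_ultrametric_tree <- function(tree, ultra_tol = 1e-6) {
  u <- attr(tree, "ultrametric")
  if (is.null(u)) u <- attr(validate_tree(tree, ultra_tol), "ultrametric")
  isTRUE(u)
}

#' Align a tree and a trait dataset to a common species set
#'
#' @param tree a `phylo` object.
#' @param data a [trait_dataset()] (or named vector coercible to one).
#' @param policy `"intersect"` prunes both objects to the shared species
#'   (pruning preserves branch-length sums along retained paths);
#'   `"error"` requires identical name sets.
#' @return `list(tree = , data = )` with matching species.
#' @export
align_tree_and_traits <- function(tree, data, policy = c("intersect", "error")) {
  policy <- match.arg(policy)
  data <- as_trait_dataset(data)
  shared <- intersect(tree$tip.label, names(data$tips))
  if (length(shared) == 0) stop("no species shared between tree and traits")
  if (policy == "error") {
    if (!setequal(tree$tip.label, names(data$tips)))
      stop("tree tips and trait species differ (policy = 'error'); ",
           length(setdiff(tree$tip.label, names(data$tips))), " tree-only, ",
           length(setdiff(names(data$tips), tree$tip.label)), " trait-only")
  }
  if (!setequal(tree$tip.label, shared)) {
    if (length(shared) < 2)
      stop("fewer than 2 shared species; cannot prune tree")
    tree <- validate_tree(ape::keep.tip(tree, shared))
  }
  data$tips <- data$tips[tree$tip.label]
  list(tree = tree, data = data)
}

#' Pagel's lambda branch-length transform for a dated tree
#'
#' Multiplies internal branch lengths by `lambda` and extends each terminal
#' branch so that every root-to-tip depth keeps its original value. At
#' `lambda = 1` the tree is returned unchanged; at `lambda = 0` all internal
#' structure collapses (a star-like tree in expectation).
#'
#' @param tree an ultrametric `phylo` object.
#' @param lambda a real in `[0, 1]`.
#' @return The transformed tree (same topology, same tip depths).
#' @export
lambda_transform <- function(tree, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  tree <- validate_tree(tree)
  if (!is_ultrametric_tree(tree))
    stop("lambda transform requires an ultrametric tree ",
         "(tip-depth preservation is undefined otherwise)")
  if (lambda == 1) return(tree)
  ntip <- length(tree$tip.label)
  depth <- attr(tree, "node_depth")
  is_term <- tree$edge[, 2] <= ntip
  el <- tree$edge.length
  el[!is_term] <- el[!is_term] * lambda
  # terminal branch = tip depth - lambda * parent depth
  pd <- depth[tree$edge[is_term, 1]]
  el[is_term] <- depth[tree$edge[is_term, 2]] - lambda * pd
  tree$edge.length <- el
  validate_tree(tree)
}
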