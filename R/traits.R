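#' Discrete trait dataset over a declared state space
#'
#' Species map to nonempty subsets of the state space: a singleton is a known
#' state, a larger subset encodes ambiguity, the full set means missing.
#'
#' @param x a named character vector of states (ambiguity encoded as
#'   `"state1|state2"`), or a named list of character vectors.
#' @param state_space ordered character vector of state labels; defaults to
#'   the sorted union of observed states.
#' @return An object of class `trait_dataset` with elements `states` and
#'   `tips` (named list of character subsets).
#' @examples
#' td <- trait_dataset(c(sp1 = "AU", sp2 = "MH", sp3 = "AU|PMH"),
#'                     state_space = c("AU", "PMH", "MH"))
#' @export
trait_dataset <- function(x, state_space = NULL) {
  if (is.factor(x)) x <- stats::setNames(as.character(x), names(x))
  if (is.character(x)) {
    if (is.null(names(x))) stop("trait vector must be named by species")
    tips <- strsplit(x, "|", fixed = TRUE)
    names(tips) <- names(x)
  } else if (is.list(x)) {
    tips <- lapply(x, as.character)
  } else stop("unsupported trait input")
  if (anyDuplicated(names(tips)))
    stop("duplicate species names in trait data")
  if (any(lengths(tips) == 0) || any(vapply(tips, function(s)
    any(is.na(s) | s == ""), logical(1))))
    stop("every species must map to a nonempty set of states")
  obs <- unique(unlist(tips))
  if (is.null(state_space)) state_space <- sort(obs)
  bad <- setdiff(obs, state_space)
  if (length(bad))
    stop("states outside the declared state space: ",
         paste(bad, collapse = ", "))
  structure(list(states = as.character(state_space), tips = tips),
            class = "trait_dataset")
}

as_trait_dataset <- function(x, state_space = NULL) {
  if (inherits(x, "trait_dataset")) x else trait_dataset(x, state_space)
}

#' @export
print.trait_dataset <- function(x, ...) {
  cat("Trait dataset:", length(x$tips), "species,",
      length(x$states), "states (", paste(x$states, collapse = ", "), ")\n")
  amb <- sum(lengths(x$tips) > 1)
  if (amb) cat(" ", amb, "species with ambiguous state\n")
  tab <- table(factor(unlist(x$tips[lengths(x$tips) == 1]),
                      levels = x$states))
  print(tab)
  invisible(x)
}

#' Read / write trait tables
#'
#' TSV with header `species<TAB>state`; ambiguity encoded as
#' `state1|state2`.
#'
#' @param path file path.
#' @param state_space optional ordered state labels.
#' @return A [trait_dataset()].
#' @export
read_trait_tsv <- function(path, state_space = NULL) {
  if (!file.exists(path)) stop("trait file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("trait table needs columns species, state")
  trait_dataset(stats::setNames(df[[2]], df[[1]]), state_space)
}

#' @rdname read_trait_tsv
#' @param data a [trait_dataset()].
#' @export
write_trait_tsv <- function(data, path) {
  data <- as_trait_dataset(data)
  df <- data.frame(species = names(data$tips),
                   state = vapply(data$tips, paste, "", collapse = "|"),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# k x ntip 0/1 conditional likelihood matrix in tree tip order
tip_partials <- function(data, tree) {
  data <- as_trait_dataset(data)
  k <- length(data$states)
  miss <- setdiff(tree$tip.label, names(data$tips))
  if (length(miss))
    stop("species missing from trait data (align first): ",
         paste(utils::head(miss, 5), collapse = ", "))
  L <- matrix(0, k, length(tree$tip.label),
              dimnames = list(data$states, tree$tip.label))
  for (i in seq_along(tree$tip.label))
    L[data$tips[[tree$tip.label[i]]], i] <- 1
  L
}
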