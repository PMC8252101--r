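# The coupled-character hypothesis suite: seven constrained ARD models over
# the five-state trophic-by-association character, compared by BIC.

suite_expected_k <- c("free" = 20L, "model1" = 16L, "model2" = 16L,
                      "model3" = 16L, "model4" = 15L, "model5" = 12L,
                      "model6" = 11L)

#' The coupled-character model suite
#'
#' Seven ARD models over the five coupled states (`AU-R`, `AU-ES`,
#' `AU-RES`, `MH-RES`, `MH-ES`): the free model (20 parameters) and six
#' nested constrained models restricting how lineages enter and leave full
#' mycoheterotrophy (16, 16, 16, 15, 12, 11 parameters). Models 4 and 6
#' implement the published verbal descriptions (entry to mycoheterotrophy
#' requires the mixed association as obligate intermediate; reversals occur
#' only from the mixed association); the constraint sets of models 1, 2, 3
#' and 5 are bundled reconstructions constrained to the published
#' parameter counts. Constraint sets are data (editable text files, one
#' forbidden transition per line), not code; the load-time parameter-count
#' assertion guards against drift.
#'
#' @param dir directory of constraint files (default: the bundled set).
#' @return Named list of models, each `list(name, states, constraints,
#'   expected_k)`.
#' @export
model_suite <- function(dir = NULL) {
  if (is.null(dir))
    dir <- system.file("extdata", "models", package = "mycotroph",
                       mustWork = TRUE)
  states <- coupled_states()
  out <- lapply(names(suite_expected_k), function(nm) {
    path <- file.path(dir, paste0(nm, ".txt"))
    cs <- read_constraints(path)
    k <- n_params(param_index(states, "ARD", cs))
    if (k != suite_expected_k[[nm]])
      stop("constraint file ", path, " implies ", k,
           " free parameters; expected ", suite_expected_k[[nm]],
           " (the published count)")
    list(name = nm, states = states, constraints = cs,
         expected_k = suite_expected_k[[nm]])
  })
  stats::setNames(out, names(suite_expected_k))
}

#' Fit the hypothesis suite and select by BIC
#'
#' Fits every model of the suite to the coupled five-state data by maximum
#' likelihood, computes `BIC = -2 logL + k ln(n)` with `n` the number of
#' analysed tip species, and selects the lowest-BIC model (ties broken by
#' fewest parameters, then name order). Models whose optimisation did not
#' converge are flagged and excluded from selection. Stepping-stone
#' marginal likelihoods can be added as an extra column.
#'
#' @param tree a `phylo`.
#' @param data coupled-character [trait_dataset()] (aligned to the tree, or
#'   alignable by intersection).
#' @param suite a [model_suite()].
#' @param root,starts,seed passed to [fit_mk()].
#' @param marginal also compute stepping-stone log marginal likelihoods.
#' @param ss_args list of arguments for [stepping_stone()].
#' @return Object of class `model_comparison`: a report `table` (model,
#'   k, loglik, BIC, sorted by BIC), `selected` (model name), `fits`, `n`.
#' @export
fit_model_suite <- function(tree, data, suite = model_suite(),
                            root = "equal", starts = 5, seed = NULL,
                            marginal = FALSE, ss_args = list()) {
  data <- as_trait_dataset(data)
  al <- align_tree_and_traits(tree, data)
  n <- length(al$tree$tip.label)
  fits <- lapply(suite, function(m)
    tryCatch(fit_mk(al$tree, al$data, model = "ARD",
                    constraints = m$constraints, root = root,
                    starts = starts, seed = seed),
             error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, what = "error")
  tab <- data.frame(
    model = names(suite),
    k = vapply(suite, function(m) m$expected_k, 0L),
    loglik = vapply(fits, function(f)
      if (inherits(f, "error")) NA_real_ else f$loglik, 0),
    converged = vapply(fits, function(f)
      if (inherits(f, "error")) FALSE else f$converged, TRUE),
    stringsAsFactors = FALSE)
  tab$BIC <- bic(tab$loglik, tab$k, n)
  if (marginal) {
    tab$log_ml <- vapply(seq_along(suite), function(i) {
      m <- suite[[i]]
      do.call(stepping_stone,
              c(list(al$tree, al$data, model = "ARD",
                     constraints = m$constraints, root = root), ss_args)
      )$log_ml
    }, 0)
  }
  elig <- which(tab$converged & is.finite(tab$BIC))
  if (length(elig) == 0) stop("no model converged; nothing to select")
  if (!all(tab$converged))
    warning("model(s) excluded from selection (not converged): ",
            paste(tab$model[!tab$converged], collapse = ", "))
  ord <- elig[order(tab$BIC[elig], tab$k[elig], tab$model[elig])]
  selected <- tab$model[ord[1]]
  tab <- tab[order(tab$BIC), ]
  rownames(tab) <- NULL
  structure(list(table = tab, selected = selected, fits = fits, n = n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Coupled-character model comparison (n =", x$n, "species)\n\n")
  tab <- x$table
  disp <- data.frame(
    Model = tab$model,
    `No. of parameters` = tab$k,
    `Log L` = sprintf("%.2f", tab$loglik),
    BIC = sprintf("%.2f", tab$BIC),
    check.names = FALSE)
  if (!is.null(tab$log_ml)) disp$`Log ML` <- sprintf("%.2f", tab$log_ml)
  disp$` ` <- ifelse(tab$model == x$selected, "<- selected",
                     ifelse(tab$converged, "", "(not converged)"))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Export a model-comparison report
#'
#' @param x a `model_comparison`.
#' @param path output path; `.json` writes JSON, anything else TSV.
#' @export
write_model_report <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(n = x$n, selected = x$selected,
                              table = x$table),
                         path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
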