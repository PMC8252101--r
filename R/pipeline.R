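# End-to-end orchestration: each stage reads files, runs the corresponding
# analysis, writes outputs plus a JSON run manifest into a fixed directory
# layout (coded/, fits/, simmap/, mcmc/, reports/).

#' Assemble a pipeline run configuration
#'
#' @param tree path to a dated tree (Newick).
#' @param presence path to the species-by-family presence TSV.
#' @param trophic path to the trophic table TSV.
#' @param out output directory.
#' @param character `"trophic"`, `"association"` or `"coupled"`.
#' @param definition `"strict"` or `"relaxed"` partial-mycoheterotrophy
#'   rule.
#' @param seed integer seed (mandatory for stochastic stages).
#' @param ... further stage options stored verbatim.
#' @export
run_config <- function(tree = NULL, presence = NULL, trophic = NULL,
                       out = "mycotroph_out",
                       character = c("coupled", "trophic", "association"),
                       definition = c("strict", "relaxed"), seed = NULL,
                       ...) {
  structure(list(tree = tree, presence = presence, trophic = trophic,
                 out = out, character = match.arg(character),
                 definition = match.arg(definition), seed = seed, ...),
            class = "run_config")
}

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing input: ", what, " (", if (is.null(path)) "unset"
         else path, ")")
  path
}

pipe_log <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%OS1"), paste0(...)))
}

write_manifest <- function(cfg, stage, outdir, extra = list()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- unclass(cfg)
  tmp <- tempfile()
  saveRDS(cfg_plain, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    c(list(stage = stage,
           package_version = as.character(utils::packageVersion(
             "mycotroph")),
           config = cfg_plain, config_md5 = hash), extra),
    file.path(outdir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(hash)
}

#' Pipeline stage: code traits from raw tables
#'
#' Reads the presence matrix and trophic table, applies family filtering
#' and the lifestyle map, and writes the coded trophic, association and
#' coupled characters as TSV under `out/coded/`.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list of the coded datasets.
#' @export
pipeline_code <- function(cfg) {
  pres <- read_presence_tsv(require_file(cfg$presence, "presence matrix"))
  tro <- utils::read.delim(require_file(cfg$trophic, "trophic table"),
                           sep = "\t")
  if (nrow(tro) == 0 || length(pres$species) == 0)
    stop("empty input tables")
  outdir <- file.path(cfg$out, "coded")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  filt <- filter_families(pres)
  rem <- attr(filt, "removed")
  if (nrow(rem)) pipe_log("WARN", nrow(rem), " fungal families removed")
  assoc <- withCallingHandlers(
    association_dataset(filt, coding = "collapsed"),
    warning = function(w) { pipe_log("WARN", conditionMessage(w))
      invokeRestart("muffleWarning") })
  assoc_full <- suppressWarnings(association_dataset(filt,
                                                     coding = "subset"))
  troph <- trophic_dataset(tro, definition = cfg$definition)
  coupled <- withCallingHandlers(
    couple_dataset(troph, assoc),
    warning = function(w) { pipe_log("WARN", conditionMessage(w))
      invokeRestart("muffleWarning") })
  write_trait_tsv(troph, file.path(outdir, "trophic.tsv"))
  write_trait_tsv(assoc, file.path(outdir, "association.tsv"))
  write_trait_tsv(assoc_full, file.path(outdir, "association_subsets.tsv"))
  write_trait_tsv(coupled, file.path(outdir, "coupled.tsv"))
  utils::write.table(rem, file.path(outdir, "removed_families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "code", cfg$out,
                 list(n_species = length(pres$species),
                      n_families_kept = length(filt$families)))
  invisible(list(trophic = troph, association = assoc, coupled = coupled))
}

coded_dataset <- function(cfg) {
  path <- file.path(cfg$out, "coded", paste0(cfg$character, ".tsv"))
  space <- switch(cfg$character,
                  trophic = c("AU", "PMH", "MH"),
                  association = c("R", "ES", "RES"),
                  coupled = coupled_states())
  read_trait_tsv(require_file(path, "coded character (run code first)"),
                 space)
}

#' Pipeline stage: maximum-likelihood Mk fit
#'
#' @param cfg a [run_config()]; honours `cfg$model` (default `"ARD"`).
#' @export
pipeline_fit <- function(cfg) {
  tree <- read_tree(require_file(cfg$tree, "tree"))
  data <- coded_dataset(cfg)
  al <- align_tree_and_traits(tree, data)
  model <- if (is.null(cfg$model)) "ARD" else cfg$model
  fit <- fit_mk(al$tree, al$data, model = model, seed = cfg$seed)
  outdir <- file.path(cfg$out, "fits")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(character = cfg$character, model = model,
         loglik = fit$loglik, k_params = fit$k_params,
         bic = bic(fit$loglik, fit$k_params, fit$ntip),
         converged = fit$converged, rates = as.list(fit$rates)),
    file.path(outdir, paste0("fit_", cfg$character, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(cfg, "fit", cfg$out)
  invisible(fit)
}

#' Pipeline stage: Pagel's lambda signal test
#' @param cfg a [run_config()].
#' @export
pipeline_lambda <- function(cfg) {
  tree <- read_tree(require_file(cfg$tree, "tree"))
  data <- coded_dataset(cfg)
  al <- align_tree_and_traits(tree, data)
  lf <- fit_lambda(al$tree, al$data, seed = cfg$seed)
  outdir <- file.path(cfg$out, "fits")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(character = cfg$character, lambda = lf$lambda,
         loglik = lf$loglik, loglik0 = lf$loglik0, loglik1 = lf$loglik1,
         flat = lf$flat),
    file.path(outdir, paste0("lambda_", cfg$character, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(cfg, "lambda", cfg$out)
  invisible(lf)
}

#' Pipeline stage: stochastic character mapping
#'
#' Fits the model (or uses `cfg$model`), samples `cfg$nsim` histories
#' (default 100) and writes transition summaries, origin counts and the
#' SIMMAP export under `out/simmap/`.
#' @param cfg a [run_config()]; `cfg$seed` is mandatory.
#' @export
pipeline_simmap <- function(cfg) {
  if (is.null(cfg$seed)) stop("seed is mandatory for simmap")
  tree <- read_tree(require_file(cfg$tree, "tree"))
  data <- coded_dataset(cfg)
  al <- align_tree_and_traits(tree, data)
  model <- if (is.null(cfg$model)) "ARD" else cfg$model
  fit <- fit_mk(al$tree, al$data, model = model, seed = cfg$seed)
  nsim <- if (is.null(cfg$nsim)) 100 else cfg$nsim
  hs <- sample_histories(al$tree, al$data, fit$Q, nsim = nsim,
                         seed = cfg$seed)
  sm <- summarize_histories(hs)
  outdir <- file.path(cfg$out, "simmap")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(sm$count_summary,
                     file.path(outdir, "transition_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_simmap(hs[seq_len(min(10, length(hs)))],
               file.path(outdir, "histories.simmap.nwk"))
  org <- if (cfg$character == "trophic") count_origins(hs, "MH")
  else if (cfg$character == "coupled")
    count_origins(hs, c("MH-RES", "MH-ES")) else NULL
  if (!is.null(org))
    jsonlite::write_json(
      list(median = org$median, map = org$map, q5 = org$q5,
           q95 = org$q95),
      file.path(outdir, "mh_origins.json"), auto_unbox = TRUE,
      digits = NA)
  write_manifest(cfg, "simmap", cfg$out, list(nsim = nsim))
  invisible(list(fit = fit, histories = hs, summary = sm, origins = org))
}

#' Pipeline stage: MultiState MCMC
#' @param cfg a [run_config()]; honours `cfg$iterations`, `cfg$burnin`,
#'   `cfg$thinning`, `cfg$rj` (reversible jump).
#' @export
pipeline_mcmc <- function(cfg) {
  if (is.null(cfg$seed)) stop("seed is mandatory for mcmc")
  tree <- read_tree(require_file(cfg$tree, "tree"))
  data <- coded_dataset(cfg)
  al <- align_tree_and_traits(tree, data)
  config <- mcmc_config(
    iterations = if (is.null(cfg$iterations)) 110000 else cfg$iterations,
    burnin = if (is.null(cfg$burnin)) 10000 else cfg$burnin,
    thinning = if (is.null(cfg$thinning)) 100 else cfg$thinning,
    seed = cfg$seed)
  res <- if (isTRUE(cfg$rj))
    rj_mcmc(al$tree, al$data, config = config)
  else mcmc_multistate(al$tree, al$data, config = config)
  outdir <- file.path(cfg$out, "mcmc")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    data.frame(sample = seq_len(nrow(res$samples)), res$samples,
               loglik = res$loglik, check.names = FALSE),
    file.path(outdir, "trace.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(unclass(config),
                       file.path(outdir, "trace_config.json"),
                       auto_unbox = TRUE)
  write_manifest(cfg, "mcmc", cfg$out)
  invisible(res)
}

#' Pipeline stage: stepping-stone marginal likelihood
#' @param cfg a [run_config()]; honours `cfg$stones`, `cfg$ss_iters`.
#' @export
pipeline_ss <- function(cfg) {
  if (is.null(cfg$seed)) stop("seed is mandatory for ss")
  tree <- read_tree(require_file(cfg$tree, "tree"))
  data <- coded_dataset(cfg)
  al <- align_tree_and_traits(tree, data)
  ml <- stepping_stone(
    al$tree, al$data,
    stones = if (is.null(cfg$stones)) 100 else cfg$stones,
    iters = if (is.null(cfg$ss_iters)) 10000 else cfg$ss_iters,
    seed = cfg$seed)
  outdir <- file.path(cfg$out, "reports")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(log_ml = ml$log_ml, replicates = ml$replicates,
         stones = ml$stones, flags = ml$flags),
    file.path(outdir, "marginal_likelihood.json"), auto_unbox = TRUE,
    digits = NA)
  write_manifest(cfg, "ss", cfg$out)
  invisible(ml)
}

#' Pipeline stage: the coupled-character hypothesis suite
#' @param cfg a [run_config()] with `character = "coupled"`.
#' @export
pipeline_hypothesis <- function(cfg) {
  tree <- read_tree(require_file(cfg$tree, "tree"))
  cfg$character <- "coupled"
  data <- coded_dataset(cfg)
  cmp <- fit_model_suite(tree, data, seed = cfg$seed)
  outdir <- file.path(cfg$out, "reports")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_model_report(cmp, file.path(outdir, "model_comparison.tsv"))
  write_model_report(cmp, file.path(outdir, "model_comparison.json"))
  write_manifest(cfg, "hypothesis", cfg$out,
                 list(selected = cmp$selected))
  invisible(cmp)
}

#' Pipeline stage: generate a synthetic bundle
#' @param cfg a [run_config()]; `cfg$seed` mandatory, honours
#'   `cfg$n_tips`.
#' @export
pipeline_simulate <- function(cfg) {
  if (is.null(cfg$seed)) stop("seed is mandatory for simulate")
  b <- sim_orchid_like(cfg$seed,
                       n_tips = if (is.null(cfg$n_tips)) 519
                       else cfg$n_tips)
  write_bundle(b, cfg$out)
  write_manifest(cfg, "simulate", cfg$out,
                 list(realized = as.list(b$realized)))
  invisible(b)
}
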