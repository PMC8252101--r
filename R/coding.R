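#' Built-in fungal-family lifestyle map
#'
#' The 17 fungal families known to contain putative orchid mycorrhizal
#' fungi, each assigned one lifestyle: rhizoctonia-like (`RHI`;
#' Tulasnellaceae, Ceratobasidiaceae, Serendipitaceae), ectomycorrhizal
#' (`ECM`), mixed (`ECM/SAP`) or saprotrophic (`SAP`). The assignment is a
#' bundled, editable config file (`extdata/lifestyles.tsv`), not code; the
#' default `ECM/SAP` vs `SAP` split within the seven saprotroph-containing
#' families places Pezizaceae and Pyronemataceae in `ECM/SAP`.
#'
#' @param path optional path to a custom `family<TAB>lifestyle` table.
#' @return Named character vector: family -> lifestyle.
#' @export
default_lifestyles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lifestyles.tsv", package = "mycotroph",
                        mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", colClasses = "character")
  if (anyDuplicated(df$family)) stop("duplicate families in lifestyle map")
  ok <- c("RHI", "ECM", "ECM/SAP", "SAP")
  if (!all(df$lifestyle %in% ok))
    stop("unknown lifestyle label(s): ",
         paste(setdiff(df$lifestyle, ok), collapse = ", "))
  stats::setNames(df$lifestyle, df$family)
}

#' Species-by-fungal-family presence matrix
#'
#' @param presence logical or 0/1 matrix, species rows, family columns.
#' @return Object of class `fungal_matrix`.
#' @export
fungal_matrix <- function(presence) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence matrix needs species rownames and family colnames")
  if (anyDuplicated(rownames(presence))) stop("duplicate species names")
  if (anyDuplicated(colnames(presence))) stop("duplicate family names")
  mode(presence) <- "logical"
  if (any(is.na(presence))) stop("presence matrix contains NA")
  structure(list(species = rownames(presence),
                 families = colnames(presence),
                 presence = presence),
            class = "fungal_matrix")
}

#' @export
print.fungal_matrix <- function(x, ...) {
  cat("Fungal association matrix:", length(x$species), "species x",
      length(x$families), "families;",
      sum(x$presence), "presences\n")
  invisible(x)
}

#' Read a presence matrix from TSV
#'
#' Species rows, family columns, 0/1 entries; first column holds species
#' names.
#' @param path file path.
#' @export
read_presence_tsv <- function(path) {
  if (!file.exists(path)) stop("presence matrix not found: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty presence matrix: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  fungal_matrix(m > 0)
}

#' @rdname read_presence_tsv
#' @param mat a [fungal_matrix()].
#' @export
write_presence_tsv <- function(mat, path) {
  df <- data.frame(species = mat$species,
                   mat$presence + 0L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter fungal families before trait coding
#'
#' Drops families associated with at most one species (singleton records
#' carry no comparative signal), then restricts to a whitelist of families
#' with known mycorrhizal members. Every removal is recorded with its reason
#' in the `removed` attribute. Idempotent.
#'
#' @param mat a [fungal_matrix()].
#' @param retained whitelist of family names (default: the 17 built-in
#'   families of [default_lifestyles()]).
#' @param min_species minimum number of associated species to keep a family.
#' @return Filtered `fungal_matrix` with attribute `removed`
#'   (data.frame: family, reason).
#' @export
filter_families <- function(mat, retained = names(default_lifestyles()),
                            min_species = 2L) {
  stopifnot(inherits(mat, "fungal_matrix"))
  nsp <- colSums(mat$presence)
  drop_rare <- mat$families[nsp < min_species]
  drop_off <- setdiff(mat$families, c(retained, drop_rare))
  keep <- setdiff(mat$families, c(drop_rare, drop_off))
  if (length(keep) == 0)
    stop("no fungal families left after filtering")
  removed <- data.frame(
    family = c(drop_rare, drop_off),
    reason = c(rep("fewer than 2 associated species", length(drop_rare)),
               rep("not on retained whitelist", length(drop_off))),
    stringsAsFactors = FALSE)
  out <- fungal_matrix(mat$presence[, keep, drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Symbiotic-association state of one species
#'
#' Collapses a fungal-family presence vector to association flags: `R` if
#' any rhizoctonia-like family is present, `E` if any ectomycorrhizal, `S`
#' if any saprotrophic. `ECM/SAP` families set both `E` and `S` under
#' `policy = "both"`, only `S` under `"sap_only"`.
#'
#' @param row named logical/0-1 vector over families (one species).
#' @param lifestyles family -> lifestyle map.
#' @param ecm_sap_policy `"both"` or `"sap_only"`.
#' @return Character vector, a subset of `c("R","E","S")`; length zero when
#'   the species has no record among the mapped families.
#' @export
association_state <- function(row, lifestyles = default_lifestyles(),
                              ecm_sap_policy = c("both", "sap_only")) {
  ecm_sap_policy <- match.arg(ecm_sap_policy)
  fams <- names(row)[as.logical(row)]
  ls <- lifestyles[intersect(fams, names(lifestyles))]
  flags <- character(0)
  if (any(ls == "RHI")) flags <- c(flags, "R")
  if (any(ls == "ECM")) flags <- c(flags, "E")
  if (any(ls == "ECM/SAP") && ecm_sap_policy == "both")
    flags <- union(flags, "E")
  if (any(ls %in% c("SAP", "ECM/SAP"))) flags <- c(flags, "S")
  intersect(c("R", "E", "S"), unique(flags))
}

#' Code association states for a whole matrix
#'
#' @param mat a filtered [fungal_matrix()].
#' @inheritParams association_state
#' @param no_record what to do with species whose row is all-zero:
#'   `"exclude"` drops them with a warning, `"ambiguous"` keeps them fully
#'   ambiguous over the 7 nonempty subsets.
#' @param coding `"subset"` emits full subset strings (R, E, S, RE, RS, ES,
#'   RES); `"collapsed"` emits the reduced 3-level coding R / ES / RES used
#'   by the coupled character.
#' @return A [trait_dataset()].
#' @export
association_dataset <- function(mat, lifestyles = default_lifestyles(),
                                ecm_sap_policy = c("both", "sap_only"),
                                no_record = c("exclude", "ambiguous"),
                                coding = c("subset", "collapsed")) {
  no_record <- match.arg(no_record)
  coding <- match.arg(coding)
  ecm_sap_policy <- match.arg(ecm_sap_policy)
  states <- vapply(mat$species, function(sp) {
    fl <- association_state(mat$presence[sp, ], lifestyles, ecm_sap_policy)
    if (length(fl) == 0) NA_character_
    else if (coding == "subset") paste(fl, collapse = "")
    else collapse_association(fl)
  }, "")
  space <- if (coding == "subset")
    c("R", "E", "S", "RE", "RS", "ES", "RES") else c("R", "ES", "RES")
  if (anyNA(states)) {
    n0 <- sum(is.na(states))
    if (no_record == "exclude") {
      warning(n0, " species with no mycorrhizal record excluded")
      states <- states[!is.na(states)]
    } else {
      warning(n0, " species with no mycorrhizal record kept as ambiguous")
      states[is.na(states)] <- paste(space, collapse = "|")
    }
  }
  trait_dataset(states, state_space = space)
}

collapse_association <- function(flags) {
  has_r <- "R" %in% flags
  has_es <- any(c("E", "S") %in% flags)
  if (has_r && has_es) "RES" else if (has_r) "R" else "ES"
}

#' Trophic mode of one species
#'
#' Curated labels pass through. Isotope records are classified by the
#' configurable rule: a species lacking chlorophyll is fully
#' mycoheterotrophic (`MH`); a chlorophyllous species significantly enriched
#' in both 13C and 15N relative to autotrophic reference plants is partially
#' mycoheterotrophic under the strict definition, enrichment in at least one
#' isotope suffices under the relaxed definition; otherwise autotrophic
#' (`AU`). Significance calls are supplied by the user as booleans; raw
#' isotope replicates are not re-analysed here.
#'
#' @param label curated `"AU"`, `"PMH"` or `"MH"`, or `NULL`.
#' @param isotope list with logical fields `significant_13C`,
#'   `significant_15N` and optionally `chlorophyllous` (default `TRUE`).
#' @param definition `"strict"` or `"relaxed"` partial-mycoheterotrophy rule.
#' @return One of `"AU"`, `"PMH"`, `"MH"`.
#' @export
trophic_mode <- function(label = NULL, isotope = NULL,
                         definition = c("strict", "relaxed")) {
  definition <- match.arg(definition)
  if (!is.null(label)) {
    if (!label %in% c("AU", "PMH", "MH"))
      stop("curated label must be AU, PMH or MH, got '", label, "'")
    return(label)
  }
  if (is.null(isotope))
    stop("either a curated label or an isotope record is required")
  chl <- if (is.null(isotope$chlorophyllous)) TRUE else
    isTRUE(isotope$chlorophyllous)
  if (!chl) return("MH")
  s13 <- isTRUE(isotope$significant_13C)
  s15 <- isTRUE(isotope$significant_15N)
  pmh <- if (definition == "strict") s13 && s15 else s13 || s15
  if (pmh) "PMH" else "AU"
}

#' Code trophic modes for a species table
#'
#' @param df data.frame with column `species` and either `label` or the
#'   isotope fields `significant_13C`, `significant_15N`,
#'   `chlorophyllous`.
#' @inheritParams trophic_mode
#' @return A [trait_dataset()] over `c("AU","PMH","MH")`.
#' @export
trophic_dataset <- function(df, definition = c("strict", "relaxed")) {
  definition <- match.arg(definition)
  states <- vapply(seq_len(nrow(df)), function(i) {
    lab <- if ("label" %in% names(df) && !is.na(df$label[i]) &&
               nzchar(df$label[i])) df$label[i] else NULL
    iso <- if (is.null(lab))
      list(significant_13C = as.logical(df$significant_13C[i]),
           significant_15N = as.logical(df$significant_15N[i]),
           chlorophyllous = if ("chlorophyllous" %in% names(df))
             as.logical(df$chlorophyllous[i]) else TRUE)
    else NULL
    trophic_mode(lab, iso, definition)
  }, "")
  trait_dataset(stats::setNames(states, df$species),
                state_space = c("AU", "PMH", "MH"))
}

#' The coupled trophic-by-association five-state space
#'
#' @return `c("AU-R","AU-ES","AU-RES","MH-RES","MH-ES")`.
#' @export
coupled_states <- function() c("AU-R", "AU-ES", "AU-RES", "MH-RES", "MH-ES")

#' Couple trophic mode and symbiotic association into one character
#'
#' Association flags collapse to `R` (rhizoctonias only), `ES` (ECM and/or
#' SAP, no rhizoctonias) or `RES` (rhizoctonias together with ECM/SAP), and
#' pair with trophic mode to give the five legal states `AU-R`, `AU-ES`,
#' `AU-RES`, `MH-RES`, `MH-ES`. `MH-R` lies outside the state space: a fully
#' mycoheterotrophic species relying on rhizoctonias alone is rejected.
#' Partially mycoheterotrophic species are merged into `AU` by default (the
#' five-state space has no PMH states) or excluded.
#'
#' @param trophic `"AU"`, `"PMH"` or `"MH"`.
#' @param assoc character subset of `c("R","E","S")` (or a collapsed label
#'   `"R"`, `"ES"`, `"RES"`).
#' @param pmh `"merge_au"` or `"exclude"`.
#' @return A coupled state label, or `NA_character_` for an excluded PMH
#'   species.
#' @export
couple_states <- function(trophic, assoc, pmh = c("merge_au", "exclude")) {
  pmh <- match.arg(pmh)
  if (!trophic %in% c("AU", "PMH", "MH")) stop("unknown trophic mode")
  if (trophic == "PMH") {
    if (pmh == "exclude") return(NA_character_)
    trophic <- "AU"
  }
  a <- if (length(assoc) == 1 && assoc %in% c("R", "ES", "RES")) assoc
  else collapse_association(assoc)
  if (trophic == "MH" && a == "R")
    stop("state MH-R is outside the five-state space ",
         "(full mycoheterotroph with rhizoctonias only)")
  paste0(trophic, "-", a)
}

#' Build the coupled five-state dataset for a species set
#'
#' @param trophic a [trait_dataset()] over AU/PMH/MH (unambiguous).
#' @param assoc a [trait_dataset()] in collapsed R/ES/RES coding (or subset
#'   coding, which is collapsed on the fly).
#' @inheritParams couple_states
#' @return A [trait_dataset()] over [coupled_states()]. Species whose
#'   combination is illegal (MH with rhizoctonias only) are dropped with a
#'   warning; excluded PMH species are dropped silently per policy.
#' @export
couple_dataset <- function(trophic, assoc, pmh = c("merge_au", "exclude")) {
  pmh <- match.arg(pmh)
  sp <- intersect(names(trophic$tips), names(assoc$tips))
  if (length(sp) == 0) stop("no shared species to couple")
  out <- character(0); bad <- character(0)
  for (s in sp) {
    tm <- trophic$tips[[s]]; as_ <- assoc$tips[[s]]
    if (length(tm) != 1 || length(as_) != 1) next # ambiguous: skip
    cs <- tryCatch(couple_states(tm, as_, pmh), error = function(e) "bad")
    if (identical(cs, "bad")) { bad <- c(bad, s); next }
    if (!is.na(cs)) out[s] <- cs
  }
  if (length(bad))
    warning(length(bad), " species with the illegal MH + rhizoctonia-only ",
            "combination dropped")
  trait_dataset(out, state_space = coupled_states())
}
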