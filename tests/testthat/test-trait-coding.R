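test_that("built-in lifestyle map covers the 17 families with the right classes", {
  ls <- default_lifestyles()
  expect_length(ls, 17)
  expect_equal(unname(ls["Tulasnellaceae"]), "RHI")
  expect_equal(unname(ls["Serendipitaceae"]), "RHI")
  expect_equal(unname(ls["Russulaceae"]), "ECM")
  expect_equal(unname(ls["Inocybaceae"]), "ECM")
  expect_equal(unname(ls["Mycenaceae"]), "SAP")
  expect_equal(unname(ls["Psathyrellaceae"]), "SAP")
  expect_equal(unname(ls["Pezizaceae"]), "ECM/SAP")
  expect_equal(sum(ls == "RHI"), 3)
})

make_presence <- function() {
  m <- matrix(FALSE, 4, 4,
              dimnames = list(paste0("sp", 1:4),
                              c("Tulasnellaceae", "Russulaceae",
                                "Mycenaceae", "Rareaceae")))
  m["sp1", "Tulasnellaceae"] <- TRUE
  m["sp2", c("Tulasnellaceae", "Russulaceae", "Mycenaceae")] <- TRUE
  m["sp3", c("Russulaceae", "Mycenaceae")] <- TRUE
  m["sp4", "Rareaceae"] <- TRUE  # singleton family
  fungal_matrix(m)
}

test_that("filter_families drops singletons and off-whitelist families, idempotently", {
  fm <- make_presence()
  filt <- filter_families(fm)
  expect_setequal(filt$families,
                  c("Tulasnellaceae", "Russulaceae", "Mycenaceae"))
  rem <- attr(filt, "removed")
  expect_true("Rareaceae" %in% rem$family)
  expect_match(rem$reason[rem$family == "Rareaceae"], "single|fewer")

  # whitelist removal of a common family
  m2 <- fm$presence
  colnames(m2)[4] <- "Commonaceae"
  m2[, "Commonaceae"] <- TRUE   # present in all 4 species but off-list
  filt2 <- filter_families(fungal_matrix(m2))
  expect_false("Commonaceae" %in% filt2$families)
  expect_match(attr(filt2, "removed")$reason[
    attr(filt2, "removed")$family == "Commonaceae"], "whitelist")

  # idempotence
  filt3 <- filter_families(filt)
  expect_equal(filt3$presence, filt$presence)
  expect_error(
    filter_families(fungal_matrix(matrix(c(TRUE, FALSE), 2, 1,
      dimnames = list(c("a", "b"), "Loneaceae")))),
    "no fungal families")
})

test_that("association_state maps lifestyles to flags and is monotone", {
  ls <- default_lifestyles()
  row <- function(fams) {
    v <- stats::setNames(rep(0, 17), names(ls))
    v[fams] <- 1
    v
  }
  expect_equal(association_state(row("Tulasnellaceae"), ls), "R")
  expect_equal(association_state(
    row(c("Tulasnellaceae", "Russulaceae", "Mycenaceae")), ls),
    c("R", "E", "S"))
  expect_equal(association_state(row("Pezizaceae"), ls,
                                 ecm_sap_policy = "both"), c("E", "S"))
  expect_equal(association_state(row("Pezizaceae"), ls,
                                 ecm_sap_policy = "sap_only"), "S")
  expect_length(association_state(row(character(0)), ls), 0)

  # monotone: adding a family never removes a flag
  set.seed(5)
  for (i in 1:25) {
    fams <- sample(names(ls), sample(1:5, 1))
    extra <- sample(setdiff(names(ls), fams), 1)
    f1 <- association_state(row(fams), ls)
    f2 <- association_state(row(c(fams, extra)), ls)
    expect_true(all(f1 %in% f2))
  }
})

test_that("trophic_mode applies curated labels and isotope rules", {
  expect_equal(trophic_mode("MH", definition = "strict"), "MH")
  expect_equal(trophic_mode("MH", definition = "relaxed"), "MH")
  expect_equal(trophic_mode(isotope = list(chlorophyllous = FALSE)), "MH")
  iso1 <- list(significant_13C = TRUE, significant_15N = FALSE)
  expect_equal(trophic_mode(isotope = iso1, definition = "relaxed"), "PMH")
  expect_equal(trophic_mode(isotope = iso1, definition = "strict"), "AU")
  iso2 <- list(significant_13C = TRUE, significant_15N = TRUE)
  expect_equal(trophic_mode(isotope = iso2, definition = "strict"), "PMH")
  expect_equal(trophic_mode(isotope = iso2, definition = "relaxed"), "PMH")
  expect_error(trophic_mode(), "either a curated label or an isotope")
  expect_error(trophic_mode("XX"), "AU, PMH or MH")
})

test_that("couple_states is total on the legal grid and rejects exactly MH-R", {
  expect_equal(couple_states("AU", "R"), "AU-R")
  expect_equal(couple_states("MH", c("R", "E", "S")), "MH-RES")
  expect_equal(couple_states("MH", "E"), "MH-ES")
  expect_equal(couple_states("PMH", "R"), "AU-R")       # merged into AU
  expect_true(is.na(couple_states("PMH", "R", pmh = "exclude")))
  for (tm in c("AU", "MH")) for (a in c("R", "ES", "RES")) {
    if (tm == "MH" && a == "R") {
      expect_error(couple_states(tm, a), "outside the five-state space")
    } else {
      expect_true(couple_states(tm, a) %in% coupled_states())
    }
  }
})

test_that("association and coupled datasets flow from a presence matrix", {
  fm <- make_presence()
  filt <- filter_families(fm)
  ad <- association_dataset(filt, coding = "collapsed")
  expect_equal(unlist(ad$tips[c("sp1", "sp2", "sp3")]),
               c(sp1 = "R", sp2 = "RES", sp3 = "ES"))
  troph <- trait_dataset(c(sp1 = "AU", sp2 = "AU", sp3 = "MH"),
                         c("AU", "PMH", "MH"))
  cd <- couple_dataset(troph, ad)
  expect_equal(unlist(cd$tips),
               c(sp1 = "AU-R", sp2 = "AU-RES", sp3 = "MH-ES"))
  # MH + rhizoctonia-only is dropped with a warning
  troph2 <- trait_dataset(c(sp1 = "MH", sp2 = "AU", sp3 = "MH"),
                          c("AU", "PMH", "MH"))
  expect_warning(cd2 <- couple_dataset(troph2, ad), "illegal")
  expect_false("sp1" %in% names(cd2$tips))
})

test_that("trait TSV round-trips including ambiguity", {
  td <- trait_dataset(c(s1 = "AU", s2 = "AU|PMH", s3 = "MH"),
                      c("AU", "PMH", "MH"))
  tf <- tempfile(fileext = ".tsv")
  write_trait_tsv(td, tf)
  back <- read_trait_tsv(tf, c("AU", "PMH", "MH"))
  expect_equal(back$tips, td$tips)
  expect_equal(back$states, td$states)
})
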