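# Curated catalog of terminal-glycotope diagnostic ions.
#
# Each row is one diagnostic ion of one glycotope. Ions whose masses follow
# from permethylated-fragment arithmetic (B / B-MeOH / glycosidic and
# elimination losses / monosulfated B anions / C ions) carry
# derivation = "computed" and are generated through the mass engine at build
# time; cross-ring (A/X), E, D, Z and reduced-end (GalNAc-ol) satellite ions
# whose generation rules live in the sulfoglycomics fragmentation literature
# are carried as curated literals at their reported nominal values.

.ion_row <- function(glycotope, ion_label, mz, polarity, ms_level,
                     derivation, role, parent_mz = NA_real_,
                     citation = "") {
  data.frame(glycotope = glycotope, ion_label = ion_label, mz = mz,
             polarity = polarity, ms_level = as.integer(ms_level),
             derivation = derivation, role = role, parent_mz = parent_mz,
             citation = citation, stringsAsFactors = FALSE)
}

.curated_cite <- "curated: permethylated-glycan negative-mode sulfoglycomics fragmentation literature"
.curated_cite_pos <- "curated: reduced-end core-1 reporter ions, empirical"

#' Build the diagnostic-ion catalog
#'
#' Assembles the glycotope definitions used throughout the pipeline:
#' positive-mode sialic-acid and glycotope oxonium reporters (MS2, with
#' product-dependent MS3 confirmations for the galactosylated sialyl-LacNAc
#' family), and negative-mode diagnostic ions for sulfated glycotopes
#' (3-O-sulfo-Gal, 4-O-sulfo-GalNAc as in sulfo-LacdiNAc, internal
#' 6-O-sulfo-GlcNAc, the HNK-1 epitope SO3-3HexA-3Hex-4HexNAc, sulfated
#' core-2 6-arm satellite series) plus the methyl-phospho-Hex reporter that
#' discriminates mannose-6-phosphate from sulfo-HexA by accurate mass
#' (297.07 vs 297.03).
#'
#' Ions with `derivation == "computed"` are generated through the mass
#' engine; `"curated"` ions are literals with provenance in `citation`.
#' MS3 ions carry the m/z of the MS2 product ion they are acquired from in
#' `parent_mz`. `role` separates the ions that define a glycotope
#' (`"required"`) from corroborating satellites (`"supporting"`).
#'
#' A deliberate, MS-level-keyed mass collision is encoded: the positive
#' MS2 B ion of KDN-Hex-HexNAc and the positive MS3 Hex-(NeuAc)Hex ion are
#' isobaric at m/z 784.40 (KDN + HexNAc == NeuAc + Hex), and are
#' disambiguated only by MS level.
#'
#' @return A data frame of class `glycotope_catalog` with columns
#'   `glycotope`, `ion_label`, `mz`, `polarity`, `ms_level`, `derivation`,
#'   `role`, `parent_mz`, `citation`.
#' @examples
#' cat <- build_catalog()
#' subset(cat, glycotope == "sulfo-HNK-1" & role == "required")
#' @export
build_catalog <- function() {
  cc <- glyco_constants()
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- .ion_row(...)
  comp_cite <- "computed: permethylated B/oxonium-ion arithmetic"

  ## --- positive mode, sialic-acid reporters -------------------------------
  b_neuac <- b_ion_mz("NeuAc")
  add("NeuAc", "B1", b_neuac, "positive", 2, "computed", "required",
      citation = comp_cite)
  add("NeuAc", "dB1(-MeOH)", neutral_loss_mz(b_neuac, "meoh"), "positive", 2,
      "computed", "supporting", citation = comp_cite)
  b_neugc <- b_ion_mz("NeuGc")
  add("NeuGc", "B1", b_neugc, "positive", 2, "computed", "required",
      citation = comp_cite)
  add("NeuGc", "dB1(-MeOH)", neutral_loss_mz(b_neugc, "meoh"), "positive", 2,
      "computed", "supporting", citation = comp_cite)
  b_kdn <- b_ion_mz("KDN")
  add("KDN", "dB1(-MeOH)", neutral_loss_mz(b_kdn, "meoh"), "positive", 2,
      "computed", "required", citation = comp_cite)
  add("KDN", "B1", b_kdn, "positive", 2, "computed", "supporting",
      citation = "computed: B1 rarely observed; the -MeOH ion dominates")

  ## --- positive mode, sialylated LacdiNAc (ovary-type) --------------------
  for (sia in c("NeuAc", "NeuGc")) {
    g <- paste0(sia, "-LacdiNAc")
    b2 <- b_ion_mz(c(sia, "HexNAc"))
    b3 <- b_ion_mz(c(sia, "HexNAc", "HexNAc"))
    add(g, "B2", b2, "positive", 2, "computed", "required",
        citation = comp_cite)
    add(g, "dB2(-MeOH)", neutral_loss_mz(b2, "meoh"), "positive", 2,
        "computed", "supporting", citation = comp_cite)
    add(g, "B3", b3, "positive", 2, "computed", "supporting",
        citation = comp_cite)
    add(g, "dB3(-MeOH)", neutral_loss_mz(b3, "meoh"), "positive", 2,
        "computed", "supporting", citation = comp_cite)
  }

  ## --- positive mode, KDN-capped LacNAc (intestine-type) ------------------
  b_kdnlac <- b_ion_mz(c("KDN", "Hex", "HexNAc"))
  add("KDN-LacNAc", "B3", b_kdnlac, "positive", 2, "computed", "required",
      citation = comp_cite)
  add("KDN-LacNAc", "dB3(-MeOH)", neutral_loss_mz(b_kdnlac, "meoh"),
      "positive", 2, "computed", "supporting", citation = comp_cite)

  ## --- positive mode, galactosylated sialyl-LacNAc family (brain-type) ----
  b4 <- b_ion_mz(c("Hex", "NeuAc", "Hex", "HexNAc"))
  add("Gal-NeuAc-Gal-GlcNAc", "B4", b4, "positive", 2, "computed", "required",
      citation = comp_cite)
  add("Gal-NeuAc-Gal-GlcNAc", "dB4(-MeOH)", neutral_loss_mz(b4, "meoh"),
      "positive", 2, "computed", "supporting", citation = comp_cite)
  b_desial <- neutral_loss_mz(b4, "NeuAc-OH")
  add("Gal-NeuAc-Gal-GlcNAc", "B4-NeuAc(OH)", b_desial, "positive", 2,
      "computed", "supporting", citation = comp_cite)
  add("Gal-NeuAc-Gal-GlcNAc", "B4-NeuAc(OH)-MeOH",
      neutral_loss_mz(b_desial, "meoh"), "positive", 2, "computed",
      "supporting", citation = comp_cite)
  ms3_784 <- b_ion_mz(c("Hex", "NeuAc", "Hex"))
  add("Gal-NeuAc-Gal-GlcNAc", "MS3 Hex-(NeuAc)Hex", ms3_784, "positive", 3,
      "computed", "required", parent_mz = b4, citation = comp_cite)

  for (sia in c("NeuAc", "NeuGc")) {
    g <- paste0("Galb4-sialyl-LeX-", sia)
    b5 <- b_ion_mz(c("Hex", sia, "Hex", "dHex", "HexNAc"))
    defuc <- neutral_loss_mz(b5, "dHex-elim")
    add(g, "B5", b5, "positive", 2, "computed", "required",
        citation = comp_cite)
    add(g, "B5-Fuc(elim)", defuc, "positive", 2, "computed", "supporting",
        citation = comp_cite)
    add(g, "Fuc(HO)HexNAc",
        neutral_loss_mz(b_ion_mz(c("dHex", "HexNAc")), "demethyl"),
        "positive", 2, "computed", "supporting", citation = comp_cite)
    add(g, "B5-Fuc(elim)-Sia(OH)",
        neutral_loss_mz(defuc, paste0(sia, "-OH")), "positive", 2,
        "computed", "supporting", citation = comp_cite)
    ms3 <- b_ion_mz(c("Hex", sia, "Hex"))
    add(g, paste0("MS3 Hex-(", sia, ")Hex"), ms3, "positive", 3, "computed",
        if (sia == "NeuAc") "supporting" else "required",
        parent_mz = b5, citation = comp_cite)
  }

  ## --- positive mode, non-sialylated Gal-Gal-(Fuc)GlcNAc ------------------
  b_ggfg <- b_ion_mz(c("Hex", "Hex", "dHex", "HexNAc"))
  add("Gal-Gal-Fuc-GlcNAc", "B4", b_ggfg, "positive", 2, "computed",
      "required", citation = comp_cite)
  add("Gal-Gal-Fuc-GlcNAc", "B3(non-Fuc)", b_ion_mz(c("Hex", "Hex", "HexNAc")),
      "positive", 2, "computed", "supporting", citation = comp_cite)
  add("Gal-Gal-Fuc-GlcNAc", "B4-Fuc(OH)", neutral_loss_mz(b_ggfg, "dHex-OH"),
      "positive", 2, "computed", "supporting", citation = comp_cite)
  add("Gal-Gal-Fuc-GlcNAc", "B4-Fuc(elim)", neutral_loss_mz(b_ggfg, "dHex-elim"),
      "positive", 2, "computed", "supporting", citation = comp_cite)

  ## --- positive mode, Fuc-GalNAc (ovary O-glycan glycotope) ---------------
  b_fg <- b_ion_mz(c("dHex", "HexNAc"))
  add("Fuc-GalNAc", "B2", b_fg, "positive", 2, "computed", "required",
      citation = comp_cite)
  add("Fuc-GalNAc", "Fuc(HO)HexNAc", neutral_loss_mz(b_fg, "demethyl"),
      "positive", 2, "computed", "supporting", citation = comp_cite)

  ## --- positive mode, core-1 arm isomer reporters (curated) ---------------
  add("core1-isomer-reporters", "reduced-end 280", 280, "positive", 2,
      "curated", "required", citation = .curated_cite_pos)
  add("core1-isomer-reporters", "reduced-end 294", 294, "positive", 2,
      "curated", "required", citation = .curated_cite_pos)

  ## --- negative mode, 3-O-sulfated Gal -------------------------------------
  add("3-O-sulfo-Gal", "B1", sulfo_b_anion_mz("Hex"), "negative", 2,
      "computed", "required", citation = comp_cite)
  add("3-O-sulfo-Gal", "E1", 253, "negative", 2, "curated", "supporting",
      citation = .curated_cite)
  add("3-O-sulfo-Gal", "low-mass 153", 153, "negative", 2, "curated",
      "supporting", citation = .curated_cite)
  add("3-O-sulfo-Gal", "low-mass 181", 181, "negative", 2, "curated",
      "supporting", citation = .curated_cite)
  add("3-O-sulfo-Gal-4GlcNAc", "3,5A2", 371, "negative", 2, "curated",
      "required", citation = .curated_cite)
  add("3-O-sulfo-Gal-3GlcNAc", "2,4A2", 357, "negative", 2, "curated",
      "required", citation = .curated_cite)
  add("3-O-sulfo-Gal-3GlcNAc", "1,3A2", 398, "negative", 2, "curated",
      "supporting", citation = .curated_cite)

  ## --- negative mode, 4-O-sulfated GalNAc (sulfo-LacdiNAc) ----------------
  add("4-O-sulfo-GalNAc", "B1", sulfo_b_anion_mz("HexNAc"), "negative", 2,
      "computed", "required", citation = comp_cite)
  add("4-O-sulfo-GalNAc", "3,5A1", 167, "negative", 2, "curated",
      "supporting", citation = .curated_cite)

  ## --- negative mode, internal 6-O-sulfated GlcNAc ------------------------
  add("6-O-sulfo-GlcNAc", "internal 264", 264, "negative", 2, "curated",
      "required", citation = .curated_cite)
  add("6-O-sulfo-GlcNAc", "internal 234", 234, "negative", 2, "curated",
      "supporting", citation = .curated_cite)
  add("6-O-sulfo-GlcNAc", "internal 195", 195, "negative", 2, "curated",
      "supporting", citation = .curated_cite)

  ## --- negative mode, HNK-1 epitope (SO3-3HexA-3Hex-4HexNAc) --------------
  add("sulfo-HNK-1", "B1", sulfo_b_anion_mz("HexA"), "negative", 2,
      "computed", "required", citation = comp_cite)
  add("sulfo-HNK-1", "B2", sulfo_b_anion_mz(c("HexA", "Hex")), "negative", 2,
      "computed", "required", citation = comp_cite)
  add("sulfo-HNK-1", "B3", sulfo_b_anion_mz(c("HexA", "Hex", "HexNAc")),
      "negative", 2, "computed", "required", citation = comp_cite)
  for (v in list(c("E2", 471), c("E3", 675), c("3,5A3", 589), c("D", 1140),
                 c("low-mass 181", 181), c("low-mass 267", 267),
                 c("3,5A2 371", 371))) {
    add("sulfo-HNK-1", v[[1]], as.numeric(v[[2]]), "negative", 2, "curated",
        "supporting", citation = .curated_cite)
  }

  ## --- negative mode, sulfated sialylated LacNAc families -----------------
  add("sulfo-sialyl-LacNAc", "B3", sulfo_b_anion_mz(c("NeuAc", "Hex", "HexNAc")),
      "negative", 2, "computed", "required", citation = comp_cite)
  add("sulfo-Gal-NeuAc-Gal-GlcNAc", "B4",
      sulfo_b_anion_mz(c("Hex", "NeuAc", "Hex", "HexNAc")), "negative", 2,
      "computed", "required", citation = comp_cite)

  ## --- negative mode, sulfated (Fuc-)LacNAc on the core-2 6-arm -----------
  # Satellite ions arise from cleavages across the GalNAc-ol; curated. The
  # fucosylated twin series is the same set shifted by one Fuc increment.
  sat <- c(`sat 588` = 588, `sat 616` = 616, `sat 632` = 632,
           `sat 676` = 676, `sat 745` = 745, `sat 759` = 759, `Z1` = 789)
  add("sulfo-LacNAc-core2-6arm", "B2", sulfo_b_anion_mz(c("Hex", "HexNAc")),
      "negative", 2, "computed", "required", citation = comp_cite)
  for (i in seq_along(sat)) {
    add("sulfo-LacNAc-core2-6arm", names(sat)[i], sat[[i]], "negative", 2,
        "curated", "supporting", citation = .curated_cite)
  }
  fuc <- residue_increment_mass("dHex")
  add("sulfo-FucLacNAc-core2-6arm", "B2",
      sulfo_b_anion_mz(c("Hex", "dHex", "HexNAc")), "negative", 2,
      "computed", "required", citation = comp_cite)
  sat_fuc <- sat[names(sat) != "sat 759"] + fuc
  for (i in seq_along(sat_fuc)) {
    add("sulfo-FucLacNAc-core2-6arm",
        paste0(sub(" .*", "", names(sat_fuc)[i]), " ", floor(sat_fuc[[i]])),
        sat_fuc[[i]], "negative", 2, "curated", "supporting",
        citation = paste0(.curated_cite, "; Fuc-shifted satellite"))
  }

  ## --- negative mode, sulfated LacNAc on an extended core 1 ---------------
  b3_ext <- sulfo_b_anion_mz(c("Hex", "HexNAc", "Hex"))
  add("sulfo-LacNAc-ext-core1", "B3", b3_ext, "negative", 2, "computed",
      "required", citation = comp_cite)
  add("sulfo-LacNAc-ext-core1", "C3", b3_ext + glyco_constants()[["water"]],
      "negative", 2, "computed", "supporting", citation = comp_cite)
  add("sulfo-LacNAc-ext-core1", "E3", 702, "negative", 2, "curated",
      "supporting", citation = .curated_cite)

  ## --- negative mode, mannose-6-phosphate reporters -----------------------
  add("M6P", "methyl-phospho-Hex",
      b_ion_mz("Hex") + cc[["methylphospho_anion_shift"]], "negative", 2,
      "computed", "required",
      citation = "computed: O-methylated phosphate anion shift (+HPO3 - 2H)")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("glycotope_catalog", "data.frame")
  out
}

#' Glycotope-level metadata
#'
#' Annotation of each catalog glycotope: sialic-acid variant, sulfation
#' site, and organ association. Organ association is metadata for reporting
#' only and is never consulted by matching logic.
#'
#' @return Data frame with columns `glycotope`, `sialic_variant`,
#'   `sulfation_site`, `organ`.
#' @export
glycotope_info <- function() {
  data.frame(
    glycotope = c("NeuAc", "NeuGc", "KDN",
                  "NeuAc-LacdiNAc", "NeuGc-LacdiNAc", "KDN-LacNAc",
                  "Gal-NeuAc-Gal-GlcNAc",
                  "Galb4-sialyl-LeX-NeuAc", "Galb4-sialyl-LeX-NeuGc",
                  "Gal-Gal-Fuc-GlcNAc", "Fuc-GalNAc",
                  "core1-isomer-reporters",
                  "3-O-sulfo-Gal", "3-O-sulfo-Gal-4GlcNAc",
                  "3-O-sulfo-Gal-3GlcNAc", "4-O-sulfo-GalNAc",
                  "6-O-sulfo-GlcNAc", "sulfo-HNK-1", "sulfo-sialyl-LacNAc",
                  "sulfo-Gal-NeuAc-Gal-GlcNAc", "sulfo-LacNAc-core2-6arm",
                  "sulfo-FucLacNAc-core2-6arm", "sulfo-LacNAc-ext-core1",
                  "M6P"),
    sialic_variant = c("NeuAc", "NeuGc", "KDN",
                       "NeuAc", "NeuGc", "KDN",
                       "NeuAc", "NeuAc", "NeuGc",
                       "none", "none", "none",
                       "none", "none", "none", "none", "none", "none",
                       "NeuAc", "NeuAc", "none", "none", "none", "none"),
    sulfation_site = c(rep("none", 12),
                       "3-O-Gal", "3-O-Gal", "3-O-Gal", "4-O-GalNAc",
                       "6-O-GlcNAc", "3-O-HexA", "6-O-GlcNAc", "3-O-Gal",
                       "3-O-Gal", "3-O-Gal", "3-O-Gal", "none"),
    organ = c("brain", "ovary", "intestine",
              "ovary", "ovary", "intestine",
              "brain", "common", "common",
              "intestine", "ovary", "common",
              "common", "common", "common", "brain", "common", "brain",
              "common", "common", "intestine", "intestine", "intestine",
              "common"),
    stringsAsFactors = FALSE
  )
}

#' Diagnostic ions of one glycotope
#'
#' @param glycotope_name name of a catalog glycotope.
#' @param polarity optional filter, `"positive"` or `"negative"`.
#' @param ms_level optional filter, 2 or 3.
#' @param catalog a catalog from [build_catalog()] (the default).
#' @return The matching catalog rows, ordered by m/z (possibly zero rows).
#' @examples
#' ions_for("3-O-sulfo-Gal", "negative", 2)
#' @export
ions_for <- function(glycotope_name, polarity = NULL, ms_level = NULL,
                     catalog = build_catalog()) {
  if (!glycotope_name %in% catalog$glycotope) {
    stop("unknown glycotope '", glycotope_name, "'; available: ",
         paste(unique(catalog$glycotope), collapse = ", "))
  }
  out <- catalog[catalog$glycotope == glycotope_name, , drop = FALSE]
  if (!is.null(polarity)) out <- out[out$polarity == polarity, , drop = FALSE]
  if (!is.null(ms_level)) out <- out[out$ms_level == ms_level, , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.catalog_cols <- c("glycotope", "ion_label", "mz", "polarity", "ms_level",
                   "derivation", "role", "parent_mz", "citation")

#' Write / read a catalog as TSV or JSON
#'
#' The on-disk schema has columns `glycotope`, `ion_label`, `mz`,
#' `polarity`, `ms_level`, `derivation`, `role`, `parent_mz`, `citation`,
#' so users can extend the catalog without touching code.
#'
#' @param catalog a `glycotope_catalog`.
#' @param path file path.
#' @return `catalog_read_tsv()`/`catalog_read_json()` return a
#'   `glycotope_catalog`; the writers return `path` invisibly.
#' @export
catalog_write_tsv <- function(catalog, path) {
  write.table(catalog[, .catalog_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname catalog_write_tsv
#' @export
catalog_read_tsv <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  out <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "")
  missing <- setdiff(.catalog_cols, names(out))
  if (length(missing)) {
    stop("catalog TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  out$ms_level <- as.integer(out$ms_level)
  out$mz <- as.numeric(out$mz)
  out$parent_mz <- as.numeric(out$parent_mz)
  out$citation[is.na(out$citation)] <- ""
  class(out) <- c("glycotope_catalog", "data.frame")
  out
}

#' @rdname catalog_write_tsv
#' @export
catalog_write_json <- function(catalog, path) {
  jsonlite::write_json(as.data.frame(catalog[, .catalog_cols]), path,
                       digits = NA, na = "null", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname catalog_write_tsv
#' @export
catalog_read_json <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  out <- jsonlite::fromJSON(path)
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (!"parent_mz" %in% names(out)) out$parent_mz <- NA_real_
  out$parent_mz <- suppressWarnings(as.numeric(out$parent_mz))
  out$ms_level <- as.integer(out$ms_level)
  if (is.null(out$citation)) out$citation <- ""
  out$citation[is.na(out$citation)] <- ""
  out <- out[, .catalog_cols]
  class(out) <- c("glycotope_catalog", "data.frame")
  out
}
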