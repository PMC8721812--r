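# Diagnostic-ion mining: ppm matching, glycotope quantification, precursor
# filtering and glycosyl-composition fitting.

.empty_matches <- function() {
  data.frame(scan_id = integer(0), ms_level = integer(0),
             glycotope = character(0), ion_label = character(0),
             theoretical_mz = numeric(0), observed_mz = numeric(0),
             ppm = numeric(0), intensity = numeric(0), role = character(0),
             stringsAsFactors = FALSE)
}

#' Match catalog diagnostic ions in one MS2/MS3 spectrum
#'
#' For every catalog ion of the spectrum's polarity and MS level, the single
#' nearest peak within `tol_ppm` is reported. Within a glycotope, one peak
#' may satisfy at most one catalog ion: assignments are made greedily by
#' increasing absolute ppm error, ties broken toward the lower theoretical
#' m/z, so matching is deterministic. For MS3 spectra, catalog ions are only
#' considered when the spectrum's precursor m/z lies within
#' `parent_tol` of the ion's recorded MS2 parent ion.
#'
#' @param spectrum a [spectrum_record()] with `ms_level` 2 or 3.
#' @param catalog a [build_catalog()] table.
#' @param tol_ppm matching tolerance in ppm (default 5, the preset used for
#'   diagnostic-ion filtering).
#' @param parent_tol absolute m/z tolerance for MS3 parent-ion matching
#'   (default 0.7, a typical isolation half-width).
#' @return Data frame of ion matches (zero rows if none): `scan_id`,
#'   `ms_level`, `glycotope`, `ion_label`, `theoretical_mz`, `observed_mz`,
#'   `ppm`, `intensity`, `role`.
#' @export
match_diagnostic_ions <- function(spectrum, catalog, tol_ppm = 5,
                                  parent_tol = 0.7) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  if (spectrum$ms_level < 2L) {
    stop("diagnostic-ion matching requires an MS2 or MS3 spectrum")
  }
  sub <- catalog[catalog$polarity == spectrum$polarity &
                   catalog$ms_level == spectrum$ms_level, , drop = FALSE]
  if (spectrum$ms_level == 3L && nrow(sub)) {
    keep <- is.na(sub$parent_mz) |
      abs(sub$parent_mz - spectrum$precursor_mz) <= parent_tol
    sub <- sub[keep, , drop = FALSE]
  }
  if (!nrow(sub) || !length(spectrum$mz)) return(.empty_matches())

  # all (ion, peak) pairs within tolerance
  cand <- list()
  for (i in seq_len(nrow(sub))) {
    lo <- sub$mz[i] * (1 - tol_ppm * 1e-6)
    hi <- sub$mz[i] * (1 + tol_ppm * 1e-6)
    j1 <- findInterval(lo, spectrum$mz) + 1L
    j2 <- findInterval(hi, spectrum$mz)
    if (j2 >= j1) {
      js <- j1:j2
      cand[[length(cand) + 1L]] <- data.frame(
        ion = i, peak = js,
        ppm = ppm_error(spectrum$mz[js], sub$mz[i])
      )
    }
  }
  if (!length(cand)) return(.empty_matches())
  cand <- do.call(rbind, cand)
  cand <- cand[order(abs(cand$ppm), sub$mz[cand$ion]), , drop = FALSE]

  # greedy assignment per glycotope: each ion at most one peak, each peak at
  # most one ion of a given glycotope
  taken_ion <- logical(nrow(sub))
  taken_peak <- character(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$ion[k]
    key <- paste(sub$glycotope[i], cand$peak[k])
    if (!taken_ion[i] && !key %in% taken_peak) {
      taken_ion[i] <- TRUE
      taken_peak <- c(taken_peak, key)
      keep[k] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    scan_id = spectrum$scan_id, ms_level = spectrum$ms_level,
    glycotope = sub$glycotope[cand$ion], ion_label = sub$ion_label[cand$ion],
    theoretical_mz = sub$mz[cand$ion],
    observed_mz = spectrum$mz[cand$peak], ppm = cand$ppm,
    intensity = spectrum$intensity[cand$peak],
    role = sub$role[cand$ion], stringsAsFactors = FALSE
  )
  out <- out[order(out$theoretical_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match diagnostic ions across all MS2/MS3 scans of a run
#' @inheritParams match_diagnostic_ions
#' @param run a [glycan_run()].
#' @return Row-bound match table over all level-2/3 scans.
#' @export
match_run <- function(run, catalog, tol_ppm = 5, parent_tol = 0.7) {
  scans <- run_spectra(run, ms_level = 2:3)
  if (!length(scans)) return(.empty_matches())
  out <- do.call(rbind, lapply(scans, match_diagnostic_ions, catalog = catalog,
                               tol_ppm = tol_ppm, parent_tol = parent_tol))
  rownames(out) <- NULL
  out
}

#' Summed, normalized diagnostic-ion intensity per glycotope
#'
#' Sums matched diagnostic-ion intensities per glycotope over all MS2 (and,
#' by default, MS3) scans of a run, and normalizes each glycotope's sum to
#' the total over all glycotopes searched. This is the composite bar-chart
#' quantity used to compare glycotope distribution and relative abundance
#' across samples.
#'
#' @inheritParams match_run
#' @param combine_ms3 if `TRUE` (default) MS3 intensities are added to the
#'   MS2 sums; if `FALSE` shares are computed from MS2 alone (both level
#'   sums are always reported).
#' @return Data frame of class `glycotope_report`: `glycotope`,
#'   `ms2_intensity`, `ms3_intensity`, `summed_intensity`, `n_scans`,
#'   `share`. Shares sum to 1 when any match exists; an all-zero report
#'   (with a warning) is returned when nothing matches.
#' @export
summarize_glycotopes <- function(run, catalog, tol_ppm = 5,
                                 combine_ms3 = TRUE, parent_tol = 0.7) {
  m <- match_run(run, catalog, tol_ppm = tol_ppm, parent_tol = parent_tol)
  gly <- unique(catalog$glycotope)
  s2 <- s3 <- setNames(numeric(length(gly)), gly)
  nsc <- setNames(integer(length(gly)), gly)
  if (nrow(m)) {
    a2 <- tapply(m$intensity[m$ms_level == 2L], m$glycotope[m$ms_level == 2L],
                 sum)
    a3 <- tapply(m$intensity[m$ms_level == 3L], m$glycotope[m$ms_level == 3L],
                 sum)
    s2[names(a2)] <- a2
    s3[names(a3)] <- a3
    ns <- tapply(m$scan_id, m$glycotope, function(x) length(unique(x)))
    nsc[names(ns)] <- ns
  }
  total <- if (combine_ms3) s2 + s3 else s2
  denom <- sum(total)
  share <- if (denom > 0) total / denom else {
    warning("no diagnostic ions matched anywhere in the run")
    total
  }
  out <- data.frame(glycotope = gly, ms2_intensity = unname(s2[gly]),
                    ms3_intensity = unname(s3[gly]),
                    summed_intensity = unname(total[gly]),
                    n_scans = unname(nsc[gly]), share = unname(share[gly]),
                    stringsAsFactors = FALSE)
  class(out) <- c("glycotope_report", "data.frame")
  out
}

#' Filter precursors by diagnostic-ion content and fit compositions
#'
#' Retains precursors whose MS2 spectra contain at least `min_diag` matched
#' catalog ions, merging scans whose precursor m/z agree within `tol_ppm`
#' at the same charge into one candidate, and (optionally) mass-fits each
#' candidate to glycosyl compositions.
#'
#' @inheritParams match_run
#' @param min_diag minimum number of distinct matched MS2 diagnostic ions
#'   per scan (default 2).
#' @param glycan_class composition class for fitting.
#' @param fit if `TRUE` (default), run [fit_composition()] on each candidate.
#' @param bounds passed to [fit_composition()].
#' @return Data frame of candidates: `precursor_mz`, `charge` (NA if
#'   undetermined), `polarity`, `n_scans`, `diag_count`, `glycotopes`, and
#'   when `fit = TRUE` the top composition (`composition`, `adduct`,
#'   `fit_z`, `fit_ppm`, `ambiguous`).
#' @export
filter_candidate_precursors <- function(run, catalog, min_diag = 2,
                                        tol_ppm = 5,
                                        glycan_class = c("O-glycan",
                                                         "N-glycan"),
                                        fit = TRUE, bounds = NULL,
                                        parent_tol = 0.7) {
  glycan_class <- match.arg(glycan_class)
  scans <- run_spectra(run, ms_level = 2L)
  empty <- data.frame(precursor_mz = numeric(0), charge = integer(0),
                      polarity = character(0), n_scans = integer(0),
                      diag_count = integer(0), glycotopes = character(0),
                      stringsAsFactors = FALSE)
  if (!length(scans)) return(empty)
  per_scan <- lapply(scans, function(s) {
    m <- match_diagnostic_ions(s, catalog, tol_ppm = tol_ppm)
    nd <- length(unique(paste(m$glycotope, m$ion_label)))
    list(scan = s, n = nd,
         glycotopes = sort(unique(m$glycotope)))
  })
  per_scan <- Filter(function(x) x$n >= min_diag, per_scan)
  if (!length(per_scan)) return(empty)

  # group by charge + precursor m/z within tol_ppm (single-linkage on the
  # sorted m/z values)
  key_charge <- vapply(per_scan, function(x) {
    ch <- x$scan$precursor_charge
    if (is.na(ch)) -1L else ch
  }, integer(1))
  mzs <- vapply(per_scan, function(x) x$scan$precursor_mz, numeric(1))
  groups <- rep(NA_integer_, length(per_scan))
  gid <- 0L
  for (ch in unique(key_charge)) {
    sel <- which(key_charge == ch)
    sel <- sel[order(mzs[sel])]
    prev <- NA_real_
    for (i in sel) {
      if (is.na(prev) || abs(ppm_error(mzs[i], prev)) > tol_ppm) {
        gid <- gid + 1L
      }
      groups[i] <- gid
      prev <- mzs[i]
    }
  }
  rows <- lapply(unique(groups), function(g) {
    xs <- per_scan[groups == g]
    ch <- key_charge[groups == g][1]
    data.frame(
      precursor_mz = mean(vapply(xs, function(x) x$scan$precursor_mz,
                                 numeric(1))),
      charge = if (ch == -1L) NA_integer_ else ch,
      polarity = xs[[1]]$scan$polarity,
      n_scans = length(xs),
      diag_count = sum(vapply(xs, function(x) x$n, integer(1))),
      glycotopes = paste(sort(unique(unlist(lapply(xs, `[[`, "glycotopes")))),
                         collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$precursor_mz), , drop = FALSE]
  rownames(out) <- NULL
  if (fit) {
    fits <- lapply(seq_len(nrow(out)), function(i) {
      best_candidate_fit(out$precursor_mz[i], out$charge[i], out$polarity[i],
                         glycan_class = glycan_class, tol_ppm = tol_ppm,
                         bounds = bounds)
    })
    out$composition <- vapply(fits, function(f) f$composition, character(1))
    out$adduct <- vapply(fits, function(f) f$adduct, character(1))
    out$fit_z <- vapply(fits, function(f) f$z, integer(1))
    out$fit_ppm <- vapply(fits, function(f) f$ppm, numeric(1))
    out$ambiguous <- vapply(fits, function(f) f$ambiguous, logical(1))
  }
  out
}

# Try the polarity's adduct hypotheses (positive: [M+H]+ then [M+Na]+;
# negative: [M-H]- and [M-2H]2-) and, when the charge is undetermined,
# z = 1 and 2; the best absolute-ppm composition wins.
best_candidate_fit <- function(mz, charge, polarity, glycan_class,
                               tol_ppm = 5, bounds = NULL) {
  adducts <- if (polarity == "positive") c("proton", "sodium")
             else "deprotonated"
  zs <- if (is.na(charge)) 1:2 else charge
  best <- list(composition = NA_character_, adduct = NA_character_,
               z = NA_integer_, ppm = NA_real_, ambiguous = NA)
  for (ad in adducts) {
    for (z in zs) {
      fits <- fit_composition(mz, z = z, adduct = ad,
                              glycan_class = glycan_class,
                              tol_ppm = tol_ppm, bounds = bounds)
      if (nrow(fits) && (is.na(best$ppm) || abs(fits$ppm[1]) < abs(best$ppm))) {
        best <- list(composition = fits$composition[1], adduct = ad,
                     z = as.integer(z), ppm = fits$ppm[1],
                     ambiguous = fits$ambiguous[1])
      }
    }
  }
  best
}

.default_bounds <- list(Hex = 12L, HexNAc = 8L, dHex = 4L, NeuAc = 4L,
                        NeuGc = 4L, KDN = 4L, HexA = 2L, sulfate = 3L,
                        phosphate = 1L)

#' Fit a precursor m/z to glycosyl compositions by accurate mass
#'
#' Exhaustively enumerates residue and modification counts within `bounds`
#' under the class constraints (N-glycans: HexNAc >= 2, Hex >= 3; reduced
#' O-glycans: HexNAc >= 1) and returns every composition whose theoretical
#' ion m/z lies within `tol_ppm` of the observation, sorted by absolute ppm
#' error. Near-ties whose theoretical masses fall within `2 * tol_ppm` of
#' the top hit are flagged ambiguous, with a note naming the residue
#' substitution relative to the top hit (the classic confusions are
#' NeuGc <-> NeuAc + (Hex - dHex) and NeuAc <-> KDN + (HexNAc - Hex)).
#'
#' @param precursor_mz observed precursor m/z.
#' @param z charge.
#' @param adduct `"proton"`, `"sodium"` or `"deprotonated"`.
#' @param glycan_class `"N-glycan"` or `"O-glycan"`.
#' @param reduced reduced end; defaults to `TRUE` for O-glycans (released by
#'   reductive elimination) and `FALSE` for N-glycans.
#' @param tol_ppm tolerance in ppm (default 5).
#' @param bounds named list of maximum counts; defaults are Hex 12,
#'   HexNAc 8, dHex 4, each sialic acid 4, HexA 2, sulfate 3, phosphate 1.
#'   Set a bound to 0 to disallow a residue or modification.
#' @return Data frame (possibly zero rows): residue/modifier counts,
#'   `neutral_mass`, `theoretical_mz`, `ppm`, `composition` (a compact
#'   label), `ambiguous`, `ambiguity_note`.
#' @examples
#' fit_composition(937.41, z = 1, adduct = "deprotonated",
#'                 glycan_class = "O-glycan")[1, ]
#' @export
fit_composition <- function(precursor_mz, z = 1L,
                            adduct = c("proton", "sodium", "deprotonated"),
                            glycan_class = c("O-glycan", "N-glycan"),
                            reduced = NULL, tol_ppm = 5, bounds = NULL) {
  adduct <- match.arg(adduct)
  glycan_class <- match.arg(glycan_class)
  if (is.null(reduced)) reduced <- glycan_class == "O-glycan"
  b <- .default_bounds
  if (!is.null(bounds)) b[names(bounds)] <- lapply(bounds, as.integer)

  target <- neutral_from_mz(precursor_mz, adduct, z)
  # the ppm window is defined on the observed m/z scale
  half <- precursor_mz * tol_ppm * 1e-6 * z
  if (target <= 0) {
    return(.empty_fits())
  }
  cc <- glyco_constants()
  termini <- if (reduced) cc[["alditol_adjust"]] else cc[["free_reducing_adjust"]]

  inc <- setNames(residue_table()$increment_mass, residue_table()$name)
  mods <- setNames(modifier_table()$neutral_delta, modifier_table()$name)

  # meet-in-the-middle: grid A over (Hex, HexNAc, dHex), grid B over
  # (NeuAc, NeuGc, KDN, HexA, sulfate, phosphate)
  hex_min <- if (glycan_class == "N-glycan") 3L else 0L
  hexnac_min <- if (glycan_class == "N-glycan") 2L
                else if (reduced) 1L else 0L
  ga <- expand.grid(Hex = hex_min:b$Hex, HexNAc = hexnac_min:b$HexNAc,
                    dHex = 0:b$dHex)
  ga$mass <- ga$Hex * inc[["Hex"]] + ga$HexNAc * inc[["HexNAc"]] +
    ga$dHex * inc[["dHex"]]
  gb <- expand.grid(NeuAc = 0:b$NeuAc, NeuGc = 0:b$NeuGc, KDN = 0:b$KDN,
                    HexA = 0:b$HexA, sulfate = 0:b$sulfate,
                    phosphate = 0:b$phosphate)
  gb$mass <- gb$NeuAc * inc[["NeuAc"]] + gb$NeuGc * inc[["NeuGc"]] +
    gb$KDN * inc[["KDN"]] + gb$HexA * inc[["HexA"]] +
    gb$sulfate * mods[["sulfate"]] + gb$phosphate * mods[["phosphate"]]

  oa <- order(ga$mass)
  ga <- ga[oa, , drop = FALSE]
  rem <- target - termini - gb$mass
  j1 <- findInterval(rem - half, ga$mass) + 1L
  j2 <- findInterval(rem + half, ga$mass)
  hits <- which(j2 >= j1)
  if (!length(hits)) return(.empty_fits())
  rows <- lapply(hits, function(i) {
    js <- j1[i]:j2[i]
    cbind(ga[js, c("Hex", "HexNAc", "dHex"), drop = FALSE],
          gb[rep(i, length(js)), c("NeuAc", "NeuGc", "KDN", "HexA",
                                   "sulfate", "phosphate"), drop = FALSE])
  })
  out <- do.call(rbind, rows)
  # total residue count >= 1 and drop the all-zero residue row
  res_cols <- c("dHex", "Hex", "HexA", "HexNAc", "KDN", "NeuAc", "NeuGc")
  out <- out[rowSums(out[, res_cols]) >= 1, , drop = FALSE]
  if (!nrow(out)) return(.empty_fits())
  out$neutral_mass <- as.numeric(as.matrix(out[, res_cols]) %*%
                                   inc[res_cols]) +
    out$sulfate * mods[["sulfate"]] + out$phosphate * mods[["phosphate"]] +
    termini
  delta <- switch(adduct, proton = cc[["proton"]],
                  sodium = cc[["sodium_cation"]],
                  deprotonated = -cc[["proton"]])
  out$theoretical_mz <- (out$neutral_mass + z * delta) / z
  out$ppm <- ppm_error(precursor_mz, out$theoretical_mz)
  out <- out[abs(out$ppm) <= tol_ppm, , drop = FALSE]
  if (!nrow(out)) return(.empty_fits())
  out$composition <- apply(out[, c(res_cols, "sulfate", "phosphate")], 1,
                           function(r) {
                             r <- r[r > 0]
                             paste0(names(r), r, collapse = "")
                           })
  # deterministic ranking: absolute ppm, label as tie-break
  out <- out[order(abs(out$ppm), out$composition), , drop = FALSE]
  # ambiguity: theoretical masses within 2*tol of the top hit
  top <- out$theoretical_mz[1]
  out$ambiguous <- abs(ppm_error(out$theoretical_mz, top)) <= 2 * tol_ppm &
    seq_len(nrow(out)) > 1L
  if (nrow(out) > 1L && any(out$ambiguous)) {
    out$ambiguous[1] <- TRUE
  }
  out$ambiguity_note <- ""
  if (any(out$ambiguous)) {
    ref <- out[1, res_cols]
    for (i in which(out$ambiguous & seq_len(nrow(out)) > 1L)) {
      d <- unlist(out[i, res_cols] - ref)
      d <- d[d != 0]
      out$ambiguity_note[i] <- paste0(
        "vs rank 1: ", paste0(names(d), ifelse(d > 0, "+", ""), d,
                              collapse = ", "))
    }
    out$ambiguity_note[1] <- "isobaric near-tie present"
  }
  rownames(out) <- NULL
  out
}

.empty_fits <- function() {
  out <- data.frame(Hex = integer(0), HexNAc = integer(0), dHex = integer(0),
                    NeuAc = integer(0), NeuGc = integer(0), KDN = integer(0),
                    HexA = integer(0), sulfate = integer(0),
                    phosphate = integer(0), neutral_mass = numeric(0),
                    theoretical_mz = numeric(0), ppm = numeric(0),
                    composition = character(0), ambiguous = logical(0),
                    ambiguity_note = character(0), stringsAsFactors = FALSE)
  out
}

#' Export a glycotope report or candidate table as TSV
#'
#' Columns are written in a stable, documented order so outputs are
#' byte-reproducible across runs.
#'
#' @param x a `glycotope_report` or candidate data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_report <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a TSV written by [export_report()]
#' @param path file path.
#' @return Data frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, na.strings = "")
}
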