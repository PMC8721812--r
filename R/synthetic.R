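# Deterministic synthetic LC-MS/MS run generator with ground truth.
#
# Emulates the data the pipeline is designed for: Gaussian elution profiles
# per species (anomeric doublets for non-reduced glycans), data-dependent
# HCD-MS2 on the top-N precursors per MS1 cycle containing the species'
# catalog diagnostic ions at intensities proportional to the precursor
# signal (equal ionization response across species), product-dependent MS3
# on configured trigger ions, plus decoy peaks, multiplicative intensity
# noise and ppm jitter. Generation is a pure function of
# (mixture, noise spec, acquisition settings): the RNG state is restored on
# exit and the same seed reproduces the run byte for byte.

#' Declare one glycan species of a synthetic mixture
#'
#' @param composition a [glycan_composition()].
#' @param glycotopes character vector of catalog glycotope names the species
#'   carries (drives which diagnostic ions its MS2 spectra contain).
#' @param abundance abundance in arbitrary units (> 0); equals the MS1 apex
#'   intensity under the equal-response model.
#' @param rt elution apex in seconds.
#' @param rt_width Gaussian elution sigma in seconds (> 0).
#' @param label species label; defaults to the composition string.
#' @param doublet emit an anomeric doublet (two LC peaks); only permitted
#'   for non-reduced compositions.
#' @param doublet_split fraction of the abundance in the first anomer peak.
#' @param doublet_sep separation of the two anomer apexes in seconds.
#' @param polarity ionization polarity of the species.
#' @param adduct,z adduct and charge of the tracked precursor.
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(composition, glycotopes, abundance, rt,
                         rt_width = 6, label = NULL, doublet = FALSE,
                         doublet_split = 0.6, doublet_sep = NULL,
                         polarity = c("positive", "negative"),
                         adduct = NULL, z = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(composition, "glycan_composition"),
            abundance > 0, rt_width > 0)
  if (doublet && composition$reduced_end) {
    stop("anomeric doublets only occur for non-reduced compositions")
  }
  if (is.null(adduct)) {
    adduct <- if (polarity == "positive") "proton" else "deprotonated"
  }
  if (is.null(doublet_sep)) doublet_sep <- 5 * rt_width
  if (is.null(label)) label <- format(composition)
  structure(
    list(composition = composition, glycotopes = glycotopes,
         abundance = abundance, rt = rt, rt_width = rt_width, label = label,
         doublet = isTRUE(doublet), doublet_split = doublet_split,
         doublet_sep = doublet_sep, polarity = polarity, adduct = adduct,
         z = as.integer(z)),
    class = "species_spec"
  )
}

#' Noise model for synthetic runs
#'
#' @param seed RNG seed; generation is fully reproducible from it.
#' @param intensity_sigma multiplicative (log-normal) intensity noise sigma
#'   as a fraction (0.1 = 10%).
#' @param ppm_sigma Gaussian m/z jitter sigma in ppm, applied to every peak.
#' @param decoy_n decoy peaks added to every MS2/MS3 spectrum.
#' @param decoy_range m/z range of decoy peaks.
#' @param baseline_n baseline noise peaks per MS1 scan.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(seed = 1L, intensity_sigma = 0.1, ppm_sigma = 2,
                       decoy_n = 20L, decoy_range = c(150, 1500),
                       baseline_n = 0L) {
  stopifnot(intensity_sigma >= 0, ppm_sigma >= 0, decoy_n >= 0,
            baseline_n >= 0)
  structure(list(seed = as.integer(seed), intensity_sigma = intensity_sigma,
                 ppm_sigma = ppm_sigma, decoy_n = as.integer(decoy_n),
                 decoy_range = decoy_range, baseline_n = as.integer(baseline_n)),
            class = "noise_spec")
}

#' Zero-noise spec (for closure tests)
#' @param seed RNG seed (unused when all sigmas are zero, kept for identity).
#' @return A [noise_spec()] with all noise terms zero.
#' @export
zero_noise <- function(seed = 1L) {
  noise_spec(seed = seed, intensity_sigma = 0, ppm_sigma = 0, decoy_n = 0L,
             baseline_n = 0L)
}

.species_precursor_mz <- function(sp) {
  precursor_mz(composition_neutral_mass(sp$composition), sp$adduct, sp$z)
}

.species_profile <- function(sp, t) {
  if (sp$doublet) {
    sp$abundance * (sp$doublet_split *
                      exp(-(t - sp$rt)^2 / (2 * sp$rt_width^2)) +
                    (1 - sp$doublet_split) *
                      exp(-(t - sp$rt - sp$doublet_sep)^2 /
                            (2 * sp$rt_width^2)))
  } else {
    sp$abundance * exp(-(t - sp$rt)^2 / (2 * sp$rt_width^2))
  }
}

# relative fragment response by catalog role
.role_height <- c(required = 1.0, supporting = 0.5)

#' Generate a synthetic multi-level LC-MS/MS run
#'
#' @param mixture list of [species_spec()]s (non-empty).
#' @param noise a [noise_spec()].
#' @param catalog diagnostic-ion catalog supplying the fragment content of
#'   MS2/MS3 spectra.
#' @param scan_interval MS1 cycle time in seconds.
#' @param ms2_top_n data-dependent MS2 selections per MS1 cycle.
#' @param ms3_triggers numeric vector of MS2 product m/z values that trigger
#'   an MS3 scan (matched within `trigger_tol` m/z).
#' @param trigger_tol absolute m/z tolerance for MS3 triggering.
#' @param rt_range run time span in seconds; defaults to covering every
#'   species' elution to +/- 4 sigma.
#' @param min_precursor_intensity MS1 intensity below which a precursor is
#'   not selected for MS2.
#' @param ms2_yield fragment intensity per unit precursor intensity for
#'   required ions (supporting ions get half).
#' @return A [glycan_run()].
#' @export
generate_run <- function(mixture, noise = noise_spec(),
                         catalog = build_catalog(), scan_interval = 1,
                         ms2_top_n = 5L, ms3_triggers = numeric(0),
                         trigger_tol = 0.01, rt_range = NULL,
                         min_precursor_intensity = 1e-6, ms2_yield = 0.1) {
  if (!length(mixture)) stop("mixture must contain at least one species")
  stopifnot(all(vapply(mixture, inherits, logical(1), "species_spec")),
            inherits(noise, "noise_spec"))

  # private RNG stream: reproducible from the noise seed, restores state
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(noise$seed)

  if (is.null(rt_range)) {
    ends <- vapply(mixture, function(sp) {
      sp$rt + (if (sp$doublet) sp$doublet_sep else 0) + 4 * sp$rt_width
    }, numeric(1))
    starts <- vapply(mixture, function(sp) sp$rt - 4 * sp$rt_width,
                     numeric(1))
    rt_range <- c(max(0, min(starts)), max(ends))
  }
  times <- seq(rt_range[1], rt_range[2], by = scan_interval)
  polarities <- unique(vapply(mixture, `[[`, character(1), "polarity"))
  prec_mz <- vapply(mixture, .species_precursor_mz, numeric(1))

  jitter_mz <- function(mz) {
    if (noise$ppm_sigma > 0 && length(mz)) {
      mz * (1 + rnorm(length(mz), 0, noise$ppm_sigma * 1e-6))
    } else mz
  }
  jitter_int <- function(x) {
    if (noise$intensity_sigma > 0 && length(x)) {
      x * exp(rnorm(length(x), 0, noise$intensity_sigma))
    } else x
  }
  decoys <- function(ref_intensity) {
    n <- noise$decoy_n
    if (n == 0) return(list(mz = numeric(0), intensity = numeric(0)))
    list(mz = runif(n, noise$decoy_range[1], noise$decoy_range[2]),
         intensity = runif(n, 0.01, 0.3) * ref_intensity)
  }

  spectra <- list()
  scan_id <- 0L
  for (t in times) {
    for (pol in polarities) {
      sel <- which(vapply(mixture, `[[`, character(1), "polarity") == pol)
      prof <- vapply(mixture[sel], .species_profile, numeric(1), t = t)
      # MS1 scan
      scan_id <- scan_id + 1L
      ms1_id <- scan_id
      mz1 <- prec_mz[sel]
      int1 <- jitter_int(prof)
      keep <- int1 > 0
      mz1 <- jitter_mz(mz1[keep]); int1 <- int1[keep]
      if (noise$baseline_n > 0) {
        bs <- decoys(max(c(int1, 1)))
        nbl <- noise$baseline_n
        mz1 <- c(mz1, runif(nbl, noise$decoy_range[1], noise$decoy_range[2]))
        int1 <- c(int1, runif(nbl, 0.001, 0.05) * max(c(int1, 1)))
      }
      spectra[[length(spectra) + 1L]] <- spectrum_record(
        scan_id = ms1_id, ms_level = 1L, retention_time = t, polarity = pol,
        mz = mz1, intensity = int1)

      # data-dependent MS2 on the top-N species precursors
      ord <- order(prof, decreasing = TRUE)
      picks <- ord[prof[ord] > min_precursor_intensity]
      picks <- head(picks, ms2_top_n)
      for (p in picks) {
        sp <- mixture[[sel[p]]]
        ions <- catalog[catalog$glycotope %in% sp$glycotopes &
                          catalog$polarity == pol &
                          catalog$ms_level == 2L, , drop = FALSE]
        if (!nrow(ions)) next
        base_int <- ms2_yield * prof[p] * .role_height[ions$role]
        dk <- decoys(max(base_int))
        frag_mz <- jitter_mz(c(ions$mz, dk$mz))
        frag_int <- c(jitter_int(unname(base_int)), dk$intensity)
        scan_id <- scan_id + 1L
        ms2_id <- scan_id
        spectra[[length(spectra) + 1L]] <- spectrum_record(
          scan_id = ms2_id, ms_level = 2L,
          retention_time = t + 0.01 * match(p, picks), polarity = pol,
          mz = frag_mz, intensity = frag_int,
          precursor_mz = prec_mz[sel[p]], precursor_charge = sp$z)

        # product-dependent MS3
        for (trig in ms3_triggers) {
          hit <- which(abs(ions$mz - trig) <= trigger_tol)
          if (!length(hit)) next
          ms3 <- catalog[catalog$glycotope %in% sp$glycotopes &
                           catalog$polarity == pol &
                           catalog$ms_level == 3L &
                           !is.na(catalog$parent_mz) &
                           abs(catalog$parent_mz - trig) <= trigger_tol, ,
                         drop = FALSE]
          if (!nrow(ms3)) next
          b3 <- 0.3 * ms2_yield * prof[p] * .role_height[ms3$role]
          dk3 <- decoys(max(b3))
          scan_id <- scan_id + 1L
          spectra[[length(spectra) + 1L]] <- spectrum_record(
            scan_id = scan_id, ms_level = 3L,
            retention_time = t + 0.01 * match(p, picks) + 0.005,
            polarity = pol,
            mz = jitter_mz(c(ms3$mz, dk3$mz)),
            intensity = c(jitter_int(unname(b3)), dk3$intensity),
            precursor_mz = trig, precursor_charge = 1L,
            parent_scan_id = ms2_id)
        }
      }
    }
  }
  glycan_run(spectra, source = sprintf("synthetic(seed=%d)", noise$seed))
}

#' Closed-form expectations for a synthetic mixture
#'
#' Expected glycotope shares and XIC apex table under the equal-response
#' model of [generate_run()]: each selected MS2 scan carries all of a
#' species' catalog MS2 ions at intensities proportional to the precursor
#' signal (required ions at weight 1, supporting at 0.5), so a glycotope's
#' expected summed intensity is proportional to
#' `sum over species of abundance x total ion weight`, provided every
#' species elutes fully within the run with a common peak width.
#'
#' @param mixture list of [species_spec()]s.
#' @param catalog diagnostic-ion catalog (must match the one used for
#'   generation and mining).
#' @param ms3_triggers triggers used at generation time; MS3 ion weights
#'   (at the generator's 0.3 relative MS3 yield) are included for species
#'   whose MS2 ions fire a trigger.
#' @param trigger_tol trigger tolerance, as in [generate_run()].
#' @return List with `shares` (named numeric over all catalog glycotopes,
#'   summing to 1 when nonzero) and `apexes` (data frame `label`, `rt`,
#'   `height` of expected MS1 apex positions, doublets as two rows).
#' @export
ground_truth <- function(mixture, catalog = build_catalog(),
                         ms3_triggers = numeric(0), trigger_tol = 0.01) {
  gly <- unique(catalog$glycotope)
  w <- setNames(numeric(length(gly)), gly)
  for (sp in mixture) {
    ions <- catalog[catalog$glycotope %in% sp$glycotopes &
                      catalog$polarity == sp$polarity &
                      catalog$ms_level == 2L, , drop = FALSE]
    if (nrow(ions)) {
      add <- tapply(.role_height[ions$role], ions$glycotope, sum)
      w[names(add)] <- w[names(add)] + sp$abundance * add
    }
    if (length(ms3_triggers) && nrow(ions)) {
      fired <- vapply(ms3_triggers, function(tr) {
        any(abs(ions$mz - tr) <= trigger_tol)
      }, logical(1))
      for (tr in ms3_triggers[fired]) {
        ms3 <- catalog[catalog$glycotope %in% sp$glycotopes &
                         catalog$polarity == sp$polarity &
                         catalog$ms_level == 3L &
                         !is.na(catalog$parent_mz) &
                         abs(catalog$parent_mz - tr) <= trigger_tol, ,
                       drop = FALSE]
        if (nrow(ms3)) {
          add <- tapply(0.3 * .role_height[ms3$role], ms3$glycotope, sum)
          w[names(add)] <- w[names(add)] + sp$abundance * add
        }
      }
    }
  }
  shares <- if (sum(w) > 0) w / sum(w) else w
  apexes <- do.call(rbind, lapply(mixture, function(sp) {
    if (sp$doublet) {
      data.frame(label = sp$label,
                 rt = c(sp$rt, sp$rt + sp$doublet_sep),
                 height = sp$abundance * c(sp$doublet_split,
                                           1 - sp$doublet_split),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = sp$label, rt = sp$rt, height = sp$abundance,
                 stringsAsFactors = FALSE)
    }
  }))
  list(shares = shares, apexes = apexes)
}
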