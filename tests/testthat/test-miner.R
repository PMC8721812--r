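# Diagnostic-ion matching, glycotope quantification, precursor filtering
# and composition fitting.

cat_tab <- build_catalog()

test_that("diagnostic ions match within tolerance, with known ppm jitter", {
  b <- b_ion_mz("NeuAc")
  db <- neutral_loss_mz(b, "meoh")
  sp <- make_ms2(c(shift_ppm(b, 2), shift_ppm(db, -2)), c(1000, 400))
  m <- match_diagnostic_ions(sp, cat_tab, tol_ppm = 5)
  neuac <- m[m$glycotope == "NeuAc", ]
  expect_equal(nrow(neuac), 2L)
  expect_equal(sort(abs(neuac$ppm)), c(2, 2), tolerance = 1e-6)

  # +8 ppm: rejected at 5 ppm, accepted at 10 ppm
  sp8 <- make_ms2(shift_ppm(b, 8), 1000)
  expect_equal(nrow(match_diagnostic_ions(sp8, cat_tab, tol_ppm = 5)), 0L)
  m10 <- match_diagnostic_ions(sp8, cat_tab, tol_ppm = 10)
  expect_true("NeuAc" %in% m10$glycotope)

  # empty peak list and level-1 input
  empty <- make_ms2(numeric(0), numeric(0))
  expect_equal(nrow(match_diagnostic_ions(empty, cat_tab)), 0L)
  ms1 <- spectrum_record(1L, 1L, 0, "positive", mz = b, intensity = 1)
  expect_error(match_diagnostic_ions(ms1, cat_tab), "MS2 or MS3")
})

test_that("the nearest peak wins and ties break deterministically", {
  b <- b_ion_mz("NeuAc")
  sp <- make_ms2(c(shift_ppm(b, -4), shift_ppm(b, 1)), c(10, 20))
  m <- match_diagnostic_ions(sp, cat_tab)
  m <- m[m$glycotope == "NeuAc", ]
  expect_equal(nrow(m), 1L)
  expect_equal(m$ppm, 1, tolerance = 1e-6)
  expect_equal(m$intensity, 20)
})

test_that("matching equals the brute-force all-pairs oracle on a noisy run", {
  mix <- list(core1_species("NeuAc", 100, 30, rt_width = 4),
              core1_species("KDN", 40, 45, rt_width = 4))
  run <- generate_run(mix, noise_spec(seed = 42, intensity_sigma = 0.1,
                                      ppm_sigma = 2, decoy_n = 15),
                      scan_interval = 4, ms2_top_n = 2)
  scans <- run_spectra(run, ms_level = 2:3)
  expect_lte(length(run$spectra), 50)
  expect_gt(length(scans), 5)
  for (s in scans) {
    got <- match_diagnostic_ions(s, cat_tab, tol_ppm = 5)
    ref <- oracle_match(s, cat_tab, tol_ppm = 5)
    expect_equal(got$theoretical_mz, ref$theoretical_mz, tolerance = 1e-12)
    expect_equal(got$observed_mz, ref$observed_mz, tolerance = 1e-12)
    expect_equal(got$intensity, ref$intensity, tolerance = 1e-12)
  }
})

test_that("glycotope shares recover a 3:1 mixture exactly at zero noise", {
  mix <- list(core1_species("NeuAc", 3, 30), core1_species("NeuGc", 1, 60))
  run <- generate_run(mix, zero_noise(), scan_interval = 2, ms2_top_n = 2,
                      rt_range = c(0, 110))
  rep <- summarize_glycotopes(run, cat_tab)
  expect_s3_class(rep, "glycotope_report")
  expect_equal(sum(rep$share), 1, tolerance = 1e-9)
  expect_equal(rep$share[rep$glycotope == "NeuAc"], 0.75, tolerance = 0.02)
  expect_equal(rep$share[rep$glycotope == "NeuGc"], 0.25, tolerance = 0.02)
  expect_equal(sum(rep$share[!rep$glycotope %in% c("NeuAc", "NeuGc")]), 0)
})

test_that("a single-glycotope run gets share 1 and empty runs warn", {
  run <- generate_run(list(core1_species("KDN", 5, 20)), zero_noise(),
                      scan_interval = 2, ms2_top_n = 1)
  rep <- summarize_glycotopes(run, cat_tab)
  expect_equal(rep$share[rep$glycotope == "KDN"], 1)
  # run with scans but nothing matching the catalog
  blank <- glycan_run(list(
    spectrum_record(1L, 1L, 0, "positive", mz = 900, intensity = 1),
    spectrum_record(2L, 2L, 0.1, "positive", mz = 111.111, intensity = 5,
                    precursor_mz = 900)))
  expect_warning(rep0 <- summarize_glycotopes(blank, cat_tab), "no diagnostic")
  expect_true(all(rep0$share == 0))
})

test_that("MS3-only evidence is credited to the right glycotope by level", {
  # MS2 parent with no catalog ions; MS3 at 784.40 under parent 1029.52
  ms1 <- spectrum_record(1L, 1L, 0, "positive", mz = 2000, intensity = 10)
  ms2 <- spectrum_record(2L, 2L, 0.1, "positive", mz = c(555.5, 1029.5224),
                         intensity = c(5, 8), precursor_mz = 2000)
  ms3 <- spectrum_record(3L, 3L, 0.2, "positive", mz = 784.3962,
                         intensity = 50, precursor_mz = 1029.5224,
                         parent_scan_id = 2L)
  run <- glycan_run(list(ms1, ms2, ms3))
  rep <- summarize_glycotopes(run, cat_tab)
  # the 1029.52 MS2 peak matches the B4; the MS3 784 goes to the same
  # glycotope (level-keyed), never to KDN-LacNAc whose 784 is an MS2 ion
  expect_gt(rep$share[rep$glycotope == "Gal-NeuAc-Gal-GlcNAc"], 0)
  expect_equal(rep$share[rep$glycotope == "KDN-LacNAc"], 0)
  expect_equal(rep$ms3_intensity[rep$glycotope == "Gal-NeuAc-Gal-GlcNAc"], 50)
  # with combine_ms3 = FALSE the MS3 intensity is excluded from shares
  rep2 <- summarize_glycotopes(run, cat_tab, combine_ms3 = FALSE)
  expect_equal(rep2$summed_intensity[rep2$glycotope == "Gal-NeuAc-Gal-GlcNAc"],
               rep2$ms2_intensity[rep2$glycotope == "Gal-NeuAc-Gal-GlcNAc"])
})

test_that("MS3 matching is keyed on the recorded parent ion", {
  # same 784.40 fragment, but under the 1203.61 parent: credited to the
  # fucosylated glycotope's supporting MS3 ion, not to the 1029.52 one
  ms1 <- spectrum_record(1L, 1L, 0, "positive", mz = 2000, intensity = 10)
  ms2 <- spectrum_record(2L, 2L, 0.1, "positive", mz = 1203.6116,
                         intensity = 8, precursor_mz = 2000)
  ms3 <- spectrum_record(3L, 3L, 0.2, "positive", mz = 784.3962,
                         intensity = 30, precursor_mz = 1203.6116,
                         parent_scan_id = 2L)
  m <- match_diagnostic_ions(ms3, cat_tab)
  expect_equal(m$glycotope, "Galb4-sialyl-LeX-NeuAc")
})

test_that("precursor filtering keeps >= min_diag spectra and merges groups", {
  b1 <- b_ion_mz("NeuAc"); b2 <- neutral_loss_mz(b1, "meoh")
  two_ion <- function(id, pmz) {
    ms1 <- spectrum_record(id, 1L, id, "positive", mz = pmz, intensity = 1)
    ms2 <- spectrum_record(id + 1L, 2L, id + 0.1, "positive",
                           mz = c(b1, b2), intensity = c(10, 5),
                           precursor_mz = pmz, precursor_charge = 1L)
    list(ms1, ms2)
  }
  one_ion <- spectrum_record(10L, 2L, 10, "positive", mz = b1,
                             intensity = 10, precursor_mz = 700,
                             precursor_charge = 1L)
  run <- glycan_run(c(two_ion(1L, 873.4803),
                      two_ion(4L, shift_ppm(873.4803, 3)),
                      list(one_ion)))
  cands <- filter_candidate_precursors(run, cat_tab, min_diag = 2, fit = FALSE)
  # the two 2-ion scans share a precursor within 5 ppm -> one candidate with
  # summed ion count; the 1-ion scan at 700 is excluded
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$n_scans, 2L)
  expect_equal(cands$diag_count, 4L)
  expect_false(any(abs(cands$precursor_mz - 700) < 1))
  # at min_diag = 1 the 700 precursor appears too
  cands1 <- filter_candidate_precursors(run, cat_tab, min_diag = 1,
                                        fit = FALSE)
  expect_equal(nrow(cands1), 2L)
})

test_that("mining is monotone in tolerance and threshold", {
  mix <- list(core1_species("NeuAc", 10, 20, rt_width = 4),
              core1_species("NeuGc", 5, 30, rt_width = 4))
  run <- generate_run(mix, noise_spec(seed = 7, ppm_sigma = 3, decoy_n = 10),
                      scan_interval = 4, ms2_top_n = 2)
  sums <- vapply(c(1, 2, 5, 10), function(tol) {
    sum(summarize_glycotopes(run, cat_tab, tol_ppm = tol)$summed_intensity)
  }, numeric(1))
  expect_true(all(diff(sums) >= 0))
  ncand <- vapply(1:4, function(md) {
    nrow(filter_candidate_precursors(run, cat_tab, min_diag = md,
                                     fit = FALSE))
  }, numeric(1))
  expect_true(all(diff(ncand) <= 0))
})

test_that("mining the same run twice is byte-identical", {
  mix <- list(core1_species("NeuAc", 10, 20, rt_width = 4))
  run <- generate_run(mix, noise_spec(seed = 3), scan_interval = 4,
                      ms2_top_n = 1)
  f1 <- tempfile(); f2 <- tempfile()
  export_report(summarize_glycotopes(run, cat_tab), f1)
  export_report(summarize_glycotopes(run, cat_tab), f2)
  expect_identical(readLines(f1), readLines(f2))
  r <- read_report(f1)
  expect_equal(r$share, summarize_glycotopes(run, cat_tab)$share,
               tolerance = 1e-6)
})

test_that("composition fitting recovers the printed sulfated O-glycans", {
  # sulfated NeuAc-sialylated core 1, [M-H]- printed as 937
  hits <- fit_composition(937.41, z = 1, adduct = "deprotonated",
                          glycan_class = "O-glycan")
  expect_gt(nrow(hits), 0)
  expect_equal(hits$composition[1], "Hex1HexNAc1NeuAc1sulfate1")
  expect_true(hits$ambiguous[1])  # NeuGc+dHex / KDN+HexNAc isobars co-fit
  expect_true(any(grepl("NeuGc", hits$ambiguity_note[-1]) |
                    grepl("KDN", hits$ambiguity_note[-1])))

  # non-sulfated core 1 at the exact theoretical [M+H]+ (printed 873.5)
  core1 <- glycan_composition(c(NeuAc = 1, Hex = 1, HexNAc = 1),
                              reduced_end = TRUE)
  mzp <- precursor_mz(composition_neutral_mass(core1), "proton", 1)
  hits2 <- fit_composition(mzp, z = 1, adduct = "proton",
                           glycan_class = "O-glycan")
  expect_equal(hits2$composition[1], "Hex1HexNAc1NeuAc1")
  expect_equal(hits2$ppm[1], 0, tolerance = 1e-6)

  # below any plausible N-glycan mass
  expect_equal(nrow(fit_composition(100, z = 1, adduct = "proton",
                                    glycan_class = "N-glycan")), 0L)
})

test_that("fitting respects bounds, class constraints and charge", {
  # disallowing sulfate removes the 937 assignment entirely
  none <- fit_composition(937.41, z = 1, adduct = "deprotonated",
                          glycan_class = "O-glycan",
                          bounds = list(sulfate = 0, phosphate = 0,
                                        HexA = 0))
  expect_false(any(grepl("sulfate", none$composition)))
  # every N-glycan hit satisfies the core constraint
  ng <- fit_composition(2000.99, z = 1, adduct = "proton",
                        glycan_class = "N-glycan", tol_ppm = 50)
  if (nrow(ng)) {
    expect_true(all(ng$HexNAc >= 2 & ng$Hex >= 3))
  }
  # a doubly deprotonated precursor maps back to the right neutral mass
  comp <- glycan_composition(c(Hex = 5, HexNAc = 4, NeuGc = 1), sulfate = 2,
                             glycan_class = "N-glycan")
  mz2 <- precursor_mz(composition_neutral_mass(comp), "deprotonated", 2)
  hits <- fit_composition(mz2, z = 2, adduct = "deprotonated",
                          glycan_class = "N-glycan")
  expect_equal(hits$composition[1], "Hex5HexNAc4NeuGc1sulfate2")
  expect_equal(hits$ppm[1], 0, tolerance = 1e-6)
})

test_that("candidate fitting picks adduct and charge by best ppm", {
  # a sodiated positive-mode precursor with unknown charge
  comp <- glycan_composition(c(NeuAc = 1, Hex = 1, HexNAc = 1),
                             reduced_end = TRUE)
  mzna <- precursor_mz(composition_neutral_mass(comp), "sodium", 1)
  b1 <- b_ion_mz("NeuAc"); b2 <- neutral_loss_mz(b1, "meoh")
  run <- glycan_run(list(
    spectrum_record(1L, 1L, 0, "positive", mz = mzna, intensity = 10),
    spectrum_record(2L, 2L, 0.1, "positive", mz = c(b1, b2),
                    intensity = c(10, 5), precursor_mz = mzna)))
  cands <- filter_candidate_precursors(run, cat_tab, min_diag = 2)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$adduct, "sodium")
  expect_equal(cands$fit_z, 1L)
  expect_equal(cands$composition, "Hex1HexNAc1NeuAc1")
})
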