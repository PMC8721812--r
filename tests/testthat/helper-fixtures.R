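# Shared fixture builders: tiny hand-constructed spectra and runs.

make_ms2 <- function(mz, intensity = rep(100, length(mz)), scan_id = 1L,
                     rt = 10, polarity = "positive", precursor_mz = 1000,
                     precursor_charge = 1L) {
  spectrum_record(scan_id = scan_id, ms_level = 2L, retention_time = rt,
                  polarity = polarity, mz = mz, intensity = intensity,
                  precursor_mz = precursor_mz,
                  precursor_charge = precursor_charge)
}

# shift an m/z by a signed ppm amount
shift_ppm <- function(mz, ppm) mz * (1 + ppm * 1e-6)

# canonical test species: sialylated core-1 O-glycans carrying exactly one
# sialic-acid reporter glycotope each
core1_species <- function(sia, abundance, rt, n_sia = 1L, rt_width = 6,
                          label = NULL, ...) {
  comp <- glycan_composition(setNames(c(1L, 1L, n_sia),
                                      c("Hex", "HexNAc", sia)),
                             reduced_end = TRUE, glycan_class = "O-glycan")
  species_spec(comp, glycotopes = sia, abundance = abundance, rt = rt,
               rt_width = rt_width, label = label, ...)
}
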