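# Independent brute-force oracles used to check the mass engine and the
# ppm matcher. These deliberately do not reuse package internals: atomic
# masses are written down independently (AME2020 values) and the formula
# parser is a different implementation.

oracle_atomic <- c(C = 12.0, H = 1.007825032, N = 14.003074005,
                   O = 15.994914620, S = 31.972071174, P = 30.973761998)
oracle_electron <- 0.000548580

oracle_formula_mass <- function(formula) {
  total <- 0
  rest <- formula
  while (nzchar(rest)) {
    el <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    rest <- substring(rest, nchar(el) + 1)
    num <- regmatches(rest, regexpr("^[0-9]*", rest))
    rest <- substring(rest, nchar(num) + 1)
    n <- if (nzchar(num)) as.numeric(num) else 1
    total <- total + oracle_atomic[[el]] * n
  }
  total
}

# all-pairs nearest-peak-within-tolerance search: the reference behaviour
# for match_diagnostic_ions on one spectrum
oracle_match <- function(spectrum, catalog, tol_ppm = 5, parent_tol = 0.7) {
  sub <- catalog[catalog$polarity == spectrum$polarity &
                   catalog$ms_level == spectrum$ms_level, , drop = FALSE]
  if (spectrum$ms_level == 3L && nrow(sub)) {
    sub <- sub[is.na(sub$parent_mz) |
                 abs(sub$parent_mz - spectrum$precursor_mz) <= parent_tol, ,
               drop = FALSE]
  }
  hits <- list()
  for (i in seq_len(nrow(sub))) {
    best_j <- NA_integer_
    best_ppm <- Inf
    for (j in seq_along(spectrum$mz)) {
      p <- 1e6 * (spectrum$mz[j] - sub$mz[i]) / sub$mz[i]
      if (abs(p) <= tol_ppm && abs(p) < abs(best_ppm)) {
        best_ppm <- p
        best_j <- j
      }
    }
    if (!is.na(best_j)) {
      hits[[length(hits) + 1L]] <- data.frame(
        glycotope = sub$glycotope[i], theoretical_mz = sub$mz[i],
        observed_mz = spectrum$mz[best_j],
        intensity = spectrum$intensity[best_j], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(glycotope = character(0), theoretical_mz = numeric(0),
                      observed_mz = numeric(0), intensity = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$theoretical_mz), , drop = FALSE]
}
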