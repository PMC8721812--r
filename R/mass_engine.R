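# Monoisotopic mass arithmetic for permethylated glycans.
#
# All masses are monoisotopic Da. Residue "increments" are the masses added
# to a growing permethylated chain by one glycosidically linked residue;
# termini adjustments convert a sum of increments into a neutral molecule
# (free reducing end vs borohydride-reduced alditol). Electron mass is folded
# into the charged-species constants (proton, sodium, B-cation cap), so ion
# m/z arithmetic stays within ~0.002 Da of the exact electron-aware value.

.element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163
)

#' Monoisotopic mass of an elemental formula
#'
#' Sums monoisotopic atomic masses for a simple CHNOSP formula given either
#' as a string (e.g. `"C9H16O5"`) or as a named count vector
#' (e.g. `c(C = 9, H = 16, O = 5)`).
#'
#' @param formula character scalar like `"C11H19NO5"`, or a named numeric
#'   vector of element counts.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("C9H16O5")    # permethylated Hex increment, 204.0998
#' formula_mass(c(C = 1, H = 4, O = 1))  # methanol, 32.0262
#' @export
formula_mass <- function(formula) {
  if (is.character(formula)) {
    stopifnot(length(formula) == 1L)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    toks <- regmatches(formula, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    counts <- numeric(0)
    for (tk in toks) {
      el <- gsub("[0-9]+", "", tk)
      n <- sub("^[A-Za-z]+", "", tk)
      n <- if (nzchar(n)) as.numeric(n) else 1
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + n
    }
    formula <- counts
  }
  bad <- setdiff(names(formula), names(.element_masses))
  if (length(bad)) {
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  sum(.element_masses[names(formula)] * formula)
}

# Canonical permethylated residue increments. HexA is the methyl-esterified
# permethylated residue (the carboxyl is esterified during permethylation).
.residue_table <- data.frame(
  name = c("dHex", "Hex", "HexA", "HexNAc", "KDN", "NeuAc", "NeuGc"),
  formula = c("C8H14O4", "C9H16O5", "C9H14O6", "C11H19NO5",
              "C14H24O8", "C16H27NO8", "C17H29NO9"),
  increment_mass = c(174.08920, 204.09977, 218.07904, 245.12632,
                     320.14712, 361.17367, 391.18423),
  stringsAsFactors = FALSE
)

#' Residue classes known to the mass engine
#' @return Data frame with columns `name`, `formula`, `increment_mass`.
#' @export
residue_table <- function() .residue_table

#' Permethylated residue increment mass
#'
#' @param name residue class: one of `dHex`, `Hex`, `HexA`, `HexNAc`,
#'   `KDN`, `NeuAc`, `NeuGc` (vectorised).
#' @return Increment mass(es) in Da.
#' @examples
#' residue_increment_mass("Hex")   # 204.0998
#' residue_increment_mass("dHex")  # 174.0892, the Fuc increment
#' @export
residue_increment_mass <- function(name) {
  idx <- match(name, .residue_table$name)
  if (anyNA(idx)) {
    stop("unknown residue class(es): ",
         paste(unique(name[is.na(idx)]), collapse = ", "),
         "; known classes are ", paste(.residue_table$name, collapse = ", "))
  }
  .residue_table$increment_mass[idx]
}

# Termini / fragment / adduct constants (Da). sulfo_anion_shift converts a
# non-sulfated B-cation m/z into the corresponding monosulfated B-anion m/z
# (+SO3 - CH2 - 2H); methylphospho_anion_shift is the analogue for an
# O-methylated phosphate (+HPO3 - 2H, the methyl is retained), which yields
# the 297.07 methyl-phospho-Hex fragment that discriminates M6P from the
# isobaric-by-nominal-mass sulfo-HexA fragment at 297.03.
.glyco_constants <- c(
  free_reducing_adjust     = 46.04186,
  alditol_adjust           = 62.07316,
  b_cation_cap             = 15.02293,
  meoh_loss                = 32.02621,
  demethyl_internal        = 14.01565,
  sulfo_anion_shift        = 63.92551,
  methylphospho_anion_shift = 77.95068,
  water                    = 18.01056,
  proton                   = 1.00728,
  sodium_cation            = 22.98922
)

#' Termini, fragment and adduct constants
#' @return Named numeric vector of constants in Da.
#' @export
glyco_constants <- function() .glyco_constants

# Neutral mass deltas of modifications applied to a fully permethylated
# molecule. Sulfate and phosphate each replace one methyl (+X - CH2);
# methyl-phosphate keeps the methyl on the phosphate oxygen (+HPO3).
.modifier_table <- data.frame(
  name = c("sulfate", "phosphate", "methyl-phosphate"),
  neutral_delta = c(65.94116, 65.95068, 79.96633),
  stringsAsFactors = FALSE
)

#' Modification deltas for permethylated glycans
#' @return Data frame with columns `name` and `neutral_delta` (Da).
#' @export
modifier_table <- function() .modifier_table

#' Construct a glycan composition
#'
#' A composition is the unit of precursor mass fitting: residue counts,
#' modification counts, a reduced-end flag (alditol, as for O-glycans
#' released by reductive elimination, vs free reducing end as for
#' PNGase-released N-glycans) and a glycan class used for plausibility
#' constraints (N-glycans must contain the chitobiose-trimannosyl core,
#' i.e. HexNAc >= 2 and Hex >= 3; reduced O-glycans must contain the
#' GalNAc-ol, i.e. HexNAc >= 1).
#'
#' @param counts named integer vector of residue counts, names drawn from
#'   [residue_table()].
#' @param sulfate,phosphate,methyl_phosphate modification counts.
#' @param reduced_end logical; `TRUE` for alditols.
#' @param glycan_class `"N-glycan"` or `"O-glycan"`.
#' @param check enforce class plausibility constraints (default `TRUE`).
#' @return An object of class `glycan_composition`.
#' @examples
#' glycan_composition(c(NeuAc = 1, Hex = 1, HexNAc = 1),
#'                    sulfate = 1, reduced_end = TRUE,
#'                    glycan_class = "O-glycan")
#' @export
glycan_composition <- function(counts, sulfate = 0L, phosphate = 0L,
                               methyl_phosphate = 0L, reduced_end = FALSE,
                               glycan_class = c("O-glycan", "N-glycan"),
                               check = TRUE) {
  glycan_class <- match.arg(glycan_class)
  if (is.null(names(counts)) || !all(names(counts) %in% .residue_table$name)) {
    stop("counts must be named by residue class (",
         paste(.residue_table$name, collapse = ", "), ")")
  }
  if (any(counts < 0) || any(c(sulfate, phosphate, methyl_phosphate) < 0)) {
    stop("residue and modifier counts must be non-negative")
  }
  full <- setNames(integer(nrow(.residue_table)), .residue_table$name)
  full[names(counts)] <- as.integer(counts)
  if (sum(full) < 1) stop("composition must contain at least one residue")
  if (check) {
    if (glycan_class == "N-glycan" && (full[["HexNAc"]] < 2 || full[["Hex"]] < 3)) {
      stop("N-glycan composition requires HexNAc >= 2 and Hex >= 3")
    }
    if (glycan_class == "O-glycan" && reduced_end && full[["HexNAc"]] < 1) {
      stop("reduced O-glycan composition requires HexNAc >= 1 (the GalNAc-ol)")
    }
  }
  structure(
    list(counts = full,
         sulfate = as.integer(sulfate),
         phosphate = as.integer(phosphate),
         methyl_phosphate = as.integer(methyl_phosphate),
         reduced_end = isTRUE(reduced_end),
         glycan_class = glycan_class),
    class = "glycan_composition"
  )
}

#' @export
format.glycan_composition <- function(x, ...) {
  res <- x$counts[x$counts > 0]
  s <- paste0(names(res), res, collapse = "")
  mods <- c(sulfate = x$sulfate, phosphate = x$phosphate,
            `methyl-phosphate` = x$methyl_phosphate)
  mods <- mods[mods > 0]
  if (length(mods)) s <- paste0(s, "+", paste0(names(mods), mods, collapse = "+"))
  paste0(s, if (x$reduced_end) " (reduced)" else " (free reducing end)",
         " [", x$glycan_class, "]")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Neutral monoisotopic mass of a permethylated glycan composition
#'
#' Sum of residue increments, plus the termini adjustment (alditol for
#' reduced compositions, otherwise free reducing end), plus modification
#' deltas.
#'
#' @param comp a [glycan_composition()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' comp <- glycan_composition(c(NeuAc = 1, Hex = 1, HexNAc = 1),
#'                            sulfate = 1, reduced_end = TRUE)
#' composition_neutral_mass(comp)  # 938.414; [M-H]- = 937.41
#' @export
composition_neutral_mass <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  termini <- if (comp$reduced_end) .glyco_constants[["alditol_adjust"]]
             else .glyco_constants[["free_reducing_adjust"]]
  sum(comp$counts * .residue_table$increment_mass) + termini +
    comp$sulfate * .modifier_table$neutral_delta[1] +
    comp$phosphate * .modifier_table$neutral_delta[2] +
    comp$methyl_phosphate * .modifier_table$neutral_delta[3]
}

#' Precursor m/z from a neutral mass
#'
#' @param neutral_mass neutral monoisotopic mass in Da.
#' @param adduct `"proton"` (\[M+zH\]z+), `"sodium"` (\[M+zNa\]z+) or
#'   `"deprotonated"` (\[M-zH\]z-).
#' @param z charge (positive integer; the polarity is implied by the adduct).
#' @return m/z of the ion.
#' @examples
#' precursor_mz(872.47, "proton", 1)        # 873.48
#' precursor_mz(938.41, "deprotonated", 1)  # 937.41
#' @export
precursor_mz <- function(neutral_mass, adduct = c("proton", "sodium",
                                                  "deprotonated"), z = 1L) {
  adduct <- match.arg(adduct)
  if (length(z) != 1L || is.na(z) || z < 1) stop("z must be a positive integer")
  delta <- switch(adduct,
                  proton = .glyco_constants[["proton"]],
                  sodium = .glyco_constants[["sodium_cation"]],
                  deprotonated = -.glyco_constants[["proton"]])
  (neutral_mass + z * delta) / z
}

#' Invert precursor m/z to a neutral mass
#' @inheritParams precursor_mz
#' @param mz observed precursor m/z.
#' @return Neutral mass in Da.
#' @export
neutral_from_mz <- function(mz, adduct = c("proton", "sodium",
                                           "deprotonated"), z = 1L) {
  adduct <- match.arg(adduct)
  if (length(z) != 1L || is.na(z) || z < 1) stop("z must be a positive integer")
  delta <- switch(adduct,
                  proton = .glyco_constants[["proton"]],
                  sodium = .glyco_constants[["sodium_cation"]],
                  deprotonated = -.glyco_constants[["proton"]])
  mz * z - z * delta
}

#' Positive-mode oxonium (B) ion m/z
#'
#' The non-reducing-end glycosidic fragment cation of a permethylated
#' glycan: the sum of residue increments capped by the terminal methyl that
#' forms the oxocarbenium ion.
#'
#' @param sequence character vector of residue classes, non-reducing end
#'   first (order does not affect the mass).
#' @return m/z of the singly charged B cation.
#' @examples
#' b_ion_mz("NeuAc")                                  # 376.20
#' b_ion_mz(c("dHex", "HexNAc"))                      # 434.24
#' b_ion_mz(c("Hex", "NeuAc", "Hex", "HexNAc"))       # 1029.52
#' @export
b_ion_mz <- function(sequence) {
  if (length(sequence) == 0) stop("sequence must contain at least one residue")
  sum(residue_increment_mass(sequence)) + .glyco_constants[["b_cation_cap"]]
}

#' Negative-mode monosulfated B-ion m/z
#'
#' Converts the positive-mode B cation of a sequence into the corresponding
#' monosulfated B anion by the sulfation anion shift (+SO3 - CH2 - 2H):
#' one methyl is replaced by the sulfate and the ion is observed
#' deprotonated.
#'
#' @inheritParams b_ion_mz
#' @return m/z of the singly charged monosulfated B anion.
#' @examples
#' sulfo_b_anion_mz("Hex")                      # 283.05
#' sulfo_b_anion_mz("HexA")                     # 297.03 (HNK-1 B1)
#' sulfo_b_anion_mz(c("HexA", "Hex", "HexNAc")) # 746.25 (HNK-1 B3)
#' @export
sulfo_b_anion_mz <- function(sequence) {
  b_ion_mz(sequence) + .glyco_constants[["sulfo_anion_shift"]]
}

#' Neutral-loss m/z arithmetic for fragment ions
#'
#' Applies the neutral losses that generate the satellite ions of
#' permethylated-glycan fragmentation: methanol elimination (-32.0262,
#' indicating an unsubstituted 3-position), internal OMe -> OH demethylation
#' (-14.0157, e.g. after glycosidic loss of a substituent), or loss of a
#' whole residue. A residue can leave either as `"<residue>-OH"` (glycosidic
#' cleavage leaving a hydroxyl: increment + 14.0157) or as
#' `"<residue>-elim"` (3-substituent elimination taking the methoxy with it:
#' increment + 32.0262).
#'
#' @param base_mz starting fragment m/z.
#' @param loss one of `"meoh"`, `"demethyl"`, `"<residue>-OH"`,
#'   `"<residue>-elim"` where `<residue>` is a residue class.
#' @return m/z after the loss.
#' @examples
#' neutral_loss_mz(376.1966, "meoh")       # 344.17 (dNeuAc+)
#' neutral_loss_mz(434.2384, "demethyl")   # 420.22 (Fuc(HO)HexNAc+)
#' neutral_loss_mz(1203.6117, "dHex-elim") # 997.50 (Fuc elimination)
#' @export
neutral_loss_mz <- function(base_mz, loss) {
  delta <- if (identical(loss, "meoh")) {
    .glyco_constants[["meoh_loss"]]
  } else if (identical(loss, "demethyl")) {
    .glyco_constants[["demethyl_internal"]]
  } else if (grepl("-OH$", loss)) {
    residue_increment_mass(sub("-OH$", "", loss)) +
      .glyco_constants[["demethyl_internal"]]
  } else if (grepl("-elim$", loss)) {
    residue_increment_mass(sub("-elim$", "", loss)) +
      .glyco_constants[["meoh_loss"]]
  } else {
    stop("unknown loss: ", loss)
  }
  out <- base_mz - delta
  if (any(out <= 0)) stop("neutral loss exceeds the fragment mass")
  out
}

#' Signed parts-per-million mass error
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return Signed ppm error, `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(1000.005, 1000)  # +5
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Display m/z at the printed precision
#'
#' Glycomics figures conventionally print truncated (floored) monoisotopic
#' m/z for annotated fragments, and 2-decimal values where close species
#' must be discriminated. The engine always carries full precision; this
#' helper renders a value for display.
#'
#' @param mz m/z value(s).
#' @param digits 0 (default) truncates to the integer part; otherwise rounds
#'   to `digits` decimals.
#' @return Numeric vector at display precision.
#' @examples
#' mz_display(376.1966)       # 376
#' mz_display(297.0274, 2)    # 297.03
#' @export
mz_display <- function(mz, digits = 0) {
  if (digits == 0) floor(mz) else round(mz, digits)
}
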