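---
title: "Glycotope-centric mining of permethylated-glycan LC-MS/MS runs"
author: "glycomine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycotope-centric mining of permethylated-glycan LC-MS/MS runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomine)
```

## The problem

Terminal glycan epitopes — glycotopes such as sialylated LacNAc and
LacdiNAc, Lewis-type fucosylated units, the HNK-1 epitope
(SO~3~-3GlcAβ1-3Galβ1-4GlcNAc) and 3-O-sulfated galactose — are the parts
of N- and O-glycans that carbohydrate-binding proteins actually read. In
organisms such as zebrafish the picture is complicated by an extra
β4-galactose on the Galβ1-4GlcNAc building block and by three sialic acids
(NeuAc, NeuGc, KDN) whose mass relationships create systematic composition
ambiguities: the NeuGc−NeuAc difference equals Hex−deoxyHex (30.0106 Da)
and NeuAc−KDN equals HexNAc−Hex (41.0265 Da), so MS^1^ masses alone cannot
resolve many species.

The workflow implemented here sidesteps MS^1^ ambiguity by quantifying
glycotopes directly from their fragment ions. Permethylated glycans are
analysed by nano-LC with HCD-MS^2^ and product-dependent CID-MS^3^
acquisition in positive mode (and by negative-mode MS^2^ for
sulfate-enriched fractions). Each glycotope produces characteristic
oxonium (B) ions and satellites whose masses follow from fixed
permethylated residue increments, and the pipeline:

1. matches a curated catalog of diagnostic ions against every MS^2^/MS^3^
   scan at a strict ppm tolerance (default 5 ppm);
2. sums the matched intensities per glycotope and normalizes each sum to
   the total, giving the relative glycotope distribution of the sample;
3. retains precursors whose MS^2^ spectra contain at least 2 targeted ions
   (default) and fits their masses to glycosyl compositions;
4. profiles identified species by accurate-mass extracted ion
   chromatograms (XICs) normalized to a reference structure.

## Mass model

All masses are monoisotopic. A permethylated residue contributes a fixed
increment: dHex 174.0892, Hex 204.0998, HexA 218.0790 (carboxyl
methyl-esterified, as permethylation leaves it), HexNAc 245.1263, KDN
320.1471, NeuAc 361.1737, NeuGc 391.1842 Da. Internally the package stores
these at five decimals, computed from elemental formulas; the extra digit
keeps the two isobaric identities above satisfied with margin and lets
exactly co-fitting compositions separate deterministically. Termini
constants convert increment sums into molecules or ions:

* free reducing end +46.0419, alditol (reduced) +62.0732;
* B (oxonium) cation cap +15.0229 (terminal methyl, electron included);
* methanol elimination −32.0262 (an unsubstituted 3-position),
  internal OMe→OH demethylation −14.0157;
* monosulfated B anion = B cation + 63.9255 (+SO~3~ − CH~2~ − 2H: the
  sulfate replaces a methyl and the ion is observed deprotonated);
* sulfate on a neutral molecule +65.9412; an O-methylated phosphate
  +79.9663, giving the methyl-phospho-Hex anion at *m/z* 297.07 that is
  separated by accurate mass from the sulfo-HexA B~1~ at 297.03 — the
  discriminator between mannose-6-phosphate and HNK-1 bearing species.

Electron mass is folded into the charged-species constants; the residual
error of ignoring it elsewhere is below 0.002 Da, an order of magnitude
under the 0.01 Da comparison precision used for display. Published spectra
annotate fragments at truncated (floored) integer *m/z*, with two decimals
where discrimination requires it; `mz_display()` renders either convention
while all computation stays at full precision.

## The diagnostic-ion catalog

`build_catalog()` assembles 24 glycotope definitions with 82 ions. Ions
whose masses follow from the arithmetic above (B ions, −MeOH satellites,
glycosidic/elimination losses, monosulfated B anions, C ions) are
`derivation = "computed"`; cross-ring (^3,5^A, ^2,4^A, ^1,3^A), E, D, Z
and GalNAc-ol satellite ions are `derivation = "curated"` literals at
their reported nominal values, because their generation rules involve
fragmentation chemistry that simple increment arithmetic does not encode.
The fucosylated core-2 6-arm satellite series is the non-fucosylated
series shifted by exactly one Fuc increment (174.089 Da). Each ion carries
a `role` (`required` defines the glycotope; `supporting` corroborates) and
MS^3^ ions record the MS^2^ product ion they are acquired from
(`parent_mz`).

One mass collision is deliberate and level-keyed: KDN-Hex-HexNAc^+^
(positive MS^2^) and Hex-(NeuAc)Hex^+^ (positive MS^3^ under the 1029.52
product) are isobaric at *m/z* 784.40 because KDN + HexNAc equals
NeuAc + Hex. The matcher never confuses them: catalog ions only apply at
their own MS level, and MS^3^ ions additionally require the scan's
precursor to match their recorded parent within 0.7 Da (a typical
isolation half-width). The required ions of different glycotopes are
otherwise unique within each polarity and MS level at 5 ppm; the tests
enforce this.

Organ-association annotations in `glycotope_info()` (brain / intestine /
ovary / common) are reporting metadata only and never influence matching.
The catalog ships as TSV (`inst/extdata/glycotope_catalog.tsv`) so users
can extend it without touching code.

```{r catalog}
cat_tab <- build_catalog()
ions_for("sulfo-HNK-1", "negative", 2)[, c("ion_label", "mz", "derivation", "role")]
```

## Matching, quantification and filtering

`match_diagnostic_ions()` reports, for every applicable catalog ion, the
single nearest peak within the ppm tolerance. Within one glycotope a peak
may satisfy at most one ion; assignments are made greedily by increasing
absolute ppm error with ties broken toward the lower theoretical mass, so
results are deterministic and, on small runs, provably identical to an
all-pairs brute-force search (tested). `summarize_glycotopes()` sums
matched intensities per glycotope — MS^2^ and MS^3^ are tallied separately
and combined by default (`combine_ms3 = FALSE` separates them, since
published bar charts do not state the convention) — and normalizes each
sum to the total over all glycotopes searched. Intensity means centroid
peak height throughout: the model is centroided data, and published
processing does not distinguish height from area.

`filter_candidate_precursors()` keeps MS^2^ scans with at least
`min_diag = 2` matched target ions, merges scans whose precursors agree
within the ppm tolerance at the same charge, and fits each candidate with
`fit_composition()`: exhaustive enumeration of residue and modification
counts within bounds (defaults Hex ≤ 12, HexNAc ≤ 8, dHex ≤ 4, each
sialic acid ≤ 4, HexA ≤ 2, sulfate ≤ 3, phosphate ≤ 1) under class
constraints — N-glycans need HexNAc ≥ 2 and Hex ≥ 3 (the
chitobiose-trimannosyl core), reduced O-glycans need the GalNAc-ol. The
enumeration is a vectorised meet-in-the-middle over two sub-grids, so the
full default space is searched in well under a second. Hits are ranked by
absolute ppm error with the composition label as a deterministic
tie-break; near-ties within twice the tolerance are flagged `ambiguous`
with a note naming the residue substitution relative to the top hit
(typically the NeuGc ↔ NeuAc + (Hex − dHex) and NeuAc ↔ KDN +
(HexNAc − Hex) confusions). Precursors with unknown charge are tried at
z = 1 and 2; positive mode tries [M+H]^+^ then [M+Na]^+^, negative mode
[M−H]^−^ and [M−2H]^2−^ — the adduct/charge combination with the best ppm
wins.

```{r fit}
fit_composition(937.41, z = 1, adduct = "deprotonated",
                glycan_class = "O-glycan")[1:3, c("composition", "ppm",
                                                  "ambiguous",
                                                  "ambiguity_note")]
```

## XIC profiling

`extract_xic()` sums, per MS^1^ scan, the intensity within ±5 ppm of any
of a species' target masses (adducts, charge states and anomers of one
species are tracked as one trace); overlapping target windows are
rejected at trace-definition time so intensity is never double-counted.
`detect_apexes()` takes local maxima of a 3-point moving-average-smoothed
trace, keeping those above 5% of the trace maximum by default — the
smoothing and prominence settings are declared defaults, configurable,
since published processing does not state them. Non-reduced N-glycans
elute as anomeric doublets; the generator and the profiler treat a
doublet as one species with two apexes. `normalize_traces()` divides all
traces by the reference apex (e.g. the ubiquitous Man~9~GlcNAc~2~ for
N-glycans, or the most abundant structure per sample), making the
reference apex exactly 1. Retention time is modeled in seconds and no
cross-run alignment is attempted: the supported comparison is overlaid
within-run XICs.

## The synthetic-run generator

`generate_run()` renders a declared mixture as a multi-level run:
Gaussian elution per species (60/40 anomeric doublets where flagged, at a
default separation of five peak sigmas so the doublet is
chromatographically resolved), MS^1^ scans on a fixed cycle time,
data-dependent MS^2^ on the top-N precursors per cycle containing the
species' catalog diagnostic ions with intensity proportional to the
precursor signal (required ions at weight 1, supporting at 0.5, at a 10%
fragment yield), and MS^3^ scans triggered when an MS^2^ product matches
a configured trigger mass (MS^3^ yield 0.3 of the triggering peak). Noise
comprises multiplicative log-normal intensity scatter, Gaussian ppm
jitter on every peak, uniform decoy peaks per MS^2^/MS^3^ spectrum and
optional MS^1^ baseline peaks. Defaults (10% intensity scatter, 2 ppm
jitter, 20 decoys per spectrum) emulate a well-calibrated Orbitrap
acquisition. Generation is a pure function of (mixture, noise seed): the
caller's RNG state is untouched and identical inputs give identical runs.

Model simplifications, and hence what passing tests do and do not show:
ionization response is equal across species (published intensity
comparisons implicitly assume the same), isotope envelopes are omitted
(the diagnostic-ion logic is monoisotopic throughout), fragmentation
efficiency does not depend on structure, undermethylation and unknown
adducts are absent, and DDA selection operates on the species' elution
profiles with decoys confined to fragment spectra and MS^1^ baseline. ppm
jitter applies to peak lists; the recorded precursor isolation targets
carry the species' theoretical m/z, so composition-recovery tests probe
the fitting logic rather than MS^1^ centroid averaging. Recovery of known
mixing ratios under these conditions validates the bookkeeping and
matching machinery — not vendor peak picking, chimeric spectra or
real-world ionization bias.

`ground_truth()` gives the closed-form expectations: glycotope shares
proportional to abundance × summed ion weight (exact when species share a
peak width and elute fully within the run), and the XIC apex table. The
test suite closes the loop: mined shares of a zero-noise run match ground
truth to 10^−6^, and a seeded 6-species run at the default noise recovers
shares within ±0.10 with the generating composition ranked first for at
least 90% of candidate precursors.

## Numerical and design choices

* **Exact isobars.** With formula-exact constants, compositions related by
  the NeuAc/KDN and NeuGc/NeuAc swaps would tie to the last floating-point
  digit. The 5-decimal stored table separates most of them by ~10^−5^ Da,
  so a precursor generated from the same table always ranks its own
  composition first; residual exact ties fall back to the composition
  label. Either way the `ambiguous` flag marks every such cluster — the
  honest statement is that accurate mass alone cannot distinguish them,
  which is precisely why diagnostic fragments are the primary readout.
* **Problem sizes.** Tests and examples use runs of a few hundred to a
  few thousand spectra (2 s cycle time, 4–6 s peak sigmas), ample to
  estimate shares while keeping the whole suite in seconds.
* **Degenerate inputs.** A run with no matches yields an all-zero report
  with a warning (not an error); a flat XIC yields zero apexes; a
  composition search below the smallest valid mass returns an empty
  table; empty B-ion sequences, negative intensities, level-1 spectra
  passed to the matcher and zero reference apexes are errors.
* **MS^3^ credit.** A shared fragment mass is credited by MS level and
  parent ion, mirroring the dual annotation of the 784.40 ion; the MS^3^
  contribution of the fucosylated variant under the 1203.61 parent is
  recorded as supporting so required ions stay unique.

## Known limitations

The package quantifies glycotopes and fits compositions; it does not
elucidate topology or linkage, search spectral libraries, or estimate
FDR. Average masses, isotope fine structure and non-permethylated mass
systems are out of scope, as are vendor raw formats and profile-mode peak
picking. Organ-level biological conclusions require real data; the
synthetic generator only establishes that the machinery recovers known
ground truth under its stated noise model.
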