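Package: glycomine
Title: Glycotope-Centric Mining of LC-MS/MS Data from Permethylated Glycans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for glycotope-centric analysis of nano-LC-MS/MS runs of
    permethylated N- and O-glycans, including sulfated glycans analysed in
    negative ion mode. Provides exact monoisotopic mass arithmetic for
    permethylated residues, sulfate/phosphate modifications and oxonium (B)
    fragments; a curated catalog of diagnostic MS2/MS3 ions for terminal
    glycotopes such as sialylated LacNAc/LacdiNAc variants, the HNK-1
    epitope and 3-O-sulfated galactose; ppm-tolerance diagnostic-ion
    matching with summed-intensity glycotope quantification; precursor
    filtering and glycosyl-composition fitting by accurate mass;
    accurate-mass extracted ion chromatograms; and a deterministic
    synthetic-run generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    mzR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
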