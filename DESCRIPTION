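Package: pepscreen
Title: Pooled Peptide-Inhibitor Screen Analysis and Target Deconvolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for proteome-wide pooled peptide-inhibitor
    screens in which each peptide's coding sequence acts as its own barcode.
    Builds C-terminal k-mer peptide libraries from a proteome, converts
    screen sequencing reads into quality-filtered, normalized count tables,
    calls enriched (protective) peptides, maps hit peptides onto
    protein-protein interaction interface segments with bounded mismatches
    and disease-GO-term ranking, proposes extended peptide variants from the
    source protein, and fits fluorescence-polarization saturation and
    competitive-displacement binding curves. Includes a seeded synthetic-data
    generator producing every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
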