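Package: vesiprot
Title: Proteogenomic Identification and Quantification of Extracellular Vesicle Cargo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds customized mutant-protein search databases from coding
    variants (single-residue substitutions from cSNVs; six-frame translated
    windows around INDELs), consolidates peptide-spectrum matches into
    identified wild-type and mutant protein lists with target-decoy peptide
    FDR control and a unique-peptide filter, quantifies proteins between
    vesicle compartments by the ratio of normalized spectral counts (RSc)
    with fold-change and exclusivity calls, and tests oncogenic enrichment
    of cargo by chi-square against categorized gene backgrounds, including
    TPM-derived expression backgrounds. A synthetic-data module generates a
    self-contained toy study (reference transcriptome, spiked variants,
    per-compartment PSM streams with planted fold changes) with full ground
    truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
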