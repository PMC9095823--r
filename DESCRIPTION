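Package: tmtdep
Title: TMT Isobaric Proteomics Quantification, Differential Expression and
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Peptide-to-protein relative quantification for TMT isobaric
    reporter-intensity data (peptide centralization, per-channel median
    correction, median rollup over unique peptides), replicate-reproducibility
    quality control, differential protein expression calling with fold-change
    and p-value thresholds, fold-change severity binning, Fisher exact term
    enrichment with Benjamini-Hochberg correction and hierarchical clustering
    of enrichment profiles, and concordance analysis between targeted (PRM)
    and discovery (TMT) ratios. Includes a synthetic-data generator with known
    protein-level ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
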