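Package: aonpipe
Title: Single-Unit Odor-Response Analysis and Differential Abundance Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for extracellular tetrode recordings from the
    anterior olfactory nucleus and their molecular companions. Covers spike
    detection by median-absolute-deviation thresholding of common-median
    referenced, band-pass filtered traces; unit inclusion criteria (baseline
    rate, session stability, refractory contamination); peristimulus time
    histograms with z-scored odor-response classification and
    excitation/inhibition ratios; Welch ANOVA with Dunnett many-to-one
    post-tests and Benjamini-Hochberg correction; geNorm reference-gene
    normalization of codeset counts with fold-change arithmetic; and a
    SWATH-style proteomics chain (peptide Q-value filtering, cyclic loess
    normalization, summation roll-up, empirical-Bayes moderated t).
    Ground-truthed synthetic generators for spike sessions, raw voltage
    traces, count tables and peptide tables make every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    limma,
    mvtnorm,
    signal,
    stats,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
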