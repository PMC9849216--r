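Package: fragaxis
Title: Orientation-Aware Cell-Free DNA Fragmentomics and Ending-Preference Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how plasma cell-free DNA (cfDNA) is fragmented
    relative to nucleosome structure and DNA methylation. The package profiles
    fragment ends in an orientation-aware manner (upstream and downstream ends
    treated separately) against a nucleosome-center track, detects the 10-bp
    helical periodicity of end positions by detrended periodogram analysis,
    partitions bisulfite-type reads into hyper- and hypo-methylated classes and
    relates fragment size to methylation, computes 5' fragment end-motif
    spectra, and scores samples with an ending-preference index (E-index) built
    from pooled healthy-control end counts for cancer detection. A synthetic
    cfDNA generator with a methylation-sensitive nucleosomal cut model provides
    fully reproducible fragment sets, nucleosome tracks, methylation landscapes
    and reference sequence for testing every stage without access to controlled
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
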