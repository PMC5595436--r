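Package: acylsugar
Title: Acylsugar Metabolomics: Mass-Based Annotation, Surface-Metabolite
    Diversity, Chemical-Space Enumeration and VIGS Fragment Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-wide acylsugar metabolomics: decomposition of
    LC/MS pseudomolecular ion masses into candidate acylsugar compositions
    with CID fragment prediction and scoring; filtering, normalisation and
    alignment of multi-sample peak tables with a peak-sharing matrix;
    Shannon-entropy diversity statistics (per-sample entropy, peak
    specificity, sample specialization index) with producer versus
    non-producer distribution comparison; combinatorial enumeration of the
    theoretical acylsugar space; selection of off-target-safe transcript
    regions for virus-induced gene silencing (VIGS) constructs; and seeded
    synthetic-data generators for peak tables and toy transcriptomes so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
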