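Package: crossbind
Title: Cross-Species Comparison of Hox ChIP Target Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing chromatin-immunoprecipitation (ChIP) target
    repertoires of a transcription factor between distantly related species.
    Peaks are assigned to nearest genes, target sets are projected onto a
    reference gene space through ortholog tables and partitioned into exhaustive
    Venn regions with hypergeometric overlap statistics, functional categories
    are scored by fold over-representation and enrichment with
    Benjamini-Hochberg correction, motif occurrence is scored against randomly
    sampled non-coding background with empirical p-values, and ordered arrays
    of transcription-factor binding sites around anchor peaks are compared
    between species. A seeded synthetic-data generator produces paired
    two-species datasets with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
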