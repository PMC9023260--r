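Package: aremotif
Title: ARE and GAAA Motif Analysis of 3'UTR Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Motif-level characterization of 3'UTR sequence sets for studies of
    AU-rich element (ARE) binding proteins of the ZFP36/TTP family and the
    stabilizing ELAV-like proteins. Provides overlapping k-mer scanning,
    counting, deletion and window extraction for the AUUUA pentamer, the
    UAUUUAU 7-mer and the GAAA motif; a parameterized AREScore-like 3'UTR
    scoring function (pentamer count, pentamer proximity, flanking AU
    content); a 7-mer binding-rule classifier exercised on a packaged panel
    of gel-shift RNA probes; Kolmogorov-Smirnov comparison of motif-count
    distributions across differential-expression categories; hypergeometric
    gene-list overlap tests (exact and normal approximation); GAAA-count
    binning; a seeded generator of synthetic 3'UTR cohorts with planted,
    category-dependent motif densities; and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
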