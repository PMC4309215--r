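Package: refstab
Title: Reference-Gene Stability Screening for Altered-Gravity Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies stably expressed reference ("housekeeping") genes in
    multi-condition microarray experiments, with presets for the two flight
    platforms used in gravitational cell biology (parabolic flight and
    sounding rocket). Provides probe-to-gene aggregation with minimum-probe
    and inter-probe variance rules, coefficient-of-variation stability
    screening, pairwise Welch tests over gravity-condition contrasts with a
    g-stable/g-sensitive verdict matrix, one-way ANOVA with
    Benjamini-Hochberg correction, four reference-gene stability algorithms
    (geNorm, NormFinder, BestKeeper, comparative delta-Ct) with a composite
    ranking, and a synthetic probe-level data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
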