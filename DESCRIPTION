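Package: chipsite
Title: High-Resolution Transcription Factor Binding Site Detection from
    ChIP-Seq Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step detection of transcription factor binding sites from
    mapped single-end ChIP-seq reads. Step one clusters strand-pooled tag
    5'-ends into candidate regions and tests them for enrichment with a
    Poisson model whose rate is a dynamic local background (optionally
    normalised against a control library), with Benjamini-Hochberg control
    of the false discovery rate. Step two pinpoints individual binding
    sites, including multiple closely spaced sites within one region, by
    sliding no-intercept least-squares fits of a gamma-derived single-site
    tag-density template along the smoothed strand-specific tag profiles.
    Includes a simulator that draws strand-specific tags from the same
    template for ground-truth benchmarking, and resolution metrics for
    scoring detections against known site positions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
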