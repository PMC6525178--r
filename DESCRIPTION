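Package: fishsect
Title: Section-Thickness Bias in FISH Gene Copy-Number Enumeration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric-probabilistic model of how FFPE section thickness
    biases per-nucleus gene copy-number counts in fluorescence in situ
    hybridization (FISH) assays. Models nuclei as spheres truncated by the
    microtome slab, derives the signal-retention probability from
    spherical-cap geometry and the observer's enumeration window, propagates
    it through a binomial thinning model to observed-count distributions,
    maps those to guideline categories (negative/equivocal/positive), and
    produces thin-to-thick correction tables with interval estimates. A
    Monte Carlo sectioning simulator provides an independent stochastic
    check of every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
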