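Package: consig
Title: Simulation and Benchmarking of Connected Differential Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pairs of interconnected differential expression
    signatures through a three-layer decomposition of the per-gene log2
    fold-change: a modality layer (up-, non-, or down-regulated), a
    sub-modality layer selecting an amplitude distribution, and a
    probability layer mapped through the sub-modality's quantile function.
    A parametric symmetric transition model (connectivity score c, noise
    factor gamma) or an arbitrary row-stochastic transition matrix links
    the two signatures; sub-modality and probability layers transition
    independently, deterministically, stochastically, or through discrete
    and continuous copulas (Frank, Plackett, Gauss) calibrated to a target
    Pearson correlation. A read-count pipeline turns signatures into
    negative-binomial counts with replicate variability and re-infers
    signatures by a Wald test, and a benchmarking harness evaluates seven
    connectivity scores (CMAP KS score, weighted connectivity score,
    connectivity strength score, and four extreme similarity metrics) by
    average precision. Parameters can be fitted from a real log2
    fold-change vector by mode detection and gamma-mixture decomposition.
License: GPL (>= 3)
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
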