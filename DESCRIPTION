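Package: mirrorcode
Title: Cross-Context Decoding of Executed and Observed Actions in Premotor Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether single neurons and neural populations
    encode observed actions with the same code used during executed actions.
    Implements event-anchored relative-time (quartile) binning of trial-based
    spike recordings, Friedman-test mirror-neuron screening, Kruskal-Wallis
    action-coding tables with Benjamini-Hochberg correction, three
    complementary shared-code criteria (bin-wise rank-sum discharge
    comparison, bootstrap action-preference similarity indices, and
    cross-task diagonal linear discriminant classification), a permutation
    (derangement) null for the independence of visual and motor codes,
    a two-Gaussian accuracy-angle boundary analysis, run-length action-segment
    statistics, pseudo-population decoding, and a synthetic Poisson
    spike-train generator with planted coding profiles for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
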