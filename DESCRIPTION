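Package: pensonar
Title: Sonar-Based Quantification of Fish Avoidance Behaviour in Net Pens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how farmed fish respond to point-source
    sound and light stimuli from 360-degree mechanical scanning sonar.
    Provides an agent-based generator of synthetic sonar scan streams with
    known ground-truth avoidance behaviour, rendering of (bearing, range)
    echo samples to centred circular-scan images, cumulative fish presence
    (CFP) imaging over trimmed before/during/after phase windows,
    three-category segmentation of CFP images (fish pattern, out of sonar
    range, invalid) with a deterministic classical backend and a trainable
    backend, inner-perimeter avoidance-distance estimation, and a
    permutational ANOVA engine for univariate Euclidean distances with
    mixed fixed/random factors, Freedman-Lane residual permutation,
    Monte-Carlo asymptotic p-values, term pooling and pairwise tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    EBImage,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr
Config/testthat/edition: 3
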