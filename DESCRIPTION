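Package: sortalign
Title: Categoricality and Representational Alignment Analysis of Free-Sort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing free-sort (spatial arrangement) experiments in
    which participants place items on a two-dimensional canvas so that proximity
    encodes similarity. Implements the categoricality score (log ratio of mean
    between- to mean within-category pairwise distance), pairwise
    representational alignment (Fisher-z transformed Spearman correlation of
    pairwise item-distance vectors), k-medoids cluster-number estimation with
    silhouette-based model selection, dyad bridging of individual scores,
    condition-effect and mediation analyses, family-resemblance stimulus
    synthesis by spline perturbation, match-to-sample trial-list generation,
    synthetic sorter simulation, and random-placement null simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    cluster,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
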