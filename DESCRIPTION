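Package: achconnect
Title: Larval Dispersal Connectivity and Centre-Edge Population Genetics
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test the genetic predictions of the abundant-centre
    hypothesis in coastal species with planktonic larvae. Generates synthetic
    coastal domains and daily surface-current fields, simulates passively
    drifting larvae with hourly bilinear advection and shore settlement,
    aggregates trajectories into asymmetric connectivity matrices, computes
    stepping-stone connection probabilities by Floyd-Warshall shortest paths
    on log-transformed probabilities, and clusters locations by maximising
    directed weighted modularity. Implements the population-genetic statistics
    needed for centre-versus-edge comparisons: haplotype and nucleotide
    diversity, AMOVA-based Phi-PT, Nei F-ST and Hedrick's G''-ST with
    permutation significance, rarefied allelic richness with bootstrap
    confidence intervals, Bruvo distances with minimum spanning networks,
    diversity-difference permutation tests and Bonferroni correction, plus
    mussel-cover summaries and an integrated centre-versus-edge verdict.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    mgcv,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
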