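Package: nichesignal
Title: Phylogenetic Signal in Local-Scale Environmental Niches of Forest Trees
Version: 1.0.0
Authors@R: person("Plot", "Ecology Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates local-scale environmental niches of tree species in a
    mapped forest-dynamics plot from quadrat-level topographic and soil data,
    tests species-habitat associations with torus-translation null models, and
    quantifies phylogenetic signal in the resulting niches and habitat
    preferences using Blomberg's K with a tip-permutation null, Sankoff
    parsimony permutation tests, and the net relatedness and nearest taxon
    indices (standardized effect sizes of MPD and MNTD). Ships a synthetic
    forest-plot generator (pure-birth phylogeny, Brownian-motion niche optima
    with a tunable conservatism knob, spatially autocorrelated environment
    fields, Gaussian niche-response stem placement) so every stage of the
    pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
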