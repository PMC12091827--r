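Package: barniche
Title: Binned Ancestral Range Reconstruction of Climatic Niche Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolution of climatic niches over a dated
    phylogeny using binned ancestral range (BAR) character coding. Species
    accessible areas (M) are simulated by iterated dispersal over an
    environmental-suitability surface; per-variable niche ranges are coded
    into equal-width bins with present/absent/uncertain states; ancestral
    binned niches are reconstructed by maximum likelihood under a symmetric
    two-state Markov model with ambiguous tips; branch-wise changes are
    classified as expansions, retractions or stasis at the upper and lower
    niche limits and projected back into geographic space. Includes a
    synthetic-data generator (autocorrelated environmental grids, Yule
    trees, interval niches evolved with known events, occurrence sampling)
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
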