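Package: chromacomm
Title: Pollinator-Vision Flower Color Dispersion in Co-Flowering Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing community assembly of flower color as seen
    by insect pollinators. Models floral reflectance spectra through
    receptor-noise-limited color vision systems (trichromatic bee and
    tetrachromatic fly viewers), computes pairwise chromatic distances,
    compares observed co-flowering communities against richness-matched
    null communities for both color disparity and mean pairwise
    phylogenetic distance, summarises habitat surveys into a PCA-based
    seep index, and relates trait dispersion to habitat via ANCOVA with
    spatial autocorrelation diagnostics. Includes a seeded synthetic-data
    generator that emulates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    car,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
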