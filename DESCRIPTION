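Package: beetlesym
Title: Cuticle Color Scoring and Symbiont Molecular Evolution in Grain Beetles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for studying bacteriome-associated
    endosymbionts of stored-product beetles and their effects on host
    phenotype. Implements a brightness-masked cuticle redness index for
    RGB photographs of the beetle metasternum (square region extraction,
    rank-based exclusion of highlight and shadow pixels, per-pixel
    R - mean(R,G,B) averaging), nucleotide composition summaries (AT
    content on ungapped unambiguous sites), model-corrected pairwise
    distances (Jukes-Cantor 1969 and Kimura 2-parameter), two-lineage
    relative rate tests with column-bootstrap variance, and
    neighbor-joining phylogeny reconstruction with bootstrap support.
    A seeded synthetic-data module generates cuticle images, alignments
    evolved under JC69/K2P, composition-biased sequences and two-group
    weight samples with known ground truth, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
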