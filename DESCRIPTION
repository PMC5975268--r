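Package: tdrlkit
Title: Equivalent Tandem Duplication Random Loss Rearrangements of
    Circular Gene Orders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models unichromosomal circular gene orders (e.g. mitochondrial
    genomes) as rotation-equivalence classes of permutations and analyses
    them under the tandem duplication random loss (TDRL) rearrangement.
    Computes directed TDRL distances, enumerates the complete set of
    equivalent TDRL triples (F, S, p) for order pairs that differ by a
    single TDRL, derives the minimal partial-duplication window of each
    TDRL, filters candidates by conserved gene groups and by intergenic
    regions explainable as incomplete gene loss, and renders the results
    as tables, text grids, SVG matrices and ggplot2 figures. Includes
    seeded simulators and exhaustive oracles for validation on small
    instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
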