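Package: memscape
Title: Moran's Eigenvector Map Landscape Genetics and Management-Unit
    Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for partitioning drivers of spatial genetic variation in
    continuously distributed populations typed at codominant microsatellite
    loci. Implements duplicate-genotype resolution for non-invasive sampling,
    classical population-genetic statistics (Weir-Cockerham F_ST, expected and
    observed heterozygosity, rarefied allelic richness, F_IS, exact
    Hardy-Weinberg and linkage-equilibrium tests, Mantel tests and
    correlograms), spatial genetic regression on Moran's eigenvector maps
    (MEM) with permutation-based forward selection and redundancy analysis,
    landscape-resistance models built from vector features with
    least-cost-path distances, variation partitioning of genetic structure
    into isolation-by-distance and isolation-by-resistance fractions, and a
    variation-partitioning framework for comparing management-unit
    delineation scenarios. Includes a spatially explicit forward-time
    microsatellite simulator for isolation-by-distance,
    isolation-by-resistance and panmictic scenarios with known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
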