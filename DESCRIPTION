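Package: geoGCF
Title: Gene Cluster Family Dereplication, Novelty Scoring, and
    Depth-Conditioned Community Statistics for Geothermal Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing microbial biosynthetic potential across
    geothermal sites from BiG-SCAPE-style similarity networks of predicted
    biosynthetic gene clusters (BGCs). Dereplicates BGCs into gene cluster
    families (GCFs) as connected components of distance-thresholded
    similarity networks, scores family and per-BGC novelty against
    reference clusters with a sentinel distance for reference-unconnected
    BGCs, builds presence-absence GCF profiles and genus-level taxonomic
    profiles from contig classifications, and links biosynthetic
    composition to environmental and tectonic context with sequencing-depth
    conditioned multivariate statistics (partial redundancy analysis,
    PERMANOVA, ANOSIM, multivariate dispersion, variation partitioning)
    and univariate tests, all implemented with explicit permutation
    schemes and seeds. A seeded synthetic-study generator with planted
    family structure, environmental effects and a sequencing-depth
    detection bias provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
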