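Package: biogeonet
Title: Function-Taxon Networks for Soil Biogeochemical Cycle Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers couplings between soil biogeochemical cycles (C, N, P, S,
    Fe) from annotated metagenomic contigs. Provides a curated biomarker-gene
    catalog mapping pathways to KEGG KO / Pfam accessions, per-sample marker
    abundance profiling with taxonomic assignment rates, environmental
    gradient statistics (Shannon diversity, Bray-Curtis dissimilarity with
    principal coordinate analysis, distance-decay of community similarity,
    multiple regression on distance matrices with Mantel-style permutation
    tests, latitude trend models and gene-environment rank correlations), and
    a weighted function-taxon bipartite network clustered by modularity
    maximisation at a tunable resolution. Network modules that contain
    pathways from two or more element cycles are reported as candidate cycle
    couplings together with the taxa connecting them. A synthetic-data
    generator emulates a latitudinal soil transect with a pH gradient,
    log-linear marker abundance trends and planted function-taxon modules, so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    geosphere,
    jsonlite,
    mclust,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
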