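Package: mitochron
Title: Mitogenome Assembly, Tiling Primer Design and Molecular Dating for Sibling-Species Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for reconstructing and dating mosquito
    mitochondrial genomes from shotgun sequencing data. Simulates dated Yule
    species trees, clock-like mitogenome evolution and paired-end reads with a
    configurable mitochondrial-to-nuclear copy ratio; enriches mitochondrial
    reads by multiplicity and abundance heuristics; performs small de Bruijn
    assembly with coverage cutoffs, reference anchoring, IUPAC overlap
    collapsing and majority-vote polishing; designs overlapping long-range PCR
    tiling primers from a variant-masked consensus; extracts and codon-aligns
    the 13 mitochondrial protein-coding genes under the invertebrate
    mitochondrial code into a partitioned supermatrix; and estimates phylogeny
    and divergence times by neighbor joining, partitioned likelihood, and a
    strict-clock Bayesian dating sampler with calibration priors or a fixed
    insect mitochondrial substitution rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    phytools,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Collate:
    'utils.R'
    'template.R'
    'timetree.R'
    'models.R'
    'evolve.R'
    'reads.R'
    'enrich.R'
    'assemble.R'
    'amplicons.R'
    'genealign.R'
    'likelihood.R'
    'distances.R'
    'modelselect.R'
    'mcmc.R'
    'mitochron-package.R'
    'RcppExports.R'
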