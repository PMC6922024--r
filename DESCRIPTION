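Package: flockdiv
Title: SNP-Array Population Genomics for Livestock: ROH, LD-Based Ne,
    Diversity and Structure
Version: 0.1.0
Authors@R:
    person("flockdiv", "developers", email = "flockdiv@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for within- and between-population
    genomic analysis of diploid biallelic SNP-array genotypes, aimed at
    livestock diversity studies.  Reads and writes PLINK text (PED/MAP)
    and binary (BED/BIM/FAM) panels, merges array panels by SNP
    intersection, applies call-rate/MAF/autosome quality control and
    relatedness pruning on a unified additive relationship (UAR) matrix.
    Computes observed and unbiased expected heterozygosity, rarefied
    allelic richness and Fis with bootstrap confidence intervals;
    detects runs of homozygosity (ROH) with a window-free consecutive
    runs scan and derives the genomic inbreeding coefficient F_ROH;
    estimates historical effective population size trajectories from
    distance-binned linkage disequilibrium; and quantifies population
    structure with pairwise Weir-Cockerham FST, identity-by-state
    distances, classical multidimensional scaling and principal
    component analysis, with exporters for SplitsTree, ADMIXTURE and
    TreeMix.  A Wright-Fisher gene-dropping simulator with recorded
    ground truth (pedigree inbreeding, Ne history, drift divergence,
    autozygous tracts) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
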