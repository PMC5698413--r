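Package: ylineage
Title: Y-Chromosome Lineage Dating, Diversity and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the population-genetic analysis of Y-chromosome
    lineages from SNP and STR data: a post-calling variant filter cascade
    (callable-depth, region-mask, heterozygote and sample-QC filters),
    perfect-phylogeny tree construction and haplogroup assignment against a
    defining-SNP hierarchy with population frequency tables, rho-statistic
    TMRCA estimation from SNPs and Y-STRs with Saillard standard errors,
    Y-STR diversity statistics and longitude correlations, hierarchical
    analysis of molecular variance (AMOVA) with permutation tests,
    median-joining haplotype networks, and a coalescent simulator of joint
    SNP + STR panels with known genealogies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    vcfR,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
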