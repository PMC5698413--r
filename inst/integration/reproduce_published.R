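#!/usr/bin/env Rscript
# Optional integration workflow against the published North African
# E-M183 data.  These inputs are NOT shipped with the package and must be
# downloaded by the user:
#
#   1. The whole-Y VCF (figshare dataset "North_African_Ychromosome_dataset
#      _vcf") -> pass as --vcf, together with a BED mask of the ~4.88 Mb
#      unique high-quality Y regions -> --mask.
#   2. The supplementary Y-STR haplotype table (12 single-copy YFiler loci,
#      185 E-M183 individuals) exported as CSV with columns
#      sample,population,longitude,<locus...> -> --strs, plus a CSV of
#      sample,haplogroup assignments -> --assign.
#
# Expected results when run on those inputs (as published):
#   * SNP rho TMRCA for E-M183 at the fast rate (1e-9/site/year over
#     4.88 Mb): about 1730 [1481, 1979] years.
#   * STR rho TMRCA at 1/858 per haplotype/year: about 2012 [1583, 2441] y.
#   * AMOVA among-population variance about 8.1%; coastal-vs-inland
#     (Western Sahara + Algerian Reguibates as the inland group) about
#     16.5%; among-subclade about 8.6%.
#   * DYS458*17 at about 71% in PF6789 carriers vs 31% in other E-M183.
#
# Usage:
#   Rscript reproduce_published.R --vcf data.vcf --mask regions.bed \
#       --strs strs.csv --assign assignments.csv --groups groups.csv

suppressMessages(library(ylineage))

argv <- commandArgs(trailingOnly = TRUE)
opt <- function(flag) {
  i <- match(flag, argv)
  if (is.na(i)) NULL else argv[i + 1]
}

if (!is.null(opt("--vcf"))) {
  res <- run_filter_cascade(opt("--vcf"), opt("--mask"))
  cat("filter cascade:\n"); print(res$report)
  tree <- build_perfect_phylogeny(res$vm)
  est <- tmrca_from_rho(rho_snp(tree),
                        mutation_rate_spec(snp_rate = 1e-9), "snp")
  cat("SNP rho TMRCA (fast rate):\n"); print(est)
  est_slow <- tmrca_from_rho(rho_snp(tree),
                             mutation_rate_spec(snp_rate = 6.17e-10), "snp")
  cat("SNP rho TMRCA (slow rate):\n"); print(est_slow)
}

if (!is.null(opt("--strs"))) {
  strs <- read_str_table(opt("--strs"))
  est <- tmrca_from_rho(rho_str(strs), mutation_rate_spec(), "str")
  cat("STR rho TMRCA (1/858 per haplotype/year):\n"); print(est)

  cat("AMOVA among populations:\n")
  print(amova(strs, n_perm = 10000, seed = 1))

  if (!is.null(opt("--groups"))) {
    g <- read.csv(opt("--groups"))
    groups <- setNames(as.character(g[[2]]), g[[1]])
    cat("AMOVA coastal vs inland groups:\n")
    print(amova(strs, groups = groups, n_perm = 10000, seed = 2))
  }

  if (!is.null(opt("--assign"))) {
    a <- read.csv(opt("--assign"))
    asg <- a[[2]][match(strs$sample, a[[1]])]
    cat("AMOVA among subclades:\n")
    print(amova(strs, populations = asg, n_perm = 10000, seed = 3))
    cat("DYS458 allele split for PF6789:\n")
    print(allele_split(strs, asg, "DYS458", "PF6789", defs = em183_defs()))
    cat("haplotypes shared across subclades:\n")
    print(shared_haplotypes(strs, asg))
  }
}
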