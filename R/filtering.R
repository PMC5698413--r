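#' Set low-depth genotypes missing (callable-site filter)
#'
#' Genotypes supported by fewer than `min_reads` reads are set to missing;
#' sites left missing in every sample are dropped.  Depth-failing calls
#' become missing rather than ancestral so that downstream mutation-count
#' statistics (rho) are not deflated.
#'
#' @param vm a [variant_matrix()] with a depth matrix.
#' @param min_reads minimum read support for a call to be retained
#'   (inclusive; the default 5 keeps depth-5 calls).
#' @return filtered `variant_matrix`.
#' @export
apply_callable_filter <- function(vm, min_reads = 5) {
  if (is.null(vm$depth))
    stop("variant matrix carries no depth field; cannot apply callable filter")
  vm$geno[vm$depth < min_reads | is.na(vm$depth)] <- NA_integer_
  keep <- rowSums(!is.na(vm$geno)) > 0
  subset_sites(vm, keep)
}

#' Restrict sites to a region mask
#'
#' Keeps only sites whose (1-based) position falls inside a kept interval of
#' the 0-based half-open mask: position `p` is kept iff `p - 1` lies in some
#' `[start, end)`.
#'
#' @param vm a [variant_matrix()].
#' @param mask a [region_mask()].
#' @return filtered `variant_matrix`, with the retained mask length in
#'   attribute `"kept_length"`.
#' @export
apply_region_mask <- function(vm, mask) {
  stopifnot(inherits(mask, "region_mask"))
  out <- subset_sites(vm, mask_contains(mask, vm$pos))
  attr(out, "kept_length") <- mask$kept_length
  out
}

#' Remove heterozygous calls
#'
#' On the haploid Y chromosome a heterozygous diploid call is an artefact
#' (mismapping or contamination); every genotype coded heterozygous (`2`) is
#' set to missing, making the matrix strictly haploid.
#'
#' @param vm a [variant_matrix()].
#' @return haploid `variant_matrix` with attribute `"n_removed"` giving the
#'   number of calls converted to missing.
#' @export
remove_heterozygous_calls <- function(vm) {
  het <- which(vm$geno == 2L)
  vm$geno[het] <- NA_integer_
  attr(vm, "n_removed") <- length(het)
  vm
}

#' Per-sample quality control
#'
#' Removes samples with a missing-call fraction at or above `max_missing`
#' or a mean read depth (over the currently retained sites) below
#' `min_mean_depth`.  Both thresholds follow the usual resequencing-QC
#' convention: a missing share of 5 percent or more fails, < 10x mean depth fails.
#'
#' @param vm a [variant_matrix()].
#' @param max_missing missing fraction at or above which a sample fails.
#' @param min_mean_depth mean depth below which a sample fails.
#' @return list with elements `vm` (filtered matrix) and `report` (a
#'   data.frame with one row per input sample: missing fraction, mean depth,
#'   pass flag).
#' @export
sample_qc <- function(vm, max_missing = 0.05, min_mean_depth = 10) {
  miss <- colMeans(is.na(vm$geno))
  if (n_sites(vm) == 0L) miss <- rep(0, n_samples(vm))
  mdep <- if (is.null(vm$depth)) rep(NA_real_, n_samples(vm)) else
    colMeans(vm$depth, na.rm = TRUE)
  pass <- miss < max_missing &
    (is.na(mdep) | mdep >= min_mean_depth)
  report <- data.frame(sample = vm$samples, missing_fraction = miss,
                       mean_depth = mdep, pass = pass,
                       row.names = NULL)
  if (!any(pass)) stop("sample QC removed every sample")
  list(vm = subset_samples(vm, pass), report = report)
}

#' Run the full post-calling filter cascade
#'
#' Applies, in order: region mask, callable-depth filter, heterozygote
#' removal, and sample QC, recording site/sample counts after each stage.
#' Upstream raw-call and hard-filter counts belong to the external variant
#' caller and are labelled as such in the report.
#'
#' @param vcf_path path to the input VCF.
#' @param mask_path path to the BED mask of kept regions (or `NULL` to skip
#'   masking).
#' @param min_reads,max_missing,min_mean_depth stage thresholds, see
#'   [apply_callable_filter()] and [sample_qc()].
#' @return list with `vm` (the final matrix), `report` (per-stage counts)
#'   and `qc` (the per-sample QC table).
#' @export
run_filter_cascade <- function(vcf_path, mask_path = NULL, min_reads = 5,
                               max_missing = 0.05, min_mean_depth = 10) {
  vm <- read_vcf_matrix(vcf_path)
  stages <- data.frame(stage = "input", n_sites = n_sites(vm),
                       n_samples = n_samples(vm))
  if (!is.null(mask_path)) {
    mask <- if (inherits(mask_path, "region_mask")) mask_path else
      read_region_mask(mask_path)
    vm <- apply_region_mask(vm, mask)
    stages <- rbind(stages, data.frame(stage = "region_mask",
                                       n_sites = n_sites(vm),
                                       n_samples = n_samples(vm)))
  }
  vm <- apply_callable_filter(vm, min_reads = min_reads)
  stages <- rbind(stages, data.frame(stage = "callable", n_sites = n_sites(vm),
                                     n_samples = n_samples(vm)))
  vm <- remove_heterozygous_calls(vm)
  stages <- rbind(stages, data.frame(stage = "het_removed",
                                     n_sites = n_sites(vm),
                                     n_samples = n_samples(vm)))
  qc <- sample_qc(vm, max_missing = max_missing,
                  min_mean_depth = min_mean_depth)
  vm <- qc$vm
  # sites may become invariant once failing samples leave; keep them (they
  # are still callable sites) but drop all-missing rows
  keep <- rowSums(!is.na(vm$geno)) > 0
  vm <- subset_sites(vm, keep)
  stages <- rbind(stages, data.frame(stage = "sample_qc",
                                     n_sites = n_sites(vm),
                                     n_samples = n_samples(vm)))
  list(vm = vm, report = stages, qc = qc$report)
}
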