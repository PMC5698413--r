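#' Variant matrix of haploid Y-chromosome calls
#'
#' A `variant_matrix` holds per-sample genotype calls and read depths at a
#' set of Y-chromosome sites.  Genotypes are coded as integers: `0` =
#' ancestral (reference), `1` = derived (alternate), `2` = heterozygous call
#' (diploid artefact awaiting removal on this haploid chromosome), `NA` =
#' missing.  Sites are rows, samples columns; positions are 1-based as in
#' VCF and strictly increasing.
#'
#' @param pos integer vector of 1-based positions, strictly increasing.
#' @param ref,alt character vectors of ancestral / derived alleles.
#' @param samples character vector of sample identifiers.
#' @param geno integer matrix `length(pos) x length(samples)` in
#'   `{0, 1, 2, NA}`.
#' @param depth integer matrix of read depths, same dimensions (or `NULL`).
#' @param ids optional variant names (defaults to `chrY_<pos>`).
#' @return object of class `variant_matrix`.
#' @export
variant_matrix <- function(pos, ref, alt, samples, geno, depth = NULL,
                           ids = NULL) {
  pos <- as.integer(pos)
  if (is.unsorted(pos, strictly = TRUE))
    stop("positions must be strictly increasing")
  geno <- matrix(as.integer(geno), length(pos), length(samples))
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(depth)) {
    depth <- matrix(as.integer(depth), length(pos), length(samples))
  }
  if (is.null(ids))
    ids <- if (length(pos)) paste0("chrY_", pos) else character(0)
  dimnames(geno) <- list(ids, samples)
  if (!is.null(depth)) dimnames(depth) <- dimnames(geno)
  structure(list(pos = pos, ref = as.character(ref), alt = as.character(alt),
                 samples = as.character(samples), geno = geno, depth = depth,
                 ids = as.character(ids)),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d sites x %d samples (%s depth)\n",
              n_sites(x), n_samples(x),
              if (is.null(x$depth)) "no" else "with"))
  invisible(x)
}

#' @rdname variant_matrix
#' @param vm a `variant_matrix`.
#' @export
n_sites <- function(vm) length(vm$pos)

#' @rdname variant_matrix
#' @export
n_samples <- function(vm) length(vm$samples)

# Subset rows (sites) / columns (samples) preserving structure.
subset_sites <- function(vm, i) {
  variant_matrix(vm$pos[i], vm$ref[i], vm$alt[i], vm$samples,
                 vm$geno[i, , drop = FALSE],
                 if (!is.null(vm$depth)) vm$depth[i, , drop = FALSE],
                 vm$ids[i])
}

subset_samples <- function(vm, j) {
  variant_matrix(vm$pos, vm$ref, vm$alt, vm$samples[j],
                 vm$geno[, j, drop = FALSE],
                 if (!is.null(vm$depth)) vm$depth[, j, drop = FALSE],
                 vm$ids)
}

#' Read a VCF into a variant matrix
#'
#' Parses a VCF 4.x file (plain or gzipped) with `vcfR` and converts the GT
#' and DP fields into the haploid integer coding of [variant_matrix()].
#' Both haploid (`0`, `1`) and diploid (`0/0`, `0/1`, `1/1`, phased or not)
#' GT strings are accepted; heterozygous diploid calls are coded `2` and are
#' expected to be cleared later by [remove_heterozygous_calls()].
#'
#' @param path VCF file path.
#' @return a `variant_matrix`.
#' @export
read_vcf_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7, dimnames = list(NULL, colnames(fix)))
  pos <- as.integer(fix[, "POS"])
  samples <- colnames(v@gt)[-1]
  if (nrow(fix) == 0L) {
    return(variant_matrix(integer(0), character(0), character(0), samples,
                          matrix(integer(0), 0, length(samples)),
                          matrix(integer(0), 0, length(samples)),
                          character(0)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  code_gt <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0", "0/0", "0|0")] <- 0L
    out[g %in% c("1", "1/1", "1|1")] <- 1L
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 2L
    out
  }
  geno <- matrix(code_gt(as.vector(gt)), nrow(gt), ncol(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("chrY_", pos[is.na(ids) | ids == "."])
  o <- order(pos)
  variant_matrix(pos[o], fix[o, "REF"], fix[o, "ALT"], samples,
                 geno[o, , drop = FALSE],
                 if (!is.null(dp)) matrix(as.integer(dp), nrow(dp), ncol(dp))[o, , drop = FALSE],
                 ids[o])
}

#' Write a variant matrix to VCF
#'
#' Emits VCF 4.2 with haploid GT (`0`/`1`/`.`; heterozygous code 2 written
#' as `0/1`), per-sample DP, and the ancestral allele in the `AA` INFO tag.
#' The file is gzip-compressed if `path` ends in `.gz`.
#'
#' @param vm a `variant_matrix`.
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf_matrix <- function(vm, path) {
  meta <- c("##fileformat=VCFv4.2",
            "##contig=<ID=chrY>",
            "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  n <- n_sites(vm)
  fix <- cbind(CHROM = rep("chrY", n), POS = as.character(vm$pos),
               ID = vm$ids, REF = vm$ref, ALT = vm$alt,
               QUAL = rep(".", n), FILTER = rep(".", n),
               INFO = paste0("AA=", vm$ref))
  gchr <- matrix(".", n, n_samples(vm))
  gchr[which(vm$geno == 0L)] <- "0"
  gchr[which(vm$geno == 1L)] <- "1"
  gchr[which(vm$geno == 2L)] <- "0/1"
  dp <- if (is.null(vm$depth)) matrix(".", n, n_samples(vm)) else {
    d <- matrix(as.character(vm$depth), n, n_samples(vm))
    d[is.na(d)] <- "."
    d
  }
  gt <- matrix(paste(gchr, dp, sep = ":"), n, n_samples(vm))
  gt <- cbind(FORMAT = rep("GT:DP", n), gt)
  colnames(gt) <- c("FORMAT", vm$samples)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", colnames(gt)), collapse = "\t"), con)
  if (n > 0)
    writeLines(apply(cbind(fix, gt), 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a BED region mask
#'
#' Reads a 3+ column BED file (chrom, start, end; 0-based half-open) into a
#' `region_mask`: a sorted, non-overlapping set of kept intervals.
#'
#' @param path BED file path.
#' @return a `region_mask` object.
#' @export
read_region_mask <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t",
                  col.names = c("chrom", "start", "end")[1:3],
                  colClasses = c("character", "integer", "integer"),
                  fill = FALSE)[, 1:3]
  region_mask(b$start, b$end)
}

#' Construct a region mask
#'
#' @param start,end integer vectors of 0-based half-open interval bounds
#'   (`[start, end)`), describing the regions to keep.
#' @return a `region_mask` object with the total kept length attached.
#' @export
region_mask <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end <= start)) stop("empty or inverted interval in mask")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1 && any(start[-1] < end[-length(end)]))
    stop("mask intervals overlap or are unsorted")
  structure(list(start = start, end = end,
                 kept_length = sum(end - start)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask: %d intervals, %.0f bp kept\n",
              length(x$start), x$kept_length))
  invisible(x)
}

# TRUE for each 1-based position falling inside a kept interval.
mask_contains <- function(mask, pos) {
  p0 <- pos - 1  # 0-based coordinate of the base
  idx <- findInterval(p0, mask$start)
  idx >= 1 & p0 < mask$end[pmax(idx, 1L)]
}
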