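#' Allele frequency split between a target clade and its complement
#'
#' For one STR locus, the frequency of each allele (repeat count) among
#' samples assigned to a target haplogroup versus all other samples in the
#' comparison set — e.g. DYS458 alleles in PF6789 carriers versus other
#' E-M183 chromosomes.  Report percentages are integers (half-up); raw
#' fractions are retained.
#'
#' @param strs an `str_haplotypes` table.
#' @param assignments haplogroup label per sample (same order as `strs`).
#' @param locus locus column name.
#' @param target_clade haplogroup name; samples whose assignment equals the
#'   clade or any of its descendants (when `defs` is given) form the target
#'   group.
#' @param defs optional [haplogroup_defs()] used to expand the clade to its
#'   descendants and to restrict the complement to the hierarchy's top
#'   clade.
#' @return data.frame with one row per allele: frequencies and integer
#'   percentages in target and complement.
#' @export
allele_split <- function(strs, assignments, locus, target_clade,
                         defs = NULL) {
  if (!locus %in% names(strs)) stop("locus not present: ", locus)
  stopifnot(length(assignments) == nrow(strs))
  target_labels <- target_clade
  universe <- rep(TRUE, nrow(strs))
  if (!is.null(defs)) {
    below <- descendants_of(defs, target_clade)
    target_labels <- c(target_clade, paste0(target_clade, "*"),
                       below, paste0(below, "*"))
    universe <- assignments %in% c(haplogroup_labels(defs))
  }
  in_target <- universe & assignments %in% target_labels
  in_comp <- universe & !assignments %in% target_labels
  if (!any(in_target) || !any(in_comp))
    stop("target or complement group is empty")
  a <- strs[[locus]]
  alleles <- sort(unique(a[universe]))
  ft <- vapply(alleles, function(x) mean(a[in_target] == x), 0)
  fc <- vapply(alleles, function(x) mean(a[in_comp] == x), 0)
  data.frame(locus = locus, allele = alleles,
             freq_in_target = ft, freq_in_complement = fc,
             percent_target = round_half_up(100 * ft),
             percent_complement = round_half_up(100 * fc),
             n_target = sum(in_target), n_complement = sum(in_comp),
             row.names = NULL)
}

#' Haplotypes shared across subclades
#'
#' Lists every multi-locus STR haplotype observed in two or more distinct
#' haplogroup assignments — the signature of a radiation too recent for
#' STRs to have differentiated the subclades.
#'
#' @param strs an `str_haplotypes` table.
#' @param assignments haplogroup label per sample.
#' @return data.frame with the haplotype key, the clades sharing it
#'   (comma-separated, sorted), and the total count; empty when no
#'   haplotype spans two clades.
#' @export
shared_haplotypes <- function(strs, assignments) {
  key <- apply(str_matrix(strs), 1, paste, collapse = "|")
  by_key <- split(as.character(assignments), key)
  multi <- Filter(function(cl) length(unique(cl)) >= 2, by_key)
  if (!length(multi))
    return(data.frame(haplotype = character(0), clades = character(0),
                      n = integer(0)))
  out <- data.frame(
    haplotype = names(multi),
    clades = vapply(multi, function(cl)
      paste(sort(unique(cl)), collapse = ","), ""),
    n = lengths(multi), row.names = NULL)
  out[order(out$haplotype), , drop = FALSE]
}
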