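#' Gene (haplotype) diversity
#'
#' Nei's unbiased gene diversity `D = n/(n-1) * (1 - sum p_i^2)` over the
#' frequencies of distinct multi-locus haplotypes, with its sampling
#' standard deviation from Nei's variance formula.
#'
#' @param haplotypes an `str_haplotypes` table, numeric matrix (samples x
#'   loci), or a vector of haplotype keys.
#' @return list with `diversity` and `sd`.
#' @export
gene_diversity <- function(haplotypes) {
  keys <- haplotype_keys(haplotypes)
  n <- length(keys)
  if (n < 2) stop("gene diversity requires n >= 2")
  p <- as.numeric(table(keys)) / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  D <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(diversity = D, sd = sqrt(max(V, 0)))
}

haplotype_keys <- function(h) {
  if (is.matrix(h)) return(apply(h, 1, paste, collapse = "|"))
  if (inherits(h, "data.frame")) return(apply(str_matrix(h), 1, paste, collapse = "|"))
  as.character(h)
}

#' Mean number of pairwise differences
#'
#' Average over all `n(n-1)/2` haplotype pairs of either the number of loci
#' with unequal repeat counts (`loci_differing`) or the single-step
#' mutational distance (`stepwise`, sum over loci of absolute differences).
#'
#' @param haplotypes `str_haplotypes` table or numeric matrix.
#' @param metric `"loci_differing"` or `"stepwise"`.
#' @return mean pairwise difference.
#' @export
mean_pairwise_differences <- function(haplotypes,
                                      metric = c("loci_differing", "stepwise")) {
  metric <- match.arg(metric)
  m <- if (is.matrix(haplotypes)) haplotypes else str_matrix(haplotypes)
  if (anyNA(m)) stop("missing repeat counts")
  n <- nrow(m)
  if (n < 2) stop("need n >= 2")
  d <- str_distance_matrix(m, if (metric == "stepwise") "stepwise" else "loci_differing")
  sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
}

#' Per-locus heterozygosity (unbiased gene diversity of alleles)
#'
#' For each locus, `n/(n-1) * (1 - sum p_a^2)` over allele (repeat-count)
#' frequencies; monomorphic loci score 0.
#'
#' @param haplotypes `str_haplotypes` table or numeric matrix.
#' @return list with `per_locus` (named vector) and `mean`.
#' @export
locus_heterozygosity <- function(haplotypes) {
  m <- if (is.matrix(haplotypes)) haplotypes else str_matrix(haplotypes)
  n <- nrow(m)
  if (n < 2) stop("need n >= 2")
  h <- apply(m, 2, function(col) {
    p <- as.numeric(table(col)) / n
    n / (n - 1) * (1 - sum(p^2))
  })
  list(per_locus = h, mean = mean(h))
}

#' Per-locus allele-size variance
#'
#' Sample variance (n-1 denominator) of the repeat counts at each locus;
#' the mean across loci is the usual single-number summary of STR
#' molecular diversity.
#'
#' @param haplotypes `str_haplotypes` table or numeric matrix.
#' @return list with `per_locus` and `mean`.
#' @export
allele_size_variance <- function(haplotypes) {
  m <- if (is.matrix(haplotypes)) haplotypes else str_matrix(haplotypes)
  if (nrow(m) < 2) stop("need n >= 2")
  v <- apply(m, 2, var)
  list(per_locus = v, mean = mean(v))
}

#' Per-unit diversity summary
#'
#' Computes sample size, gene diversity, mean pairwise differences
#' (stepwise), mean locus heterozygosity and mean allele-size variance for
#' each population (or any other grouping), carrying longitude through when
#' present.
#'
#' @param strs an `str_haplotypes` table.
#' @param by grouping column (default `"population"`).
#' @return data.frame with one row per group; groups with n < 2 are
#'   reported with `NA` statistics.
#' @export
diversity_by <- function(strs, by = "population") {
  groups <- split(seq_len(nrow(strs)), strs[[by]])
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    sub <- strs[i, , drop = FALSE]
    lon <- if ("longitude" %in% names(strs)) strs$longitude[i][1] else NA
    if (length(i) < 2)
      return(data.frame(unit = g, n = length(i), gene_diversity = NA,
                        mean_pairwise_diff = NA, mean_heterozygosity = NA,
                        allele_size_variance = NA, longitude = lon))
    data.frame(unit = g, n = length(i),
               gene_diversity = gene_diversity(sub)$diversity,
               mean_pairwise_diff = mean_pairwise_differences(sub, "stepwise"),
               mean_heterozygosity = locus_heterozygosity(sub)$mean,
               allele_size_variance = allele_size_variance(sub)$mean,
               longitude = lon)
  })
  do.call(rbind, rows)
}

#' Spearman correlation with longitude, exact small-sample P
#'
#' Rank correlation between a per-unit diversity statistic and longitude.
#' With 8 or fewer units the two-sided P-value is computed by full
#' enumeration of all permutations (the only valid test at the handful of
#' populations typical of these analyses); beyond that, the large-sample
#' t approximation is used.  Ties are handled with midranks.
#'
#' @param stats data.frame as from [diversity_by()], with a `longitude`
#'   column.
#' @param field column of `stats` to correlate.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_longitude <- function(stats, field) {
  ok <- is.finite(stats[[field]]) & is.finite(stats$longitude)
  x <- stats$longitude[ok]; y <- stats[[field]][ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 units with longitude")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(t), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p_value, n = n, method = method)
}
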