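#' Pairwise STR haplotype distance matrix
#'
#' `loci_differing` counts loci with unequal repeat counts (the
#' haplotype-level F_ST metric); `stepwise_squared` is the squared
#' single-step distance `sum (delta repeats)^2` (the R_ST-style metric);
#' `stepwise` is the plain single-step distance `sum |delta|`.
#'
#' @param haplotypes `str_haplotypes` table or numeric matrix (samples x
#'   loci), complete data.
#' @param metric `"loci_differing"`, `"stepwise_squared"` or `"stepwise"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
str_distance_matrix <- function(haplotypes,
                                metric = c("loci_differing",
                                           "stepwise_squared", "stepwise")) {
  metric <- match.arg(metric)
  m <- if (is.matrix(haplotypes)) haplotypes else str_matrix(haplotypes)
  if (anyNA(m)) stop("missing repeat counts; complete data required")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    diff <- abs(sweep(m[(i + 1):n, , drop = FALSE], 2, m[i, ]))
    v <- switch(metric,
                loci_differing = rowSums(diff > 0),
                stepwise_squared = rowSums(diff^2),
                stepwise = rowSums(diff))
    d[i, (i + 1):n] <- v
    d[(i + 1):n, i] <- v
  }
  d
}

# Sum of squared deviations of a stratum from a (squared-)distance matrix:
# SSD = sum_{i<j in S} d2_ij / |S|, via the full-matrix form / (2|S|).
ssd_of <- function(d2, idx) sum(d2[idx, idx]) / (2 * length(idx))

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions molecular variance among groups, among populations within
#' groups, and within populations, from a matrix of squared inter-haplotype
#' distances (Excoffier's sums-of-squared-deviations formulation with the
#' standard unequal-sample-size coefficients).  With no `groups` argument a
#' one-level design (among/within populations) is fitted.  Phi statistics
#' are the distance-based fixation indices: `Phi_ST` (total population
#' structure), and for two-level designs `Phi_CT` (among groups) and
#' `Phi_SC` (among populations within groups).  Negative variance
#' components are reported as estimated, per AMOVA convention.
#'
#' Permutation P-values (when `n_perm > 0`): samples are permuted among
#' populations for `Phi_ST`, whole populations among groups for `Phi_CT`,
#' and samples among populations within groups for `Phi_SC`;
#' `p = (#{perm >= observed} + 1) / (n_perm + 1)`.
#'
#' @param haplotypes `str_haplotypes` table or numeric matrix.
#' @param populations population label per sample (defaults to the table's
#'   `population` column).
#' @param groups optional named vector mapping population -> group for the
#'   two-level design.
#' @param metric distance metric, see [str_distance_matrix()]; the
#'   haplotype-difference metric is the F_ST-style default.
#' @param n_perm number of label permutations for P-values (0 = skip).
#' @param seed integer seed for the permutations.
#' @return object of class `amova_result`: data.frame `components` (df,
#'   SSD, variance component, percent of total), list `phi`, list
#'   `p_values`, `n_permutations`.
#' @export
amova <- function(haplotypes, populations = NULL, groups = NULL,
                  metric = "loci_differing", n_perm = 0, seed = NULL) {
  m <- if (is.matrix(haplotypes)) haplotypes else str_matrix(haplotypes)
  if (is.null(populations) && inherits(haplotypes, "data.frame"))
    populations <- haplotypes$population
  populations <- as.character(populations)
  stopifnot(length(populations) == nrow(m))
  sizes <- table(populations)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding population(s) with n = 1: ", paste(drop, collapse = ", "))
    keep <- !populations %in% drop
    m <- m[keep, , drop = FALSE]
    populations <- populations[keep]
  }
  if (length(unique(populations)) < 2) stop("need >= 2 populations")
  d2 <- str_distance_matrix(m, metric)
  res <- amova_components(d2, populations, groups)
  if (n_perm > 0) {
    if (n_perm < 100) stop("n_perm must be >= 100")
    if (!is.null(seed)) set.seed(seed)
    res$p_values <- amova_permute(d2, populations, groups, res$phi, n_perm)
    res$n_permutations <- n_perm
  }
  res
}

# Variance components from a squared-distance matrix and labels.
amova_components <- function(d2, populations, groups = NULL) {
  N <- length(populations)
  pops <- unique(populations)
  P <- length(pops)
  idx_pop <- split(seq_len(N), populations)
  n_p <- lengths(idx_pop)
  ssd_total <- ssd_of(d2, seq_len(N))
  ssd_wp <- sum(vapply(idx_pop, function(i) ssd_of(d2, i), 0))
  if (is.null(groups)) {
    df_ap <- P - 1; df_wp <- N - P
    ssd_ap <- ssd_total - ssd_wp
    ms_ap <- ssd_ap / df_ap
    sigma_c <- ssd_wp / df_wp
    n0 <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_a <- (ms_ap - sigma_c) / n0
    total <- sigma_a + sigma_c
    comp <- data.frame(
      source = c("among_populations", "within_populations", "total"),
      df = c(df_ap, df_wp, N - 1),
      SSD = c(ssd_ap, ssd_wp, ssd_total),
      sigma2 = c(sigma_a, sigma_c, total),
      percent = 100 * c(sigma_a, sigma_c, total) / total)
    phi <- list(PHI_ST = sigma_a / total)
  } else {
    grp_of_pop <- groups[populations]
    if (anyNA(grp_of_pop)) stop("every population must be mapped to a group")
    idx_grp <- split(seq_len(N), grp_of_pop)
    G <- length(idx_grp)
    if (G < 2) {
      # single group: collapses to the one-level design
      return(amova_components(d2, populations, NULL))
    }
    N_g <- lengths(idx_grp)
    ssd_wg <- sum(vapply(idx_grp, function(i) ssd_of(d2, i), 0))
    ssd_ag <- ssd_total - ssd_wg
    ssd_ap_wg <- ssd_wg - ssd_wp
    df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
    ms_ag <- ssd_ag / df_ag
    ms_ap <- ssd_ap_wg / df_ap
    sigma_c <- ssd_wp / df_wp
    # unequal-n coefficients
    sum_npg <- vapply(names(idx_grp), function(g) {
      pops_g <- unique(populations[idx_grp[[g]]])
      sum(n_p[pops_g]^2) / N_g[g]
    }, 0)
    n_coef <- (N - sum(sum_npg)) / (P - G)
    n1_coef <- (sum(sum_npg) - sum(n_p^2) / N) / (G - 1)
    n2_coef <- (N - sum(N_g^2) / N) / (G - 1)
    sigma_b <- (ms_ap - sigma_c) / n_coef
    sigma_a <- (ms_ag - sigma_c - n1_coef * sigma_b) / n2_coef
    total <- sigma_a + sigma_b + sigma_c
    comp <- data.frame(
      source = c("among_groups", "among_populations_within_groups",
                 "within_populations", "total"),
      df = c(df_ag, df_ap, df_wp, N - 1),
      SSD = c(ssd_ag, ssd_ap_wg, ssd_wp, ssd_total),
      sigma2 = c(sigma_a, sigma_b, sigma_c, total),
      percent = 100 * c(sigma_a, sigma_b, sigma_c, total) / total)
    phi <- list(PHI_CT = sigma_a / total,
                PHI_SC = sigma_b / (sigma_b + sigma_c),
                PHI_ST = (sigma_a + sigma_b) / total)
  }
  structure(list(components = comp, phi = phi, p_values = NULL,
                 n_permutations = 0),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  print(x$components, row.names = FALSE)
  for (nm in names(x$phi)) {
    cat(sprintf("%s = %.4f", nm, x$phi[[nm]]))
    if (!is.null(x$p_values[[nm]]))
      cat(sprintf("  (P = %.5g, %d permutations)", x$p_values[[nm]],
                  x$n_permutations))
    cat("\n")
  }
  invisible(x)
}

amova_permute <- function(d2, populations, groups, phi_obs, n_perm) {
  N <- length(populations)
  p <- list()
  # Phi_ST: permute samples among populations
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- populations[sample.int(N)]
    st <- amova_components(d2, perm, NULL)$phi$PHI_ST
    if (st >= phi_obs$PHI_ST - 1e-12) hits <- hits + 1L
  }
  p$PHI_ST <- (hits + 1) / (n_perm + 1)
  if (!is.null(groups) && length(unique(groups)) >= 2) {
    pops <- unique(populations)
    # Phi_CT: permute whole populations among groups
    hits <- 0L
    for (b in seq_len(n_perm)) {
      g <- setNames(sample(groups[pops]), pops)
      ct <- amova_components(d2, populations, g)$phi$PHI_CT
      if (ct >= phi_obs$PHI_CT - 1e-12) hits <- hits + 1L
    }
    p$PHI_CT <- (hits + 1) / (n_perm + 1)
    # Phi_SC: permute samples among populations within their group
    grp_of_sample <- groups[populations]
    hits <- 0L
    for (b in seq_len(n_perm)) {
      perm <- populations
      for (g in unique(grp_of_sample)) {
        i <- which(grp_of_sample == g)
        perm[i] <- populations[i][sample.int(length(i))]
      }
      sc <- amova_components(d2, perm, groups)$phi$PHI_SC
      if (sc >= phi_obs$PHI_SC - 1e-12) hits <- hits + 1L
    }
    p$PHI_SC <- (hits + 1) / (n_perm + 1)
  }
  p
}

#' Permutation test for AMOVA Phi statistics
#'
#' Convenience wrapper around [amova()] returning the permutation P-values
#' only.
#'
#' @inheritParams amova
#' @return named list of P-values.
#' @export
permutation_test <- function(haplotypes, populations = NULL, groups = NULL,
                             metric = "loci_differing", n_perm = 1000,
                             seed = NULL) {
  amova(haplotypes, populations, groups, metric,
        n_perm = n_perm, seed = seed)$p_values
}
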