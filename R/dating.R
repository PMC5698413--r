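#' Rho statistic on a mutation-count tree
#'
#' The rho statistic is the mean number of mutations separating the sampled
#' lineages from their common ancestor: `rho = (1/n) * sum over tips of the
#' root-to-tip mutation count`, computed branch-wise as
#' `sum_b (n_b / n) * l_b` where `l_b` is the number of mutations on branch
#' `b` and `n_b` the number of tips below it.  Its standard error is the
#' Saillard estimator `sigma = sqrt(sum_b (n_b / n)^2 * l_b)`, which treats
#' branch counts as independent Poisson draws.  Under rate constancy
#' `rho = mu * T`, so rho converts linearly to a TMRCA
#' (see [tmrca_from_rho()]).
#'
#' @param tree rooted [ape::phylo] whose `edge.length` are mutation counts
#'   (e.g. from [build_perfect_phylogeny()] or a simulated genealogy with
#'   counts attached).
#' @param node optional internal node number: date this clade instead of
#'   the root.  The basal node of the edge table is taken as the root; a
#'   tree stored as a basal polytomy is treated as rooted there.
#' @return object of class `rho_estimate` with `rho`, `sigma`, `n_tips`.
#' @export
rho_snp <- function(tree, node = NULL) {
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1)
    stop("tree must be rooted (a single root node)")
  if (!is.null(node)) tree <- ape::extract.clade(tree, node)
  n <- length(tree$tip.label)
  if (n < 1) stop("focal node has no descendant tips")
  ntips_below <- function(tr) {
    nb <- nrow(tr$edge)
    cnt <- integer(max(tr$edge))
    cnt[seq_len(n)] <- 1L
    tr <- ape::reorder.phylo(tr, "postorder")
    for (e in seq_len(nb))
      cnt[tr$edge[e, 1]] <- cnt[tr$edge[e, 1]] + cnt[tr$edge[e, 2]]
    list(tree = tr, nb = cnt)
  }
  if (n == 1) {
    rho <- sum(tree$edge.length)
    sigma <- sqrt(rho)
  } else {
    tb <- ntips_below(tree)
    w <- tb$nb[tb$tree$edge[, 2]] / n
    rho <- sum(w * tb$tree$edge.length)
    sigma <- sqrt(sum(w^2 * tb$tree$edge.length))
  }
  structure(list(rho = rho, sigma = sigma, n_tips = n, mode = "snp"),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("rho = %.4g (sigma %.4g), n = %d tips", x$rho, x$sigma, x$n_tips))
  if (!is.null(x$tmrca))
    cat(sprintf("; TMRCA %.0f y [%.0f, %.0f]", x$tmrca, x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Rho statistic from STR haplotypes
#'
#' Rho is the mean single-step distance (sum over loci of absolute
#' repeat-count differences) from each haplotype to the founder.  With
#' `founder = "modal"` the founder is the per-locus modal repeat vector —
#' the haplotype minimising the mean distance to the sample.  The standard
#' error uses the star-genealogy approximation `sqrt(rho / n)` (the
#' Saillard estimator collapses to it when every lineage is independent),
#' which is the appropriate regime for rapidly radiating haplogroups.
#'
#' @param strs an `str_haplotypes` table (or plain numeric matrix of repeat
#'   counts, samples x loci) with no missing values.
#' @param founder `"modal"`, or a named numeric vector of founder repeats.
#' @param loci optional locus subset.
#' @return a `rho_estimate` with the founder haplotype attached.
#' @export
rho_str <- function(strs, founder = "modal", loci = NULL) {
  m <- if (is.matrix(strs)) strs else str_matrix(strs, loci)
  if (!is.null(loci)) m <- m[, loci, drop = FALSE]
  if (ncol(m) == 0) stop("empty locus set")
  if (nrow(m) < 2) stop("need at least two haplotypes")
  if (anyNA(m)) stop("missing repeat counts; complete data required")
  if (identical(founder, "modal")) {
    founder <- apply(m, 2, function(col) {
      tb <- table(col)
      as.numeric(names(tb)[which.max(tb)])
    })
  } else {
    founder <- founder[colnames(m)]
    if (anyNA(founder)) stop("founder must cover every locus")
  }
  d <- rowSums(abs(sweep(m, 2, founder)))
  n <- nrow(m)
  rho <- mean(d)
  structure(list(rho = rho, sigma = sqrt(rho / n), n_tips = n, mode = "str",
                 founder = founder, distances = d),
            class = "rho_estimate")
}

#' Convert a rho estimate to a TMRCA in years
#'
#' Under rate constancy `rho = mu * T`.  In SNP mode `mu` is the per-year
#' mutation rate over the callable sequence (`snp_rate * callable_length`);
#' in STR mode it is the per-haplotype rate `str_rate` (default 1/858 per
#' year, i.e. `T = rho * 858`).  The confidence interval is
#' `T +/- ci_multiplier * sigma_T`, with sigma scaled by the same factor as
#' rho.
#'
#' @param est a `rho_estimate` from [rho_snp()] or [rho_str()].
#' @param rates a [mutation_rate_spec()].
#' @param mode `"snp"` or `"str"` (defaults to the estimate's own mode).
#' @param ci_multiplier half-width of the CI in sigma units (1.96 for a
#'   nominal 95 percent normal interval).
#' @return the completed `rho_estimate` with `tmrca`, `ci_low`, `ci_high`.
#' @export
tmrca_from_rho <- function(est, rates = mutation_rate_spec(),
                           mode = NULL, ci_multiplier = 1.96) {
  mode <- mode %||% est$mode
  mu <- switch(mode,
               snp = rates$snp_rate * rates$callable_length,
               str = rates$str_rate,
               stop("mode must be 'snp' or 'str'"))
  if (mu <= 0) stop("mutation rate must be positive")
  est$tmrca <- est$rho / mu
  sT <- est$sigma / mu
  est$ci_low <- max(0, est$tmrca - ci_multiplier * sT)
  est$ci_high <- est$tmrca + ci_multiplier * sT
  est$rate <- mu
  est$mode <- mode
  est
}

#' Effective per-variable-site substitution rate
#'
#' When a clock analysis is run on variable sites only, the genome-wide
#' per-site rate must be rescaled by callable length over the number of
#' variable sites: `rate * callable_length / n_variable_sites`.
#'
#' @param rates a [mutation_rate_spec()].
#' @param n_variable_sites number of variable sites in the alignment (> 0).
#' @return per-variable-site per-year rate.
#' @export
effective_rate_per_variable_site <- function(rates, n_variable_sites) {
  if (n_variable_sites <= 0) stop("n_variable_sites must be positive")
  rates$snp_rate * rates$callable_length / n_variable_sites
}
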