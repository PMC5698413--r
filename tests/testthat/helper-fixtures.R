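# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# A small variant matrix from explicit genotype rows (one string per site,
# characters 0/1/2/N per sample).
vm_from_strings <- function(rows, pos = NULL, depth = 30L,
                            samples = NULL) {
  n <- nchar(rows[1])
  geno <- t(vapply(rows, function(r) {
    ch <- strsplit(r, "")[[1]]
    out <- suppressWarnings(as.integer(ch))
    out
  }, integer(n)))
  if (is.null(pos)) pos <- seq_len(length(rows)) * 10L
  if (is.null(samples)) samples <- paste0("s", seq_len(n))
  variant_matrix(pos, rep("A", length(rows)), rep("G", length(rows)),
                 samples, geno,
                 matrix(depth, length(rows), n))
}

# Write a variant matrix to a temporary VCF and return the path.
tmp_vcf <- function(vm) {
  p <- tempfile(fileext = ".vcf")
  write_vcf_matrix(vm, p)
  p
}

# STR haplotype table from a repeat matrix.
str_table <- function(m, population = "pop", longitude = 0,
                      loci = NULL) {
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(m)))
  d <- data.frame(sample = paste0("s", seq_len(nrow(m))),
                  population = population, longitude = longitude)
  d[loci] <- as.data.frame(m)
  class(d) <- c("str_haplotypes", "data.frame")
  d
}

# Brute-force enumeration of all minimum spanning trees of a complete graph
# given a distance matrix (n <= 7): returns the set of edges (i < j) that
# occur in at least one MST, via Cayley enumeration of spanning trees.
all_mst_edges <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 7)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(edges)
  # enumerate all spanning trees = subsets of n-1 edges forming a tree
  combs <- utils::combn(ne, n - 1)
  best <- Inf; in_some <- logical(ne)
  costs <- apply(combs, 2, function(ix) sum(d[edges[ix, , drop = FALSE]]))
  is_tree <- apply(combs, 2, function(ix) {
    comp <- seq_len(n)
    for (k in ix) {
      a <- comp[edges[k, 1]]; b <- comp[edges[k, 2]]
      if (a == b) return(FALSE)
      comp[comp == b] <- a
    }
    TRUE
  })
  mst_cost <- min(costs[is_tree])
  for (c_i in which(is_tree & abs(costs - mst_cost) < 1e-9))
    in_some[combs[, c_i]] <- TRUE
  cbind(edges[in_some, , drop = FALSE],
        weight = d[edges[in_some, , drop = FALSE]])
}

# Exact expected single-step distance from the founder after time t at
# per-haplotype rate per year `rate` spread over `k` loci with uniform
# weights: per locus, the net displacement after N ~ Poisson(lambda) steps
# of +/-1; E|net| by enumeration (floor-at-1 reflection ignored, valid for
# founders far from 1).
expected_step_distance <- function(t, rate, k, kmax = 60) {
  lam <- rate * t / k
  e_abs_walk <- function(nsteps) {
    if (nsteps == 0) return(0)
    j <- 0:nsteps
    sum(abs(nsteps - 2 * j) * choose(nsteps, j)) / 2^nsteps
  }
  per_locus <- sum(vapply(0:kmax, function(nn)
    stats::dpois(nn, lam) * e_abs_walk(nn), 0))
  k * per_locus
}
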