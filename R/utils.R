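#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention of population-genetics
#' frequency tables), unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stage index,
# so each stochastic stage of a pipeline gets an independent stream.
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.numeric(master) * 7919 + as.numeric(k) * 104729) %% 2147483629 + 1)
}

# All permutations of seq_len(n) as a matrix (n! rows); used for exact
# permutation tests at small n (n <= 8 -> at most 40,320 rows).
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = nrow(sub) * n, ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    blk <- matrix(rest[sub], nrow(sub), n - 1L)
    out[r + seq_len(nrow(sub)), ] <- cbind(i, blk)
    r <- r + nrow(sub)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
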