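test_that("distance matrices match hand computation and are metric", {
  m <- rbind(c(13, 29), c(15, 29))
  colnames(m) <- c("L1", "L2")
  expect_equal(str_distance_matrix(m, "loci_differing")[1, 2], 1)
  expect_equal(str_distance_matrix(m, "stepwise_squared")[1, 2], 4)
  expect_equal(str_distance_matrix(m, "stepwise")[1, 2], 2)
  expect_equal(str_distance_matrix(rbind(m[1, ], m[1, ]))[1, 2], 0)
  set.seed(3)
  r <- matrix(sample(8:15, 7 * 3, TRUE), 7, 3,
              dimnames = list(NULL, paste0("L", 1:3)))
  d <- str_distance_matrix(r, "loci_differing")
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality for the loci-differing metric
  for (i in 1:7) for (j in 1:7) for (k in 1:7)
    if (d[i, j] > d[i, k] + d[k, j] + 1e-12)
      fail(sprintf("triangle violated at %d,%d,%d", i, j, k))
  succeed()
})

test_that("one-level AMOVA matches the classical nested-ANOVA oracle", {
  # single locus, squared-difference distance: AMOVA variance components
  # coincide with the random-effects one-way ANOVA on the repeat counts
  set.seed(21)
  x <- c(rnorm(4, 10), rnorm(4, 14), rnorm(4, 11))
  pop <- rep(c("A", "B", "C"), each = 4)
  m <- matrix(round(x), 12, 1, dimnames = list(NULL, "L1"))
  res <- amova(m, pop, metric = "stepwise_squared")
  fit <- stats::aov(m[, 1] ~ factor(pop))
  ss <- summary(fit)[[1]]
  expect_equal(res$components$SSD[1], ss$`Sum Sq`[1])   # among
  expect_equal(res$components$SSD[2], ss$`Sum Sq`[2])   # within
  sigma_w <- ss$`Mean Sq`[2]
  sigma_a <- (ss$`Mean Sq`[1] - sigma_w) / 4            # balanced n = 4
  expect_equal(res$components$sigma2[1], sigma_a)
  expect_equal(res$components$sigma2[2], sigma_w)
  expect_equal(res$phi$PHI_ST, sigma_a / (sigma_a + sigma_w))
  expect_equal(sum(res$components$percent[1:2]), 100)
})

test_that("two-level AMOVA matches the balanced nested aov oracle", {
  set.seed(31)
  # 2 groups x 2 populations x 5 samples, single locus
  grp <- rep(c("G1", "G2"), each = 10)
  pop <- rep(c("p1", "p2", "p3", "p4"), each = 5)
  x <- round(c(rnorm(5, 10), rnorm(5, 12), rnorm(5, 16), rnorm(5, 18)))
  m <- matrix(x, 20, 1, dimnames = list(NULL, "L1"))
  groups <- c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = "G2")
  res <- amova(m, pop, groups = groups, metric = "stepwise_squared")
  fit <- stats::aov(x ~ factor(grp) + factor(grp):factor(pop))
  ss <- summary(fit)[[1]]
  expect_equal(res$components$SSD[1:3], ss$`Sum Sq`, tolerance = 1e-9)
  # balanced expected mean squares: MS_wp = sc; MS_pg = sc + 5 sb;
  # MS_g = sc + 5 sb + 10 sa
  sc <- ss$`Mean Sq`[3]
  sb <- (ss$`Mean Sq`[2] - sc) / 5
  sa <- (ss$`Mean Sq`[1] - sc - 5 * sb) / 10
  expect_equal(res$components$sigma2[1:3], c(sa, sb, sc), tolerance = 1e-9)
  expect_equal(res$phi$PHI_CT, sa / (sa + sb + sc))
  expect_equal(res$phi$PHI_SC, sb / (sb + sc))
  expect_equal(res$phi$PHI_ST, (sa + sb) / (sa + sb + sc))
  expect_equal(sum(res$components$percent[1:3]), 100)
})

test_that("AMOVA equals a brute-force mean-squared-distance oracle (<= 12 samples)", {
  # independent oracle coded directly from the SSD definition with double
  # loops, on unbalanced multi-locus designs
  set.seed(41)
  for (rep in 1:5) {
    n_p <- sample(2:5, 3, TRUE)
    pop <- rep(c("A", "B", "C"), n_p)
    N <- length(pop)
    m <- matrix(sample(9:14, N * 3, TRUE), N, 3,
                dimnames = list(NULL, paste0("L", 1:3)))
    res <- amova(m, pop, metric = "loci_differing")
    d <- matrix(0, N, N)
    for (i in 1:N) for (j in 1:N) d[i, j] <- sum(m[i, ] != m[j, ])
    ssd_tot <- sum(d) / (2 * N)
    ssd_wp <- 0
    for (p in unique(pop)) {
      i <- which(pop == p)
      ssd_wp <- ssd_wp + sum(d[i, i]) / (2 * length(i))
    }
    expect_equal(res$components$SSD[3], ssd_tot)
    expect_equal(res$components$SSD[2], ssd_wp)
    expect_equal(res$components$SSD[1], ssd_tot - ssd_wp)
    sigma_w <- ssd_wp / (N - 3)
    n0 <- (N - sum(n_p^2) / N) / 2
    sigma_a <- ((ssd_tot - ssd_wp) / 2 - sigma_w) / n0
    expect_equal(res$phi$PHI_ST, sigma_a / (sigma_a + sigma_w))
  }
})

test_that("complete fixation gives Phi_ST = 1 and 100% among-population variance", {
  m <- rbind(matrix(10, 5, 2), matrix(14, 5, 2))
  colnames(m) <- c("L1", "L2")
  pop <- rep(c("A", "B"), each = 5)
  res <- amova(m, pop)
  expect_equal(res$phi$PHI_ST, 1)
  expect_equal(res$components$percent[1], 100)
  expect_equal(res$components$sigma2[2], 0)
})

test_that("permuted labels centre Phi_ST on zero", {
  set.seed(51)
  m <- matrix(sample(9:14, 30 * 4, TRUE), 30, 4,
              dimnames = list(NULL, paste0("L", 1:4)))
  phis <- replicate(60, {
    pop <- sample(rep(c("A", "B", "C"), each = 10))
    amova(m, pop)$phi$PHI_ST
  })
  # mean Phi under the null is ~ -1/(N-1) scale, i.e. near 0
  expect_lt(abs(mean(phis)), 0.02)
})

test_that("fixed two-population case yields the minimal permutation p-value", {
  m <- rbind(matrix(10, 10, 2), matrix(14, 10, 2))
  colnames(m) <- c("L1", "L2")
  pop <- rep(c("A", "B"), each = 10)
  p <- permutation_test(m, pop, n_perm = 999, seed = 7)
  expect_equal(p$PHI_ST, 1 / 1000)
  # reproducible under the same seed
  p2 <- permutation_test(m, pop, n_perm = 999, seed = 7)
  expect_identical(p, p2)
})

test_that("null permutation p-values are roughly uniform", {
  set.seed(61)
  m0 <- matrix(sample(9:14, 20 * 3, TRUE), 20, 3,
               dimnames = list(NULL, paste0("L", 1:3)))
  ps <- replicate(100, {
    pop <- sample(rep(c("A", "B"), each = 10))
    mm <- m0[sample(20), ]
    permutation_test(mm, pop, n_perm = 120, seed = sample.int(1e6, 1))$PHI_ST
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate designs are handled per convention", {
  m <- matrix(sample(9:14, 9 * 2, TRUE), 9, 2,
              dimnames = list(NULL, c("L1", "L2")))
  pop <- c(rep("A", 4), rep("B", 4), "C")      # C has n = 1
  expect_warning(res <- amova(m, pop), "n = 1")
  expect_equal(res$components$df[1], 1)        # only A and B remain
  # a two-level design with a single group collapses to one level
  groups1 <- c(A = "G", B = "G")
  res1 <- amova(m[1:8, ], pop[1:8], groups = groups1)
  res0 <- amova(m[1:8, ], pop[1:8])
  expect_equal(res1$components, res0$components)
  expect_error(amova(m[1:4, ], rep("A", 4)), ">= 2 populations")
})
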