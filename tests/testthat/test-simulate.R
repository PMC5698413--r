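test_that("star genealogies have equal branch lengths and exact depth", {
  tr <- simulate_genealogy(genealogy_model(4, 1000, "star"))
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$edge.length, rep(1000, 4))
  expect_equal(attr(tr, "tmrca"), 1000)
  expect_error(genealogy_model(1, 1000, "star"), "n_samples")
  expect_error(genealogy_model(4, 0, "star"), "tmrca")
})

test_that("pairwise coalescence time has the expected exponential mean", {
  scale <- 1500
  set.seed(11)
  reps <- 10000
  times <- replicate(reps, {
    tr <- simulate_genealogy(genealogy_model(2, scale, "coalescent_const"))
    attr(tr, "tmrca")
  })
  # E[T2] = scale; MC mean within 3 SE (sd of Exp(1/scale) is scale)
  expect_lt(abs(mean(times) - scale), 3 * scale / sqrt(reps))
})

test_that("seeded genealogies are bit-reproducible", {
  m <- genealogy_model(8, 2000, "coalescent_const", seed = 42)
  t1 <- simulate_genealogy(m)
  t2 <- simulate_genealogy(m)
  expect_identical(t1$edge, t2$edge)
  expect_identical(t1$edge.length, t2$edge.length)
  t3 <- simulate_genealogy(genealogy_model(8, 2000, "coalescent_growth",
                                           growth_rate = 1e-3, seed = 7))
  t4 <- simulate_genealogy(genealogy_model(8, 2000, "coalescent_growth",
                                           growth_rate = 1e-3, seed = 7))
  expect_identical(t3$edge.length, t4$edge.length)
})

test_that("coalescent trees are valid rooted binary phylo objects", {
  for (s in 1:5) {
    tr <- simulate_genealogy(genealogy_model(10, 3000, "coalescent_const"),
                             seed = s)
    expect_s3_class(tr, "phylo")
    expect_true(ape::is.binary(tr))
    expect_true(ape::is.rooted(tr))
    depths <- ape::node.depth.edgelength(tr)
    # ultrametric: all tips at the same depth = realized TMRCA
    expect_equal(max(abs(depths[1:10] - attr(tr, "tmrca"))), 0,
                 tolerance = 1e-9)
  }
})

test_that("SNP mutation counts follow the Poisson mean over the genealogy", {
  rates <- mutation_rate_spec(snp_rate = 1e-9, callable_length = 4.88e6)
  tr <- simulate_genealogy(genealogy_model(100, 2000, "star"))
  set.seed(21)
  reps <- 200
  per_tip <- replicate(reps, {
    vm <- drop_snp_mutations(tr, rates)
    mean(colSums(vm$geno == 1L, na.rm = TRUE))
  })
  lam <- 1e-9 * 4.88e6 * 2000  # 9.76 mutations per tip
  se <- sqrt(lam / (100 * reps))
  expect_lt(abs(mean(per_tip) - lam), 3 * se)
})

test_that("zero SNP rate yields zero variants and descent logic is nested", {
  tr <- simulate_genealogy(genealogy_model(6, 2000, "coalescent_const"),
                           seed = 3)
  rates0 <- mutation_rate_spec(snp_rate = 0)
  expect_equal(n_sites(drop_snp_mutations(tr, rates0, seed = 1)), 0)
  # every variant's carrier set matches the tip set of its branch
  rates <- mutation_rate_spec(snp_rate = 2e-8)
  vm <- drop_snp_mutations(tr, rates, seed = 5)
  edge_of <- attr(vm, "site_edge")
  sets <- ylineage:::edge_tip_sets(tr)
  ok <- vapply(seq_len(n_sites(vm)), function(i)
    identical(as.integer(sort(unname(which(vm$geno[i, ] == 1L)))),
              as.integer(sort(unname(sets[[edge_of[i]]])))), TRUE)
  expect_true(all(ok))
})

test_that("infinite-sites holds: no site is hit twice, all pairs compatible", {
  tr <- simulate_genealogy(genealogy_model(12, 2500, "coalescent_const"),
                           seed = 9)
  vm <- drop_snp_mutations(tr, mutation_rate_spec(snp_rate = 3e-8), seed = 10)
  expect_false(any(duplicated(vm$pos)))
  # four-gamete test on every site pair (ancestral state known): carrier
  # sets must be nested or disjoint
  sets <- apply(vm$geno == 1L, 1, which, simplify = FALSE)
  for (a in seq_along(sets)) for (b in seq_len(a - 1L)) {
    i <- length(intersect(sets[[a]], sets[[b]]))
    ok <- i == 0 || i == length(sets[[a]]) || i == length(sets[[b]])
    if (!ok) fail(sprintf("sites %d and %d violate four gametes", a, b))
  }
  succeed()
})

test_that("STR evolution matches Poisson counts and the step-distance oracle", {
  rates <- mutation_rate_spec()  # str_rate = 1/858, 13 loci
  tr <- simulate_genealogy(genealogy_model(200, 2000, "star"))
  set.seed(31)
  reps <- 200
  res <- replicate(reps, {
    st <- evolve_strs(tr, rates)
    d <- rowSums(abs(sweep(str_matrix(st <- st), 2, YFILER_FOUNDER[YFILER_LOCI])))
    c(mean_dist = mean(d), n_mut = sum(attr(st, "branch_mutations")))
  })
  lam <- 2000 / 858  # expected mutations per lineage
  # raw mutation count is exactly Poisson
  se_mut <- sqrt(lam / (200 * reps))
  expect_lt(abs(mean(res["n_mut", ]) / 200 - lam), 3 * se_mut)
  # net distance is smaller: same-locus steps can cancel; exact expectation
  # from the Poisson +/-1 walk enumeration
  exp_d <- expected_step_distance(2000, 1 / 858, 13)
  expect_lt(exp_d, lam)  # sanity: cancellation reduces the mean
  se_d <- sd(res["mean_dist", ]) / sqrt(reps)
  expect_lt(abs(mean(res["mean_dist", ]) - exp_d), 3 * se_d)
})

test_that("zero STR rate copies the founder everywhere; floor reflects at 1", {
  tr <- simulate_genealogy(genealogy_model(5, 1000, "star"))
  st <- evolve_strs(tr, mutation_rate_spec(str_rate = 0), seed = 1)
  m <- str_matrix(st)
  for (i in 1:5) expect_equal(unname(m[i, ]), unname(as.numeric(YFILER_FOUNDER)))
  # a locus driven hard downward never drops below 1
  rates <- mutation_rate_spec(str_rate = 0.5, str_loci = "L1",
                              per_locus_weights = 1)
  st2 <- evolve_strs(simulate_genealogy(genealogy_model(30, 100, "star")),
                     rates, founder = c(L1 = 2L), seed = 2)
  expect_true(all(str_matrix(st2) >= 1))
})

test_that("multi-population panels keep labels, longitudes and truth", {
  pops <- data.frame(name = c("A", "B"), n = c(5, 7),
                     longitude = c(-10, 10), tmrca = c(1000, 2000),
                     topology = "star")
  rates <- mutation_rate_spec(snp_rate = 1e-8)
  pan <- generate_population_panel(pops, rates, seed = 5)
  expect_equal(n_samples(pan$variants), 12)
  expect_equal(sum(pan$strs$population == "A"), 5)
  expect_equal(unique(pan$strs$longitude[pan$strs$population == "B"]), 10)
  expect_equal(pan$truth$A$tmrca, 1000)
  expect_false(any(duplicated(pan$variants$pos)))
  expect_error(generate_population_panel(
    data.frame(name = c("A", "A"), n = c(2, 2), longitude = 0),
    rates, seed = 1), "duplicate")
})

test_that("panels sharing one genealogy carry no population signal", {
  pops <- data.frame(name = c("A", "B"), n = c(10, 10), longitude = c(0, 1),
                     tmrca = 2000, topology = "coalescent_const")
  pan <- generate_population_panel(pops, mutation_rate_spec(), seed = 8,
                                   shared_genealogy = TRUE)
  am <- amova(pan$strs)
  # exchangeable labels: among-population Phi centred on 0 (well below
  # fixation levels); a single draw just needs to be small
  expect_lt(abs(am$phi$PHI_ST), 0.35)
})

test_that("panels round-trip through VCF/CSV/Newick/JSON losslessly", {
  pops <- data.frame(name = c("A", "B"), n = c(4, 3), longitude = c(-5, 5))
  pan <- generate_population_panel(pops, mutation_rate_spec(snp_rate = 5e-9),
                                   seed = 13)
  dir <- tempfile()
  write_panel(pan, dir)
  back <- read_panel(dir)
  expect_equal(back$variants$pos, pan$variants$pos)
  expect_equal(unname(back$variants$geno), unname(pan$variants$geno))
  expect_equal(back$variants$samples, pan$variants$samples)
  expect_equal(str_matrix(back$strs), str_matrix(pan$strs))
  expect_equal(back$strs$longitude, pan$strs$longitude)
  expect_equal(back$truth$A$tmrca, pan$truth$A$tmrca)
  unlink(dir, recursive = TRUE)
})

test_that("an empty variant set writes a header-only VCF that reads back", {
  vm <- variant_matrix(integer(0), character(0), character(0),
                       c("s1", "s2"), matrix(integer(0), 0, 2),
                       matrix(integer(0), 0, 2))
  p <- tempfile(fileext = ".vcf")
  write_vcf_matrix(vm, p)
  expect_true(any(grepl("^#CHROM", readLines(p))))
  back <- read_vcf_matrix(p)
  expect_equal(n_sites(back), 0)
  expect_equal(back$samples, c("s1", "s2"))
})
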