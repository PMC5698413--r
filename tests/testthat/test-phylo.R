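test_that("nested carrier sets build the hand-derived caterpillar tree", {
  # carriers: A={1,2,3,4} (stem edge), B={1,2} nested in A, C={1} in B
  vm <- vm_from_strings(c("1111", "1100", "1000"), pos = c(10, 20, 30))
  tr <- build_perfect_phylogeny(vm)
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4)
  # tip 1 carries all three variants: path length 3 mutations
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[1:4], c(3, 2, 1, 1))
  # clade {1,2} exists
  mrca12 <- ape::getMRCA(tr, c("s1", "s2"))
  clade <- ape::extract.clade(tr, mrca12)
  expect_setequal(clade$tip.label, c("s1", "s2"))
})

test_that("a single sample yields a one-tip tree carrying its variants", {
  vm <- vm_from_strings(c("1", "1", "0"), pos = c(5, 6, 7), samples = "only")
  tr <- build_perfect_phylogeny(vm)
  expect_equal(length(tr$tip.label), 1)
  expect_equal(sum(tr$edge.length), 2)
})

test_that("four-gamete violations are reported with the offending sites", {
  # carriers {1,2} and {2,3}: overlapping, neither nested
  vm <- vm_from_strings(c("110", "011"), pos = c(10, 20))
  expect_error(build_perfect_phylogeny(vm), "four-gamete")
})

test_that("variant groups land on one edge with the right mutation counts", {
  # two variants with identical carriers {1,2} stack on one edge
  vm <- vm_from_strings(c("1100", "1100", "0011"), pos = c(1, 2, 3))
  tr <- build_perfect_phylogeny(vm)
  ev <- attr(tr, "edge_variants")
  stacked <- ev[[which(tr$edge.length == 2)]]
  expect_setequal(stacked, c("chrY_1", "chrY_2"))
  expect_equal(sum(tr$edge.length), 3)
})

test_that("reconstruction recovers simulated coalescent topologies (RF = 0)", {
  skip_if_not_installed("phangorn")
  # rate high enough that every internal branch carries a mutation
  rates <- mutation_rate_spec(snp_rate = 1e-7)
  for (s in c(2, 5, 8)) {
    tr <- simulate_genealogy(genealogy_model(8, 3000, "coalescent_const"),
                             seed = s)
    vm <- drop_snp_mutations(tr, rates, seed = s + 100)
    rec <- build_perfect_phylogeny(vm)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(rec)), 0)
  }
})

test_that("haplogroup assignment walks the hierarchy and stars paraclades", {
  defs <- em183_defs()
  full <- c(M183 = 1L, SM001 = 1L, PF6794 = 1L, PF6789 = 1L,
            CTS12227 = 0L, Z5009 = 0L)
  expect_equal(assign_haplogroup(full, defs), "PF6789")
  basal <- c(M183 = 1L, SM001 = 0L, PF6794 = 0L, PF6789 = 0L,
             CTS12227 = 0L, Z5009 = 0L)
  expect_equal(assign_haplogroup(basal, defs), "M183*")
  sm <- c(M183 = 1L, SM001 = 1L, PF6794 = 0L, PF6789 = 0L,
          CTS12227 = 0L, Z5009 = 0L)
  expect_equal(assign_haplogroup(sm, defs), "SM001*")
  other <- c(M183 = 0L, SM001 = 0L, PF6794 = 0L, PF6789 = 0L,
             CTS12227 = 0L, Z5009 = 0L)
  expect_equal(assign_haplogroup(other, defs), "ROOT*")
  # inconsistency: derived PF6789 but ancestral PF6794
  bad <- c(M183 = 1L, SM001 = 1L, PF6794 = 0L, PF6789 = 1L,
           CTS12227 = 0L, Z5009 = 0L)
  expect_error(assign_haplogroup(bad, defs), "inconsistent")
  # missing defining call on an edge blocks descent (conservative)
  blocked <- c(M183 = 1L, SM001 = NA, PF6794 = NA, PF6789 = NA,
               CTS12227 = NA, Z5009 = NA)
  expect_equal(assign_haplogroup(blocked, defs), "M183*")
  # call order is irrelevant
  expect_equal(assign_haplogroup(rev(full), defs), "PF6789")
})

test_that("terminal-clade assignment works for each SM001 subclade", {
  defs <- em183_defs()
  for (term in c("CTS12227", "Z5009")) {
    calls <- setNames(rep(0L, 6),
                      c("M183", "SM001", "PF6794", "PF6789", "CTS12227",
                        "Z5009"))
    calls[c("M183", "SM001", term)] <- 1L
    expect_equal(assign_haplogroup(calls, defs), term)
  }
})

test_that("frequency tables reproduce published per-population percentages", {
  counts <- read.csv(system.file("extdata", "em183_published_counts.csv",
                                 package = "ylineage"), check.names = FALSE)
  cols <- c("M183*", "SM001*", "PF6794*", "PF6789", "CTS12227", "Z5009",
            "Other")
  assignments <- character(0); populations <- character(0)
  for (i in seq_len(nrow(counts))) for (cl in cols) {
    k <- counts[i, cl]
    assignments <- c(assignments, rep(ifelse(cl == "Other", "ROOT*", cl), k))
    populations <- c(populations, rep(counts$population[i], k))
  }
  tab <- frequency_table(assignments, populations)
  expect_equal(tab$N[match(counts$population, tab$population)], counts$N)
  got <- tab$percent_top[match(counts$population, tab$population)]
  expect_equal(got[counts$population == "Western Sahara"], 76.92)
  expect_equal(got[counts$population == "Morocco"], 62.14)
  expect_equal(got[counts$population == "Algeria (Reguibates)"], 82.05)
  expect_equal(got[counts$population == "Tunisia"], 36.26)
  expect_equal(got[counts$population == "Near East"], 1.60)
  expect_equal(got[counts$population == "Iberian Peninsula"], 2.03)
  # row sums equal N for every population
  expect_equal(rowSums(tab[, cols]), tab$N, ignore_attr = TRUE)
  # all-Other population yields 0.00
  tab0 <- frequency_table(c("ROOT*", "ROOT*"), c("X", "X"))
  expect_equal(tab0$percent_top, 0)
})

test_that("subclade shares over top-clade chromosomes match hand arithmetic", {
  counts <- read.csv(system.file("extdata", "em183_published_counts.csv",
                                 package = "ylineage"), check.names = FALSE)
  ib <- counts[counts$population == "Iberian Peninsula", ]
  assignments <- c(rep("M183*", ib$`M183*`), rep("SM001*", ib$`SM001*`),
                   rep("PF6794*", ib$`PF6794*`), rep("PF6789", ib$PF6789),
                   rep("CTS12227", ib$CTS12227), rep("Z5009", ib$Z5009),
                   rep("ROOT*", ib$Other))
  tab <- frequency_table(assignments, rep("Iberia", length(assignments)))
  res <- percent_over_top_clade(tab, "M183*")
  expect_equal(res$percent, 22.73)           # 5 of 22 E-M183 chromosomes
  # over all chromosomes instead: 5/1084 = 0.46
  expect_equal(round_half_up(100 * 5 / 1084, 2), 0.46)
  # population with no top-clade chromosomes is flagged, not NaN
  tab0 <- frequency_table(c("ROOT*", "ROOT*"), c("X", "X"))
  res0 <- percent_over_top_clade(tab0, "M183*")
  expect_true(is.na(res0$percent))
  expect_match(res0$note, "no top-clade")
})

test_that("rounding of table percentages is half-up to two decimals", {
  expect_equal(round_half_up(76.925, 2), 76.93)
  expect_equal(round_half_up(2.0295 * 100, 0) / 100, 2.03)
  expect_equal(round_half_up(0.005, 2), 0.01)
})
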