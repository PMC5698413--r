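#' Genealogy model specification
#'
#' Describes a single-population genealogy to simulate.  Three topologies
#' are supported: `star` (every tip hangs directly off the root at depth
#' `tmrca`, the idealised rapid-radiation genealogy under which the rho
#' statistic is unbiased), `coalescent_const` (Kingman coalescent in a
#' constant-size population) and `coalescent_growth` (coalescent under
#' exponential growth at `growth_rate` per year).  For the coalescent
#' topologies `tmrca` acts as the time-scale parameter in years (the
#' product of effective size and generation time; for `n = 2` it is the
#' expected coalescence time) and the realized tree depth is random; the
#' realized value is recorded by the simulator as the truth.
#'
#' @param n_samples number of sampled chromosomes (>= 2).
#' @param tmrca star tree depth, or coalescent time scale, in years (> 0).
#' @param topology one of `"star"`, `"coalescent_const"`,
#'   `"coalescent_growth"`.
#' @param growth_rate exponential growth rate per year (growth model only).
#' @param seed optional integer seed stored with the model.
#' @return object of class `genealogy_model`.
#' @export
genealogy_model <- function(n_samples, tmrca,
                            topology = c("star", "coalescent_const",
                                         "coalescent_growth"),
                            growth_rate = NULL, seed = NULL) {
  topology <- match.arg(topology)
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (tmrca <= 0) stop("tmrca must be positive")
  if (topology == "coalescent_growth" &&
      (is.null(growth_rate) || is.na(growth_rate)))
    stop("growth model requires growth_rate")
  structure(list(n_samples = as.integer(n_samples), tmrca = tmrca,
                 topology = topology, growth_rate = growth_rate, seed = seed),
            class = "genealogy_model")
}

#' Simulate a rooted genealogy with branch lengths in years
#'
#' @param model a [genealogy_model()].
#' @param seed integer seed (overrides the model's own seed if given).
#' @return an [ape::phylo] tree with tip labels `t1..tn`, branch lengths in
#'   years, and the realized TMRCA in attribute `"tmrca"`.
#' @export
simulate_genealogy <- function(model, seed = NULL) {
  stopifnot(inherits(model, "genealogy_model"))
  seed <- seed %||% model$seed
  if (!is.null(seed)) set.seed(seed)
  n <- model$n_samples
  if (model$topology == "star") {
    tr <- ape::stree(n, type = "star", tip.label = paste0("t", seq_len(n)))
    tr$edge.length <- rep(model$tmrca, nrow(tr$edge))
    attr(tr, "tmrca") <- model$tmrca
    return(tr)
  }
  # Kingman coalescent, time in years with scale = tmrca (Ne x generation
  # time).  Under growth, the population was smaller in the past so the
  # coalescence rate accelerates as exp(g * t) looking backwards.
  scale <- model$tmrca
  g <- model$growth_rate
  lineages <- as.list(seq_len(n))      # each: vector of tip ids
  node_time <- rep(0, n)               # time of the node atop each lineage
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  labels <- paste0("t", seq_len(n))
  next_node <- n + 2L                  # ape convention: root is n+1
  node_of <- seq_len(n)                # current ape node id per lineage
  t_now <- 0
  k <- n
  parent_ids <- integer(0); child_ids <- integer(0); edge_len <- numeric(0)
  times <- rep(0, n)                   # time atop each active lineage
  while (k > 1) {
    rate <- choose(k, 2) / scale
    if (model$topology == "coalescent_const") {
      w <- rexp(1, rate)
    } else {
      # inhomogeneous rate lambda(t) = choose(k,2)/scale * exp(g t); invert
      # the integrated hazard
      u <- runif(1)
      w <- log(exp(g * t_now) - scale * g * log(u) / choose(k, 2)) / g - t_now
    }
    t_new <- t_now + w
    pick <- sample.int(k, 2)
    # the final coalescence is the root, which ape numbers n+1
    parent <- if (k == 2) n + 1L else next_node
    if (k > 2) next_node <- next_node + 1L
    for (ch in pick) {
      parent_ids <- c(parent_ids, parent)
      child_ids <- c(child_ids, node_of[ch])
      edge_len <- c(edge_len, t_new - times[ch])
    }
    keep <- setdiff(seq_len(k), pick)
    node_of <- c(node_of[keep], parent)
    times <- c(times[keep], t_new)
    t_now <- t_new
    k <- k - 1L
  }
  tr <- structure(list(edge = cbind(parent_ids, child_ids),
                       edge.length = edge_len,
                       tip.label = labels,
                       Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "tmrca") <- t_now
  tr
}

#' Mutation-rate specification for joint SNP + STR simulation and dating
#'
#' @param snp_rate substitution rate per site per year; the conventional
#'   "fast" Y rate is `1e-9`, the "slow" rate `6.17e-10`.
#' @param callable_length length (bp) of the callable unique Y sequence over
#'   which SNP mutations accrue; default 4.88 Mb.
#' @param str_rate STR mutation rate per haplotype per year; the default is
#'   the YHRD-derived 1/858 for the YFiler single-copy panel.
#' @param str_loci ordered STR locus names.
#' @param per_locus_weights fractions (summing to 1) apportioning haplotype
#'   mutations among loci; default uniform.
#' @return object of class `mutation_rate_spec`.
#' @export
mutation_rate_spec <- function(snp_rate = 1e-9, callable_length = 4.88e6,
                               str_rate = 1 / 858, str_loci = YFILER_LOCI,
                               per_locus_weights = NULL) {
  if (is.null(per_locus_weights))
    per_locus_weights <- rep(1 / length(str_loci), length(str_loci))
  if (abs(sum(per_locus_weights) - 1) > 1e-12)
    stop("per_locus_weights must sum to 1")
  if (length(per_locus_weights) != length(str_loci))
    stop("one weight per locus required")
  structure(list(snp_rate = snp_rate, callable_length = callable_length,
                 str_rate = str_rate, str_loci = str_loci,
                 per_locus_weights = per_locus_weights),
            class = "mutation_rate_spec")
}

# Number of tips below each edge of a phylo tree, plus tip-descendant lists.
edge_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  sets <- vector("list", nrow(tree$edge))
  rec <- function(node) {
    if (node <= n) return(node)
    out <- integer(0)
    for (e in kids[[as.character(node)]]) {
      s <- rec(tree$edge[e, 2])
      sets[[e]] <<- s
      out <- c(out, s)
    }
    out
  }
  rec(n + 1L)
  sets
}

#' Drop SNP mutations on a genealogy (infinite-sites model)
#'
#' Each branch receives `Poisson(snp_rate * callable_length * years)`
#' mutations; each mutation lands at a fresh site (no site is hit twice)
#' and its derived allele is carried by every tip descending from the
#' branch.  Simulated read depth is constant (30x) unless `depth` is given.
#'
#' @param tree genealogy ([ape::phylo], branch lengths in years).
#' @param rates a [mutation_rate_spec()].
#' @param seed integer seed.
#' @param depth constant read depth to record per call (default 30).
#' @return a [variant_matrix()] with attribute `"branch_mutations"` (counts
#'   per edge, ordered as `tree$edge`).
#' @export
drop_snp_mutations <- function(tree, rates, seed = NULL, depth = 30L) {
  if (rates$callable_length <= 0) stop("callable_length must be positive")
  if (!is.null(seed)) set.seed(seed)
  nb <- nrow(tree$edge)
  lam <- rates$snp_rate * rates$callable_length * tree$edge.length
  m <- rpois(nb, lam)
  total <- sum(m)
  n <- length(tree$tip.label)
  if (total > 0) {
    pos <- sort(sample.int(as.integer(rates$callable_length), total))
  } else pos <- integer(0)
  sets <- edge_tip_sets(tree)
  geno <- matrix(0L, total, n)
  edge_of <- rep(seq_len(nb), m)
  # shuffle which position belongs to which branch (positions are sorted,
  # branches are not)
  edge_of <- edge_of[sample.int(length(edge_of))]
  for (i in seq_len(total)) geno[i, sets[[edge_of[i]]]] <- 1L
  vm <- variant_matrix(pos, rep("A", total), rep("G", total),
                       tree$tip.label, geno,
                       matrix(as.integer(depth), total, n))
  attr(vm, "branch_mutations") <- m
  attr(vm, "site_edge") <- edge_of
  vm
}

#' Evolve STR haplotypes along a genealogy (single-step model)
#'
#' Mutations arrive on each branch as `Poisson(str_rate * years)`; each is
#' assigned to a locus by `per_locus_weights` and steps the repeat count by
#' +1 or -1 with equal probability.  Repeat counts cannot drop below 1: a
#' downward step at count 1 reflects to +1.
#'
#' @param tree genealogy with branch lengths in years.
#' @param rates a [mutation_rate_spec()].
#' @param founder named integer vector of founder repeat counts (>= 2) over
#'   `rates$str_loci`; defaults to [YFILER_FOUNDER] restricted to the locus
#'   set.
#' @param seed integer seed.
#' @return `str_haplotypes` data.frame: `sample` column plus one integer
#'   column per locus; attribute `"branch_mutations"` holds per-edge counts.
#' @export
evolve_strs <- function(tree, rates, founder = NULL, seed = NULL) {
  loci <- rates$str_loci
  if (is.null(founder)) {
    founder <- YFILER_FOUNDER[loci]
    if (anyNA(founder)) founder <- setNames(rep(12L, length(loci)), loci)
  }
  founder <- founder[loci]
  if (anyNA(founder) || any(founder < 2))
    stop("founder must give a repeat count >= 2 for every locus")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  nb <- nrow(tree$edge)
  m <- rpois(nb, rates$str_rate * tree$edge.length)
  # states propagate root -> tips in cladewise edge order
  states <- matrix(NA_integer_, n + tree$Nnode, length(loci))
  states[n + 1L, ] <- as.integer(founder)
  for (e in seq_len(nb)) {
    h <- states[tree$edge[e, 1], ]
    if (m[e] > 0) {
      loc <- sample.int(length(loci), m[e], replace = TRUE,
                        prob = rates$per_locus_weights)
      step <- sample(c(-1L, 1L), m[e], replace = TRUE)
      for (j in seq_len(m[e])) {
        s <- if (h[loc[j]] == 1L && step[j] < 0L) 1L else step[j]
        h[loc[j]] <- h[loc[j]] + s
      }
    }
    states[tree$edge[e, 2], ] <- h
  }
  out <- data.frame(sample = tree$tip.label,
                    states[seq_len(n), , drop = FALSE])
  names(out) <- c("sample", loci)
  attr(out, "branch_mutations") <- m
  class(out) <- c("str_haplotypes", "data.frame")
  out
}

#' Simulate a multi-population SNP + STR panel
#'
#' Each population is simulated from its own genealogy (or, with
#' `shared_genealogy = TRUE`, all populations are arbitrary label-blocks of
#' one common genealogy — the exchangeable-labels null for AMOVA).  SNP
#' sites are drawn from a common positional pool so the infinite-sites
#' property holds panel-wide; a population is ancestral at every other
#' population's private sites.
#'
#' @param pops data.frame with columns `name`, `n`, `longitude` and
#'   optionally `tmrca`, `topology`, `growth_rate` (defaults: 2000 years,
#'   star).
#' @param rates a [mutation_rate_spec()].
#' @param seed master integer seed (sub-seeds are derived per stage).
#' @param shared_genealogy simulate one genealogy of total size and split
#'   labels across populations.
#' @param founder founder STR haplotype (see [evolve_strs()]).
#' @return object of class `sim_panel`: list with `variants`
#'   (a [variant_matrix()]), `strs` (an `str_haplotypes` table with
#'   `population` and `longitude` columns), `genealogies` (list of phylo),
#'   and `truth` (per-population realized TMRCA and mutation totals).
#' @export
generate_population_panel <- function(pops, rates, seed = 1,
                                      shared_genealogy = FALSE,
                                      founder = NULL) {
  if (anyDuplicated(pops$name)) stop("duplicate population names")
  if (nrow(pops) < 1) stop("at least one population required")
  pops$tmrca <- pops$tmrca %||% rep(2000, nrow(pops))
  pops$topology <- pops$topology %||% rep("star", nrow(pops))
  trees <- list(); strs <- list(); genos <- list(); truth <- list()
  if (shared_genealogy) {
    mdl <- genealogy_model(sum(pops$n), pops$tmrca[1], pops$topology[1],
                           growth_rate = pops$growth_rate[1] %||% NULL)
    tr <- simulate_genealogy(mdl, seed = derive_seed(seed, 0))
    vm <- drop_snp_mutations(tr, rates, seed = derive_seed(seed, 1))
    st <- evolve_strs(tr, rates, founder = founder,
                      seed = derive_seed(seed, 2))
    pop_lab <- rep(pops$name, pops$n)
    ids <- paste0(pop_lab, "_", unlist(lapply(pops$n, seq_len)))
    vm$samples <- ids; colnames(vm$geno) <- ids
    if (!is.null(vm$depth)) colnames(vm$depth) <- ids
    st$sample <- ids
    st$population <- pop_lab
    st$longitude <- rep(pops$longitude, pops$n)
    truth <- list(shared = list(tmrca = attr(tr, "tmrca"),
                                n_snp_mutations = sum(attr(vm, "branch_mutations")),
                                n_str_mutations = sum(attr(st, "branch_mutations"))))
    return(structure(list(variants = vm, strs = st, genealogies = list(tr),
                          truth = truth, pops = pops),
                     class = "sim_panel"))
  }
  pool <- NULL  # positions already used, to keep sites unique panel-wide
  all_pos <- integer(0); all_geno <- list(); all_ids <- character(0)
  samp_ids <- character(0)
  str_rows <- list()
  for (i in seq_len(nrow(pops))) {
    mdl <- genealogy_model(pops$n[i], pops$tmrca[i], pops$topology[i],
                           growth_rate = pops$growth_rate[i] %||% NULL)
    tr <- simulate_genealogy(mdl, seed = derive_seed(seed, 10 * i))
    vm <- drop_snp_mutations(tr, rates, seed = derive_seed(seed, 10 * i + 1))
    st <- evolve_strs(tr, rates, founder = founder,
                      seed = derive_seed(seed, 10 * i + 2))
    ids <- paste0(pops$name[i], "_", seq_len(pops$n[i]))
    tr$tip.label <- ids
    vm$samples <- ids; colnames(vm$geno) <- ids
    if (!is.null(vm$depth)) colnames(vm$depth) <- ids
    st$sample <- ids
    st$population <- pops$name[i]
    st$longitude <- pops$longitude[i]
    trees[[pops$name[i]]] <- tr
    str_rows[[i]] <- st
    genos[[i]] <- vm
    truth[[pops$name[i]]] <-
      list(tmrca = attr(tr, "tmrca"),
           n_snp_mutations = sum(attr(vm, "branch_mutations")),
           n_str_mutations = sum(attr(st, "branch_mutations")))
  }
  # merge variant matrices: resolve positional collisions by shifting to the
  # next free position (collision probability is tiny for L ~ Mb)
  used <- new.env()
  total_n <- sum(pops$n)
  samp_ids <- unlist(lapply(genos, function(v) v$samples))
  rows <- list(); pos_all <- integer(0)
  col_off <- 0L
  recs <- list()
  for (i in seq_along(genos)) {
    v <- genos[[i]]
    for (k in seq_len(n_sites(v))) {
      p <- v$pos[k]
      while (!is.null(used[[as.character(p)]])) p <- p + 1L
      used[[as.character(p)]] <- TRUE
      g <- integer(total_n)
      g[col_off + which(v$geno[k, ] == 1L)] <- 1L
      recs[[length(recs) + 1L]] <- list(pos = p, g = g)
    }
    col_off <- col_off + n_samples(v)
  }
  if (length(recs)) {
    o <- order(vapply(recs, `[[`, 0, "pos"))
    pos <- vapply(recs, `[[`, 0, "pos")[o]
    geno <- do.call(rbind, lapply(recs[o], `[[`, "g"))
  } else {
    pos <- integer(0); geno <- matrix(0L, 0, total_n)
  }
  vm <- variant_matrix(pos, rep("A", length(pos)), rep("G", length(pos)),
                       samp_ids, geno,
                       matrix(30L, length(pos), total_n))
  st <- do.call(rbind, str_rows)
  rownames(st) <- NULL
  class(st) <- c("str_haplotypes", "data.frame")
  structure(list(variants = vm, strs = st, genealogies = trees,
                 truth = truth, pops = pops),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat(sprintf("sim_panel: %d populations, %d samples, %d SNP sites, %d STR loci\n",
              nrow(x$pops), n_samples(x$variants), n_sites(x$variants),
              sum(!names(x$strs) %in% c("sample", "population", "longitude"))))
  invisible(x)
}

#' Write a simulated panel to standard file formats
#'
#' Emits the variant matrix as VCF, the STR table (with population and
#' longitude columns) as CSV, the genealogies as Newick, and the truth
#' record as JSON; [read_panel()] round-trips them.
#'
#' @param panel a `sim_panel`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "variants.vcf"),
             strs = file.path(dir, "strs.csv"),
             trees = file.path(dir, "genealogies.nwk"),
             truth = file.path(dir, "truth.json"))
  write_vcf_matrix(panel$variants, paths[["vcf"]])
  write.csv(as.data.frame(panel$strs)[, c("sample", "population", "longitude",
            setdiff(names(panel$strs), c("sample", "population", "longitude")))],
            paths[["strs"]], row.names = FALSE)
  trs <- panel$genealogies
  class(trs) <- "multiPhylo"
  ape::write.tree(trs, file = paths[["trees"]])
  jsonlite::write_json(panel$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a panel written by [write_panel()]
#'
#' @param dir directory holding `variants.vcf`, `strs.csv`,
#'   `genealogies.nwk` and `truth.json`.
#' @return a `sim_panel` (genealogy tip truth only as far as Newick retains
#'   it).
#' @export
read_panel <- function(dir) {
  vm <- read_vcf_matrix(file.path(dir, "variants.vcf"))
  st <- read_str_table(file.path(dir, "strs.csv"))
  trs <- ape::read.tree(file.path(dir, "genealogies.nwk"))
  if (inherits(trs, "phylo")) trs <- list(trs)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(variants = vm, strs = st, genealogies = trs, truth = truth,
                 pops = unique(st[, c("population", "longitude")])),
            class = "sim_panel")
}

#' Read a Y-STR haplotype table
#'
#' CSV with header `sample,population,longitude,<locus...>`; longitudes are
#' decimal degrees, repeat counts integers.
#'
#' @param path CSV path.
#' @return an `str_haplotypes` data.frame.
#' @export
read_str_table <- function(path) {
  st <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "population", "longitude")
  if (!all(need %in% names(st)))
    stop("STR table must have columns sample, population, longitude")
  st$longitude <- as.numeric(st$longitude)
  class(st) <- c("str_haplotypes", "data.frame")
  st
}

# Extract the numeric repeat-count matrix (samples x loci) from an STR table.
str_matrix <- function(strs, loci = NULL) {
  meta <- c("sample", "population", "longitude")
  if (is.null(loci)) loci <- setdiff(names(strs), meta)
  m <- as.matrix(as.data.frame(strs)[, loci, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- strs$sample
  m
}
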