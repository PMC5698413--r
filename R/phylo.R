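#' Build a perfect phylogeny from a binary variant matrix
#'
#' Y-SNP data are effectively homoplasy-free, so the genealogy can be
#' reconstructed deterministically: every variant must label exactly one
#' edge, which is possible iff the derived-carrier sets of all site pairs
#' are nested or disjoint (the four-gamete condition with known ancestral
#' state).  Violations raise an error naming an offending site pair rather
#' than being resolved heuristically.
#'
#' Missing calls are imputed to the site's majority state (ties to
#' ancestral) and the number of imputations is reported in attribute
#' `"n_imputed"`.  Variants sharing a carrier set are stacked on one edge;
#' edge lengths equal the number of variants on the edge, ready for rho
#' dating.
#'
#' @param vm a haploid [variant_matrix()] (codes 0/1/NA only).
#' @return rooted [ape::phylo] tree whose tips are the samples; edge
#'   lengths are mutation counts and attribute `"edge_variants"` lists the
#'   variant ids on each edge.
#' @export
build_perfect_phylogeny <- function(vm) {
  g <- vm$geno
  if (any(g == 2L, na.rm = TRUE))
    stop("matrix contains heterozygous calls; run remove_heterozygous_calls first")
  n_imp <- 0L
  if (anyNA(g)) {
    for (i in seq_len(nrow(g))) {
      na <- is.na(g[i, ])
      if (any(na)) {
        maj <- if (sum(g[i, !na] == 1L) > sum(g[i, !na] == 0L)) 1L else 0L
        g[i, na] <- maj
        n_imp <- n_imp + sum(na)
      }
    }
  }
  n <- ncol(g)
  samples <- vm$samples
  informative <- rowSums(g == 1L) > 0
  g <- g[informative, , drop = FALSE]
  ids <- vm$ids[informative]
  # group variants by identical carrier sets
  key <- apply(g == 1L, 1, function(r) paste(which(r), collapse = ","))
  grp <- split(seq_along(key), key)
  sets <- lapply(grp, function(ii) which(g[ii[1], ] == 1L))
  vars <- lapply(grp, function(ii) ids[ii])
  sizes <- vapply(sets, length, 0L)
  # four-gamete check: each pair of carrier sets nested or disjoint
  o <- order(-sizes)
  sets <- sets[o]; vars <- vars[o]; sizes <- sizes[o]
  ns <- length(sets)
  for (a in seq_len(ns)) for (b in seq_len(ns)) {
    if (b <= a) next
    i <- length(intersect(sets[[a]], sets[[b]]))
    if (i > 0 && i < sizes[[b]])
      stop(sprintf("four-gamete violation between %s and %s: sites are neither nested nor disjoint",
                   vars[[a]][1], vars[[b]][1]))
  }
  if (n == 1L) {
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         edge.length = sum(informative),
                         tip.label = samples, Nnode = 1L),
                    class = "phylo")
    attr(tr, "edge_variants") <- list(ids)
    attr(tr, "n_imputed") <- n_imp
    return(tr)
  }
  # laminar family -> tree: parent of a set is the smallest proper superset.
  # Singleton sets become tip pendant edges; larger sets become internal
  # nodes; tips attach to the smallest set containing them (or the root).
  node_id <- integer(ns)              # ape node id for each internal set
  root <- n + 1L
  next_node <- n + 1L
  parent_of_set <- integer(ns)
  for (s in seq_len(ns)) {
    if (sizes[s] == 1L) next
    next_node <- next_node + 1L
    node_id[s] <- next_node
  }
  # root is n+1; internal sets occupy n+2 ... ; but ape wants Nnode counted
  find_parent <- function(s) {
    best <- 0L; bestsz <- Inf
    for (t in seq_len(ns)) {
      if (t == s || sizes[t] <= sizes[s]) next
      if (all(sets[[s]] %in% sets[[t]]) && sizes[t] < bestsz) {
        best <- t; bestsz <- sizes[t]
      }
    }
    best
  }
  par <- integer(0); chi <- integer(0); len <- numeric(0)
  evars <- list()
  for (s in seq_len(ns)) {
    p <- find_parent(s)
    pnode <- if (p == 0L) root else node_id[p]
    cnode <- if (sizes[s] == 1L) sets[[s]][1] else node_id[s]
    par <- c(par, pnode); chi <- c(chi, cnode)
    len <- c(len, length(vars[[s]]))
    evars[[length(evars) + 1L]] <- vars[[s]]
  }
  # attach each tip lacking a pendant set to its smallest containing set
  has_pendant <- unlist(sets[sizes == 1L])
  for (tip in seq_len(n)) {
    if (tip %in% has_pendant) next
    best <- 0L; bestsz <- Inf
    for (t in seq_len(ns)) {
      if (sizes[t] > 1L && tip %in% sets[[t]] && sizes[t] < bestsz) {
        best <- t; bestsz <- sizes[t]
      }
    }
    pnode <- if (best == 0L) root else node_id[best]
    par <- c(par, pnode); chi <- c(chi, tip)
    len <- c(len, 0)
    evars[[length(evars) + 1L]] <- character(0)
  }
  nnode <- next_node - n
  tr <- structure(list(edge = cbind(par, chi), edge.length = len,
                       tip.label = samples, Nnode = nnode),
                  class = "phylo")
  idx <- ape::reorder.phylo(tr, "cladewise", index.only = TRUE)
  tr$edge <- tr$edge[idx, , drop = FALSE]
  tr$edge.length <- tr$edge.length[idx]
  evars <- evars[idx]
  attr(tr, "edge_variants") <- evars
  attr(tr, "n_imputed") <- n_imp
  tr
}

#' Read a haplogroup-defining-SNP hierarchy
#'
#' TSV with columns `child`, `parent`, `variants` (comma-separated defining
#' variant names); one row per non-root haplogroup.  The root is the parent
#' that never appears as a child.
#'
#' @param path TSV path.
#' @return object of class `haplogroup_defs`.
#' @export
read_haplogroup_defs <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  haplogroup_defs(d$child, d$parent, strsplit(d$variants, ","))
}

#' Construct a haplogroup hierarchy
#'
#' @param child,parent character vectors defining the edges.
#' @param variants list of character vectors: the defining variants of each
#'   child (>= 1 per child).
#' @return object of class `haplogroup_defs` with elements `child`,
#'   `parent`, `variants`, `root`.
#' @export
haplogroup_defs <- function(child, parent, variants) {
  if (any(lengths(variants) < 1)) stop("every haplogroup needs >= 1 defining variant")
  root <- setdiff(parent, child)
  if (length(root) != 1) stop("hierarchy must have a single root")
  structure(list(child = as.character(child), parent = as.character(parent),
                 variants = lapply(variants, as.character), root = root),
            class = "haplogroup_defs")
}

#' @export
print.haplogroup_defs <- function(x, ...) {
  cat(sprintf("haplogroup_defs: %d haplogroups below root %s\n",
              length(x$child), x$root))
  invisible(x)
}

#' The default E-M183 subclade hierarchy
#'
#' M183 at the top; SM001 below it; Z5009, CTS12227 and PF6794 as SM001
#' subclades; PF6789 below PF6794.
#'
#' @return a [haplogroup_defs()] object.
#' @export
em183_defs <- function() {
  read_haplogroup_defs(system.file("extdata", "em183_tree.tsv",
                                   package = "ylineage"))
}

# status of one haplogroup edge for a sample: 1 derived, 0 ancestral,
# NA all-missing; mixed derived+ancestral within an edge is an error.
edge_status <- function(calls, variants) {
  st <- calls[variants]
  if (all(is.na(st))) return(NA_integer_)
  st <- st[!is.na(st)]
  if (any(st == 1L) && any(st == 0L))
    stop(sprintf("conflicting calls among defining variants %s",
                 paste(variants, collapse = ",")))
  if (all(st == 1L)) 1L else 0L
}

#' Assign a sample to a haplogroup
#'
#' Descends the defining-SNP hierarchy from the root, following the (at
#' most one) child edge whose defining variants are derived.  The deepest
#' node with a fully derived path is returned; if that node has known
#' subclades for which the sample is ancestral or unresolved, the starred
#' paraclade label (`"SM001*"`) is returned.  An edge whose defining
#' variants are all missing blocks descent (conservative shallow
#' assignment).  A sample derived for a subclade but ancestral for an
#' ancestor's defining variant raises an inconsistency error.
#'
#' @param calls named vector of variant states (`0` ancestral, `1` derived,
#'   `NA` missing), named by variant id.
#' @param defs a [haplogroup_defs()].
#' @return haplogroup label; samples ancestral at the top-level marker get
#'   `"<root>*"`.
#' @export
assign_haplogroup <- function(calls, defs) {
  status <- setNames(vapply(seq_along(defs$child), function(i)
    edge_status(calls, defs$variants[[i]]), 0L), defs$child)
  node <- defs$root
  repeat {
    kids <- defs$child[defs$parent == node]
    if (!length(kids)) return(node)            # terminal clade
    der <- kids[!is.na(status[kids]) & status[kids] == 1L]
    if (length(der) > 1)
      stop(sprintf("sample derived for sibling clades %s",
                   paste(der, collapse = ", ")))
    if (!length(der)) {
      # no derived child: check nothing deeper claims descent
      below <- descendants_of(defs, kids)
      bad <- below[!is.na(status[below]) & status[below] == 1L]
      if (length(bad))
        stop(sprintf("inconsistent calls: derived at %s but not at its ancestor(s) under %s",
                     bad[1], node))
      return(paste0(node, "*"))
    }
    node <- der
  }
}

descendants_of <- function(defs, nodes) {
  out <- character(0)
  frontier <- nodes
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- defs$child[defs$parent %in% frontier]
  }
  out
}

# All labels assign_haplogroup can produce for a hierarchy, in preorder:
# starred paraclades for internal nodes, plain names for terminal clades.
haplogroup_labels <- function(defs) {
  rec <- function(node) {
    kids <- defs$child[defs$parent == node]
    if (!length(kids)) return(node)
    c(paste0(node, "*"), unlist(lapply(kids, rec)))
  }
  kids <- defs$child[defs$parent == defs$root]
  unlist(lapply(kids, rec))
}

#' Population-by-haplogroup frequency table
#'
#' Counts assignments per population and haplogroup column.  Columns are
#' the hierarchy's labels (starred paraclades and terminal clades) in
#' preorder, plus `Other` for samples whose assignment is outside the
#' hierarchy (ancestral at the top marker).  The final column gives the
#' percentage of chromosomes inside the top clade, to two decimals with
#' half-up rounding.
#'
#' @param assignments character vector of haplogroup labels (one per
#'   sample), as produced by [assign_haplogroup()].
#' @param populations character vector of population labels, same length.
#' @param defs a [haplogroup_defs()] (default [em183_defs()]); its top
#'   clade defines the percentage column.
#' @return data.frame of class `frequency_table`: one row per population,
#'   count columns, `N`, and `percent_top`.
#' @export
frequency_table <- function(assignments, populations, defs = em183_defs()) {
  stopifnot(length(assignments) == length(populations))
  labs <- haplogroup_labels(defs)
  a <- ifelse(assignments %in% labs, assignments, "Other")
  a <- factor(a, levels = c(labs, "Other"))
  tab <- table(populations, a)
  out <- as.data.frame.matrix(tab)
  out <- data.frame(population = rownames(tab), out, check.names = FALSE,
                    row.names = NULL)
  out$N <- as.integer(rowSums(tab))
  out$percent_top <- round_half_up(100 * (out$N - out$Other) / out$N, 2)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Subclade percentage over top-clade chromosomes
#'
#' For each population, the share of chromosomes inside the top clade that
#' fall in a given column — e.g. the fraction of E-M183 chromosomes that
#' are paragroup M183*.
#'
#' @param tab a [frequency_table()].
#' @param column a count column of `tab`.
#' @return data.frame with per-population percent (two decimals, half-up);
#'   populations with no top-clade chromosomes are flagged `NA` with a
#'   `note` rather than dividing by zero.
#' @export
percent_over_top_clade <- function(tab, column) {
  if (!column %in% names(tab)) stop("unknown column: ", column)
  denom <- tab$N - tab$Other
  pct <- ifelse(denom > 0, round_half_up(100 * tab[[column]] / denom, 2), NA)
  data.frame(population = tab$population, count = tab[[column]],
             n_top_clade = denom, percent = pct,
             note = ifelse(denom > 0, "", "no top-clade chromosomes"),
             row.names = NULL)
}
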