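# Collapse an STR table into distinct haplotypes with frequencies and
# (optionally) population composition; rows sorted canonically so results
# do not depend on input order.
collapse_haplotypes <- function(strs, loci = NULL) {
  m <- if (is.matrix(strs)) strs else str_matrix(strs, loci)
  if (anyNA(m)) stop("missing repeat counts")
  key <- apply(m, 1, paste, collapse = "|")
  o <- order(key)
  m <- m[o, , drop = FALSE]; key <- key[o]
  first <- !duplicated(key)
  hap <- m[first, , drop = FALSE]
  freq <- as.integer(table(key)[key[first]])
  pops <- NULL
  if (inherits(strs, "data.frame") && "population" %in% names(strs)) {
    pop <- strs$population[o]
    pops <- lapply(split(pop, key), function(p) table(p))
    pops <- pops[key[first]]
  }
  rownames(hap) <- NULL
  list(hap = hap, freq = freq, pops = pops, key = key[first])
}

# Weighted stepwise distance between haplotype-matrix rows.
weighted_step_dist <- function(hap, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, ncol(hap))
  n <- nrow(hap)
  d <- matrix(0, n, n)
  for (i in seq_len(max(n - 1, 0))) {
    diff <- abs(sweep(hap[(i + 1):n, , drop = FALSE], 2, hap[i, ]))
    v <- as.numeric(diff %*% weights)
    d[i, (i + 1):n] <- v
    d[(i + 1):n, i] <- v
  }
  d
}

# epsilon-relaxed minimum spanning network over a distance matrix:
# repeatedly find the minimal inter-cluster distance sigma, add every
# inter-cluster link with d <= sigma + epsilon, and merge the clusters so
# linked.  With epsilon = 0 this is the union of all minimum spanning trees.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  comp <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  while (length(unique(comp)) > 1) {
    inter <- outer(comp, comp, "!=") & upper.tri(d)
    sigma <- min(d[inter])
    sel <- which(inter & d <= sigma + epsilon, arr.ind = TRUE)
    from <- c(from, sel[, 1]); to <- c(to, sel[, 2]); w <- c(w, d[sel])
    # merge clusters connected by the new links
    for (k in seq_len(nrow(sel))) {
      a <- comp[sel[k, 1]]; b <- comp[sel[k, 2]]
      if (a != b) comp[comp == b] <- a
    }
  }
  data.frame(from = from, to = to, weight = w)
}

#' Minimum spanning network of STR haplotypes
#'
#' The epsilon-relaxed minimum spanning network: contains every edge that
#' occurs in some minimum spanning tree of the haplotype distance graph,
#' plus all links within `epsilon` of the minimal connection cost at each
#' agglomeration step.  No median (inferred) nodes are added.
#'
#' @param strs `str_haplotypes` table or numeric repeat matrix.
#' @param epsilon relaxation tolerance in distance units (default 0).
#' @param weights per-locus weights for the stepwise distance (default
#'   uniform).
#' @return object of class `haplo_network`.
#' @export
minimum_spanning_network <- function(strs, epsilon = 0, weights = NULL) {
  cc <- collapse_haplotypes(strs)
  d <- weighted_step_dist(cc$hap, weights)
  edges <- if (nrow(cc$hap) > 1) msn_edges(d, epsilon) else
    data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  haplo_network(cc$hap, cc$freq, rep("observed", nrow(cc$hap)), edges,
                epsilon, cc$pops)
}

haplo_network <- function(hap, freq, type, edges, epsilon, pops = NULL) {
  structure(list(haplotypes = hap, freq = freq, type = type,
                 edges = edges, epsilon = epsilon, pops = pops),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d observed + %d median nodes, %d edges (epsilon = %g)\n",
              sum(x$type == "observed"), sum(x$type == "median"),
              nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Median-joining network of STR haplotypes
#'
#' Bandelt's median-joining construction for multi-state (repeat count)
#' data: starting from the epsilon-relaxed minimum spanning network,
#' repeatedly generate candidate median vectors as the per-locus medians of
#' triplets mutually connected in the current network, add those whose
#' connection cost is within `epsilon` of the best candidate, and
#' recompute the network, until no new median arises.  Median nodes left
#' with degree <= 2 (no Steiner role) are pruned.  Duplicated observed
#' haplotypes are collapsed with their frequency; median nodes carry
#' frequency 0.
#'
#' @inheritParams minimum_spanning_network
#' @param max_iter iteration cap; exceeding it raises an error (network
#'   growth diagnostics attached).
#' @return object of class `haplo_network`.
#' @export
median_joining <- function(strs, epsilon = 0, weights = NULL, max_iter = 50) {
  cc <- collapse_haplotypes(strs)
  hap <- cc$hap
  type <- rep("observed", nrow(hap))
  freq <- cc$freq
  ww <- weights %||% rep(1, ncol(hap))
  it <- 0
  repeat {
    it <- it + 1
    if (it > max_iter)
      stop(sprintf("median-joining failed to converge in %d iterations (%d nodes)",
                   max_iter, nrow(hap)))
    d <- weighted_step_dist(hap, weights)
    net <- if (nrow(hap) > 1) msn_edges(d, epsilon) else
      data.frame(from = integer(0), to = integer(0), weight = numeric(0))
    adj <- matrix(FALSE, nrow(hap), nrow(hap))
    adj[cbind(net$from, net$to)] <- TRUE
    adj <- adj | t(adj)
    keys <- apply(hap, 1, paste, collapse = "|")
    cand <- list(); cost <- numeric(0)
    nn <- nrow(hap)
    if (nn >= 3) for (u in 1:(nn - 2)) for (v in (u + 1):(nn - 1)) for (w in (v + 1):nn) {
      nlinks <- adj[u, v] + adj[u, w] + adj[v, w]
      if (nlinks < 2) next
      med <- apply(hap[c(u, v, w), , drop = FALSE], 2, stats::median)
      k <- paste(med, collapse = "|")
      if (k %in% keys) next
      cst <- sum(ww * abs(hap[u, ] - med)) + sum(ww * abs(hap[v, ] - med)) +
        sum(ww * abs(hap[w, ] - med))
      j <- match(k, vapply(cand, function(x) paste(x, collapse = "|"), ""))
      if (is.na(j)) {
        cand[[length(cand) + 1]] <- med
        cost <- c(cost, cst)
      } else cost[j] <- min(cost[j], cst)
    }
    if (!length(cand)) break
    keep <- cost <= min(cost) + epsilon
    add <- do.call(rbind, cand[keep])
    hap <- rbind(hap, add)
    type <- c(type, rep("median", sum(keep)))
    freq <- c(freq, rep(0L, sum(keep)))
  }
  # prune median nodes that ended up with no Steiner role (degree <= 2)
  repeat {
    d <- weighted_step_dist(hap, weights)
    net <- if (nrow(hap) > 1) msn_edges(d, epsilon) else
      data.frame(from = integer(0), to = integer(0), weight = numeric(0))
    deg <- tabulate(c(net$from, net$to), nbins = nrow(hap))
    drop <- which(type == "median" & deg <= 2)
    if (!length(drop)) break
    hap <- hap[-drop, , drop = FALSE]
    type <- type[-drop]; freq <- freq[-drop]
  }
  pops <- if (is.null(cc$pops)) NULL else
    c(cc$pops, rep(list(NULL), sum(type == "median")))
  haplo_network(hap, freq, type, net, epsilon, pops)
}

#' Convert a haplotype network to igraph
#'
#' @param net a `haplo_network`.
#' @return an [igraph::graph] with node attributes `haplotype`, `freq`,
#'   `type` and edge attribute `weight`.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges,
    directed = FALSE,
    vertices = data.frame(
      name = seq_len(nrow(net$haplotypes)),
      haplotype = apply(net$haplotypes, 1, paste, collapse = "|"),
      freq = net$freq, type = net$type))
  g
}

#' Write a haplotype network as GraphML
#'
#' @param net a `haplo_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Star-likeness index of a haplotype network
#'
#' The fraction of observed haplotypes (other than the centre) lying at
#' mutational distance 1 from the centre, where the centre is the
#' highest-frequency node (ties broken lexicographically on the haplotype
#' vector).  A perfect star scores 1; deep, structured genealogies score
#' low.  Quantifies the "star-like" appearance associated with recent
#' rapid radiations.
#'
#' @param net a `haplo_network`.
#' @return value in `[0, 1]`.
#' @export
star_index <- function(net) {
  obs <- which(net$type == "observed")
  if (length(obs) < 2) return(1)
  keys <- apply(net$haplotypes, 1, paste, collapse = "|")
  cand <- obs[net$freq[obs] == max(net$freq[obs])]
  centre <- cand[order(keys[cand])][1]
  g <- as_igraph(net)
  dist <- igraph::distances(g, v = as.character(centre),
                            weights = igraph::E(g)$weight)
  others <- setdiff(obs, centre)
  mean(dist[1, as.character(others)] == 1)
}
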