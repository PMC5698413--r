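#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML file (or accepts a list), injects defaults (min_reads 5,
#' max_missing 0.05, min_mean_depth 10, epsilon 0, str_rate 1/858, fast and
#' slow SNP rates 1e-9 and 6.17e-10, callable length 4.88 Mb), and rejects
#' unknown or out-of-range keys with the offending field named.
#'
#' @param config path to a YAML file, or a named list.
#' @return normalised configuration list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  known <- c("seed", "out_dir", "stages", "populations", "vcf", "mask",
             "strs", "tree_defs", "min_reads", "max_missing",
             "min_mean_depth", "snp_rate", "snp_rate_slow", "str_rate",
             "callable_length", "epsilon", "n_perm", "groups",
             "ci_multiplier")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  defaults <- list(min_reads = 5, max_missing = 0.05, min_mean_depth = 10,
                   epsilon = 0, n_perm = 1000, snp_rate = 1e-9,
                   snp_rate_slow = 6.17e-10, str_rate = 1 / 858,
                   callable_length = 4.88e6, ci_multiplier = 1.96,
                   stages = c("simulate", "filter", "phylo", "date",
                              "diversity", "amova", "network"))
  config <- modifyList(defaults, config)
  if (config$max_missing < 0 || config$max_missing > 1)
    stop("config field max_missing must lie in [0, 1]")
  if (config$min_reads < 0) stop("config field min_reads must be >= 0")
  if (!length(config$stages)) stop("config field stages is empty")
  ok_stages <- c("simulate", "filter", "phylo", "date", "diversity",
                 "amova", "network", "assign", "assoc")
  bad <- setdiff(config$stages, ok_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("simulate" %in% config$stages && is.null(config$populations))
    stop("missing input: populations are required for the simulate stage")
  if (!"simulate" %in% config$stages && is.null(config$vcf) &&
      is.null(config$strs))
    stop("without a simulate stage, an input vcf and/or strs path is required")
  if (is.null(config$seed) && "simulate" %in% config$stages)
    stop("config field seed is required for stochastic stages")
  class(config) <- c("run_config", "list")
  config
}

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> filter -> tree building -> rho dating ->
#' diversity -> AMOVA -> network on a single configuration.  Every
#' stochastic stage receives a sub-seed derived from the master seed, so a
#' rerun with the same configuration is bit-reproducible.  Intermediate
#' artifacts and a machine-readable JSON report are written to
#' `config$out_dir` (when set); the report is also returned.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @return report list (stage counts, estimates, seed, package version).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("ylineage")),
                 stages = config$stages)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  rates <- mutation_rate_spec(snp_rate = config$snp_rate,
                              callable_length = config$callable_length,
                              str_rate = config$str_rate)
  panel <- NULL; vm <- NULL; strs <- NULL
  out <- config$out_dir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if ("simulate" %in% config$stages) {
    # YAML 1.1 parses a bare key `n` as a boolean, so configs use
    # `n_samples`; plain R lists may use either
    pops <- do.call(rbind, lapply(config$populations, function(p)
      data.frame(name = p$name, n = as.integer(p$n_samples %||% p$n),
                 longitude = as.numeric(p$longitude),
                 tmrca = as.numeric(p$tmrca %||% 2000),
                 topology = p$topology %||% "star",
                 growth_rate = as.numeric(p$growth_rate %||% NA))))
    panel <- generate_population_panel(pops, rates, seed = config$seed)
    say("simulate: %d populations, %d samples, %d SNP sites",
        nrow(pops), n_samples(panel$variants), n_sites(panel$variants))
    report$simulate <- list(n_samples = n_samples(panel$variants),
                            n_sites = n_sites(panel$variants),
                            truth = panel$truth)
    vm <- panel$variants
    strs <- panel$strs
    if (!is.null(out)) write_panel(panel, file.path(out, "panel"))
  } else {
    if (!is.null(config$vcf)) vm <- read_vcf_matrix(config$vcf)
    if (!is.null(config$strs)) strs <- read_str_table(config$strs)
  }

  if ("filter" %in% config$stages && !is.null(vm)) {
    tmp <- tempfile(fileext = ".vcf")
    write_vcf_matrix(vm, tmp)
    fc <- run_filter_cascade(tmp, config$mask,
                             min_reads = config$min_reads,
                             max_missing = config$max_missing,
                             min_mean_depth = config$min_mean_depth)
    unlink(tmp)
    vm <- fc$vm
    report$filter <- list(cascade = fc$report,
                          n_failed_samples = sum(!fc$qc$pass))
    say("filter: %d sites, %d samples after cascade", n_sites(vm),
        n_samples(vm))
  }

  tree <- NULL
  if ("phylo" %in% config$stages && !is.null(vm) && n_sites(vm) > 0) {
    tree <- build_perfect_phylogeny(vm)
    report$phylo <- list(n_tips = length(tree$tip.label),
                         n_mutations = sum(tree$edge.length))
    say("phylo: perfect phylogeny with %d tips, %d mutations",
        length(tree$tip.label), sum(tree$edge.length))
    if (!is.null(out))
      ape::write.tree(tree, file.path(out, "snp_tree.nwk"))
  }

  if ("date" %in% config$stages) {
    dates <- list()
    if (!is.null(tree)) {
      est <- tmrca_from_rho(rho_snp(tree), rates, mode = "snp",
                            ci_multiplier = config$ci_multiplier)
      dates$snp <- est[c("rho", "sigma", "tmrca", "ci_low", "ci_high",
                         "n_tips")]
      say("date/snp: rho %.3f, TMRCA %.0f [%.0f, %.0f] y", est$rho,
          est$tmrca, est$ci_low, est$ci_high)
    }
    if (!is.null(strs)) {
      est <- tmrca_from_rho(rho_str(strs), rates, mode = "str",
                            ci_multiplier = config$ci_multiplier)
      dates$str <- est[c("rho", "sigma", "tmrca", "ci_low", "ci_high",
                         "n_tips")]
      say("date/str: rho %.3f, TMRCA %.0f [%.0f, %.0f] y", est$rho,
          est$tmrca, est$ci_low, est$ci_high)
    }
    report$date <- dates
  }

  if ("diversity" %in% config$stages && !is.null(strs)) {
    div <- diversity_by(strs)
    report$diversity <- div
    if (sum(is.finite(div$longitude) & is.finite(div$mean_heterozygosity)) >= 4) {
      sp <- spearman_longitude(div, "mean_heterozygosity")
      report$diversity_longitude <- sp
      say("diversity: heterozygosity-longitude rho %.3f (P = %.3g)",
          sp$rho, sp$p_value)
    }
    if (!is.null(out))
      write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE)
  }

  if ("amova" %in% config$stages && !is.null(strs) &&
      length(unique(strs$population)) >= 2) {
    groups <- if (!is.null(config$groups)) unlist(config$groups) else NULL
    am <- amova(strs, groups = groups, n_perm = config$n_perm,
                seed = derive_seed(config$seed %||% 1, 99))
    report$amova <- list(components = am$components, phi = am$phi,
                         p_values = am$p_values)
    say("amova: Phi_ST %.4f (among-population %.1f%%)", am$phi$PHI_ST,
        am$components$percent[am$components$source == "among_populations" |
                              am$components$source == "among_groups"][1])
  }

  if ("network" %in% config$stages && !is.null(strs)) {
    net <- median_joining(strs, epsilon = config$epsilon)
    report$network <- list(n_observed = sum(net$type == "observed"),
                           n_median = sum(net$type == "median"),
                           n_edges = nrow(net$edges),
                           star_index = star_index(net))
    say("network: %d observed + %d median nodes, star index %.3f",
        report$network$n_observed, report$network$n_median,
        report$network$star_index)
    if (!is.null(out)) write_graphml(net, file.path(out, "network.graphml"))
  }

  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
    writeLines(log_lines, file.path(out, "run.log"))
  }
  report
}
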