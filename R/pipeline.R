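#' Configuration for a reproducible pipeline run
#'
#' Collects every tunable of the workflow in one object. All defaults are
#' recorded in the run log, and every output file name carries a short hash
#' of the configuration so runs with different settings never overwrite
#' each other.
#'
#' @param input Path to the delimited input table (see
#'   [read_grouped_table()]); may be `NULL` for [run_simulate()].
#' @param group_column Name of the group-label column.
#' @param output_dir Directory for outputs (created if missing).
#' @param alpha Significance level (default 0.05).
#' @param n_perm Label permutations for the differential test (default
#'   100,000).
#' @param seed Integer seed for all randomized steps.
#' @param delimiter Input field delimiter.
#' @param log_transform Log-transform the concentration columns before
#'   analysis (default FALSE; requires strictly positive values).
#' @param slope_scale Scale for the degree-distribution slope fit.
#' @param normalized_betweenness Normalize betweenness values.
#' @param min_magnitude Sign-change gate for [classify_change()].
#' @param bonferroni_differential Apply alpha / K to the differential test
#'   instead of the uncorrected alpha (default FALSE).
#' @return Object of class `run_config` with a `hash` field.
#' @export
run_config <- function(input = NULL, group_column = "group",
                       output_dir = ".", alpha = 0.05, n_perm = 1e5,
                       seed = 1L, delimiter = "\t", log_transform = FALSE,
                       slope_scale = "log-log",
                       normalized_betweenness = FALSE,
                       min_magnitude = 0.05,
                       bonferroni_differential = FALSE) {
  cfg <- list(
    input = input, group_column = group_column, output_dir = output_dir,
    alpha = alpha, n_perm = as.integer(n_perm), seed = as.integer(seed),
    delimiter = delimiter, log_transform = isTRUE(log_transform),
    slope_scale = slope_scale,
    normalized_betweenness = isTRUE(normalized_betweenness),
    min_magnitude = min_magnitude,
    bonferroni_differential = isTRUE(bonferroni_differential)
  )
  cfg$hash <- substr(rlang::hash(cfg[setdiff(names(cfg), "output_dir")]),
                     1, 8)
  structure(cfg, class = "run_config")
}

load_config_input <- function(config) {
  if (is.null(config$input)) {
    stop("`config$input` is required for this subcommand", call. = FALSE)
  }
  ds <- read_grouped_table(config$input, config$group_column,
                           config$delimiter)
  if (config$log_transform) {
    if (any(ds$values <= 0)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    ds$values <- log(ds$values)
  }
  ds
}

out_path <- function(config, name) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$output_dir, paste0(name, "_", config$hash))
}

write_run_log <- function(config, stage, extra, path) {
  log <- c(
    list(stage = stage,
         timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
         config = unclass(config)),
    extra
  )
  yaml::write_yaml(log, path, precision = 12)
  invisible(path)
}

#' Run the per-variable concentration screen
#'
#' Writes the Mann-Whitney result table (TSV) and a YAML run log with the
#' counts of significant variables at both thresholds.
#'
#' @param config A [run_config()].
#' @return Named character vector of output paths, invisibly; the result
#'   table as attribute `"result"`.
#' @export
run_screen <- function(config) {
  ds <- load_config_input(config)
  res <- mann_whitney_screen(ds, alpha = config$alpha)
  tsv <- paste0(out_path(config, "screen"), ".tsv")
  utils::write.table(res, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- paste0(out_path(config, "screen"), "_log.yaml")
  write_run_log(config, "screen", list(
    n_variables = nrow(res),
    bonferroni_threshold = attr(res, "bonferroni_threshold"),
    n_significant_bonferroni = sum(res$significant_bonferroni),
    n_significant_uncorrected = sum(res$significant_uncorrected)
  ), log)
  out <- c(table = tsv, log = log)
  attr(out, "result") <- res
  invisible(out)
}

#' Build and export the per-condition association networks
#'
#' Fits the shrinkage partial correlations for each group, tests every pair
#' against zero, thresholds at the Bonferroni-corrected alpha / K, and
#' writes GraphML, edge tables, per-node topology tables and a run log
#' (shrinkage intensity and null degree of freedom per group, threshold,
#' edge counts).
#'
#' @param config A [run_config()].
#' @return Named character vector of output paths, invisibly; the two
#'   `assoc_network` objects as attribute `"result"`.
#' @export
run_network <- function(config) {
  ds <- load_config_input(config)
  m <- length(ds$variable_names)
  k_pairs <- m * (m - 1) / 2
  threshold <- bonferroni_threshold(config$alpha, k_pairs)
  groups <- levels(ds$group_labels)
  paths <- character(0)
  nets <- list()
  log_extra <- list(threshold = threshold, K = k_pairs)
  for (g in groups) {
    fit <- fit_group(ds, g)
    pv <- edge_pvalues(fit)
    net <- build_network(pv, threshold)
    nets[[g]] <- net
    base <- out_path(config, paste0("network_", g))
    write_network(net, paste0(base, ".graphml"), "graphml")
    write_network(net, paste0(base, ".tsv"), "edge-table")
    topo <- global_summary(net, slope_scale = config$slope_scale,
                           normalized_betweenness =
                             config$normalized_betweenness)
    utils::write.table(topo$node_metrics, paste0(base, "_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, stats::setNames(
      c(paste0(base, ".graphml"), paste0(base, ".tsv"),
        paste0(base, "_nodes.tsv")),
      paste0(c("graphml_", "edges_", "nodes_"), g)))
    log_extra[[paste0("group_", g)]] <- list(
      n = fit$n, lambda = fit$lambda, kappa = attr(pv, "kappa"),
      n_edges = nrow(net$edges), connected = topo$n_connected,
      isolated = topo$n_isolated)
  }
  log <- paste0(out_path(config, "network"), "_log.yaml")
  write_run_log(config, "network", log_extra, log)
  out <- c(paths, log = log)
  attr(out, "result") <- nets
  invisible(out)
}

#' Run the differential-network analysis
#'
#' @param config A [run_config()].
#' @return Named character vector of output paths, invisibly; the
#'   `diff_edge_set` as attribute `"result"`.
#' @export
run_diffnet <- function(config) {
  ds <- load_config_input(config)
  dn <- build_differential_network(
    ds, n_perm = config$n_perm, alpha = config$alpha, seed = config$seed,
    min_magnitude = config$min_magnitude,
    bonferroni = config$bonferroni_differential
  )
  base <- out_path(config, "diffnet")
  full <- dn$pairs
  utils::write.table(full, paste0(base, "_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(dn, paste0(base, ".graphml"), "graphml")
  write_network(dn, paste0(base, ".tsv"), "edge-table")
  sig <- differential_edges(dn)
  connected <- unique(c(sig$variable_i, sig$variable_j))
  log <- paste0(base, "_log.yaml")
  write_run_log(config, "diffnet", list(
    n_permutations = dn$n_permutations,
    rng = "Mersenne-Twister",
    seed = dn$seed,
    cutoff = dn$alpha,
    lambda = as.list(dn$lambda),
    n_differential_edges = nrow(sig),
    n_connected_variables = length(connected),
    n_unconnected_variables = length(dn$nodes) - length(connected),
    categories = as.list(table(sig$category))
  ), log)
  out <- c(pairs = paste0(base, "_pairs.tsv"),
           graphml = paste0(base, ".graphml"),
           edges = paste0(base, ".tsv"), log = log)
  attr(out, "result") <- dn
  invisible(out)
}

#' Topological summary of a stored network
#'
#' Reads a GraphML network (e.g. written by [run_network()] or
#' [run_diffnet()]), prints the global-property block and writes the
#' per-node metric table plus a run log.
#'
#' @param config A [run_config()]; `config$input` must point to a GraphML
#'   file here.
#' @return Named character vector of output paths, invisibly; the
#'   `topology_summary` as attribute `"result"`.
#' @export
run_topology <- function(config) {
  g <- read_network(config$input, "graphml")
  topo <- global_summary(g, slope_scale = config$slope_scale,
                         normalized_betweenness =
                           config$normalized_betweenness)
  print(topo)
  base <- out_path(config, "topology")
  utils::write.table(topo$node_metrics, paste0(base, "_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- paste0(base, "_log.yaml")
  write_run_log(config, "topology", list(
    n_nodes = topo$n_nodes, connected = topo$n_connected,
    isolated = topo$n_isolated, edges = topo$n_edges,
    density = topo$density, average_degree = topo$average_degree,
    slope = topo$slope, slope_scale = topo$slope_scale,
    clustering = topo$mean_clustering
  ), log)
  out <- c(nodes = paste0(base, "_nodes.tsv"), log = log)
  attr(out, "result") <- topo
  invisible(out)
}

#' Simulate a two-group dataset and write it as an input table
#'
#' @param config A [run_config()]; `config$seed` seeds the draw.
#' @param spec A [simulation_spec()]; defaults to the lipoprotein-panel
#'   template.
#' @return Named character vector of output paths, invisibly; the
#'   `grouped_dataset` as attribute `"result"`.
#' @export
run_simulate <- function(config, spec = simulation_spec(seed = config$seed)) {
  ds <- sample_dataset(spec, seed = config$seed)
  base <- out_path(config, "simulated")
  tab <- data.frame(group = as.character(ds$group_labels),
                    ds$values, check.names = FALSE)
  tsv <- paste0(base, ".tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- paste0(base, "_log.yaml")
  write_run_log(config, "simulate", list(
    M = spec$M, n_A = spec$n_A, n_B = spec$n_B,
    blocks = length(spec$block_sizes),
    differential_pairs = NROW(spec$differential_edges),
    sim_seed = spec$seed
  ), log)
  out <- c(table = tsv, log = log)
  attr(out, "result") <- ds
  invisible(out)
}
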