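#' Convert a network object to an igraph graph
#'
#' Association networks and differential edge sets are converted to
#' undirected igraph graphs over their full node set (isolated nodes
#' included); for a differential edge set only the significant pairs become
#' edges and the change category travels along as an edge attribute.
#'
#' @param x An `assoc_network`, `diff_edge_set`, or igraph object.
#' @return An undirected igraph graph with vertex attribute `name`.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "igraph")) {
    return(x)
  }
  if (inherits(x, "assoc_network")) {
    edges <- x$edges[c("variable_i", "variable_j", "pcor", "p_value")]
    return(igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = x$nodes)))
  }
  if (inherits(x, "diff_edge_set")) {
    sig <- differential_edges(x)
    edges <- sig[c("variable_i", "variable_j", "r_A", "r_B", "d_obs",
                   "p_perm", "category")]
    return(igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = x$nodes)))
  }
  stop("cannot convert object of class ", paste(class(x), collapse = "/"),
       " to an igraph graph", call. = FALSE)
}

#' Node degrees
#'
#' @param network An `assoc_network`, `diff_edge_set`, or igraph object.
#' @return Named integer vector of degrees, zeros included for isolated
#'   nodes.
#' @export
node_degrees <- function(network) {
  g <- as_igraph(network)
  d <- igraph::degree(g, mode = "all", loops = FALSE)
  stats::setNames(as.integer(d), igraph::V(g)$name)
}

#' Degree distribution P(k)
#'
#' P(k) is the fraction of nodes with degree k, over observed k >= 1; nodes
#' of degree zero contribute to the denominator N (the total node count)
#' but are not listed as a support point.
#'
#' @param degrees Integer vector of node degrees (from [node_degrees()]),
#'   or a network object.
#' @return Data frame with columns `k` and `p`, and attribute `n_nodes`.
#' @export
degree_distribution <- function(degrees) {
  if (!is.numeric(degrees)) degrees <- node_degrees(degrees)
  n <- length(degrees)
  pos <- degrees[degrees >= 1]
  tab <- table(pos)
  out <- data.frame(k = as.integer(names(tab)), p = as.numeric(tab) / n)
  attr(out, "n_nodes") <- n
  out
}

#' Least-squares slope of the degree distribution
#'
#' Fits a straight line to P(k) against k on the chosen scale and returns
#' its slope. The default `"log-log"` scale reads the distribution as a
#' power law P(k) ~ k^gamma (slope = gamma); `"semilog"` regresses log P(k)
#' on k, `"linear"` P(k) on k. Only support points with P(k) > 0 enter the
#' fit.
#'
#' @param distribution Data frame from [degree_distribution()] (columns `k`,
#'   `p`), or a network object.
#' @param scale One of `"log-log"`, `"semilog"`, `"linear"`.
#' @return The fitted slope, with the scale attached as attribute `"scale"`.
#' @export
degree_slope <- function(distribution, scale = c("log-log", "semilog",
                                                 "linear")) {
  scale <- match.arg(scale)
  if (!is.data.frame(distribution)) {
    distribution <- degree_distribution(distribution)
  }
  d <- distribution[distribution$p > 0, , drop = FALSE]
  if (nrow(d) < 2L) {
    stop("need at least 2 degree values with positive probability to fit ",
         "a slope", call. = FALSE)
  }
  xy <- switch(scale,
    "log-log" = cbind(log(d$k), log(d$p)),
    "semilog" = cbind(d$k, log(d$p)),
    "linear"  = cbind(d$k, d$p)
  )
  slope <- stats::coef(stats::lm.fit(cbind(1, xy[, 1]), xy[, 2]))[2L]
  structure(unname(slope), scale = scale)
}

#' Betweenness centrality
#'
#' For each node v, the sum over pairs of other nodes (s, t) of the fraction
#' of shortest s-t paths passing through v (Freeman betweenness, undirected
#' convention counting each unordered pair once). Pairs in different
#' components contribute nothing. With `normalized = TRUE` values are
#' divided by (N-1)(N-2)/2; node ranking is unaffected.
#'
#' @inheritParams node_degrees
#' @param normalized Divide by the number of possible pairs (default FALSE,
#'   raw path counts).
#' @return Named numeric vector of betweenness values.
#' @export
node_betweenness <- function(network, normalized = FALSE) {
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

#' Local clustering coefficients
#'
#' c_i = K_i / (k_i (k_i - 1) / 2) where K_i counts the edges among the
#' neighbors of node i; for degree k_i < 2 the coefficient is defined to be
#' zero. The network-level clustering coefficient is the mean of c_i over
#' all nodes (isolated nodes included).
#'
#' @inheritParams node_degrees
#' @return Named numeric vector of per-node clustering coefficients.
#' @export
node_clustering <- function(network) {
  g <- as_igraph(network)
  ci <- igraph::transitivity(g, type = "local", isolates = "zero")
  deg <- igraph::degree(g)
  ci[deg < 2] <- 0
  stats::setNames(as.numeric(ci), igraph::V(g)$name)
}

#' Network-level topological summary
#'
#' Collects the per-node metrics and the global properties used to
#' characterize individual and differential networks: connected and
#' isolated node counts, edge count, density 2E / (N(N-1)), average degree
#' 2E / N (all N nodes, isolated included), degree distribution and its
#' fitted slope, and the mean clustering coefficient. Nodes are also ranked
#' by degree (ties broken by betweenness) to surface hubs.
#'
#' @inheritParams node_degrees
#' @param slope_scale Scale passed to [degree_slope()].
#' @param normalized_betweenness Passed to [node_betweenness()].
#' @return Object of class `topology_summary`: list with `node_metrics`
#'   (data frame `node`, `degree`, `betweenness`, `clustering`, sorted as
#'   the hub ranking), `n_nodes`, `n_connected`, `n_isolated`, `n_edges`,
#'   `density`, `average_degree`, `degree_distribution`, `slope`,
#'   `slope_scale`, `mean_clustering`.
#' @export
global_summary <- function(network, slope_scale = "log-log",
                           normalized_betweenness = FALSE) {
  g <- as_igraph(network)
  deg <- node_degrees(g)
  btw <- node_betweenness(g, normalized = normalized_betweenness)
  clu <- node_clustering(g)
  n <- length(deg)
  e <- igraph::ecount(g)
  dist <- degree_distribution(deg)
  slope <- tryCatch(degree_slope(dist, scale = slope_scale),
                    error = function(err) NA_real_)
  ord <- order(-deg, -btw, names(deg))
  node_metrics <- data.frame(
    node = names(deg), degree = unname(deg), betweenness = unname(btw),
    clustering = unname(clu), stringsAsFactors = FALSE
  )[ord, ]
  rownames(node_metrics) <- NULL
  structure(
    list(
      node_metrics = node_metrics,
      n_nodes = n,
      n_connected = sum(deg > 0),
      n_isolated = sum(deg == 0),
      n_edges = e,
      density = if (n > 1) 2 * e / (n * (n - 1)) else NA_real_,
      average_degree = 2 * e / n,
      degree_distribution = dist,
      slope = as.numeric(slope),
      slope_scale = attr(slope, "scale") %||% slope_scale,
      mean_clustering = mean(clu)
    ),
    class = "topology_summary"
  )
}

#' @export
print.topology_summary <- function(x, digits = 3, ...) {
  cat("Global network properties\n")
  cat("  Connected nodes           ", x$n_connected, "\n")
  cat("  Isolated nodes            ", x$n_isolated, "\n")
  cat("  Total number of edges     ", x$n_edges, "\n")
  cat("  Network density           ", format(round(x$density, digits)), "\n")
  cat("  Average degree            ", format(round(x$average_degree, digits)),
      "\n")
  cat("  Slope of degree distr.    ",
      if (is.na(x$slope)) "NA" else format(round(x$slope, digits)),
      paste0("(", x$slope_scale, ")"), "\n")
  cat("  Clustering coefficient    ",
      format(round(x$mean_clustering, digits)), "\n")
  hubs <- utils::head(x$node_metrics, 3)
  cat("  Top hubs: ", paste0(hubs$node, " (k=", hubs$degree, ")",
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
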