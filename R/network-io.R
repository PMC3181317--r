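#' Write a network to GraphML or a TSV edge table
#'
#' GraphML output carries the full node set (isolated nodes included) with
#' the per-edge annotations (partial correlation and p-value for
#' association networks; group-wise correlations, observed difference,
#' permutation p-value and change category for differential networks) and
#' round-trips through [read_network()]. The edge-table format is a plain
#' TSV of the edge rows.
#'
#' @param network An `assoc_network`, `diff_edge_set`, or igraph object.
#' @param path Output file path.
#' @param format `"graphml"` or `"edge-table"`.
#' @return The path, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edge-table")) {
  if (length(format) == 1L && !format %in% c("graphml", "edge-table")) {
    stop("unknown format '", format, "'; use \"graphml\" or \"edge-table\"",
         call. = FALSE)
  }
  format <- match.arg(format)
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0L) {
    stop("network has an empty node set", call. = FALSE)
  }
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    tab <- network_edge_table(network)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path File path.
#' @param format `"graphml"` (returns an igraph object) or `"edge-table"`
#'   (returns the edge data frame).
#' @export
read_network <- function(path, format = c("graphml", "edge-table")) {
  if (length(format) == 1L && !format %in% c("graphml", "edge-table")) {
    stop("unknown format '", format, "'; use \"graphml\" or \"edge-table\"",
         call. = FALSE)
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "graphml") {
    # the writer stores vertex names under both 'name' and GraphML's own
    # 'id'; keep 'name' and silence the duplicate-id notice
    g <- withCallingHandlers(
      igraph::read_graph(path, format = "graphml"),
      warning = function(w) {
        if (grepl("'id' vertex attribute", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    if ("id" %in% igraph::vertex_attr_names(g)) {
      g <- igraph::delete_vertex_attr(g, "id")
    }
    g
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
}

# Canonical edge rows for serialization.
network_edge_table <- function(network) {
  if (inherits(network, "assoc_network")) {
    data.frame(
      variable_i = network$edges$variable_i,
      variable_j = network$edges$variable_j,
      statistic = network$edges$pcor,
      p_value = network$edges$p_value,
      annotation = rep("", nrow(network$edges)),
      stringsAsFactors = FALSE
    )
  } else if (inherits(network, "diff_edge_set")) {
    sig <- differential_edges(network)
    data.frame(
      variable_i = sig$variable_i,
      variable_j = sig$variable_j,
      r_A = sig$r_A,
      r_B = sig$r_B,
      d_obs = sig$d_obs,
      p_perm = sig$p_perm,
      annotation = sig$category,
      stringsAsFactors = FALSE
    )
  } else {
    g <- as_igraph(network)
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("variable_i", "variable_j")
    el
  }
}
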