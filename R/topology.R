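# Node centrality summaries: degree, betweenness, coreness, closeness.

as_igraph <- function(network) {
  if (inherits(network, "stage_network") || inherits(network, "merged_network")) {
    network$graph
  } else if (igraph::is_igraph(network)) {
    network
  } else {
    stopf("expected a stage_network, merged_network or igraph object")
  }
}

#' Node centralities of a gene network
#'
#' Computes, per node, degree, shortest-path betweenness (unnormalised),
#' coreness (k-core index) and closeness. All metrics are unweighted (every
#' edge counts equally). Closeness is computed within each connected
#' component as the inverse mean shortest-path distance,
#' `(m - 1) / sum(d)` for a component of size m, which lies in (0, 1];
#' isolated nodes get closeness 0. `closeness = "harmonic"` instead uses
#' `sum(1/d) / (n - 1)` over all other nodes, which handles disconnected
#' graphs without the per-component restriction.
#'
#' @param network a `stage_network`, `merged_network` or igraph object.
#' @param closeness `"component"` (default) or `"harmonic"`.
#' @return a data.frame with columns `node`, `degree`, `betweenness`,
#'   `coreness`, `closeness`; empty graph gives an empty table.
#' @export
compute_centralities <- function(network, closeness = c("component", "harmonic")) {
  closeness <- match.arg(closeness)
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(data.frame(node = character(0), degree = integer(0),
                      betweenness = numeric(0), coreness = integer(0),
                      closeness = numeric(0), stringsAsFactors = FALSE))
  }
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  deg <- igraph::degree(g, loops = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  core <- igraph::coreness(g)
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (closeness == "harmonic") {
      if (length(di) == 0L) return(0)
      sum(1 / di[reach]) / length(di)
    } else {
      if (!any(reach)) return(0)
      sum(reach) / sum(di[reach])
    }
  }, numeric(1))
  data.frame(node = nodes, degree = as.integer(deg), betweenness = unname(btw),
             coreness = as.integer(core), closeness = clo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a graph to GraphML
#'
#' @param graph an igraph object (or `stage_network` / `merged_network`).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file
#'
#' @param path GraphML file.
#' @return an igraph object.
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
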