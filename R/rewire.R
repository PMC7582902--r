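# Multi-state node rewiring over the union ("central reference") network.

#' Per-node rewiring score across condition networks
#'
#' For each node of the union graph, builds one weight vector per state over
#' the node's union neighbourhood (entry = edge weight to that neighbour in
#' that state, 0 if the edge or the node is absent), normalises every
#' nonzero vector to unit Euclidean length (making the score invariant to
#' global weight rescaling), and scores
#' `Dn(v) = mean over states of || vector_state - centroid ||`.
#' Dn is 0 exactly when the node's weighted neighbourhood is identical in
#' all states, and grows as neighbourhoods diverge (two disjoint unit
#' neighbourhoods across two states give Dn = sqrt(2)/2).
#'
#' With `normalize = TRUE` every node's score is bounded by the orthogonal
#' two-state maximum sqrt(2)/2, so a degree-1 node whose single edge flips
#' between states saturates the scale; `normalize = FALSE` keeps raw weight
#' vectors, letting large rewired neighbourhoods accumulate a larger score
#' (the behaviour that makes a rewired hub stand out against sporadic
#' single-edge turnover).
#'
#' @param networks list of two or more `stage_network` objects (or igraphs
#'   with a `weight` edge attribute); names are used as state labels.
#' @param weighted if `FALSE`, edge weights are replaced by presence (0/1).
#' @param normalize if `TRUE` (default), nonzero neighbourhood vectors are
#'   scaled to unit Euclidean length before scoring.
#' @return a `rewiring_table` data.frame: `node`, `Dn`, `rank` (1 = most
#'   rewired, ties share the smaller rank), and one logical
#'   `present_<state>` column per state.
#' @export
compute_rewiring <- function(networks, weighted = TRUE, normalize = TRUE) {
  if (!is.list(networks) || length(networks) < 2L) {
    stopf("need at least 2 networks to score rewiring")
  }
  graphs <- lapply(networks, as_igraph)
  labels <- names(networks) %||% paste0("state", seq_along(networks))
  labels[!nzchar(labels)] <- paste0("state", which(!nzchar(labels)))
  # per-state adjacency lookup: node -> named weight vector of neighbours
  adj <- lapply(graphs, function(g) {
    ed <- igraph::as_data_frame(g, what = "edges")
    if (nrow(ed) == 0L) return(list())
    w <- if (weighted && !is.null(ed$weight)) ed$weight else rep(1, nrow(ed))
    ends <- c(ed$from, ed$to)
    nbrs <- c(ed$to, ed$from)
    split(stats::setNames(c(w, w), nbrs), ends)
  })
  all_nodes <- sort(Reduce(union, lapply(graphs, function(g) igraph::V(g)$name)))
  dn <- vapply(all_nodes, function(v) {
    nb <- sort(unique(unlist(lapply(adj, function(a) names(a[[v]])), use.names = FALSE)))
    if (length(nb) == 0L) return(0)
    vecs <- vapply(adj, function(a) {
      w <- a[[v]]
      out <- stats::setNames(numeric(length(nb)), nb)
      if (!is.null(w)) out[names(w)] <- w
      if (normalize) {
        nrm <- sqrt(sum(out^2))
        if (nrm > 0) out <- out / nrm
      }
      out
    }, numeric(length(nb)))
    vecs <- matrix(vecs, nrow = length(nb))  # neighbours x states
    centroid <- rowMeans(vecs)
    mean(sqrt(colSums((vecs - centroid)^2)))
  }, numeric(1))
  # rank on rounded scores: nodes at the same geometric configuration
  # (e.g. the orthogonal-neighbourhood maximum) must tie despite
  # floating-point noise from different vector lengths
  out <- data.frame(node = all_nodes, Dn = unname(dn),
                    rank = rank(-round(dn, 9), ties.method = "min"),
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_along(graphs)) {
    out[[paste0("present_", labels[i])]] <- all_nodes %in% igraph::V(graphs[[i]])$name
  }
  class(out) <- c("rewiring_table", "data.frame")
  out
}

#' Central reference network annotated with rewiring scores
#'
#' Union of the state networks with per-node attributes `Dn`, `rank` and a
#' four-level `rewiring_class`: `"none"` for Dn = 0, and among Dn > 0 nodes
#' `"least"` (below the lower quartile), `"high"` (interquartile) and
#' `"most"` (upper quartile and above). Edges carry a `states` attribute
#' listing the states they appear in.
#'
#' @param networks the same list passed to [compute_rewiring()].
#' @param table the corresponding `rewiring_table`.
#' @return igraph union graph with the attributes above.
#' @export
build_reference_network <- function(networks, table) {
  stopifnot(inherits(table, "rewiring_table"))
  graphs <- lapply(networks, as_igraph)
  labels <- names(networks) %||% paste0("state", seq_along(networks))
  labels[!nzchar(labels)] <- paste0("state", which(!nzchar(labels)))
  ed_all <- list()
  for (i in seq_along(graphs)) {
    ed <- igraph::as_data_frame(graphs[[i]], what = "edges")
    if (nrow(ed) == 0L) next
    ce <- canonical_edges(ed$from, ed$to)
    ed_all[[labels[i]]] <- data.frame(from = ce$from, to = ce$to,
                                      state = labels[i],
                                      weight = ed$weight %||% rep(1, nrow(ed)),
                                      stringsAsFactors = FALSE)
  }
  ed_all <- do.call(rbind, ed_all)
  dn <- stats::setNames(table$Dn, table$node)
  rk <- stats::setNames(table$rank, table$node)
  pos <- table$Dn[table$Dn > 0]
  cls <- rep("none", nrow(table))
  if (length(pos)) {
    q <- stats::quantile(pos, c(0.25, 0.75), names = FALSE)
    cls[table$Dn > 0] <- ifelse(table$Dn[table$Dn > 0] >= q[2], "most",
                                ifelse(table$Dn[table$Dn > 0] >= q[1], "high", "least"))
  }
  verts <- data.frame(name = table$node, Dn = table$Dn, rank = table$rank,
                      rewiring_class = cls, stringsAsFactors = FALSE)
  if (is.null(ed_all) || nrow(ed_all) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(verts), name = verts$name, Dn = verts$Dn,
                              rank = verts$rank, rewiring_class = verts$rewiring_class)
    return(g)
  }
  key <- paste(ed_all$from, ed_all$to, sep = "\r")
  agg_states <- vapply(split(ed_all$state, key), function(s) paste(sort(unique(s)), collapse = ";"), character(1))
  agg_w <- vapply(split(ed_all$weight, key), mean, numeric(1))
  uk <- names(agg_states)
  parts <- strsplit(uk, "\r", fixed = TRUE)
  ed <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                   to = vapply(parts, `[[`, character(1), 2L),
                   states = unname(agg_states), weight = unname(agg_w),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}
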