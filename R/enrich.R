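# Over-representation analysis, complementary-pathway completion and
# edge-betweenness pathway clustering.

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test of a gene list against each
#' pathway's membership, with Benjamini-Hochberg correction across
#' pathways. Pathway memberships and the gene list are intersected with the
#' background; listed genes absent from the background are dropped with a
#' warning.
#'
#' @param gene_list character vector of gene ids (e.g. selected DEGs).
#' @param universe a `pathway_universe`.
#' @param background character vector of assayable gene ids (defaults to
#'   every gene appearing in the universe memberships; standard practice is
#'   to pass the genes present on the expression matrix).
#' @param alpha adjusted-p cutoff for the `enriched` flag.
#' @return an `enrichment_table` data.frame: `pathway`, `hits`,
#'   `pathway_size`, `list_size`, `expected`, `p_value`, `p_adjusted`,
#'   `enriched`; sorted by p-value.
#' @export
ora <- function(gene_list, universe, background = NULL, alpha = 0.05) {
  stopifnot(inherits(universe, "pathway_universe"))
  if (length(gene_list) == 0L) stopf("gene list is empty")
  if (is.null(background)) {
    background <- sort(unique(unlist(universe$memberships, use.names = FALSE)))
  }
  gene_list <- unique(gene_list)
  missing <- setdiff(gene_list, background)
  if (length(missing)) {
    warnf("%d gene(s) absent from the background were dropped", length(missing))
    gene_list <- intersect(gene_list, background)
  }
  if (length(gene_list) == 0L) stopf("no gene in the list is present in the background")
  N <- length(background)
  n <- length(gene_list)
  pw <- names(universe$memberships)
  mem <- lapply(universe$memberships, intersect, background)
  K <- vapply(mem, length, integer(1))
  hits <- vapply(mem, function(m) length(intersect(m, gene_list)), integer(1))
  p <- stats::phyper(hits - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(pathway = pw, hits = hits, pathway_size = K,
                    list_size = n, expected = n * K / N,
                    p_value = p, p_adjusted = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$enriched <- out$p_adjusted < alpha
  out <- out[order(out$p_value, out$pathway), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Complete an enriched pathway set into a connected network
#'
#' Takes the enriched pathways and greedily connects the components they
#' induce in the reference pathway graph: repeatedly find the two closest
#' components (shortest reference-graph path between any cross pair of
#' members), add every node on that path as a `connector`, and repeat until
#' one component remains. Ties are broken by the lexicographically smallest
#' endpoint pair, then the lexicographically smallest path. Enriched nodes
#' in reference components with no connecting path are left as separate
#' components with a warning.
#'
#' @param enriched character vector of enriched pathway ids.
#' @param universe a `pathway_universe`.
#' @return a `pathway_network`: list with `graph` (induced subgraph of the
#'   reference graph), `roles` (named vector, `enriched`/`connector`) and
#'   `cluster` (`NULL` until [cluster_pathways()] is applied).
#' @export
complement_network <- function(enriched, universe) {
  stopifnot(inherits(universe, "pathway_universe"))
  ref <- universe$pathway_graph
  missing <- setdiff(enriched, igraph::V(ref)$name)
  if (length(missing)) stopf("enriched pathways absent from the reference graph: %s",
                             paste(missing, collapse = ", "))
  enriched <- sort(unique(enriched))
  included <- enriched
  dmat <- igraph::distances(ref, weights = NA)
  repeat {
    sub <- igraph::induced_subgraph(ref, included)
    comp <- igraph::components(sub)
    if (comp$no <= 1L) break
    memb <- stats::setNames(comp$membership, igraph::V(sub)$name)
    # closest pair of components in the reference metric
    best <- NULL
    for (ci in seq_len(comp$no - 1L)) {
      for (cj in (ci + 1L):comp$no) {
        a <- sort(names(memb)[memb == ci])
        b <- sort(names(memb)[memb == cj])
        dsub <- dmat[a, b, drop = FALSE]
        dmin <- min(dsub)
        if (!is.finite(dmin)) next
        idx <- which(dsub == dmin, arr.ind = TRUE)
        pairs <- data.frame(from = rownames(dsub)[idx[, 1]],
                            to = colnames(dsub)[idx[, 2]],
                            stringsAsFactors = FALSE)
        sw <- pairs$from > pairs$to
        pairs[sw, c("from", "to")] <- pairs[sw, c("to", "from")]
        pairs <- pairs[order(pairs$from, pairs$to), , drop = FALSE]
        cand <- list(d = dmin, from = pairs$from[1], to = pairs$to[1])
        if (is.null(best) || cand$d < best$d ||
            (cand$d == best$d && (cand$from < best$from ||
                                  (cand$from == best$from && cand$to < best$to)))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) {
      warnf("enriched pathways span disconnected reference components; returning %d components", comp$no)
      break
    }
    sp <- igraph::all_shortest_paths(ref, from = best$from, to = best$to,
                                     weights = NA)$res
    paths <- lapply(sp, function(p) igraph::V(ref)$name[p])
    keys <- vapply(paths, paste, character(1), collapse = "\r")
    path <- paths[[order(keys)[1]]]
    included <- sort(union(included, path))
  }
  roles <- stats::setNames(ifelse(included %in% enriched, "enriched", "connector"),
                           included)
  g <- igraph::induced_subgraph(ref, included)
  g <- igraph::set_vertex_attr(g, "role", value = unname(roles[igraph::V(g)$name]))
  structure(list(graph = g, roles = roles, cluster = NULL),
            class = "pathway_network")
}

#' Edge-betweenness (Girvan-Newman) pathway clustering
#'
#' Divisive clustering by repeated removal of the highest edge-betweenness
#' edge, cut at the maximum-modularity level, unweighted. Deterministic for
#' a fixed graph (vertices are kept in sorted order by the constructors in
#' this package).
#'
#' @param network a `pathway_network`, `stage_network` or igraph object.
#' @return named integer vector of cluster ids, one per node.
#' @export
cluster_pathways <- function(network) {
  g <- if (inherits(network, "pathway_network")) network$graph else as_igraph(network)
  if (igraph::vcount(g) == 0L) return(stats::setNames(integer(0), character(0)))
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL, directed = FALSE,
                                         modularity = TRUE, membership = TRUE)
  stats::setNames(as.integer(igraph::membership(cl)),
                  igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))))
}
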