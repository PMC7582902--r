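# Pathway-metabolite mapping, exclusive/common set logic and the bipartite
# pathway-metabolite network.

#' Map a pathway set to its metabolites
#'
#' Union of the metabolite sets of the given pathways, with per-pathway
#' provenance (which pathways contributed each metabolite). Pathways absent
#' from the metabolite map are skipped with a warning.
#'
#' @param pathways character vector of pathway ids.
#' @param universe a `pathway_universe`.
#' @return list with `metabolites` (sorted union) and `provenance` (named
#'   list metabolite -> sorted contributing pathways).
#' @export
pathways_to_metabolites <- function(pathways, universe) {
  stopifnot(inherits(universe, "pathway_universe"))
  pathways <- unique(pathways)
  missing <- setdiff(pathways, names(universe$metabolite_map))
  if (length(missing)) {
    warnf("%d pathway(s) absent from the metabolite map were skipped", length(missing))
    pathways <- setdiff(pathways, missing)
  }
  pairs_pw <- rep(pathways, vapply(universe$metabolite_map[pathways], length, integer(1)))
  pairs_met <- unlist(universe$metabolite_map[pathways], use.names = FALSE)
  prov <- lapply(split(pairs_pw, pairs_met), function(x) sort(unique(x)))
  list(metabolites = sort(unique(pairs_met)) %||% character(0),
       provenance = prov[order(names(prov))])
}

#' Two-set Venn partition
#'
#' Exact set algebra: ids exclusive to A, exclusive to B, and common to
#' both, each returned sorted.
#'
#' @param A,B character vectors of ids (duplicates ignored).
#' @param labels length-2 labels for the two sets.
#' @return a `set_partition`: list with `exclusive_A`, `exclusive_B`,
#'   `common`, `labels`.
#' @examples
#' venn_partition(c("m1", "m2", "m3"), c("m3", "m4"), labels = c("pre", "symp"))
#' @export
venn_partition <- function(A, B, labels = c("A", "B")) {
  A <- unique(A); B <- unique(B)
  out <- list(exclusive_A = sort(setdiff(A, B)),
              exclusive_B = sort(setdiff(B, A)),
              common = sort(intersect(A, B)),
              labels = labels)
  class(out) <- "set_partition"
  out
}

#' @export
print.set_partition <- function(x, ...) {
  cat(sprintf("set_partition: %d exclusive to %s, %d exclusive to %s, %d common\n",
              length(x$exclusive_A), x$labels[1],
              length(x$exclusive_B), x$labels[2], length(x$common)))
  invisible(x)
}

#' Pathway-metabolite bipartite network
#'
#' Connects each stage's pathways to metabolite *group* nodes: one
#' exclusive-metabolite group per stage and (optionally) one common group.
#' An edge is drawn when the pathway shares at least one metabolite with the
#' group; the `n_shared` edge attribute counts the shared metabolites and
#' the group nodes carry their set size. Setting `include_common = FALSE`
#' drops the common metabolites, keeping only stage-exclusive chemistry.
#'
#' @param stage_pathways named list (stage -> pathway ids), stages matching
#'   `partition$labels`.
#' @param universe a `pathway_universe`.
#' @param partition `set_partition` of the two stages' metabolite unions
#'   (labels must equal `names(stage_pathways)`).
#' @param include_common include the common-metabolite group node?
#' @return an igraph bipartite graph; vertex attributes `type`
#'   (`"pathway"` / `"metabolite_group"`) and `size`, edge attribute
#'   `n_shared`.
#' @export
build_bipartite <- function(stage_pathways, universe, partition,
                            include_common = TRUE) {
  stopifnot(inherits(partition, "set_partition"),
            inherits(universe, "pathway_universe"))
  stages <- names(stage_pathways)
  if (!identical(sort(stages), sort(partition$labels))) {
    stopf("names(stage_pathways) must match partition labels (%s)",
          paste(partition$labels, collapse = ", "))
  }
  excl <- stats::setNames(list(partition$exclusive_A, partition$exclusive_B),
                          partition$labels)
  groups <- stats::setNames(lapply(stages, function(s) excl[[s]]),
                            paste0("exclusive_", stages))
  if (include_common) groups$common <- partition$common

  edges <- list()
  pw_nodes <- character(0)
  for (s in stages) {
    for (p in stage_pathways[[s]]) {
      met <- universe$metabolite_map[[p]] %||% character(0)
      pw_nodes <- c(pw_nodes, p)
      own_groups <- c(paste0("exclusive_", s), if (include_common) "common")
      for (gname in own_groups) {
        n_shared <- length(intersect(met, groups[[gname]]))
        if (n_shared > 0L) {
          edges[[length(edges) + 1L]] <- data.frame(from = p, to = gname,
                                                    n_shared = n_shared,
                                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  pw_nodes <- sort(unique(pw_nodes))
  verts <- data.frame(name = c(pw_nodes, names(groups)),
                      type = c(rep("pathway", length(pw_nodes)),
                               rep("metabolite_group", length(groups))),
                      size = c(rep(NA_integer_, length(pw_nodes)),
                               vapply(groups, length, integer(1))),
                      stringsAsFactors = FALSE)
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), n_shared = integer(0))
  ed <- unique(ed)
  if (nrow(ed)) {
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(verts), name = verts$name,
                              type = verts$type, size = verts$size)
  }
  g
}
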