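# Shared fixture builders for the test suite. All randomness is seeded.

# Small simulation: 300 genes, balanced disease groups, two 20-gene modules.
small_config <- function(seed = 1, ...) {
  args <- list(
    n_genes = 300,
    n_samples_per_group = c(control = 14, pre = 12, symp = 12),
    n_de_per_direction = c(pre = 60, symp = 60),
    module_spec = list(
      list(size = 20, loading = 1, stages_active = c("control", "pre", "symp")),
      list(size = 20, loading = 1, stages_active = c("control", "pre", "symp"))
    ),
    n_pathways = 20,
    pathway_size_range = c(8, 25),
    n_metabolites = 80,
    metabolites_per_pathway_range = c(4, 12),
    planted_pathways = list(pre = c("P01", "P02"), symp = c("P03", "P04")),
    seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# Tiny weighted graph from an edge data.frame.
graph_of <- function(from, to, weight = 1) {
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight, stringsAsFactors = FALSE),
    directed = FALSE
  )
}

# Minimal hand-built pathway universe.
toy_universe <- function(memberships,
                         edges = NULL,
                         metabolite_map = NULL) {
  pw <- names(memberships)
  if (is.null(edges)) {
    edges <- if (length(pw) > 1) {
      data.frame(from = pw[-length(pw)], to = pw[-1])
    } else {
      data.frame(from = character(0), to = character(0))
    }
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = pw)
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, length(pw), name = pw)
  }
  igraph::E(g)$weight <- 1
  structure(list(pathway_graph = g, memberships = memberships,
                 metabolite_map = metabolite_map %||%
                   stats::setNames(vector("list", length(pw)), pw)),
            class = "pathway_universe")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

gene_ids_for_test <- function(n) sprintf("g%04d", seq_len(n))

# Independent brute-force betweenness: count, per node, the fraction of
# shortest paths between every ordered pair that pass through it, by full
# path enumeration (BFS layering). Usable only on very small graphs.
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  nodes <- seq_len(n)
  adj <- lapply(nodes, function(v) as.integer(igraph::neighbors(g, v)))
  all_shortest <- function(s, t) {
    # enumerate all shortest s-t paths by depth-first extension
    d <- igraph::distances(g, v = s, weights = NA)[1, ]
    if (!is.finite(d[t])) return(list())
    paths <- list()
    grow <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1L]] <<- path
        return(invisible())
      }
      for (u in adj[[v]]) {
        if (igraph::distances(g, v = u, weights = NA)[1, t] == d[t] - length(path)) {
          grow(c(path, u))
        }
      }
    }
    grow(s)
    paths
  }
  btw <- numeric(n)
  for (s in nodes) for (t in nodes) {
    if (s >= t) next
    paths <- all_shortest(s, t)
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      btw[as.integer(names(tab))] <- btw[as.integer(names(tab))] + tab / length(paths)
    }
  }
  btw
}

# Exact hypergeometric upper-tail p by enumeration over draw counts.
exact_hyper_p <- function(hits, K, N, n) {
  kk <- hits:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
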