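# End-to-end orchestration: simulate (or load) -> differential expression
# -> co-expression networks -> topology -> rewiring -> enrichment ->
# guided walks -> metabolites.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full two-stage pipeline
#'
#' Executes the whole workflow on either a simulation configuration or a
#' user-supplied dataset + universe: stagewise differential expression and
#' top-k selection, per-stage MI/CLR co-expression networks, centrality
#' tables, cross-stage rewiring over the central reference network,
#' over-representation analysis with complementary-pathway completion and
#' edge-betweenness clustering, guided/non-guided pathway walks with the
#' odds-ratio adjustment, and the exclusive/common metabolite partition
#' with its bipartite network. Every stochastic step is seeded
#' deterministically from `seed`.
#'
#' @param config a `sim_config` (simulation mode), or `NULL` when passing
#'   `dataset` and `universe` directly; exactly one input mode must be
#'   active.
#' @param dataset,universe real-mode inputs (an `expression_dataset` and a
#'   `pathway_universe`).
#' @param k,alpha top-k selection parameters per direction.
#' @param mi_k neighbour count for the MI estimator.
#' @param log_threshold log-weight edge filter for the stage networks.
#' @param n_iterations,gene_walk_length,restart_prob walk parameters.
#' @param seed master seed (defaults to `config$seed` in simulation mode).
#' @param out_dir optional directory; when given, tables (TSV) and networks
#'   (GraphML) are written there.
#' @return a `pipeline_result` list: per-stage `de`, `networks`,
#'   `centralities`, `enrichment`, `pathway_networks`, `clusters`, `walks`,
#'   `or_tables`; shared `merged`, `rewiring`, `reference`,
#'   `metabolite_partition`, `bipartite`; and a flat numeric `summary` of
#'   the headline counts.
#' @export
run_pipeline <- function(config = NULL, dataset = NULL, universe = NULL,
                         k = 150, alpha = 0.05, mi_k = 3, log_threshold = 1,
                         n_iterations = 50000, gene_walk_length = 50,
                         restart_prob = 0.15, seed = NULL, out_dir = NULL) {
  sim_mode <- !is.null(config)
  if (sim_mode == (!is.null(dataset) || !is.null(universe))) {
    stopf("supply exactly one of: a sim_config, or a dataset + universe pair")
  }
  if (sim_mode) {
    stopifnot(inherits(config, "sim_config"))
    seed <- seed %||% config$seed
    dataset <- run_stage("synthdata", simulate_expression(config))
    universe <- run_stage("synthdata", simulate_universe(config))
  } else {
    if (is.null(dataset) || is.null(universe)) {
      stopf("real mode needs both a dataset and a universe")
    }
    seed <- seed %||% 1L
  }
  stages <- c("pre", "symp")

  de <- lapply(stages, function(s) {
    run_stage(paste0("de/", s), select_top_k(fit_de(dataset, s), k = k, alpha = alpha))
  })
  names(de) <- stages
  selected <- lapply(de, function(tab) attr(tab, "selected_genes"))

  networks <- lapply(stages, function(s) {
    run_stage(paste0("coexpr/", s),
              stage_coexpression(dataset, selected[[s]], s, k = mi_k,
                                 threshold = log_threshold))
  })
  names(networks) <- stages

  centralities <- lapply(networks, function(nw) {
    run_stage("topology", compute_centralities(nw))
  })

  merged <- run_stage("coexpr", merge_stage_networks(networks$pre, networks$symp))
  rewiring <- run_stage("rewire", compute_rewiring(networks))
  reference <- run_stage("rewire", build_reference_network(networks, rewiring))

  enrichment <- lapply(stages, function(s) {
    run_stage(paste0("enrich/", s),
              ora(selected[[s]], universe, background = dataset$gene_ids))
  })
  names(enrichment) <- stages
  pathway_networks <- lapply(stages, function(s) {
    enr <- enrichment[[s]]$pathway[enrichment[[s]]$enriched]
    if (length(enr) == 0L) return(NULL)
    run_stage(paste0("enrich/", s), complement_network(enr, universe))
  })
  names(pathway_networks) <- stages
  clusters <- lapply(pathway_networks, function(pn) {
    if (is.null(pn)) return(NULL)
    run_stage("enrich", cluster_pathways(pn))
  })

  non_guided <- run_stage("walks",
                          non_guided_walk(universe, n_iterations = n_iterations,
                                          seed = seed + 1000L))
  walks <- lapply(seq_along(stages), function(i) {
    run_stage(paste0("walks/", stages[i]),
              guided_walk(networks[[stages[i]]], universe,
                          n_iterations = n_iterations,
                          gene_walk_length = gene_walk_length,
                          restart_prob = restart_prob,
                          seed = seed + 2000L + i))
  })
  names(walks) <- stages
  or_tables <- lapply(walks, function(w) run_stage("walks", odds_ratio(w, non_guided)))

  stage_pathways <- lapply(stages, function(s) {
    pn <- pathway_networks[[s]]
    if (is.null(pn)) character(0) else names(pn$roles)
  })
  names(stage_pathways) <- stages
  mets <- lapply(stage_pathways, function(pws) {
    if (length(pws) == 0L) return(character(0))
    pathways_to_metabolites(pws, universe)$metabolites
  })
  partition <- run_stage("metab", venn_partition(mets$pre, mets$symp, labels = stages))
  bip <- run_stage("metab", build_bipartite(stage_pathways, universe, partition))

  deg_venn <- venn_partition(selected$pre, selected$symp, labels = stages)
  rewired_genes <- rewiring$node[rewiring$Dn > 0]

  summary <- c(
    selected_degs_pre = length(selected$pre),
    selected_degs_symp = length(selected$symp),
    edges_pre = igraph::ecount(networks$pre$graph),
    edges_symp = igraph::ecount(networks$symp$graph),
    deg_common = length(deg_venn$common),
    rewired_genes = length(rewired_genes),
    enriched_pre = sum(enrichment$pre$enriched),
    enriched_symp = sum(enrichment$symp$enriched),
    clusters_pre = if (is.null(clusters$pre)) 0L else length(unique(clusters$pre)),
    clusters_symp = if (is.null(clusters$symp)) 0L else length(unique(clusters$symp)),
    or_relevant_pre = sum(or_tables$pre$relevant, na.rm = TRUE),
    or_relevant_symp = sum(or_tables$symp$relevant, na.rm = TRUE),
    metabolites_exclusive_pre = length(partition$exclusive_A),
    metabolites_exclusive_symp = length(partition$exclusive_B),
    metabolites_common = length(partition$common)
  )
  top_rewired <- rewiring$node[rewiring$rank == 1L][1]

  result <- structure(list(
    de = de, networks = networks, centralities = centralities,
    merged = merged, rewiring = rewiring, reference = reference,
    top_rewired = top_rewired,
    enrichment = enrichment, pathway_networks = pathway_networks,
    clusters = clusters, walks = walks, non_guided = non_guided,
    or_tables = or_tables, metabolite_partition = partition,
    bipartite = bip, deg_venn = deg_venn, summary = summary,
    seed = seed
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result (seed", x$seed, ")\n")
  cat(sprintf("  top rewired gene: %s\n", x$top_rewired))
  for (nm in names(x$summary)) cat(sprintf("  %s: %g\n", nm, x$summary[[nm]]))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline artifacts to a directory
#'
#' DEG tables, rewiring table, enrichment and OR tables as TSV; stage,
#' merged, reference and bipartite networks as GraphML; a flat
#' `summary.tsv` of the headline counts.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, `out_dir`.
#' @export
write_pipeline_artifacts <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (s in names(result$de)) {
    write_tsv(result$de[[s]], file.path(out_dir, sprintf("deg_%s.tsv", s)))
    write_graphml(result$networks[[s]], file.path(out_dir, sprintf("network_%s.graphml", s)))
    write_tsv(result$centralities[[s]], file.path(out_dir, sprintf("centralities_%s.tsv", s)))
    write_tsv(result$enrichment[[s]], file.path(out_dir, sprintf("enrichment_%s.tsv", s)))
    write_tsv(result$or_tables[[s]], file.path(out_dir, sprintf("or_%s.tsv", s)))
  }
  write_tsv(result$rewiring, file.path(out_dir, "rewiring.tsv"))
  write_graphml(result$merged, file.path(out_dir, "merged.graphml"))
  write_graphml(result$reference, file.path(out_dir, "reference.graphml"))
  write_graphml(result$bipartite, file.path(out_dir, "bipartite.graphml"))
  part <- result$metabolite_partition
  write_tsv(data.frame(set = c(rep(paste0("exclusive_", part$labels[1]), length(part$exclusive_A)),
                               rep(paste0("exclusive_", part$labels[2]), length(part$exclusive_B)),
                               rep("common", length(part$common))),
                       metabolite = c(part$exclusive_A, part$exclusive_B, part$common)),
            file.path(out_dir, "metabolite_partition.tsv"))
  write_tsv(data.frame(key = names(result$summary), value = unname(result$summary)),
            file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}
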