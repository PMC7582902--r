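#' Simulation configuration for a three-group expression study
#'
#' Builds the configuration object consumed by [simulate_expression()] and
#' [simulate_universe()]. The defaults emulate a small blood microarray study
#' of a two-stage neurodegenerative disease: 14 controls, 5 pre-symptomatic
#' and 12 symptomatic samples on a log2 intensity scale, with planted
#' over/under-expressed genes per stage, two planted co-expression modules
#' shared across stages, one "rewired hub" gene whose module membership
#' switches between the stages, and a synthetic pathway/metabolite universe
#' with pathways enriched for each stage's planted genes.
#'
#' Gene layout: module genes occupy the first indices and are also planted
#' over-expressed in both disease stages (so they survive differential
#' expression selection and appear in both stage networks); the remaining
#' planted over/under genes are stage-specific disjoint blocks; all other
#' genes carry no signal.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_group named integer vector with entries `control`,
#'   `pre`, `symp`.
#' @param n_de_per_direction named integer vector (`pre`, `symp`): planted
#'   over-expressed genes per stage (an equal number is planted
#'   under-expressed). Must be at least the total module size, since module
#'   genes count towards each stage's over-expressed quota.
#' @param de_effect log2-fold-change magnitude added to planted genes (> 0).
#' @param noise_sd standard deviation of the i.i.d. Gaussian noise.
#' @param module_spec list of module descriptions, each a list with `size`,
#'   `loading` and `stages_active` (subset of `c("control","pre","symp")`).
#'   Genes in a module share a latent factor in the groups where the module
#'   is active.
#' @param rewired_hub gene id whose module membership switches between the
#'   `pre` and `symp` stages (must belong to a module; it loads fully on its
#'   home module in pre-symptomatic samples, fully on the next module in
#'   symptomatic samples, and on both at half loading in controls), or
#'   `NULL` for no planted hub.
#' @param n_pathways,pathway_size_range number and size range of pathways in
#'   the synthetic universe.
#' @param n_metabolites,metabolites_per_pathway_range size of the metabolite
#'   pool and per-pathway draw range; drawing from a common finite pool gives
#'   the exclusive/common overlap structure downstream set logic needs.
#' @param planted_pathways named list (`pre`, `symp`) of pathway ids whose
#'   memberships over-sample that stage's planted genes.
#' @param planted_fraction fraction of a planted pathway's members drawn from
#'   the stage's planted gene pool.
#' @param hub_control_mixing fraction of each module loading the hub carries
#'   in control samples (mixed coupling before the stage switch).
#' @param hub_commit_gain multiplier on the hub's loading in its committed
#'   stage (pre: home module, symp: target module).
#' @param hub_de_gain multiplier on `de_effect` for the hub itself; the hub
#'   emulates a strongly dysregulated driver gene, so its expression shift
#'   exceeds the rank-and-file planted genes (compensating the extra
#'   variance its factor loading carries).
#' @param seed integer master seed; identical seeds give identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_group = c(control = 14, pre = 5, symp = 12),
                       n_de_per_direction = c(pre = 150, symp = 150),
                       de_effect = 2,
                       noise_sd = 0.5,
                       module_spec = list(
                         list(size = 30, loading = 1,
                              stages_active = c("control", "pre", "symp")),
                         list(size = 30, loading = 1,
                              stages_active = c("control", "pre", "symp"))
                       ),
                       rewired_hub = "g0001",
                       n_pathways = 60,
                       pathway_size_range = c(10, 40),
                       n_metabolites = 300,
                       metabolites_per_pathway_range = c(5, 20),
                       planted_pathways = list(pre = c("P01", "P02", "P03"),
                                               symp = c("P04", "P05", "P06")),
                       planted_fraction = 0.7,
                       hub_control_mixing = 0.35,
                       hub_commit_gain = 1.5,
                       hub_de_gain = 1.5,
                       seed = 1) {
  assert_scalar_count(n_genes, "n_genes")
  groups <- c("control", "pre", "symp")
  if (!all(groups %in% names(n_samples_per_group))) {
    stopf("n_samples_per_group must name all of: %s", paste(groups, collapse = ", "))
  }
  for (g in groups) assert_scalar_count(n_samples_per_group[[g]], paste0("n_samples_per_group[", g, "]"))
  for (s in c("pre", "symp")) {
    if (!s %in% names(n_de_per_direction)) stopf("n_de_per_direction must name '%s'", s)
    if (n_de_per_direction[[s]] < 0) stopf("n_de_per_direction must be nonnegative")
    if (n_de_per_direction[[s]] > n_genes / 2) stopf("n_de_per_direction[%s] exceeds n_genes/2", s)
  }
  if (!is.numeric(de_effect) || de_effect < 0) stopf("de_effect must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stopf("noise_sd must be > 0")
  msizes <- vapply(module_spec, function(m) as.integer(m$size), integer(1))
  m_total <- sum(msizes)
  for (s in c("pre", "symp")) {
    if (length(module_spec) && n_de_per_direction[[s]] < m_total) {
      stopf("n_de_per_direction[%s] (%d) must cover the %d module genes",
            s, n_de_per_direction[[s]], m_total)
    }
  }
  planted_total <- m_total +
    (n_de_per_direction[["pre"]] - m_total) + n_de_per_direction[["pre"]] +
    (n_de_per_direction[["symp"]] - m_total) + n_de_per_direction[["symp"]]
  if (planted_total > n_genes) {
    stopf("planted gene blocks (%d) exceed n_genes (%d)", planted_total, n_genes)
  }
  if (pathway_size_range[1] < 1 || pathway_size_range[2] < pathway_size_range[1]) {
    stopf("invalid pathway_size_range")
  }
  if (pathway_size_range[2] > n_genes) {
    stopf("pathway_size_range exceeds n_genes")
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = vapply(n_samples_per_group[groups], as.integer, integer(1)),
    n_de_per_direction = vapply(n_de_per_direction[c("pre", "symp")], as.integer, integer(1)),
    de_effect = de_effect,
    noise_sd = noise_sd,
    module_spec = module_spec,
    rewired_hub = rewired_hub,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    n_metabolites = as.integer(n_metabolites),
    metabolites_per_pathway_range = as.integer(metabolites_per_pathway_range),
    planted_pathways = planted_pathways,
    planted_fraction = planted_fraction,
    hub_control_mixing = hub_control_mixing,
    hub_commit_gain = hub_commit_gain,
    hub_de_gain = hub_de_gain,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

gene_ids_for <- function(n) sprintf("g%04d", seq_len(n))

#' Planted gene layout implied by a configuration
#'
#' Returns, for each stage and direction, the planted gene ids, the module
#' membership blocks and the hub's home/target modules. Shared module genes
#' are part of both stages' over-expressed sets.
#' @param config a `sim_config`.
#' @return list with `modules` (list of gene-id vectors), `de`
#'   (`de$pre$over`, `de$pre$under`, ...), and `hub` (list with `gene`,
#'   `module_home`, `module_target`, or `NULL`).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- gene_ids_for(config$n_genes)
  msizes <- vapply(config$module_spec, function(m) as.integer(m$size), integer(1))
  m_total <- sum(msizes)
  modules <- list()
  at <- 0L
  for (i in seq_along(msizes)) {
    modules[[i]] <- ids[(at + 1L):(at + msizes[i])]
    at <- at + msizes[i]
  }
  take <- function(n) {
    if (n == 0L) return(character(0))
    out <- ids[(at + 1L):(at + n)]
    at <<- at + n
    out
  }
  module_genes <- if (m_total > 0L) ids[seq_len(m_total)] else character(0)
  de <- list()
  de$pre <- list(over = c(module_genes, take(config$n_de_per_direction[["pre"]] - m_total)),
                 under = take(config$n_de_per_direction[["pre"]]))
  de$symp <- list(over = c(module_genes, take(config$n_de_per_direction[["symp"]] - m_total)),
                  under = take(config$n_de_per_direction[["symp"]]))
  hub <- NULL
  if (!is.null(config$rewired_hub) && length(modules) >= 2L) {
    home <- which(vapply(modules, function(m) config$rewired_hub %in% m, logical(1)))
    if (length(home) != 1L) stopf("rewired_hub '%s' must belong to exactly one module", config$rewired_hub)
    target <- if (home == length(modules)) 1L else home + 1L
    hub <- list(gene = config$rewired_hub, module_home = home, module_target = target)
  } else if (!is.null(config$rewired_hub) && length(modules) < 2L) {
    stopf("a rewired hub needs at least two modules")
  }
  list(modules = modules, de = de, hub = hub)
}

#' Simulate a three-group log-intensity expression matrix
#'
#' Gene value = baseline(gene) + sum over modules of loading x factor(sample)
#' + N(0, noise_sd); planted differential expression is an additive
#' `de_effect` mean shift (log2 scale) on that stage's samples. The rewired
#' hub loads on its home module's factor in control and pre-symptomatic
#' samples and on the target module's factor in symptomatic samples.
#'
#' @param config a `sim_config`.
#' @return an object of class `expression_dataset`: list with `matrix`
#'   (genes x samples), `gene_ids`, `sample_groups` (named character vector)
#'   and `truth` (the planted ground truth, see [planted_truth()]).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- planted_truth(config)
  nsg <- config$n_samples_per_group
  groups <- rep(c("control", "pre", "symp"), times = nsg)
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(nsg[["control"]])),
                  sprintf("pre_%02d", seq_len(nsg[["pre"]])),
                  sprintf("symp_%02d", seq_len(nsg[["symp"]])))
  names(groups) <- sample_ids
  n <- length(groups)
  ids <- gene_ids_for(config$n_genes)

  with_seed(config$seed, {
    mat <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                  nrow = config$n_genes, ncol = n,
                  dimnames = list(ids, sample_ids))
    mat <- mat + stats::rnorm(config$n_genes, mean = 7, sd = 1)

    # latent module factors, one value per sample, active groups only
    factors <- lapply(seq_along(config$module_spec), function(i) {
      f <- stats::rnorm(n)
      f[!(groups %in% config$module_spec[[i]]$stages_active)] <- 0
      f
    })
    for (i in seq_along(config$module_spec)) {
      lam <- config$module_spec[[i]]$loading
      if (lam != 0) {
        mat[truth$modules[[i]], ] <- mat[truth$modules[[i]], , drop = FALSE] +
          rep(lam * factors[[i]], each = length(truth$modules[[i]]))
      }
    }
    if (!is.null(truth$hub)) {
      # The hub commits to its home module in pre samples and to the target
      # module in symptomatic samples; in controls it couples to both at
      # half loading (mixed coupling before the disease-stage switch).
      hub <- truth$hub$gene
      f_home <- factors[[truth$hub$module_home]]
      f_tgt <- factors[[truth$hub$module_target]]
      lam_home <- config$module_spec[[truth$hub$module_home]]$loading
      lam_tgt <- config$module_spec[[truth$hub$module_target]]$loading
      mix <- config$hub_control_mixing %||% 0.35
      gain <- config$hub_commit_gain %||% 1.5
      ctrl <- groups == "control"
      pre_cols <- groups == "pre"
      symp_cols <- groups == "symp"
      mat[hub, ctrl] <- mat[hub, ctrl] - lam_home * f_home[ctrl] +
        mix * (lam_home * f_home[ctrl] + lam_tgt * f_tgt[ctrl])
      mat[hub, pre_cols] <- mat[hub, pre_cols] +
        (gain - 1) * lam_home * f_home[pre_cols]
      mat[hub, symp_cols] <- mat[hub, symp_cols] -
        lam_home * f_home[symp_cols] + gain * lam_tgt * f_tgt[symp_cols]
    }
    for (stage in c("pre", "symp")) {
      cols <- groups == stage
      if (config$de_effect != 0) {
        mat[truth$de[[stage]]$over, cols] <- mat[truth$de[[stage]]$over, cols, drop = FALSE] + config$de_effect
        mat[truth$de[[stage]]$under, cols] <- mat[truth$de[[stage]]$under, cols, drop = FALSE] - config$de_effect
        if (!is.null(truth$hub)) {
          extra <- ((config$hub_de_gain %||% 1.5) - 1) * config$de_effect
          mat[truth$hub$gene, cols] <- mat[truth$hub$gene, cols] + extra
        }
      }
    }
    structure(list(matrix = mat, gene_ids = ids, sample_groups = groups,
                   truth = truth),
              class = "expression_dataset")
  })
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s=%d", names(table(x$sample_groups)),
                            as.integer(table(x$sample_groups))), collapse = ", ")))
  invisible(x)
}

#' Simulate a pathway/metabolite universe
#'
#' Pathways receive gene memberships sampled from the gene pool; planted
#' pathways over-sample the corresponding stage's planted genes so they are
#' genuinely enriched in that stage's gene lists. The pathway-pathway graph
#' is a uniform random spanning tree (guaranteeing connectivity, which the
#' pathway walker requires) plus `n_pathways` extra random edges. Metabolite
#' sets are drawn from one finite pool, so pathway pairs share compounds and
#' the exclusive/common partition downstream is non-trivial.
#'
#' @param config a `sim_config`.
#' @return an object of class `pathway_universe`: list with `pathway_graph`
#'   (igraph), `memberships` (named list of gene-id vectors) and
#'   `metabolite_map` (named list of metabolite-id vectors).
#' @export
simulate_universe <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- planted_truth(config)
  ids <- gene_ids_for(config$n_genes)
  pw_ids <- sprintf("P%02d", seq_len(config$n_pathways))
  for (s in names(config$planted_pathways)) {
    missing <- setdiff(config$planted_pathways[[s]], pw_ids)
    if (length(missing)) stopf("planted pathway ids not in universe: %s", paste(missing, collapse = ", "))
  }

  with_seed(config$seed + 1L, {
    sizes <- sample(seq(config$pathway_size_range[1], config$pathway_size_range[2]),
                    config$n_pathways, replace = TRUE)
    memberships <- stats::setNames(vector("list", config$n_pathways), pw_ids)
    planted_of <- function(p) {
      for (s in names(config$planted_pathways)) {
        if (p %in% config$planted_pathways[[s]]) return(s)
      }
      NA_character_
    }
    for (i in seq_along(pw_ids)) {
      p <- pw_ids[i]
      s <- planted_of(p)
      if (!is.na(s)) {
        pool <- unique(c(truth$de[[s]]$over, truth$de[[s]]$under))
        n_pl <- min(length(pool), round(config$planted_fraction * sizes[i]))
        mem <- c(sample(pool, n_pl),
                 sample(setdiff(ids, pool), sizes[i] - n_pl))
      } else {
        mem <- sample(ids, sizes[i])
      }
      memberships[[p]] <- sort(mem)
    }

    # connectivity: random spanning tree first, then extra edges
    if (config$n_pathways > 1L) {
      perm <- sample(pw_ids)
      tree_from <- character(config$n_pathways - 1L)
      tree_to <- character(config$n_pathways - 1L)
      for (i in 2:config$n_pathways) {
        tree_from[i - 1L] <- perm[sample.int(i - 1L, 1L)]
        tree_to[i - 1L] <- perm[i]
      }
      extra <- matrix(sample(pw_ids, 2L * config$n_pathways, replace = TRUE), ncol = 2L)
      extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
      # planted pathways of a stage cross-talk: connect them directly, so
      # each stage's disease-relevant pathways form a graph neighbourhood
      planted_ed <- do.call(rbind, lapply(config$planted_pathways, function(pws) {
        if (length(pws) < 2L) return(NULL)
        t(utils::combn(sort(pws), 2L))
      }))
      if (!is.null(planted_ed)) extra <- rbind(extra, planted_ed)
      ed <- canonical_edges(c(tree_from, extra[, 1]), c(tree_to, extra[, 2]))
      edf <- unique(data.frame(from = ed$from, to = ed$to, stringsAsFactors = FALSE))
      g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                         vertices = sort(pw_ids))
    } else {
      g <- igraph::make_empty_graph(1, directed = FALSE)
      g <- igraph::set_vertex_attr(g, "name", value = pw_ids)
    }
    igraph::E(g)$weight <- 1

    met_ids <- sprintf("m%03d", seq_len(config$n_metabolites))
    rng <- config$metabolites_per_pathway_range
    metabolite_map <- stats::setNames(lapply(seq_along(pw_ids), function(i) {
      k <- sample(seq(rng[1], rng[2]), 1L)
      sort(sample(met_ids, min(k, length(met_ids))))
    }), pw_ids)

    structure(list(pathway_graph = g, memberships = memberships,
                   metabolite_map = metabolite_map),
              class = "pathway_universe")
  })
}

#' @export
print.pathway_universe <- function(x, ...) {
  cat(sprintf("pathway_universe: %d pathways, %d edges, %d metabolite-mapped pathways\n",
              igraph::vcount(x$pathway_graph), igraph::ecount(x$pathway_graph),
              length(x$metabolite_map)))
  invisible(x)
}
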