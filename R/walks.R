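# Guided random-walk pathway ranking and the odds-ratio adjustment.
#
# One iteration of the guided walk: (1) a random walk with restart on the
# gene network (transition probability proportional to edge weight, restart
# to the iteration's start gene); (2) the pathway memberships of the visited
# genes are tallied; (3) a destination pathway is sampled proportionally to
# the tally; (4) a walker on the pathway graph moves from its current
# pathway to the destination along a shortest path (uniform tie-break per
# step), incrementing the visit count F of every pathway it enters and the
# traversal count E of every edge it crosses. The walker's position
# persists across iterations. The non-guided walk replaces step (1)-(3)
# with a uniform destination draw; comparing the two visit distributions
# with an odds ratio corrects the guided ranking for pathway-graph topology
# (large, central pathways collect visits under both protocols).

#' @noRd
walk_engine <- function(universe, destinations, seed_state_start, Emat, Fvec) {
  g <- universe$pathway_graph
  pw <- igraph::V(g)$name
  np <- length(pw)
  dmat <- igraph::distances(g, weights = NA)
  nbrs <- lapply(seq_len(np), function(i) {
    as.integer(igraph::neighbors(g, i))
  })
  cur <- seed_state_start
  teleports <- 0L
  for (t in seq_along(destinations)) {
    dest <- destinations[t]
    if (dest == cur) {
      Fvec[cur] <- Fvec[cur] + 1L
      next
    }
    if (!is.finite(dmat[cur, dest])) {
      teleports <- teleports + 1L
      cur <- dest
      Fvec[dest] <- Fvec[dest] + 1L
      next
    }
    while (cur != dest) {
      cand <- nbrs[[cur]]
      cand <- cand[dmat[cand, dest] == dmat[cur, dest] - 1]
      nxt <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      Emat[cur, nxt] <- Emat[cur, nxt] + 1L
      Emat[nxt, cur] <- Emat[nxt, cur] + 1L
      Fvec[nxt] <- Fvec[nxt] + 1L
      cur <- nxt
    }
  }
  list(F = Fvec, E = Emat, position = cur, teleports = teleports)
}

#' @noRd
make_walk_result <- function(universe, Fvec, Emat, mode, n_iterations, seed,
                             unmapped = 0L, teleports = 0L) {
  pw <- igraph::V(universe$pathway_graph)$name
  names(Fvec) <- pw
  dimnames(Emat) <- list(pw, pw)
  structure(list(F = Fvec, E = Emat, Ft = sum(Fvec), mode = mode,
                 n_iterations = n_iterations, seed = seed,
                 unmapped = unmapped, teleports = teleports),
            class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  cat(sprintf("walk_result (%s): %d iterations, Ft = %d visits over %d pathways\n",
              x$mode, x$n_iterations, x$Ft, length(x$F)))
  invisible(x)
}

#' Guided random-walk pathway ranking
#'
#' Runs the guided protocol described above. The gene network steers the
#' pathway walker: genes visited by restart walks on the gene network vote,
#' through their pathway memberships, for the next destination pathway.
#' Iterations whose visited genes map to no pathway fall back to a uniform
#' destination draw (reported in `unmapped`).
#'
#' @param gene_network an igraph gene graph with a `weight` edge attribute
#'   (or a `stage_network`); vertices named by gene id. Nodes whose incident
#'   weights are all zero make the walker stay at its start gene.
#' @param universe a `pathway_universe`.
#' @param n_iterations number of walk iterations.
#' @param gene_walk_length steps of the restart walk on the gene network per
#'   iteration.
#' @param restart_prob per-step probability of returning to the iteration's
#'   start gene.
#' @param seed RNG seed; identical seeds give identical counts.
#' @return a `walk_result`: visit counts `F` (named integer), edge traversal
#'   counts `E` (matrix), total visits `Ft`, `mode`, bookkeeping fields.
#' @export
guided_walk <- function(gene_network, universe, n_iterations = 50000,
                        gene_walk_length = 50, restart_prob = 0.15, seed = 1) {
  stopifnot(inherits(universe, "pathway_universe"))
  g <- as_igraph(gene_network)
  if (igraph::vcount(g) == 0L) stopf("gene network is empty")
  assert_scalar_count(n_iterations, "n_iterations")
  assert_scalar_count(gene_walk_length, "gene_walk_length")
  if (restart_prob < 0 || restart_prob >= 1) stopf("restart_prob must be in [0, 1)")

  genes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  ng <- length(genes)
  ed <- igraph::as_data_frame(g, what = "edges")
  w <- ed$weight %||% rep(1, nrow(ed))
  # adjacency with cumulative weights for O(log deg) sampling
  adj_idx <- vector("list", ng)
  adj_cum <- vector("list", ng)
  if (nrow(ed) > 0L) {
    fi <- match(ed$from, genes); ti <- match(ed$to, genes)
    keep <- w > 0
    ends <- c(fi[keep], ti[keep]); oth <- c(ti[keep], fi[keep]); ww <- c(w[keep], w[keep])
    sp <- split(seq_along(ends), ends)
    for (nm in names(sp)) {
      i <- as.integer(nm)
      adj_idx[[i]] <- oth[sp[[nm]]]
      adj_cum[[i]] <- cumsum(ww[sp[[nm]]])
    }
  }

  pw <- igraph::V(universe$pathway_graph)$name
  np <- length(pw)
  # gene index -> integer vector of pathway indices
  gene_pw <- vector("list", ng)
  for (pi in seq_along(pw)) {
    hit <- match(intersect(universe$memberships[[pw[pi]]], genes), genes)
    for (i in hit) gene_pw[[i]] <- c(gene_pw[[i]], pi)
  }
  plen <- lengths(gene_pw)

  with_seed(seed, {
    start <- sample.int(ng, n_iterations, replace = TRUE)
    cur <- start
    visits <- matrix(0L, nrow = gene_walk_length + 1L, ncol = n_iterations)
    visits[1L, ] <- cur
    for (s in seq_len(gene_walk_length)) {
      restart <- stats::runif(n_iterations) < restart_prob
      cur[restart] <- start[restart]
      movers <- which(!restart)
      if (length(movers)) {
        sp <- split(movers, cur[movers])
        for (nm in names(sp)) {
          i <- as.integer(nm)
          idx <- sp[[nm]]
          cumw <- adj_cum[[i]]
          if (is.null(cumw)) {
            cur[idx] <- start[idx]  # stuck: degenerate to restart
          } else {
            u <- stats::runif(length(idx)) * cumw[length(cumw)]
            cur[idx] <- adj_idx[[i]][findInterval(u, cumw) + 1L]
          }
        }
      }
      visits[s + 1L, ] <- cur
    }

    # destination ~ tally of pathway memberships of visited genes, realised
    # as a uniform draw over the expanded (visit, pathway) incidence rows
    vi <- as.vector(visits)
    it <- rep(seq_len(n_iterations), each = gene_walk_length + 1L)
    npw_per_visit <- plen[vi]
    it2 <- rep(it, npw_per_visit)
    pw2 <- unlist(gene_pw[vi], use.names = FALSE)
    o <- order(it2)
    pw_sorted <- pw2[o]
    tab <- tabulate(it2, nbins = n_iterations)
    offs <- cumsum(c(0L, tab))[seq_len(n_iterations)]
    dest <- integer(n_iterations)
    mapped <- tab > 0L
    if (any(mapped)) {
      pick <- offs[mapped] + ceiling(stats::runif(sum(mapped)) * tab[mapped])
      dest[mapped] <- pw_sorted[pick]
    }
    n_unmapped <- sum(!mapped)
    if (n_unmapped) dest[!mapped] <- sample.int(np, n_unmapped, replace = TRUE)

    res <- walk_engine(universe, dest, sample.int(np, 1L),
                       matrix(0L, np, np), integer(np))
    make_walk_result(universe, res$F, res$E, "guided", n_iterations, seed,
                     unmapped = n_unmapped, teleports = res$teleports)
  })
}

#' Non-guided random-walk baseline
#'
#' Same pathway-walk protocol as [guided_walk()] but with destinations drawn
#' uniformly over pathways, so visit counts reflect pathway-graph topology
#' alone.
#'
#' @inheritParams guided_walk
#' @return a `walk_result` with `mode = "non_guided"`.
#' @export
non_guided_walk <- function(universe, n_iterations = 50000, seed = 1) {
  stopifnot(inherits(universe, "pathway_universe"))
  assert_scalar_count(n_iterations, "n_iterations")
  np <- igraph::vcount(universe$pathway_graph)
  with_seed(seed, {
    dest <- sample.int(np, n_iterations, replace = TRUE)
    res <- walk_engine(universe, dest, sample.int(np, 1L),
                       matrix(0L, np, np), integer(np))
    make_walk_result(universe, res$F, res$E, "non_guided", n_iterations, seed,
                     teleports = res$teleports)
  })
}

#' Odds ratio of guided versus non-guided pathway visits
#'
#' Per pathway, the visiting probability under each mode is
#' `P_i = F_i / Ft`, and
#' `OR_i = [P_i^G / (1 - P_i^G)] / [P_i^U / (1 - P_i^U)]`.
#' A pathway with OR of one and above is flagged relevant: the guided walker
#' visited it more than pathway-graph topology alone explains. `P = 1` or
#' `P_U = 0 < P_G` give `OR = Inf`; a pathway unvisited under both modes has
#' an undefined OR (`NA`).
#'
#' @param guided,non_guided `walk_result` objects over the same pathway set
#'   with positive total visits.
#' @return an `or_table` data.frame: `pathway`, `F_guided`, `F_non_guided`,
#'   `P_guided`, `P_non_guided`, `OR`, `relevant`; sorted by decreasing OR.
#' @examples
#' cfg <- sim_config(n_genes = 100, n_de_per_direction = c(pre = 40, symp = 40),
#'                   module_spec = list(), rewired_hub = NULL,
#'                   n_pathways = 8, n_metabolites = 40, seed = 1)
#' uni <- simulate_universe(cfg)
#' g <- igraph::make_ring(10)
#' igraph::V(g)$name <- sprintf("g%04d", 1:10)
#' igraph::E(g)$weight <- 1
#' gw <- guided_walk(g, uni, n_iterations = 500, gene_walk_length = 5, seed = 1)
#' nu <- non_guided_walk(uni, n_iterations = 500, seed = 1)
#' head(odds_ratio(gw, nu))
#' @export
odds_ratio <- function(guided, non_guided) {
  stopifnot(inherits(guided, "walk_result"), inherits(non_guided, "walk_result"))
  if (!identical(names(guided$F), names(non_guided$F))) {
    stopf("guided and non-guided runs cover different pathway sets")
  }
  if (guided$Ft <= 0 || non_guided$Ft <= 0) {
    stopf("total visit count is zero; run the walks with n_iterations > 0")
  }
  pg <- guided$F / guided$Ft
  pu <- non_guided$F / non_guided$Ft
  odds <- function(p) ifelse(p >= 1, Inf, p / (1 - p))
  og <- odds(pg); ou <- odds(pu)
  # P_G = 1 is +Inf by contract (even against P_U = 1); both modes
  # unvisited is undefined
  or <- ifelse(pg >= 1, Inf,
               ifelse(og == 0 & ou == 0, NA_real_,
                      ifelse(ou == 0, Inf, og / ou)))
  out <- data.frame(pathway = names(guided$F),
                    F_guided = as.integer(guided$F),
                    F_non_guided = as.integer(non_guided$F),
                    P_guided = unname(pg), P_non_guided = unname(pu),
                    OR = unname(or), relevant = unname(or >= 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$OR, out$pathway), ]
  rownames(out) <- NULL
  class(out) <- c("or_table", "data.frame")
  out
}

#' Annotated pathway network for odds-ratio visualisation
#'
#' Builds the pathway graph restricted to edges the guided walker actually
#' traversed, annotated per node with `OR`, a 4-level `size_bin` (OR
#' quartiles; infinite ORs in the top bin), a `top20` colour flag (ties at
#' rank 20 broken by pathway id) and a `cluster` id from edge-betweenness
#' communities; edges carry the traversal count.
#'
#' @param or_table an `or_table` from [odds_ratio()].
#' @param guided the guided `walk_result` supplying edge traversal counts.
#' @param universe the `pathway_universe`.
#' @param top_n number of top-OR pathways to flag (default 20).
#' @return an igraph with the attributes above.
#' @export
rank_pathways <- function(or_table, guided, universe, top_n = 20) {
  stopifnot(inherits(or_table, "or_table"), inherits(guided, "walk_result"),
            inherits(universe, "pathway_universe"))
  pw <- names(guided$F)
  orv <- stats::setNames(or_table$OR, or_table$pathway)[pw]
  fin <- orv[is.finite(orv) & !is.na(orv)]
  if (length(fin) >= 4L) {
    q <- stats::quantile(fin, c(0.25, 0.5, 0.75), names = FALSE)
    bin <- 1L + (orv >= q[1]) + (orv >= q[2]) + (orv >= q[3])
    bin[is.infinite(orv)] <- 4L
  } else {
    bin <- rep(1L, length(orv))
    bin[is.infinite(orv)] <- 4L
  }
  bin[is.na(orv)] <- 1L
  ord <- order(-or_table$OR, or_table$pathway)
  top <- or_table$pathway[ord][seq_len(min(top_n, nrow(or_table)))]

  E <- guided$E
  idx <- which(upper.tri(E) & E > 0, arr.ind = TRUE)
  verts <- data.frame(name = pw, OR = unname(orv), size_bin = unname(bin),
                      top20 = pw %in% top, stringsAsFactors = FALSE)
  if (nrow(idx)) {
    ed <- data.frame(from = pw[idx[, 1]], to = pw[idx[, 2]],
                     traversals = E[idx], stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(verts), name = verts$name, OR = verts$OR,
                              size_bin = verts$size_bin, top20 = verts$top20)
  }
  cl <- cluster_pathways(g)
  igraph::set_vertex_attr(g, "cluster", value = unname(cl[igraph::V(g)$name]))
}
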