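# Guided/non-guided pathway walks and the odds-ratio statistic.

two_path_universe <- function() {
  toy_universe(list(PA = c("g1", "g2"), PB = c("g3", "g4")),
               edges = data.frame(from = "PA", to = "PB"))
}

test_that("a single-pathway universe concentrates all visits on it", {
  uni <- toy_universe(list(PA = c("g1", "g2")))
  g <- graph_of("g1", "g2")
  res <- guided_walk(g, uni, n_iterations = 50, gene_walk_length = 3, seed = 1)
  expect_equal(res$Ft, unname(res$F[["PA"]]))
  expect_gt(res$Ft, 0)
})

test_that("walks are deterministic under a fixed seed and n=0 is rejected", {
  cfg <- small_config(seed = 61)
  uni <- simulate_universe(cfg)
  g <- graph_of(c("g0001", "g0002"), c("g0002", "g0003"))
  r1 <- guided_walk(g, uni, n_iterations = 500, gene_walk_length = 5, seed = 9)
  r2 <- guided_walk(g, uni, n_iterations = 500, gene_walk_length = 5, seed = 9)
  expect_identical(r1$F, r2$F)
  expect_identical(r1$E, r2$E)
  u1 <- non_guided_walk(uni, n_iterations = 500, seed = 9)
  u2 <- non_guided_walk(uni, n_iterations = 500, seed = 9)
  expect_identical(u1$F, u2$F)
  expect_error(non_guided_walk(uni, n_iterations = 0), "positive integer")
})

test_that("visit and edge counts are internally consistent", {
  cfg <- small_config(seed = 62)
  uni <- simulate_universe(cfg)
  g <- graph_of(sprintf("g%04d", 1:19), sprintf("g%04d", 2:20))
  res <- guided_walk(g, uni, n_iterations = 1000, gene_walk_length = 10, seed = 3)
  expect_equal(res$Ft, sum(res$F))
  expect_true(all(res$F >= 0))
  # every edge traversal enters a new pathway; teleports and same-pathway
  # destinations add visits without traversals
  expect_lte(sum(res$E) / 2, res$Ft)
  expect_equal(max(abs(res$E - t(res$E))), 0)
})

test_that("a weightless gene network degenerates to the start-gene membership draw", {
  uni <- two_path_universe()
  # g1,g2 in PA; g3,g4 in PB; zero-weight edges: walker never leaves start
  g <- graph_of(c("g1", "g3"), c("g2", "g4"), weight = 0)
  res <- guided_walk(g, uni, n_iterations = 4000, gene_walk_length = 5, seed = 5)
  # destinations ~ membership of uniform starts: PA and PB equally likely;
  # direct-sampling oracle: binomial(4000, 1/2) for the destination draw.
  # On the two-node pathway graph each move enters exactly one pathway, so
  # F counts destination entries (plus same-pathway stays).
  expect_equal(unname(res$F[["PA"]] / res$Ft), 0.5, tolerance = 0.05)
})

test_that("a guided walk favours the pathway whose genes dominate the network", {
  # genes of PA strongly connected, PB genes isolated in the gene network
  uni <- two_path_universe()
  wins <- 0L
  for (s in 1:10) {
    g <- graph_of(c("g1", "g1", "g2"), c("g2", "g2", "g1"), weight = 10)
    gw <- guided_walk(g, uni, n_iterations = 2000, gene_walk_length = 5, seed = s)
    nu <- non_guided_walk(uni, n_iterations = 2000, seed = s)
    if (gw$F[["PA"]] / gw$Ft > nu$F[["PA"]] / nu$Ft) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("non-guided visits are near-uniform on a vertex-transitive pathway graph", {
  # ring of 12 pathways: every node equivalent
  pw <- sprintf("P%02d", 1:12)
  uni <- toy_universe(setNames(as.list(paste0("g", 1:12)), pw),
                      edges = data.frame(from = pw, to = pw[c(2:12, 1)]))
  res <- non_guided_walk(uni, n_iterations = 50000, seed = 7)
  expect_lt(max(res$F) / min(res$F), 1.3)
})

test_that("odds ratios match hand arithmetic and the two-pathway reciprocity", {
  mk <- function(F, mode) {
    E <- matrix(0L, 2, 2, dimnames = list(names(F), names(F)))
    structure(list(F = F, E = E, Ft = sum(F), mode = mode,
                   n_iterations = sum(F), seed = 1, unmapped = 0L, teleports = 0L),
              class = "walk_result")
  }
  gw <- mk(c(A = 30, B = 10), "guided")
  nu <- mk(c(A = 20, B = 20), "non_guided")
  tab <- odds_ratio(gw, nu)
  # P_A^G = 0.75, P_A^U = 0.5 -> OR_A = (0.75/0.25)/(0.5/0.5) = 3
  expect_equal(tab$OR[tab$pathway == "A"], 3.0, tolerance = 1e-12)
  expect_equal(tab$OR[tab$pathway == "B"], 1 / 3, tolerance = 1e-12)
  expect_equal(prod(tab$OR), 1, tolerance = 1e-12)  # two-pathway reciprocity
  expect_true(tab$relevant[tab$pathway == "A"])
  expect_false(tab$relevant[tab$pathway == "B"])
  expect_equal(sum(tab$P_guided), 1, tolerance = 1e-12)
  expect_equal(sum(tab$P_non_guided), 1, tolerance = 1e-12)
  # equal probabilities -> OR exactly 1
  tab2 <- odds_ratio(mk(c(A = 15, B = 15), "guided"), nu)
  expect_equal(tab2$OR, c(1, 1))
  # degenerate cases: P_U = 0 with P_G > 0 -> Inf; both zero -> NA
  gw3 <- mk(c(A = 10, B = 0), "guided")
  nu3 <- mk(c(A = 10, B = 0), "non_guided")
  tab3 <- odds_ratio(gw3, nu3)
  expect_true(is.infinite(tab3$OR[tab3$pathway == "A"]))  # P = 1 by contract
  expect_true(is.na(tab3$OR[tab3$pathway == "B"]))
  # mismatched pathway sets are an error
  nuX <- mk(c(A = 10, C = 5), "non_guided")
  expect_error(odds_ratio(gw, nuX), "different pathway sets")
})

test_that("ranked pathway network annotates OR bins, top-20 flags and clusters", {
  cfg <- small_config(seed = 63, n_pathways = 40)
  uni <- simulate_universe(cfg)
  g <- graph_of(sprintf("g%04d", 1:9), sprintf("g%04d", 2:10), weight = 1)
  gw <- guided_walk(g, uni, n_iterations = 4000, gene_walk_length = 5, seed = 2)
  nu <- non_guided_walk(uni, n_iterations = 4000, seed = 2)
  tab <- odds_ratio(gw, nu)
  net <- rank_pathways(tab, gw, uni)
  expect_equal(sum(igraph::V(net)$top20), 20)
  # bins partition at the OR quartiles
  orv <- setNames(tab$OR, tab$pathway)
  fin <- orv[is.finite(orv)]
  q <- quantile(fin, c(0.25, 0.5, 0.75), names = FALSE)
  want <- 1L + (orv >= q[1]) + (orv >= q[2]) + (orv >= q[3])
  got <- setNames(igraph::V(net)$size_bin, igraph::V(net)$name)
  expect_equal(got[names(fin)], want[names(fin)])
  # fewer pathways than top_n -> all coloured
  uni2 <- two_path_universe()
  gw2 <- guided_walk(graph_of("g1", "g2"), uni2, n_iterations = 200,
                     gene_walk_length = 3, seed = 1)
  nu2 <- non_guided_walk(uni2, n_iterations = 200, seed = 1)
  net2 <- rank_pathways(odds_ratio(gw2, nu2), gw2, uni2)
  expect_true(all(igraph::V(net2)$top20))
})
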