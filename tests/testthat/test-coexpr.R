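# Mutual information estimation, CLR scoring, edge filtering, merging.

test_that("MI of independent genes is near zero and self-information dominates", {
  set.seed(101)
  x <- rnorm(1000); y <- rnorm(1000)
  mi <- knn_mi(rbind(a = x, b = y), k = 3)
  expect_gte(mi["a", "b"], 0)
  expect_lte(mi["a", "b"], 0.05)
  # duplicated gene: off-diagonal MI(x, x) beats any independent pair
  mi3 <- knn_mi(rbind(a = x, a2 = x, b = y), k = 3)
  expect_gt(mi3["a", "a2"], mi3["a", "b"])
  expect_gt(mi3["a", "a2"], mi3["a2", "b"])
})

test_that("MI matches the bivariate Gaussian closed form", {
  set.seed(102)
  rho <- 0.9
  x <- rnorm(2000); y <- rho * x + sqrt(1 - rho^2) * rnorm(2000)
  mi <- knn_mi(rbind(a = x, b = y), k = 3)
  expect_lt(abs(mi["a", "b"] - (-0.5 * log(1 - rho^2))), 0.1)
})

test_that("MI error against the closed form shrinks from n=200 to n=2000", {
  rho <- 0.8
  true_mi <- -0.5 * log(1 - rho^2)
  err <- sapply(1:20, function(s) {
    set.seed(s)
    sapply(c(200, 2000), function(n) {
      x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      abs(knn_mi(rbind(a = x, b = y), k = 3)["a", "b"] - true_mi)
    })
  })
  expect_lt(median(err[2, ]), median(err[1, ]))
})

test_that("MI handles constant rows by seeded jitter and validates k", {
  set.seed(103)
  x <- rbind(a = rnorm(30), b = rep(1, 30))
  mi1 <- knn_mi(x, k = 3)
  mi2 <- knn_mi(x, k = 3)
  expect_identical(mi1, mi2)  # jitter is seeded
  expect_identical(attr(mi1, "jittered"), "b")
  expect_error(knn_mi(x, k = 30), "smaller than the number of samples")
})

test_that("CLR matches hand arithmetic on a 3x3 matrix with one strong pair", {
  mi <- matrix(c(0, 0.8, 0.1,
                 0.8, 0, 0.2,
                 0.1, 0.2, 0), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sc <- clr_transform(mi)
  # hand arithmetic, off-diagonal row statistics with (n-1) sd:
  # row a: values (0.8, 0.1), mu=0.45, sd=0.4949747; z_a(b)=(0.8-0.45)/sd=0.7071068
  # row b: values (0.8, 0.2), mu=0.50, sd=0.4242641; z_b(a)=(0.8-0.50)/sd=0.7071068
  z_ab <- (0.8 - 0.45) / sd(c(0.8, 0.1))
  z_ba <- (0.8 - 0.50) / sd(c(0.8, 0.2))
  expect_equal(sc["a", "b"], sqrt(z_ab^2 + z_ba^2), tolerance = 1e-12)
  # z_a(c) and z_c(a) both below their row means -> clamped to 0
  expect_equal(sc["a", "c"], 0)
})

test_that("CLR of a constant matrix is zero and relabeling is equivariant", {
  m <- matrix(0.3, 4, 4); diag(m) <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  expect_true(all(clr_transform(m) == 0))

  set.seed(104)
  x <- matrix(rnorm(5 * 40), nrow = 5, dimnames = list(letters[1:5], NULL))
  mi <- knn_mi(x)
  perm <- c(3, 1, 5, 2, 4)
  sc1 <- clr_transform(mi)[perm, perm]
  sc2 <- clr_transform(mi[perm, perm])
  expect_equal(sc1, sc2, tolerance = 1e-12)
  expect_lt(max(abs(sc2 - t(sc2))), 1e-12)  # symmetry
})

test_that("edge filter is boundary-inclusive and matches a brute-force filter", {
  sc <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sc["a", "b"] <- sc["b", "a"] <- exp(1)   # ln = 1 exactly -> retained
  sc["a", "c"] <- sc["c", "a"] <- 1.0      # ln = 0 -> dropped
  nw <- build_stage_network(sc, threshold = 1, stage = "pre")
  ed <- igraph::as_data_frame(nw$graph)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$from, ed$to), c("a", "b"))
  expect_equal(ed$weight, exp(1))
  expect_equal(ed$log_weight, 1)

  # 10-gene random score matrix vs exhaustive pair filter
  set.seed(105)
  m <- matrix(0, 10, 10, dimnames = list(letters[1:10], letters[1:10]))
  vals <- runif(45, 0, 6)
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  nw <- build_stage_network(m, threshold = 1)
  got <- igraph::as_data_frame(nw$graph)
  got_keys <- sort(paste(pmin(got$from, got$to), pmax(got$from, got$to)))
  want <- which(upper.tri(m) & log(m) >= 1, arr.ind = TRUE)
  want_keys <- sort(paste(letters[want[, 1]], letters[want[, 2]]))
  expect_identical(got_keys, want_keys)

  expect_warning(build_stage_network(matrix(0.5, 2, 2) - diag(0.5, 2)),
                 "no edges")
})

test_that("merging assigns memberships and counts correctly", {
  n1 <- build_stage_network(
    {m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
     m["a","b"] <- m["b","a"] <- 10; m["b","c"] <- m["c","b"] <- 10; m}, stage = "pre")
  n2 <- build_stage_network(
    {m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
     m["a","b"] <- m["b","a"] <- 8; m["c","d"] <- m["d","c"] <- 8; m}, stage = "symp")
  mg <- merge_stage_networks(n1, n2)
  expect_equal(mg$node_counts, c(pre = 0, symp = 1, both = 3))  # d only in symp
  expect_equal(mg$edge_counts, c(pre = 1, symp = 1, both = 1))
  ed <- igraph::as_data_frame(mg$graph)
  ab <- ed[ed$from %in% c("a","b") & ed$to %in% c("a","b"), ]
  expect_equal(ab$membership, "both")
  expect_equal(ab$weight_pre, 10)
  expect_equal(ab$weight_symp, 8)

  # identical networks -> everything "both"; disjoint -> no "both"
  mg2 <- merge_stage_networks(n1, n1)
  expect_equal(sum(mg2$node_counts[c("pre", "symp")]), 0)
  n3 <- build_stage_network(
    {m <- matrix(0, 2, 2, dimnames = list(c("x","y"), c("x","y")))
     m["x","y"] <- m["y","x"] <- 9; m}, stage = "symp")
  mg3 <- merge_stage_networks(n1, n3)
  expect_equal(mg3$node_counts[["both"]], 0)
})

test_that("planted modules are recovered at far above the background rate", {
  cfg <- small_config(seed = 31)
  ds <- simulate_expression(cfg)
  tab <- select_top_k(fit_de(ds, "pre"))
  sel <- attr(tab, "selected_genes")
  nw <- stage_coexpression(ds, sel, "pre")
  g <- nw$graph
  mod <- intersect(ds$truth$modules[[1]], igraph::V(g)$name)
  ed <- igraph::as_data_frame(g)
  in_mod <- ed$from %in% mod & ed$to %in% mod
  rate_mod <- sum(in_mod) / choose(length(mod), 2)
  n_other <- length(setdiff(sel, unlist(ds$truth$modules)))
  other <- setdiff(igraph::V(g)$name, unlist(ds$truth$modules))
  rate_bg <- sum(ed$from %in% other & ed$to %in% other) / choose(n_other, 2)
  expect_gt(rate_mod, 5 * max(rate_bg, 1e-6))
})
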