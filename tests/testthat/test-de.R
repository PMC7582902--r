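# Differential expression: moderated t, selection, multiplicity correction.

make_dataset <- function(mat, groups) {
  structure(list(matrix = mat, gene_ids = rownames(mat),
                 sample_groups = groups, truth = NULL),
            class = "expression_dataset")
}

test_that("ordinary t equals a hand-rolled two-sample equal-variance t", {
  set.seed(42)
  n1 <- 6; n2 <- 5
  mat <- matrix(rnorm(200 * (n1 + n2)), nrow = 200,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
  colnames(mat) <- c(sprintf("c%d", 1:n1), sprintf("p%d", 1:n2))
  groups <- setNames(c(rep("control", n1), rep("pre", n2)), colnames(mat))
  tab <- fit_de(make_dataset(mat, groups), "pre")
  # independent oracle: textbook pooled-variance two-sample t per gene
  oracle <- apply(mat, 1, function(x) {
    a <- x[1:n1]; b <- x[(n1 + 1):(n1 + n2)]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
    (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  })
  expect_equal(tab$t_ordinary, unname(oracle), tolerance = 1e-10)
})

test_that("forcing the prior df to zero recovers the ordinary t exactly", {
  cfg <- small_config(seed = 21)
  ds <- simulate_expression(cfg)
  tab <- fit_de(ds, "symp", df_prior = 0)
  expect_identical(tab$t_moderated, tab$t_ordinary)
  expect_identical(tab$s2_post, tab$s2)
})

test_that("moderation matches limma::eBayes on simulated data", {
  cfg <- small_config(seed = 22)
  ds <- simulate_expression(cfg)
  tab <- fit_de(ds, "pre")
  idx <- ds$sample_groups %in% c("control", "pre")
  design <- stats::model.matrix(~ factor(ds$sample_groups[idx],
                                         levels = c("control", "pre")))
  fit <- limma::eBayes(limma::lmFit(ds$matrix[, idx], design))
  expect_equal(unname(fit$df.prior), tab$df_prior[1], tolerance = 1e-8)
  expect_equal(unname(fit$t[, 2]), tab$t_moderated, tolerance = 1e-8)
  expect_equal(unname(fit$p.value[, 2]), tab$p_value, tolerance = 1e-8)
  expect_equal(unname(fit$s2.post), tab$s2_post, tolerance = 1e-8)
})

test_that("genes identical across groups get logFC 0 and p-value 1", {
  mat <- matrix(5, nrow = 10, ncol = 8,
                dimnames = list(sprintf("g%02d", 1:10),
                                c(sprintf("c%d", 1:4), sprintf("s%d", 1:4))))
  groups <- setNames(c(rep("control", 4), rep("symp", 4)), colnames(mat))
  tab <- fit_de(make_dataset(mat, groups), "symp")
  expect_true(all(tab$logFC == 0))
  expect_true(all(tab$p_value == 1))
  expect_true(all(tab$var_floored))
})

test_that("insufficient replication is an error", {
  mat <- matrix(rnorm(30), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), c("c1", "c2", "p1")))
  groups <- setNames(c("control", "control", "pre"), colnames(mat))
  expect_error(fit_de(make_dataset(mat, groups), "pre"), "at least 2 samples")
})

test_that("moderated t shrinks relative to ordinary t on null genes", {
  cfg <- small_config(seed = 23, de_effect = 0,
                      module_spec = list(
                        list(size = 20, loading = 0, stages_active = "control"),
                        list(size = 20, loading = 0, stages_active = "control")))
  ds <- simulate_expression(cfg)
  tab <- fit_de(ds, "pre")
  expect_lte(var(tab$t_moderated), var(tab$t_ordinary))
})

test_that("selection respects k, alpha, direction and the documented tie-break", {
  # 5-gene fixture with a deliberate p tie; oracle = exhaustive sort
  tab <- data.frame(
    gene_id = c("gA", "gB", "gC", "gD", "gE"),
    logFC = c(1.0, 2.0, -1.5, 0.5, -0.2),
    p_value = c(0.01, 0.01, 0.002, 0.20, 0.01),
    stringsAsFactors = FALSE
  )
  tab$t_ordinary <- tab$t_moderated <- sign(tab$logFC)
  tab$s2 <- tab$s2_post <- 1; tab$df_residual <- 10; tab$df_prior <- 2
  tab$p_adjusted <- bh_adjust(tab$p_value)
  tab$selected <- FALSE
  tab$direction <- ifelse(tab$logFC > 0, "over", "under")
  tab$var_floored <- FALSE
  class(tab) <- c("deg_table", "data.frame")

  sel1 <- select_top_k(tab, k = 1)
  # over candidates: gA (p=.01,|1|), gB (p=.01,|2|) -> tie broken by larger |logFC|
  expect_identical(tab$gene_id[sel1$selected & sel1$direction == "over"], "gB")
  # under: gC (p=.002) beats gE (p=.01)
  expect_identical(tab$gene_id[sel1$selected & sel1$direction == "under"], "gC")

  sel <- select_top_k(tab, k = 10, alpha = 0.05)
  expect_setequal(attr(sel, "selected_genes"), c("gA", "gB", "gC", "gE"))  # gD fails alpha
  # saturation: only eligible genes selected even when k is large
  expect_equal(sum(sel$selected), 4)
})

test_that("selection recovers planted genes at strong effect and replication", {
  cfg <- small_config(seed = 24, de_effect = 2, noise_sd = 0.5,
                      n_samples_per_group = c(control = 12, pre = 12, symp = 12))
  ds <- simulate_expression(cfg)
  for (stage in c("pre", "symp")) {
    sel <- select_top_k(fit_de(ds, stage), k = 150)
    planted <- unlist(ds$truth$de[[stage]], use.names = FALSE)
    recovered <- mean(planted %in% attr(sel, "selected_genes"))
    expect_gte(recovered, 0.95)
  }
})

test_that("BH adjustment matches hand computations and validates its domain", {
  expect_equal(bh_adjust(0.01), 0.01)
  # step-up by hand: p_(i) * n / i, then cumulative minimum from the top
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.5)
  sp <- sort(p)
  adj_sorted <- rev(cummin(rev(sp * length(p) / seq_along(sp))))
  expect_equal(bh_adjust(p), adj_sorted[rank(p)])
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.1)), "\\[0, 1\\]")
})
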