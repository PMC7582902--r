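# Stagewise differential expression: two-group linear model (stage vs
# control) with empirical-Bayes variance moderation and top-k over/under
# selection.

#' Benjamini-Hochberg adjustment with domain validation
#'
#' Thin validating wrapper over `stats::p.adjust(method = "BH")` (step-up
#' with monotonicity enforcement, order-preserving).
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stopf("p must be numeric")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stopf("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Invert the trigamma function
#'
#' Newton iteration on `trigamma(x) = y`; used to solve the moment equation
#' for the prior degrees of freedom of the scaled-F variance model.
#' @noRd
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Moment-matching fit of the scaled-F model for gene variances
#'
#' Models sample variances s2 ~ s2_true * chi^2_d / d with an inverse-chi^2
#' prior on s2_true (prior df d0, scale s0^2), and estimates (d0, s0^2) by
#' matching the mean and variance of log(s2). If the moment equations have
#' no positive solution, d0 = Inf (full shrinkage to the common variance).
#' @noRd
fit_variance_prior <- function(s2, df) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 2L) return(list(df_prior = Inf, s2_prior = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1L) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Stagewise moderated differential expression
#'
#' Fits, per gene, the two-group comparison of one disease stage against
#' controls: logFC is the difference of group means (log2 units), the
#' pooled residual variance is moderated towards an empirical-Bayes prior
#' fitted across genes by moment-matching the log sample variances
#' (scaled-F model), and the moderated t-statistic is referred to a t
#' distribution with `df_residual + df_prior` degrees of freedom
#' (two-sided).
#'
#' Zero-variance genes are floored at `.Machine$double.eps` times the
#' squared gene mean and flagged in `var_floored`; a gene identical across
#' groups reports logFC 0 and p-value 1.
#'
#' @param dataset an `expression_dataset`.
#' @param stage `"pre"` or `"symp"`; compared against `"control"`.
#' @param df_prior optional override of the prior degrees of freedom
#'   (`0` reproduces the ordinary t-test exactly; `Inf` shrinks fully to the
#'   prior variance; `NULL`, the default, estimates it from the data).
#' @return a `deg_table` data.frame with one row per gene: `gene_id`,
#'   `logFC`, `t_ordinary`, `s2`, `s2_post`, `t_moderated`, `df_residual`,
#'   `df_prior`, `p_value`, `p_adjusted`, `selected`, `direction`,
#'   `var_floored`. Selection flags are filled by [select_top_k()].
#' @examples
#' cfg <- sim_config(n_genes = 200, n_de_per_direction = c(pre = 40, symp = 40),
#'                   module_spec = list(), rewired_hub = NULL, seed = 1)
#' ds <- simulate_expression(cfg)
#' tab <- select_top_k(fit_de(ds, "pre"), k = 40)
#' head(tab[tab$selected, c("gene_id", "logFC", "p_value", "direction")])
#' @export
fit_de <- function(dataset, stage = c("pre", "symp"), df_prior = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  stage <- match.arg(stage)
  grp <- dataset$sample_groups
  idx1 <- which(grp == "control")
  idx2 <- which(grp == stage)
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stopf("need at least 2 samples per group (control: %d, %s: %d)",
          length(idx1), stage, length(idx2))
  }
  m1 <- dataset$matrix[, idx1, drop = FALSE]
  m2 <- dataset$matrix[, idx2, drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  logFC <- mu2 - mu1
  ss <- rowSums((m1 - mu1)^2) + rowSums((m2 - mu2)^2)
  df_resid <- n1 + n2 - 2L
  s2 <- ss / df_resid
  floor_val <- pmax(.Machine$double.eps * rowMeans(dataset$matrix)^2, 1e-300)
  var_floored <- s2 < floor_val
  s2 <- pmax(s2, floor_val)

  cfac <- 1 / n1 + 1 / n2
  t_ord <- logFC / sqrt(s2 * cfac)

  if (is.null(df_prior)) {
    prior <- fit_variance_prior(s2[!var_floored], df_resid)
  } else {
    prior <- list(df_prior = df_prior,
                  s2_prior = mean(s2[!var_floored]))
  }
  d0 <- prior$df_prior
  if (is.infinite(d0)) {
    s2_post <- rep(prior$s2_prior, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- df_resid
  } else {
    s2_post <- (d0 * prior$s2_prior + df_resid * s2) / (d0 + df_resid)
    df_total <- df_resid + d0
  }
  t_mod <- logFC / sqrt(s2_post * cfac)
  t_mod[logFC == 0] <- 0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod)) else 2 * stats::pt(-abs(t_mod), df = df_total)

  out <- data.frame(
    gene_id = dataset$gene_ids,
    logFC = logFC,
    t_ordinary = t_ord,
    s2 = s2,
    s2_post = s2_post,
    t_moderated = t_mod,
    df_residual = df_resid,
    df_prior = d0,
    p_value = p,
    p_adjusted = bh_adjust(p),
    selected = FALSE,
    direction = ifelse(logFC > 0, "over", ifelse(logFC < 0, "under", NA_character_)),
    var_floored = var_floored,
    stringsAsFactors = FALSE,
    row.names = dataset$gene_ids
  )
  attr(out, "stage") <- stage
  attr(out, "s2_prior") <- prior$s2_prior
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Flag the top-k over- and under-expressed genes
#'
#' Ranks genes by ascending p-value within each direction (over: logFC > 0;
#' under: logFC < 0), restricted to `p_value < alpha`, and flags at most `k`
#' per direction. Ties are broken deterministically by (p-value, |logFC|
#' descending, gene id ascending). Fewer than `k` eligible genes in a
#' direction selects all of them.
#'
#' @param table a `deg_table` from [fit_de()].
#' @param k maximum genes flagged per direction.
#' @param alpha raw p-value eligibility threshold.
#' @return the table with `selected` updated; the selected gene ids are
#'   available via `attr(, "selected_genes")`.
#' @export
select_top_k <- function(table, k = 150, alpha = 0.05) {
  stopifnot(inherits(table, "deg_table"))
  assert_scalar_count(k, "k")
  table$selected <- FALSE
  ord <- order(table$p_value, -abs(table$logFC), table$gene_id)
  sel <- character(0)
  for (dir in c("over", "under")) {
    cand <- ord[!is.na(table$direction[ord]) & table$direction[ord] == dir &
                  table$p_value[ord] < alpha]
    take <- cand[seq_len(min(k, length(cand)))]
    table$selected[take] <- TRUE
    sel <- c(sel, table$gene_id[take])
  }
  attr(table, "selected_genes") <- sel
  attr(table, "k") <- k
  attr(table, "alpha") <- alpha
  table
}
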