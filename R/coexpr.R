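# Gene co-expression networks: Kraskov k-nearest-neighbour mutual
# information, CLR background correction, log-weight edge filter, and the
# merged (union) two-stage view.

#' k-nearest-neighbour mutual information matrix
#'
#' Kraskov-Stoegbauer-Grassberger (KSG-1) estimator between every pair of
#' rows of `x`: for each sample the max-norm distance to its k-th nearest
#' neighbour in the joint (x_i, x_j) space sets a ball, marginal neighbour
#' counts inside the ball enter the digamma formula
#' `MI = digamma(k) + digamma(n) - mean(digamma(nx+1) + digamma(ny+1))`.
#' Negative estimates are clamped to 0 and the diagonal is 0 by convention.
#'
#' Constant rows (zero range) are jittered with seeded uniform noise of
#' amplitude `1e-10` times the matrix range so that distances are defined;
#' affected genes are recorded in the `jittered` attribute.
#'
#' @param x numeric matrix, genes (variables) as rows, samples as columns.
#' @param k number of neighbours (default 3, the common choice for this
#'   estimator family).
#' @param jitter_seed seed for the constant-row jitter.
#' @return symmetric nonnegative MI matrix with zero diagonal.
#' @useDynLib stagenet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @export
knn_mi <- function(x, k = 3, jitter_seed = 0) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("x must be a numeric matrix")
  n <- ncol(x)
  p <- nrow(x)
  assert_scalar_count(k, "k")
  if (k >= n) stopf("k (%d) must be smaller than the number of samples (%d)", k, n)
  if (n < k + 2L) stopf("need at least k + 2 samples")

  rng <- range(x)
  const_rows <- which(apply(x, 1L, function(r) diff(range(r)) == 0))
  if (length(const_rows)) {
    amp <- 1e-10 * max(diff(rng), 1)
    x[const_rows, ] <- x[const_rows, , drop = FALSE] +
      with_seed(jitter_seed, matrix(stats::runif(length(const_rows) * n, -amp, amp),
                                    nrow = length(const_rows)))
  }

  mi <- knn_mi_cpp(x, as.integer(k))
  dimnames(mi) <- list(rownames(x), rownames(x))
  attr(mi, "jittered") <- rownames(x)[const_rows] %||% const_rows
  mi
}

#' Context likelihood of relatedness (CLR) transform
#'
#' Standardises each MI value against its row backgrounds:
#' `z_i(j) = max(0, (MI_ij - mu_i) / sigma_i)` with `mu_i`, `sigma_i` the
#' mean and (n-1)-denominator standard deviation of row i's off-diagonal
#' entries, and `score_ij = sqrt(z_i(j)^2 + z_j(i)^2)`. Rows with zero
#' spread contribute z = 0.
#'
#' @param mi square symmetric nonnegative matrix from [knn_mi()].
#' @return symmetric nonnegative score matrix with zero diagonal.
#' @export
clr_transform <- function(mi) {
  if (!is.matrix(mi) || nrow(mi) != ncol(mi)) stopf("mi must be a square matrix")
  if (any(mi < 0)) stopf("mi must be nonnegative")
  if (max(abs(mi - t(mi))) > 1e-8) stopf("mi must be symmetric")
  p <- nrow(mi)
  if (p < 2L) return(mi * 0)
  off <- !diag(TRUE, p)
  mu <- vapply(seq_len(p), function(i) mean(mi[i, off[i, ]]), numeric(1))
  sig <- vapply(seq_len(p), function(i) stats::sd(mi[i, off[i, ]]), numeric(1))
  z <- (mi - mu) / ifelse(sig > 0, sig, Inf)  # row-wise standardisation
  z[z < 0] <- 0
  z[!is.finite(z)] <- 0
  score <- sqrt(z^2 + t(z)^2)
  diag(score) <- 0
  dimnames(score) <- dimnames(mi)
  score
}

#' Build a stage network from CLR scores with the log-weight filter
#'
#' Retains edge (i, j) iff `log(score_ij) >= threshold` (natural log by
#' default; boundary inclusive, so "1 and more" keeps scores >= e).
#' Vertices are the genes incident to at least one retained edge.
#'
#' @param scores symmetric score matrix from [clr_transform()].
#' @param threshold log-weight cutoff (default 1).
#' @param stage label stored on the network.
#' @param log_base base of the logarithm used for filtering/export.
#' @return a `stage_network`: list with `stage`, `graph` (igraph with edge
#'   attributes `weight` = CLR score and `log_weight`), `threshold`.
#' @export
build_stage_network <- function(scores, threshold = 1, stage = "stage",
                                log_base = exp(1)) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) stopf("scores must be square")
  ids <- rownames(scores) %||% as.character(seq_len(nrow(scores)))
  keep <- which(upper.tri(scores) & log(scores, base = log_base) >= threshold,
                arr.ind = TRUE)
  if (nrow(keep) == 0L) {
    warnf("no edges pass log(score) >= %g; returning an empty network", threshold)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    w <- scores[keep]
    ed <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                     weight = w, log_weight = log(w, base = log_base),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                       vertices = sort(unique(c(ed$from, ed$to))))
  }
  structure(list(stage = stage, graph = g, threshold = threshold),
            class = "stage_network")
}

#' @export
print.stage_network <- function(x, ...) {
  cat(sprintf("stage_network '%s': %d genes, %d edges (log-weight >= %g)\n",
              x$stage, igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' One-call co-expression network for a stage
#'
#' Restricts the expression matrix to the given genes and to the stage's
#' samples pooled with controls (the network contrasts controls versus that
#' stage), then runs [knn_mi()], [clr_transform()] and
#' [build_stage_network()].
#'
#' @param dataset an `expression_dataset`.
#' @param genes gene ids to include (typically the selected DEGs).
#' @param stage `"pre"` or `"symp"`.
#' @param k MI neighbour count.
#' @param threshold log-weight cutoff.
#' @return a `stage_network`.
#' @export
stage_coexpression <- function(dataset, genes, stage = c("pre", "symp"),
                               k = 3, threshold = 1) {
  stage <- match.arg(stage)
  stopifnot(inherits(dataset, "expression_dataset"))
  genes <- intersect(genes, dataset$gene_ids)
  if (length(genes) < 2L) stopf("need at least 2 genes to build a network")
  cols <- dataset$sample_groups %in% c("control", stage)
  mi <- knn_mi(dataset$matrix[genes, cols, drop = FALSE], k = k)
  build_stage_network(clr_transform(mi), threshold = threshold, stage = stage)
}

#' Merge two stage networks into one attributed union network
#'
#' Union graph whose nodes and edges carry a `membership` attribute in
#' \{`pre`, `symp`, `both`\}; per-stage CLR weights are preserved as
#' `weight_pre` / `weight_symp`.
#'
#' @param pre,symp `stage_network` objects (stages "pre" and "symp").
#' @return a `merged_network`: list with `graph`, `node_counts` and
#'   `edge_counts` (named vectors over pre/symp/both).
#' @export
merge_stage_networks <- function(pre, symp) {
  stopifnot(inherits(pre, "stage_network"), inherits(symp, "stage_network"))
  ed_p <- igraph::as_data_frame(pre$graph, what = "edges")
  ed_s <- igraph::as_data_frame(symp$graph, what = "edges")
  key <- function(d) {
    if (nrow(d) == 0L) return(character(0))
    ce <- canonical_edges(d$from, d$to)
    paste(ce$from, ce$to, sep = "\r")
  }
  kp <- key(ed_p); ks <- key(ed_s)
  all_keys <- union(kp, ks)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  in_p <- all_keys %in% kp
  in_s <- all_keys %in% ks
  wp <- stats::setNames(ed_p$weight, kp)[all_keys]
  ws <- stats::setNames(ed_s$weight, ks)[all_keys]
  edge_mem <- ifelse(in_p & in_s, "both", ifelse(in_p, "pre", "symp"))
  nodes_p <- igraph::V(pre$graph)$name
  nodes_s <- igraph::V(symp$graph)$name
  all_nodes <- sort(union(nodes_p, nodes_s))
  node_mem <- ifelse(all_nodes %in% nodes_p & all_nodes %in% nodes_s, "both",
                     ifelse(all_nodes %in% nodes_p, "pre", "symp"))
  if (length(all_keys)) {
    ed <- data.frame(from = from, to = to, membership = edge_mem,
                     weight_pre = unname(wp), weight_symp = unname(ws),
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                       vertices = data.frame(name = all_nodes,
                                                             membership = node_mem))
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (length(all_nodes)) {
      g <- igraph::add_vertices(g, length(all_nodes), name = all_nodes,
                                membership = node_mem)
    }
  }
  counts <- function(mem) {
    out <- c(pre = sum(mem == "pre"), symp = sum(mem == "symp"),
             both = sum(mem == "both"))
    out
  }
  structure(list(graph = g, node_counts = counts(node_mem),
                 edge_counts = counts(edge_mem)),
            class = "merged_network")
}

#' @export
print.merged_network <- function(x, ...) {
  cat(sprintf("merged_network: %d nodes (pre %d / symp %d / both %d), %d edges\n",
              igraph::vcount(x$graph), x$node_counts[["pre"]],
              x$node_counts[["symp"]], x$node_counts[["both"]],
              igraph::ecount(x$graph)))
  invisible(x)
}
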