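# Plain-text interchange: TSV matrices, GMT gene sets, edge lists,
# pathway-metabolite maps. All files are UTF-8, tab-separated, '#' comments.

#' Write simulated inputs to plain-text fixture files
#'
#' Emits `expression.tsv` (genes as rows, header = sample ids),
#' `groups.tsv`, `memberships.gmt`, `pathway_edges.tsv` and
#' `metabolite_map.tsv` into `out_dir`. Numeric values are written with 17
#' significant digits so the files round-trip losslessly through
#' [read_fixtures()]. Pathways with an empty metabolite set are omitted from
#' the metabolite map.
#'
#' @param dataset an `expression_dataset`.
#' @param universe a `pathway_universe`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixtures <- function(dataset, universe, out_dir) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(universe, "pathway_universe"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  paths <- c(expression = file.path(out_dir, "expression.tsv"),
             groups = file.path(out_dir, "groups.tsv"),
             gmt = file.path(out_dir, "memberships.gmt"),
             pathway_edges = file.path(out_dir, "pathway_edges.tsv"),
             metabolite_map = file.path(out_dir, "metabolite_map.tsv"))

  m <- dataset$matrix
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), paths[["expression"]])

  writeLines(c("sample_id\tgroup",
               paste(names(dataset$sample_groups), dataset$sample_groups, sep = "\t")),
             paths[["groups"]])

  writeLines(vapply(names(universe$memberships), function(p) {
    paste(c(p, "synthetic", universe$memberships[[p]]), collapse = "\t")
  }, character(1)), paths[["gmt"]])

  ed <- igraph::as_data_frame(universe$pathway_graph, what = "edges")
  if (is.null(ed$weight)) ed$weight <- 1
  writeLines(c("source\ttarget\tweight",
               sprintf("%s\t%s\t%.17g", ed$from, ed$to, ed$weight)),
             paths[["pathway_edges"]])

  met <- universe$metabolite_map
  met <- met[vapply(met, length, integer(1)) > 0L]
  lines <- unlist(lapply(names(met), function(p) paste(p, met[[p]], sep = "\t")),
                  use.names = FALSE)
  writeLines(c("pathway\tmetabolite_id", lines %||% character(0)),
             paths[["metabolite_map"]])

  invisible(paths)
}

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Read an expression matrix and sample group map from TSV
#'
#' @param expression_path TSV with genes as rows; first column `gene_id`,
#'   remaining columns one per sample.
#' @param groups_path TSV with columns `sample_id` and `group`
#'   (control/pre/symp).
#' @return an `expression_dataset` (with `truth = NULL`).
#' @export
read_expression <- function(expression_path, groups_path) {
  lines <- read_tsv_lines(expression_path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(length(samples))))
  dimnames(mat) <- list(ids, samples)

  glines <- read_tsv_lines(groups_path)[-1]
  gp <- strsplit(glines, "\t", fixed = TRUE)
  groups <- stats::setNames(vapply(gp, `[[`, character(1), 2L),
                            vapply(gp, `[[`, character(1), 1L))
  if (!all(colnames(mat) %in% names(groups))) {
    stopf("samples missing from groups file: %s",
          paste(setdiff(colnames(mat), names(groups)), collapse = ", "))
  }
  structure(list(matrix = mat, gene_ids = ids,
                 sample_groups = groups[colnames(mat)], truth = NULL),
            class = "expression_dataset")
}

#' Read gene-set memberships in GMT format
#'
#' Each line is `set<TAB>description<TAB>gene1<TAB>gene2...`.
#' @param path GMT file.
#' @return named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  parts <- strsplit(read_tsv_lines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Read a weighted undirected edge list (`source  target  weight`)
#'
#' @param path edge-list TSV; a `source/target/weight` header is skipped.
#' @param vertices optional vector of vertex names to include even if
#'   isolated.
#' @return an undirected igraph with a `weight` edge attribute.
#' @export
read_edge_list <- function(path, vertices = NULL) {
  lines <- read_tsv_lines(path)
  if (length(lines) && grepl("^source\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (!is.null(vertices)) g <- igraph::add_vertices(g, length(vertices), name = vertices)
    return(g)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ed <- data.frame(from = vapply(parts, `[[`, character(1), 1L),
                   to = vapply(parts, `[[`, character(1), 2L),
                   weight = vapply(parts, function(p) {
                     if (length(p) >= 3L) as.numeric(p[3]) else 1
                   }, numeric(1)),
                   stringsAsFactors = FALSE)
  verts <- sort(unique(c(ed$from, ed$to, vertices)))
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = verts)
}

#' Read a pathway-to-metabolite map (`pathway<TAB>metabolite_id` per row)
#'
#' @param path TSV file; a header row is skipped.
#' @return named list: pathway -> sorted vector of metabolite ids.
#' @export
read_metabolite_map <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) && grepl("^pathway\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  pw <- vapply(parts, `[[`, character(1), 1L)
  met <- vapply(parts, `[[`, character(1), 2L)
  lapply(split(met, factor(pw, levels = unique(pw))), function(x) sort(unique(x)))
}

#' Read a full fixture directory back into dataset + universe
#'
#' Inverse of [write_fixtures()].
#' @param dir directory holding the files written by [write_fixtures()].
#' @return list with `dataset` and `universe`.
#' @export
read_fixtures <- function(dir) {
  dataset <- read_expression(file.path(dir, "expression.tsv"),
                             file.path(dir, "groups.tsv"))
  memberships <- read_gmt(file.path(dir, "memberships.gmt"))
  g <- read_edge_list(file.path(dir, "pathway_edges.tsv"),
                      vertices = names(memberships))
  universe <- structure(list(pathway_graph = g,
                             memberships = memberships,
                             metabolite_map = read_metabolite_map(file.path(dir, "metabolite_map.tsv"))),
                        class = "pathway_universe")
  list(dataset = dataset, universe = universe)
}
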