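#' Read and write the pipeline's delimited text formats
#'
#' All artifacts are tab-delimited text with a header row. Expression tables
#' have an `id` column (node or miRNA identifiers) followed by one column per
#' sample; group maps have columns `sample`, `group`; edge lists have columns
#' `source`, `target`, `edge_type` with `edge_type` in `ppi`, `tf`, `mirna`.
#' Doubles are written with 17 significant digits so that write/read
#' round-trips are bit-exact.
#'
#' @param mat Numeric matrix with rownames (ids) and colnames (samples).
#' @param path File path.
#' @return `read_*` functions return the parsed object; `write_*` functions
#'   return `path` invisibly.
#' @name gen_io
NULL

#' @rdname gen_io
#' @export
write_expression_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_full(df, path)
}

#' @rdname gen_io
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_plain(path)
  if (names(df)[1] != "id") stop("expression table must start with `id`",
                                 call. = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  m
}

#' @rdname gen_io
#' @param groups Named character vector (sample -> group).
#' @export
write_group_map <- function(groups, path) {
  write_tsv_full(data.frame(sample = names(groups), group = unname(groups),
                            stringsAsFactors = FALSE), path)
}

#' @rdname gen_io
#' @export
read_group_map <- function(path) {
  df <- read_tsv_plain(path, colClasses = "character")
  stats::setNames(df$group, df$sample)
}

#' @rdname gen_io
#' @param x For [write_edge_list()], a `candidate_gen` or a data frame with
#'   columns `source`, `target`, `edge_type`.
#' @export
write_edge_list <- function(x, path) {
  write_tsv_full(as_edge_table(x), path)
}

#' @rdname gen_io
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_plain(path, colClasses = "character")
  need <- c("source", "target", "edge_type")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' Flatten a candidate network to a single typed edge table
#'
#' @param x A `candidate_gen` or an already-flat edge data frame.
#' @return Data frame with columns `source`, `target`, `edge_type`.
#' @export
as_edge_table <- function(x) {
  if (inherits(x, "candidate_gen")) {
    rbind(
      data.frame(source = x$ppi_edges$node_a, target = x$ppi_edges$node_b,
                 edge_type = rep("ppi", nrow(x$ppi_edges)),
                 stringsAsFactors = FALSE),
      data.frame(source = x$tf_edges$tf, target = x$tf_edges$target,
                 edge_type = rep("tf", nrow(x$tf_edges)),
                 stringsAsFactors = FALSE),
      data.frame(source = x$mirna_edges$mirna, target = x$mirna_edges$target,
                 edge_type = rep("mirna", nrow(x$mirna_edges)),
                 stringsAsFactors = FALSE)
    )
  } else {
    df <- as.data.frame(x)
    need <- c("source", "target", "edge_type")
    if (!all(need %in% names(df))) {
      stop("edge table must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df[need]
  }
}

#' Write or read a whole cohort dataset as a set of delimited files
#'
#' Writes `<prefix>_protein.tsv`, `<prefix>_gene.tsv`, `<prefix>_mirna.tsv`
#' and `<prefix>_groups.tsv` under `dir`.
#'
#' @param data A [cohort_dataset()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix, typically the cohort label.
#' @return [write_cohort_dataset()] returns the four paths invisibly;
#'   [read_cohort_dataset()] returns a [cohort_dataset()].
#' @export
write_cohort_dataset <- function(data, dir, prefix) {
  stopifnot(inherits(data, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("protein", "gene", "mirna",
                                                "groups"), ".tsv"))
  write_expression_table(data$protein_expr, paths[1])
  write_expression_table(data$gene_expr, paths[2])
  write_expression_table(data$mirna_expr, paths[3])
  write_group_map(data$sample_groups, paths[4])
  invisible(paths)
}

#' @rdname write_cohort_dataset
#' @export
read_cohort_dataset <- function(dir, prefix) {
  p <- function(kind) file.path(dir, paste0(prefix, "_", kind, ".tsv"))
  cohort_dataset(
    protein_expr = read_expression_table(p("protein")),
    gene_expr = read_expression_table(p("gene")),
    mirna_expr = read_expression_table(p("mirna")),
    sample_groups = read_group_map(p("groups"))
  )
}

#' Write or read an identified network as delimited tables
#'
#' Writes `<prefix>_edges.tsv` (target, regulator, type, ability,
#' signed_coef, se, t, p_value) and `<prefix>_basal.tsv` (node, model,
#' estimate, se, sigma2), plus `<prefix>_nodes.tsv` carrying the node and
#' miRNA universes and cohort label.
#'
#' @param gen An [identified_gen()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return [write_identified_gen()] returns the paths invisibly;
#'   [read_identified_gen()] returns an [identified_gen()].
#' @export
write_identified_gen <- function(gen, dir, prefix) {
  stopifnot(inherits(gen, "identified_gen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", c("edges", "basal", "nodes"),
                                 ".tsv"))
  write_tsv_full(gen$edges, paths[1])
  write_tsv_full(gen$basal, paths[2])
  universe <- data.frame(
    id = c(gen$node_ids, gen$mirna_ids),
    kind = c(rep("node", length(gen$node_ids)),
             rep("mirna", length(gen$mirna_ids))),
    group = rep(as.character(gen$group),
                length(gen$node_ids) + length(gen$mirna_ids)),
    stringsAsFactors = FALSE
  )
  write_tsv_full(universe, paths[3])
  invisible(paths)
}

#' @rdname write_identified_gen
#' @export
read_identified_gen <- function(dir, prefix) {
  p <- function(kind) file.path(dir, paste0(prefix, "_", kind, ".tsv"))
  edges <- read_tsv_plain(p("edges"),
                          colClasses = c(target = "character",
                                         regulator = "character",
                                         type = "character"))
  basal <- read_tsv_plain(p("basal"),
                          colClasses = c(node = "character",
                                         model = "character"))
  universe <- read_tsv_plain(p("nodes"), colClasses = "character")
  identified_gen(
    edges, basal,
    node_ids = universe$id[universe$kind == "node"],
    mirna_ids = universe$id[universe$kind == "mirna"],
    group = if (nrow(universe)) universe$group[1] else NA_character_
  )
}

#' Write ground-truth ability tables for test harnesses
#'
#' @param gt A [generate_ground_truth()] result.
#' @param dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  stopifnot(inherits(gt, "gen_ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- rbind(
    data.frame(source = gt$ppi$node_a, target = gt$ppi$node_b,
               edge_type = rep("ppi", nrow(gt$ppi)),
               ability = gt$ppi$ability, stringsAsFactors = FALSE),
    data.frame(source = gt$tf_reg$tf, target = gt$tf_reg$target,
               edge_type = rep("tf", nrow(gt$tf_reg)),
               ability = gt$tf_reg$ability, stringsAsFactors = FALSE),
    data.frame(source = gt$mirna_reg$mirna, target = gt$mirna_reg$target,
               edge_type = rep("mirna", nrow(gt$mirna_reg)),
               ability = gt$mirna_reg$ability, stringsAsFactors = FALSE)
  )
  basal <- data.frame(
    node = rep(gt$node_ids, 1 + ncol(gt$basal_gene)),
    model = c(rep("ppi", length(gt$node_ids)),
              rep(paste0("grn:", colnames(gt$basal_gene)),
                  each = length(gt$node_ids))),
    value = c(unname(gt$basal_protein), as.vector(gt$basal_gene)),
    stringsAsFactors = FALSE
  )
  paths <- file.path(dir, c("truth_edges.tsv", "truth_basal.tsv",
                            "truth_annotations.tsv"))
  write_tsv_full(edges, paths[1])
  write_tsv_full(basal, paths[2])
  ann <- data.frame(
    node = c(gt$meth_nodes, gt$de_nodes),
    annotation = c(rep("methylation_shift", length(gt$meth_nodes)),
                   rep("differential_expression", length(gt$de_nodes))),
    stringsAsFactors = FALSE
  )
  write_tsv_full(ann, paths[3])
  invisible(paths)
}
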