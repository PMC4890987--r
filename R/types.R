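#' Cohort expression dataset
#'
#' Container for one cohort's expression data. `protein_expr` holds the
#' profiles `y_i(n)` entering the protein-association model and serving as TF
#' regressors; `gene_expr` holds the target profiles `x_i(n)` of the
#' gene-regulatory model; `mirna_expr` holds miRNA profiles `mir_l(n)`.
#' On microarray data the protein and gene profiles are the same mRNA
#' measurements overlaid onto proteins; the simulator keeps them as two
#' matrices so each generative model can hold exactly.
#'
#' @param protein_expr Numeric matrix, nodes x samples, rownames = node ids.
#' @param gene_expr Numeric matrix, nodes x samples, same dimnames as
#'   `protein_expr`.
#' @param mirna_expr Numeric matrix, miRNAs x samples, rownames = miRNA ids.
#' @param sample_groups Named character vector mapping sample id to group
#'   label; names must equal the matrices' column names.
#' @return An object of class `cohort_dataset`: a list with the three matrices
#'   plus `sample_groups`, `node_ids`, `mirna_ids`.
#' @export
cohort_dataset <- function(protein_expr, gene_expr, mirna_expr, sample_groups) {
  for (nm in c("protein_expr", "gene_expr", "mirna_expr")) {
    m <- get(nm)
    if (!is.matrix(m) || !is.numeric(m)) {
      stop(sprintf("`%s` must be a numeric matrix", nm), call. = FALSE)
    }
    if ((nrow(m) > 0 && is.null(rownames(m))) || anyDuplicated(rownames(m))) {
      stop(sprintf("`%s` must have unique rownames", nm), call. = FALSE)
    }
    if (any(!is.finite(m))) {
      stop(sprintf("`%s` contains non-finite values", nm), call. = FALSE)
    }
  }
  if (!identical(dim(protein_expr), dim(gene_expr)) ||
      !identical(rownames(protein_expr), rownames(gene_expr))) {
    stop("`protein_expr` and `gene_expr` must share dimensions and rownames",
         call. = FALSE)
  }
  if (ncol(mirna_expr) != ncol(gene_expr)) {
    stop("expression matrices must have the same number of samples",
         call. = FALSE)
  }
  samples <- colnames(gene_expr)
  if (is.null(samples) || !identical(colnames(mirna_expr), samples) ||
      !identical(colnames(protein_expr), samples)) {
    stop("all matrices must share identical sample (column) names",
         call. = FALSE)
  }
  if (is.null(names(sample_groups)) ||
      !setequal(names(sample_groups), samples) ||
      anyNA(sample_groups)) {
    stop("every sample must have a group label in `sample_groups`",
         call. = FALSE)
  }
  structure(
    list(
      protein_expr = protein_expr,
      gene_expr = gene_expr,
      mirna_expr = mirna_expr,
      sample_groups = sample_groups[samples],
      node_ids = rownames(gene_expr),
      mirna_ids = if (is.null(rownames(mirna_expr))) character() else
        rownames(mirna_expr)
    ),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>\n")
  cat(sprintf("  nodes:   %d\n", length(x$node_ids)))
  cat(sprintf("  miRNAs:  %d\n", length(x$mirna_ids)))
  tab <- table(x$sample_groups)
  cat(sprintf("  samples: %d (%s)\n", ncol(x$gene_expr),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Candidate genetic-and-epigenetic network
#'
#' Typed candidate edge lists over a shared node universe: unordered
#' protein-protein association pairs, ordered TF-to-target regulations and
#' ordered miRNA-to-target repressions. Candidate networks come from
#' interaction databases (or [emit_candidate_network()]) and typically contain
#' false-positive edges to be pruned by [identify_gen()].
#'
#' @param ppi_edges Data frame with columns `node_a`, `node_b` (unordered
#'   pairs, no self pairs).
#' @param tf_edges Data frame with columns `tf`, `target`.
#' @param mirna_edges Data frame with columns `mirna`, `target`.
#' @param node_ids Character vector of protein/gene ids.
#' @param mirna_ids Character vector of miRNA ids.
#' @param tf_ids Optional character vector of node ids designated as TFs;
#'   defaults to the distinct sources of `tf_edges`.
#' @return An object of class `candidate_gen`.
#' @export
candidate_gen <- function(ppi_edges, tf_edges, mirna_edges,
                          node_ids, mirna_ids, tf_ids = NULL) {
  ppi_edges <- as.data.frame(ppi_edges)[c("node_a", "node_b")]
  tf_edges <- as.data.frame(tf_edges)[c("tf", "target")]
  mirna_edges <- as.data.frame(mirna_edges)[c("mirna", "target")]
  if (anyDuplicated(node_ids) || anyDuplicated(mirna_ids)) {
    stop("node and miRNA ids must be unique", call. = FALSE)
  }
  bad <- c(
    setdiff(c(ppi_edges$node_a, ppi_edges$node_b, tf_edges$tf,
              tf_edges$target, mirna_edges$target), node_ids),
    setdiff(mirna_edges$mirna, mirna_ids)
  )
  if (length(bad)) {
    stop("edge endpoints missing from id lists: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  if (any(ppi_edges$node_a == ppi_edges$node_b)) {
    stop("self pairs are not allowed in `ppi_edges`", call. = FALSE)
  }
  if (is.null(tf_ids)) tf_ids <- sort(unique(tf_edges$tf))
  structure(
    list(
      ppi_edges = ppi_edges,
      tf_edges = tf_edges,
      mirna_edges = mirna_edges,
      node_ids = as.character(node_ids),
      mirna_ids = as.character(mirna_ids),
      tf_ids = as.character(tf_ids)
    ),
    class = "candidate_gen"
  )
}

#' @export
print.candidate_gen <- function(x, ...) {
  cat("<candidate_gen>\n")
  cat(sprintf("  nodes: %d (%d TFs), miRNAs: %d\n",
              length(x$node_ids), length(x$tf_ids), length(x$mirna_ids)))
  cat(sprintf("  edges: %d PPI, %d TF, %d miRNA\n",
              nrow(x$ppi_edges), nrow(x$tf_edges), nrow(x$mirna_edges)))
  invisible(x)
}

#' Identified genetic-and-epigenetic network
#'
#' Result of [identify_gen()]: the surviving regulatory abilities per target
#' after AIC order detection and t-test pruning, together with basal levels.
#'
#' @param edges Data frame with columns `target`, `regulator`, `type`
#'   (`"ppi"`, `"tf"` or `"mirna"`), `ability`, `signed_coef`, `se`, `t`,
#'   `p_value`. For miRNA edges `ability` is the repression ability `c_il`
#'   (repression enters the model as `-c_il * mir_l`), and `signed_coef`
#'   (`-c_il`) is the raw coefficient on the miRNA profile; for PPI and TF
#'   edges both columns agree.
#' @param basal Data frame with columns `node`, `model` (`"ppi"` for `h_i`,
#'   `"grn"` for `k_i`), `estimate`, `se`, `sigma2` (residual variance).
#' @param node_ids,mirna_ids The node universes the fit was run over.
#' @param group Optional cohort label.
#' @return An object of class `identified_gen`.
#' @export
identified_gen <- function(edges, basal, node_ids, mirna_ids, group = NA_character_) {
  edge_cols <- c("target", "regulator", "type", "ability", "signed_coef",
                 "se", "t", "p_value")
  edges <- as.data.frame(edges)
  if (!all(edge_cols %in% names(edges))) {
    stop("`edges` must have columns ", paste(edge_cols, collapse = ", "),
         call. = FALSE)
  }
  edges <- edges[edge_cols]
  basal <- as.data.frame(basal)
  if (!all(c("node", "model", "estimate", "se") %in% names(basal))) {
    stop("`basal` must have columns node, model, estimate, se", call. = FALSE)
  }
  if (nrow(edges) && !all(edges$type %in% c("ppi", "tf", "mirna"))) {
    stop("edge `type` must be ppi, tf or mirna", call. = FALSE)
  }
  structure(
    list(edges = edges, basal = basal,
         node_ids = as.character(node_ids),
         mirna_ids = as.character(mirna_ids),
         group = group),
    class = "identified_gen"
  )
}

#' @export
print.identified_gen <- function(x, ...) {
  cat("<identified_gen>", if (!is.na(x$group)) sprintf("[%s]", x$group), "\n")
  tab <- table(factor(x$edges$type, levels = c("ppi", "tf", "mirna")))
  cat(sprintf("  nodes: %d, miRNAs: %d\n",
              length(x$node_ids), length(x$mirna_ids)))
  cat(sprintf("  retained edges: %d ppi, %d tf, %d mirna\n",
              tab[["ppi"]], tab[["tf"]], tab[["mirna"]]))
  invisible(x)
}
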