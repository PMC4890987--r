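#' Select the differentially expressed protein pool
#'
#' Runs a one-way ANOVA per node across sample groups and keeps nodes with
#' `p < alpha`. For two groups the F statistic equals the square of the
#' pooled-variance t statistic. Nodes with zero within-group variance in all
#' groups carry no usable signal; their p-value is treated as 1 and they are
#' excluded (with a message).
#'
#' @param data A [cohort_dataset()] whose `sample_groups` contains at least
#'   two groups, or a list of cohort datasets (one per group) that share node
#'   ordering and are combined before testing.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param assay Which expression matrix to test: `"gene"` (default, the
#'   profiles entering the gene-regulatory model) or `"protein"`.
#' @return Character vector of selected node ids, with the full per-node
#'   ANOVA table as attribute `"anova"` (columns `node`, `statistic`,
#'   `p_value`, `selected`).
#' @export
select_protein_pool <- function(data, alpha = 0.05,
                                assay = c("gene", "protein")) {
  assay <- match.arg(assay)
  stopifnot_scalar_prob(alpha, "alpha")
  if (inherits(data, "cohort_dataset")) data <- list(data)
  stopifnot(is.list(data), length(data) >= 1,
            all(vapply(data, inherits, logical(1), "cohort_dataset")))
  ids <- data[[1]]$node_ids
  for (d in data) {
    if (!identical(d$node_ids, ids)) {
      stop("all cohorts must share the same node ordering", call. = FALSE)
    }
  }
  mat_name <- paste0(assay, "_expr")
  expr <- do.call(cbind, lapply(data, `[[`, mat_name))
  groups <- factor(unlist(lapply(data, `[[`, "sample_groups"), use.names = FALSE))
  if (nlevels(groups) < 2L) {
    stop("pool selection needs at least two groups", call. = FALSE)
  }
  if (min(table(groups)) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }

  res <- t(vapply(seq_len(nrow(expr)), function(i) {
    yi <- expr[i, ]
    wvar <- tapply(yi, groups, stats::var)
    if (all(wvar == 0)) return(c(NA_real_, 1))
    ft <- stats::oneway.test(yi ~ groups, var.equal = TRUE)
    p <- ft$p.value
    if (!is.finite(p)) p <- 1
    c(unname(ft$statistic), p)
  }, numeric(2)))
  tab <- data.frame(node = ids, statistic = res[, 1], p_value = res[, 2],
                    stringsAsFactors = FALSE)
  tab$selected <- tab$p_value < alpha & !is.na(tab$statistic)
  n_degenerate <- sum(is.na(tab$statistic))
  if (n_degenerate) {
    message(n_degenerate,
            " node(s) had zero within-group variance in all groups; excluded")
  }
  structure(tab$node[tab$selected], anova = tab)
}

#' Assemble the candidate network restricted to a protein pool
#'
#' Keeps only edges whose protein/gene endpoints belong to the pool, collapses
#' duplicate edges, drops self protein-protein pairs and retains a miRNA only
#' if it targets at least one pooled gene. The operation is idempotent.
#'
#' @param pool Character vector of pooled node ids (e.g. from
#'   [select_protein_pool()]).
#' @param edges Raw edge table with columns `source`, `target`, `edge_type`
#'   (values `ppi`, `tf`, `mirna`), or a [candidate_gen()] to re-filter.
#' @return A [candidate_gen()] over the pooled nodes and retained miRNAs.
#' @export
assemble_candidate_gen <- function(pool, edges) {
  pool <- as.character(pool)
  if (anyDuplicated(pool)) stop("`pool` ids must be unique", call. = FALSE)
  df <- as_edge_table(edges)
  known <- c("ppi", "tf", "mirna")
  bad <- which(!df$edge_type %in% known)
  if (length(bad)) {
    stop(sprintf(
      "unknown edge_type '%s' in edge table row %d (%s -> %s)",
      df$edge_type[bad[1]], bad[1], df$source[bad[1]], df$target[bad[1]]
    ), call. = FALSE)
  }

  ppi <- df[df$edge_type == "ppi", ]
  ppi <- ppi[ppi$source %in% pool & ppi$target %in% pool &
               ppi$source != ppi$target, , drop = FALSE]
  ppi_a <- pmin(ppi$source, ppi$target)
  ppi_b <- pmax(ppi$source, ppi$target)
  keep <- !duplicated(paste(ppi_a, ppi_b, sep = "\r"))
  ppi_edges <- data.frame(node_a = ppi_a[keep], node_b = ppi_b[keep],
                          stringsAsFactors = FALSE)

  tf <- df[df$edge_type == "tf", ]
  tf <- tf[tf$source %in% pool & tf$target %in% pool, , drop = FALSE]
  keep <- !duplicated(paste(tf$source, tf$target, sep = "\r"))
  tf_edges <- data.frame(tf = tf$source[keep], target = tf$target[keep],
                         stringsAsFactors = FALSE)

  mir <- df[df$edge_type == "mirna", ]
  mir <- mir[mir$target %in% pool, , drop = FALSE]
  keep <- !duplicated(paste(mir$source, mir$target, sep = "\r"))
  mirna_edges <- data.frame(mirna = mir$source[keep],
                            target = mir$target[keep],
                            stringsAsFactors = FALSE)

  candidate_gen(ppi_edges, tf_edges, mirna_edges,
                node_ids = pool,
                mirna_ids = sort(unique(mirna_edges$mirna)))
}
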