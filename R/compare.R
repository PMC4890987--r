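#' Common and specific core networks of two cohorts
#'
#' Intersects and differences two cohorts' core networks. Node- and
#' miRNA-level sets are compared by identifier; edges by the triple
#' (regulator, target, type). The intersection is the common core network;
#' each cohort's remainder is its specific core network, and the common and
#' specific sets partition each cohort's core.
#'
#' @param core_a,core_b [extract_core()] results sharing an identifier
#'   namespace.
#' @param labels Character vector of length 2 naming the cohorts.
#' @return An object of class `gen_comparison`: common/specific node, miRNA
#'   and edge sets (`common_nodes`, `specific_nodes_a`, ..., `common_edges`,
#'   `specific_edges_a`, `specific_edges_b`) plus `labels`.
#' @export
compare_core_gens <- function(core_a, core_b, labels = c("A", "B")) {
  stopifnot(inherits(core_a, "core_gen"), inherits(core_b, "core_gen"),
            length(labels) == 2L)
  edge_key <- function(e) {
    if (is.null(e) || !nrow(e)) return(character())
    paste(e$regulator, e$target, e$type, sep = "\r")
  }
  ka <- edge_key(core_a$core_edges)
  kb <- edge_key(core_b$core_edges)
  pick <- function(e, keep) {
    if (is.null(e)) return(NULL)
    out <- e[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(
    list(
      labels = labels,
      common_nodes = sort(intersect(core_a$core_nodes, core_b$core_nodes)),
      specific_nodes_a = sort(setdiff(core_a$core_nodes, core_b$core_nodes)),
      specific_nodes_b = sort(setdiff(core_b$core_nodes, core_a$core_nodes)),
      common_mirnas = sort(intersect(core_a$core_mirnas, core_b$core_mirnas)),
      specific_mirnas_a = sort(setdiff(core_a$core_mirnas, core_b$core_mirnas)),
      specific_mirnas_b = sort(setdiff(core_b$core_mirnas, core_a$core_mirnas)),
      common_edges = pick(core_a$core_edges, ka %in% kb),
      specific_edges_a = pick(core_a$core_edges, !(ka %in% kb)),
      specific_edges_b = pick(core_b$core_edges, !(kb %in% ka))
    ),
    class = "gen_comparison"
  )
}

#' @export
print.gen_comparison <- function(x, ...) {
  cat(sprintf("<gen_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  nodes:  %d common, %d specific to %s, %d specific to %s\n",
              length(x$common_nodes), length(x$specific_nodes_a),
              x$labels[1], length(x$specific_nodes_b), x$labels[2]))
  cat(sprintf("  miRNAs: %d common, %d / %d specific\n",
              length(x$common_mirnas), length(x$specific_mirnas_a),
              length(x$specific_mirnas_b)))
  if (!is.null(x$common_edges)) {
    cat(sprintf("  edges:  %d common, %d / %d specific\n",
                nrow(x$common_edges), nrow(x$specific_edges_a),
                nrow(x$specific_edges_b)))
  }
  invisible(x)
}

#' Flag DNA-methylation candidates from basal-level differences
#'
#' Nodes whose fitted basal levels differ between two cohorts' identified
#' networks are candidate targets of differential DNA methylation: a
#' persistent shift in a gene's basal expression that the regulatory inputs
#' do not explain. The default test is a two-estimate z-test,
#' `z = (k_A - k_B) / sqrt(SE_A^2 + SE_B^2)` with a two-sided normal p-value,
#' flagging `p < alpha`. An absolute-difference mode
#' (`method = "absolute"`) flags `|k_A - k_B| >= min_abs` instead. The flags
#' are candidate annotations, not biological claims.
#'
#' @param gen_a,gen_b [identified_gen()] results for the two cohorts.
#' @param alpha Significance level for the z-test; default 0.05.
#' @param model Which basal level to compare: `"grn"` (`k_i`, default) or
#'   `"ppi"` (`h_i`).
#' @param method `"ztest"` (default) or `"absolute"`.
#' @param min_abs Absolute-difference threshold for `method = "absolute"`.
#' @return Data frame with columns `node`, `basal_a`, `se_a`, `basal_b`,
#'   `se_b`, `delta`, `z`, `p_value`, `flagged`.
#' @export
flag_methylation_candidates <- function(gen_a, gen_b, alpha = 0.05,
                                        model = c("grn", "ppi"),
                                        method = c("ztest", "absolute"),
                                        min_abs = NULL) {
  stopifnot(inherits(gen_a, "identified_gen"),
            inherits(gen_b, "identified_gen"))
  model <- match.arg(model)
  method <- match.arg(method)
  stopifnot_scalar_prob(alpha, "alpha")
  if (method == "absolute" && is.null(min_abs)) {
    stop("`min_abs` is required for method = \"absolute\"", call. = FALSE)
  }
  ba <- gen_a$basal[gen_a$basal$model == model, ]
  bb <- gen_b$basal[gen_b$basal$model == model, ]
  shared <- intersect(ba$node, bb$node)
  ba <- ba[match(shared, ba$node), ]
  bb <- bb[match(shared, bb$node), ]
  usable <- is.finite(ba$se) & is.finite(bb$se) & (ba$se + bb$se > 0)
  if (any(!usable)) {
    warning(sum(!usable), " node(s) skipped: missing or degenerate basal SE",
            call. = FALSE)
  }
  ba <- ba[usable, ]; bb <- bb[usable, ]
  delta <- ba$estimate - bb$estimate
  z <- delta / sqrt(ba$se^2 + bb$se^2)
  p <- 2 * stats::pnorm(-abs(z))
  flagged <- if (method == "ztest") p < alpha else abs(delta) >= min_abs
  data.frame(node = ba$node, basal_a = ba$estimate, se_a = ba$se,
             basal_b = bb$estimate, se_b = bb$se,
             delta = delta, z = z, p_value = p, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Flag differentially expressed nodes between two cohorts
#'
#' Per-node two-sided pooled-variance t-test of expression between the
#' cohorts, flagging `p < alpha`. In the aging analysis such nodes are
#' candidate carriers of accumulated genetic change; here too the flag is a
#' candidate annotation only. Nodes with zero pooled variance carry no
#' signal; their p-value is set to 1 (with a message).
#'
#' @param data_a,data_b [cohort_dataset()]s sharing node ordering.
#' @param alpha Significance level; default 0.05.
#' @param assay `"gene"` (default) or `"protein"` expression.
#' @return Data frame with columns `node`, `mean_a`, `mean_b`, `t`,
#'   `p_value`, `flagged`.
#' @export
flag_differential_expression <- function(data_a, data_b, alpha = 0.05,
                                         assay = c("gene", "protein")) {
  stopifnot(inherits(data_a, "cohort_dataset"),
            inherits(data_b, "cohort_dataset"))
  assay <- match.arg(assay)
  stopifnot_scalar_prob(alpha, "alpha")
  if (!identical(data_a$node_ids, data_b$node_ids)) {
    stop("cohorts must share the same node ordering", call. = FALSE)
  }
  ma <- data_a[[paste0(assay, "_expr")]]
  mb <- data_b[[paste0(assay, "_expr")]]
  if (ncol(ma) < 2L || ncol(mb) < 2L) {
    stop("each cohort needs at least two samples", call. = FALSE)
  }
  n_degenerate <- 0L
  res <- t(vapply(seq_len(nrow(ma)), function(i) {
    a <- ma[i, ]; b <- mb[i, ]
    pooled <- ((length(a) - 1) * stats::var(a) +
                 (length(b) - 1) * stats::var(b))
    if (pooled == 0) return(c(0, 1))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2)))
  zero <- res[, 1] == 0 & res[, 2] == 1
  if (any(zero)) {
    message(sum(zero), " node(s) with zero pooled variance: p set to 1")
  }
  data.frame(node = data_a$node_ids,
             mean_a = rowMeans(ma), mean_b = rowMeans(mb),
             t = res[, 1], p_value = res[, 2],
             flagged = res[, 2] < alpha,
             stringsAsFactors = FALSE)
}
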