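#' Stack identified abilities into the network matrix H
#'
#' Builds the `(2N + O) x N` matrix whose columns are targets and whose rows
#' are regulator profiles in three blocks: rows `1..N` hold the
#' protein-association abilities (`H[k, i] = a_ik`, partner `k` of target
#' `i`), rows `N+1..2N` the TF regulatory abilities (`H[N+k, i] = b_ik`) and
#' rows `2N+1..2N+O` the negated miRNA repression abilities
#' (`H[2N+l, i] = -c_il`, the sign with which repression enters the
#' gene-regulatory model). Pruned positions are exactly zero.
#'
#' @param gen An [identified_gen()].
#' @return An object of class `network_matrix`: the matrix `H` plus
#'   `row_info` (data frame `row`, `class` in `ppi`/`tf`/`mirna`, `id`),
#'   `node_ids` and `mirna_ids`.
#' @export
build_network_matrix <- function(gen) {
  stopifnot(inherits(gen, "identified_gen"))
  nodes <- gen$node_ids
  mirnas <- gen$mirna_ids
  N <- length(nodes)
  O <- length(mirnas)
  row_info <- data.frame(
    row = seq_len(2L * N + O),
    class = c(rep("ppi", N), rep("tf", N), rep("mirna", O)),
    id = c(nodes, nodes, mirnas),
    stringsAsFactors = FALSE
  )
  H <- matrix(0, nrow = 2L * N + O, ncol = N,
              dimnames = list(paste(row_info$class, row_info$id, sep = ":"),
                              nodes))
  e <- gen$edges
  if (nrow(e)) {
    if (anyDuplicated(e[c("target", "regulator", "type")])) {
      dup <- e[duplicated(e[c("target", "regulator", "type")]), ]
      stop("duplicate identified edge(s), e.g. ",
           sprintf("%s %s -> %s", dup$type[1], dup$regulator[1],
                   dup$target[1]), call. = FALSE)
    }
    col <- match(e$target, nodes)
    row <- ifelse(
      e$type == "ppi", match(e$regulator, nodes),
      ifelse(e$type == "tf", N + match(e$regulator, nodes),
             2L * N + match(e$regulator, mirnas))
    )
    if (anyNA(col) || anyNA(row)) {
      stop("identified edges reference ids outside the node/miRNA universes",
           call. = FALSE)
    }
    H[cbind(row, col)] <- ifelse(e$type == "mirna", -e$ability, e$ability)
  }
  structure(list(H = H, row_info = row_info,
                 node_ids = nodes, mirna_ids = mirnas),
            class = "network_matrix")
}

#' @export
print.network_matrix <- function(x, ...) {
  cat(sprintf("<network_matrix> %d x %d (N=%d nodes, O=%d miRNAs), %d nonzero\n",
              nrow(x$H), ncol(x$H), length(x$node_ids), length(x$mirna_ids),
              sum(x$H != 0)))
  invisible(x)
}

#' Principal Network Projection: singular value decomposition of H
#'
#' Thin SVD `H = U D V^T` of the network matrix. Each component's eigen
#' expression fraction is its squared singular value over the total,
#' `E_m = d_m^2 / sum(d^2)`, and the projection dimension `M` is the minimal
#' number of leading components whose cumulative fraction reaches the
#' `energy` proportion (default 0.85, i.e. the components carry 85% of the
#' network from an energy point of view).
#'
#' @param nm A [build_network_matrix()] result (or a bare numeric matrix).
#' @param energy Energy proportion in (0, 1]; default 0.85.
#' @return An object of class `pnp_result` with `d` (singular values,
#'   descending), `E` (eigen expression fractions), `M`, `energy`, `V`
#'   (right singular vectors), plus the network matrix and row metadata.
#'   Scores and distances are filled in by [project_and_score()].
#' @export
pnp_decompose <- function(nm, energy = 0.85) {
  if (is.matrix(nm)) {
    row_info <- data.frame(row = seq_len(nrow(nm)),
                           class = rep("ppi", nrow(nm)),
                           id = as.character(seq_len(nrow(nm))),
                           stringsAsFactors = FALSE)
    nm <- list(H = nm, row_info = row_info,
               node_ids = as.character(seq_len(ncol(nm))),
               mirna_ids = character())
    class(nm) <- "network_matrix"
  }
  stopifnot(inherits(nm, "network_matrix"))
  stopifnot_scalar_prob(energy, "energy", open_left = TRUE, open_right = FALSE)
  H <- nm$H
  if (all(H == 0)) {
    stop("network matrix is all zero; nothing to decompose", call. = FALSE)
  }
  sv <- svd(H, nu = 0, nv = ncol(H))
  d <- sv$d
  E <- d^2 / sum(d^2)
  M <- which(cumsum(E) >= energy - 1e-12)[1]
  structure(
    list(nm = nm, d = d, E = E, M = M, energy = energy, V = sv$v,
         S = NULL, D = NULL),
    class = "pnp_result"
  )
}

#' Project network rows onto the top principal components
#'
#' Fills the projection scores `S(k, m) = h_k . v_m` (row `k` of H against
#' the m-th right singular vector) for `m = 1..M` and the projection
#' distances `D(k) = sqrt(sum_m S(k, m)^2)`, the 2-norm of each row's
#' projection onto the top-M component subspace. Rows with `D(k)` near zero
#' are essentially independent of the principal network structure.
#'
#' @param pnp A [pnp_decompose()] result.
#' @return The `pnp_result` with `S` ((2N+O) x M score matrix), `D` (distance
#'   vector) and a `scores` data frame (`row`, `class`, `id`, `distance`).
#' @export
project_and_score <- function(pnp) {
  stopifnot(inherits(pnp, "pnp_result"))
  H <- pnp$nm$H
  V_top <- pnp$V[, seq_len(pnp$M), drop = FALSE]
  S <- H %*% V_top
  D <- sqrt(rowSums(S^2))
  pnp$S <- S
  pnp$D <- D
  pnp$scores <- data.frame(
    row = pnp$nm$row_info$row,
    class = pnp$nm$row_info$class,
    id = pnp$nm$row_info$id,
    distance = unname(D),
    stringsAsFactors = FALSE
  )
  pnp
}

#' @export
print.pnp_result <- function(x, ...) {
  cat(sprintf("<pnp_result> %d singular values, M = %d (%.1f%% energy target)\n",
              length(x$d), x$M, 100 * x$energy))
  cat(sprintf("  cumulative energy through M: %.4f\n", sum(x$E[seq_len(x$M)])))
  if (!is.null(x$D)) cat(sprintf("  distances filled for %d rows\n",
                                 length(x$D)))
  invisible(x)
}

#' Per-component energy bookkeeping table
#'
#' @param pnp A [pnp_decompose()] result.
#' @return Data frame with columns `m`, `d`, `E`, `cumulative_E`, `selected`.
#' @export
pnp_components_table <- function(pnp) {
  stopifnot(inherits(pnp, "pnp_result"))
  data.frame(m = seq_along(pnp$d), d = pnp$d, E = pnp$E,
             cumulative_E = cumsum(pnp$E),
             selected = seq_along(pnp$d) <= pnp$M)
}

#' Extract the core network by thresholding projection distances
#'
#' Applies one threshold per row block: `th1` to the protein-association rows
#' (`1..N`), `th2` to the TF-regulation rows (`N+1..2N`) and `th3` to the
#' miRNA rows (`2N+1..2N+O`). A protein/gene node is core if either of its
#' two rows passes its block threshold; a miRNA is core if its row passes
#' `th3`. When an [identified_gen()] is supplied, the induced core subnetwork
#' (edges with both endpoints core) is attached.
#'
#' @param pnp A [project_and_score()] result.
#' @param th1,th2,th3 Nonnegative distance thresholds for the PPI, TF and
#'   miRNA row blocks.
#' @param gen Optional [identified_gen()] used to induce the core subnetwork.
#' @return An object of class `core_gen`: `core_nodes`, `core_mirnas`,
#'   `thresholds`, `scores` (per-row table with `core` flag) and, if `gen`
#'   was given, `core_edges`.
#' @export
extract_core <- function(pnp, th1, th2, th3, gen = NULL) {
  stopifnot(inherits(pnp, "pnp_result"))
  if (is.null(pnp$D)) pnp <- project_and_score(pnp)
  stopifnot(th1 >= 0, th2 >= 0, th3 >= 0)
  scores <- pnp$scores
  th <- c(ppi = th1, tf = th2, mirna = th3)
  scores$threshold <- unname(th[scores$class])
  # zero-distance rows are independent of the principal components and are
  # never core, even under a zero threshold
  scores$core <- scores$distance >= scores$threshold & scores$distance > 0
  core_nodes <- sort(unique(scores$id[scores$core &
                                        scores$class %in% c("ppi", "tf")]))
  core_mirnas <- sort(unique(scores$id[scores$core &
                                         scores$class == "mirna"]))
  core_edges <- NULL
  if (!is.null(gen)) {
    stopifnot(inherits(gen, "identified_gen"))
    e <- gen$edges
    reg_core <- ifelse(e$type == "mirna", e$regulator %in% core_mirnas,
                       e$regulator %in% core_nodes)
    core_edges <- e[reg_core & e$target %in% core_nodes, , drop = FALSE]
    rownames(core_edges) <- NULL
  }
  structure(
    list(core_nodes = core_nodes, core_mirnas = core_mirnas,
         thresholds = c(th1 = th1, th2 = th2, th3 = th3),
         scores = scores, core_edges = core_edges),
    class = "core_gen"
  )
}

#' @export
print.core_gen <- function(x, ...) {
  cat("<core_gen>\n")
  cat(sprintf("  thresholds: th1=%g th2=%g th3=%g\n",
              x$thresholds[["th1"]], x$thresholds[["th2"]],
              x$thresholds[["th3"]]))
  cat(sprintf("  core nodes: %d, core miRNAs: %d",
              length(x$core_nodes), length(x$core_mirnas)))
  if (!is.null(x$core_edges)) cat(sprintf(", core edges: %d",
                                          nrow(x$core_edges)))
  cat("\n")
  invisible(x)
}

#' Quantile-based thresholds for core extraction
#'
#' Convenience helper when no fixed thresholds are available: sets each
#' block's threshold to the `prob` quantile of that block's projection
#' distances, so roughly the top `(1 - prob)` share of rows per block is
#' kept.
#'
#' @param pnp A [project_and_score()] result.
#' @param prob Quantile in (0, 1); default 0.9 keeps the top 10%.
#' @return Named list with `th1`, `th2`, `th3`.
#' @export
quantile_thresholds <- function(pnp, prob = 0.9) {
  stopifnot(inherits(pnp, "pnp_result"))
  if (is.null(pnp$D)) pnp <- project_and_score(pnp)
  stopifnot_scalar_prob(prob, "prob")
  q <- function(cls) {
    d <- pnp$scores$distance[pnp$scores$class == cls]
    if (length(d)) unname(stats::quantile(d, prob)) else 0
  }
  list(th1 = q("ppi"), th2 = q("tf"), th3 = q("mirna"))
}

#' Published per-cohort core-extraction thresholds
#'
#' Threshold triples used in the peripheral-blood mononuclear cell aging
#' study that this pipeline reimplements, one row per cohort run. Provided
#' as reference configuration constants; on other data the thresholds are
#' analysis choices (see [quantile_thresholds()]).
#'
#' @return Data frame with columns `cohort`, `th1`, `th2`, `th3`.
#' @export
pnp_published_thresholds <- function() {
  data.frame(
    cohort = c("young", "elderly", "old_women", "old_men"),
    th1 = c(4.0, 0.6, 0.5, 0.8),
    th2 = c(0.015, 0.35, 0.4, 0.003),
    th3 = c(0.01, 0.03, 0.1, 0.003),
    stringsAsFactors = FALSE
  )
}
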