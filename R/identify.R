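#' Build the protein-association regression problem for one target
#'
#' The bilinear association model expresses a protein's profile as
#' `y_i(n) = sum_j a_ij y_i(n) y_j(n) + h_i + v_i(n)`, so the design holds
#' one column of products `y_i(n) * y_j(n)` per candidate partner `j` plus a
#' final intercept column for the basal level `h_i`.
#'
#' @param target Node id.
#' @param data A [cohort_dataset()].
#' @param candidates A [candidate_gen()]; partners are the PPI neighbours of
#'   `target`.
#' @return An object of class `regression_problem`: `target`, `response`
#'   (numeric vector over samples), `design` (samples x regressors matrix with
#'   labelled columns, intercept last) and `labels` (data frame `label`,
#'   `type`, `partner`).
#' @export
build_ppi_problem <- function(target, data, candidates) {
  stopifnot(inherits(data, "cohort_dataset"),
            inherits(candidates, "candidate_gen"))
  if (!target %in% data$node_ids) {
    stop("target not present in expression data: ", target, call. = FALSE)
  }
  e <- candidates$ppi_edges
  partners <- sort(unique(c(e$node_b[e$node_a == target],
                            e$node_a[e$node_b == target])))
  missing <- setdiff(partners, data$node_ids)
  if (length(missing)) {
    stop("candidate partner(s) missing from expression data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  yi <- data$protein_expr[target, ]
  # a constant partner profile makes the product regressor proportional to
  # the response itself; such an association is unidentifiable from this
  # target's regression and the candidate is dropped up front
  constant <- vapply(partners, function(j) {
    pj <- data$protein_expr[j, ]
    max(pj) == min(pj)
  }, logical(1))
  if (any(constant)) {
    message("target ", target, ": dropping candidate partner(s) with ",
            "constant profiles: ", paste(partners[constant], collapse = ", "))
    partners <- partners[!constant]
  }
  cols <- lapply(partners, function(j) yi * data$protein_expr[j, ])
  design <- cbind(
    if (length(cols)) do.call(cbind, cols) else NULL,
    rep(1, length(yi))
  )
  labels <- c(if (length(partners)) paste0("ppi:", partners), "basal")
  colnames(design) <- labels
  regression_problem(
    target = target, response = yi, design = design,
    labels = data.frame(
      label = labels,
      type = c(rep("ppi", length(partners)), "basal"),
      partner = c(partners, NA_character_),
      stringsAsFactors = FALSE
    )
  )
}

#' Build the gene-regulatory regression problem for one target
#'
#' The gene-regulatory model is
#' `x_i(n) = sum_j b_ij y_j(n) - sum_l c_il mir_l(n) + k_i + w_i(n)`:
#' TF columns hold the TF profiles `y_j(n)`, miRNA columns hold the negated
#' profiles `-mir_l(n)` (so the estimated coefficient is the repression
#' ability `c_il` itself), and the final column is the intercept for `k_i`.
#'
#' @inheritParams build_ppi_problem
#' @return A `regression_problem`; see [build_ppi_problem()].
#' @export
build_grn_problem <- function(target, data, candidates) {
  stopifnot(inherits(data, "cohort_dataset"),
            inherits(candidates, "candidate_gen"))
  if (!target %in% data$node_ids) {
    stop("target not present in expression data: ", target, call. = FALSE)
  }
  tfs <- sort(unique(candidates$tf_edges$tf[
    candidates$tf_edges$target == target &
      candidates$tf_edges$tf != target]))
  mirs <- sort(unique(candidates$mirna_edges$mirna[
    candidates$mirna_edges$target == target]))
  missing <- c(setdiff(tfs, data$node_ids), setdiff(mirs, data$mirna_ids))
  if (length(missing)) {
    stop("candidate regulator(s) missing from expression data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  xi <- data$gene_expr[target, ]
  tf_cols <- lapply(tfs, function(j) data$protein_expr[j, ])
  mir_cols <- lapply(mirs, function(l) -data$mirna_expr[l, ])
  design <- cbind(
    if (length(tf_cols)) do.call(cbind, tf_cols) else NULL,
    if (length(mir_cols)) do.call(cbind, mir_cols) else NULL,
    rep(1, length(xi))
  )
  labels <- c(if (length(tfs)) paste0("tf:", tfs),
              if (length(mirs)) paste0("mirna:", mirs),
              "basal")
  colnames(design) <- labels
  regression_problem(
    target = target, response = xi, design = design,
    labels = data.frame(
      label = labels,
      type = c(rep("tf", length(tfs)), rep("mirna", length(mirs)), "basal"),
      partner = c(tfs, mirs, NA_character_),
      stringsAsFactors = FALSE
    )
  )
}

#' Construct a regression problem directly
#'
#' Low-level constructor used by the problem builders; exposed so synthetic
#' regression problems can be composed in calibration studies. The design
#' must contain exactly one intercept column (label type `"basal"`).
#'
#' @param target Target identifier.
#' @param response Numeric response vector over samples.
#' @param design Numeric matrix, samples x regressors, columns named by
#'   `labels$label`.
#' @param labels Data frame with columns `label` (unique), `type` (one of
#'   `ppi`, `tf`, `mirna`, `basal`) and `partner` (regulator id, `NA` for the
#'   intercept).
#' @return An object of class `regression_problem`.
#' @export
regression_problem <- function(target, response, design, labels) {
  stopifnot(nrow(design) == length(response),
            !anyDuplicated(labels$label),
            sum(labels$type == "basal") == 1L)
  structure(list(target = target, response = response, design = design,
                 labels = labels),
            class = "regression_problem")
}

#' @export
print.regression_problem <- function(x, ...) {
  cat(sprintf("<regression_problem> target %s: %d samples, %d regressors (+ intercept)\n",
              x$target, length(x$response), nrow(x$labels) - 1L))
  invisible(x)
}

subset_problem <- function(problem, keep_labels) {
  keep <- problem$labels$label %in% c(keep_labels, "basal")
  regression_problem(
    target = problem$target,
    response = problem$response,
    design = problem$design[, problem$labels$label[keep], drop = FALSE],
    labels = problem$labels[keep, , drop = FALSE]
  )
}

#' Fit a regression problem by ordinary least squares
#'
#' Classical linear-model fit: estimates minimize the residual sum of
#' squares; standard errors use the unbiased residual-variance estimate
#' `RSS / (n - p)`; `t = estimate / SE` and two-sided p-values come from the
#' t distribution with `n - p` degrees of freedom. Constant regressor columns
#' (collinear with the intercept) are dropped before fitting, and remaining
#' rank deficiencies are resolved deterministically by keeping the intercept
#' and then columns left to right, dropping each column that is linearly
#' dependent on those already kept (i.e. the rightmost column of every
#' dependency goes). A perfect fit (`RSS = 0`) yields infinite `t` and zero
#' p-values for nonzero estimates.
#'
#' @param problem A `regression_problem` from [build_ppi_problem()] or
#'   [build_grn_problem()].
#' @return An object of class `fit_result`: `estimates` (data frame `label`,
#'   `type`, `partner`, `estimate`, `se`, `t`, `p_value`), `rss`,
#'   `n_samples`, `n_params`, `df_residual`, `sigma2`, `aic`, `dropped`
#'   (data frame of dropped columns with reasons), `target`.
#' @export
least_squares_fit <- function(problem) {
  stopifnot(inherits(problem, "regression_problem"))
  X <- problem$design
  y <- problem$response
  n <- length(y)
  labels <- problem$labels

  dropped <- data.frame(label = character(), reason = character(),
                        stringsAsFactors = FALSE)

  # constant non-intercept columns are collinear with the intercept
  is_basal <- labels$type == "basal"
  const <- !is_basal & apply(X, 2, function(col) max(col) == min(col))
  if (any(const)) {
    message("dropping constant regressor column(s): ",
            paste(labels$label[const], collapse = ", "))
    dropped <- rbind(dropped, data.frame(label = labels$label[const],
                                         reason = "constant",
                                         stringsAsFactors = FALSE))
    X <- X[, !const, drop = FALSE]
    labels <- labels[!const, , drop = FALSE]
    is_basal <- labels$type == "basal"
  }

  # greedy left-to-right rank filter, intercept always kept first
  ord <- c(which(is_basal), which(!is_basal))
  kept_idx <- integer(0)
  for (j in ord) {
    cand <- cbind(X[, kept_idx, drop = FALSE], X[, j])
    if (qr(cand)$rank == length(kept_idx) + 1L) kept_idx <- c(kept_idx, j)
  }
  if (length(kept_idx) < ncol(X)) {
    gone <- setdiff(seq_len(ncol(X)), kept_idx)
    warning("dropping linearly dependent regressor column(s): ",
            paste(labels$label[gone], collapse = ", "), call. = FALSE)
    dropped <- rbind(dropped, data.frame(label = labels$label[gone],
                                         reason = "collinear",
                                         stringsAsFactors = FALSE))
    keep <- sort(kept_idx)
    X <- X[, keep, drop = FALSE]
    labels <- labels[keep, , drop = FALSE]
  }

  p <- ncol(X)
  if (n <= p) {
    stop(sprintf(
      "target %s: %d samples cannot support %d parameters; reduce the candidate set",
      problem$target, n, p), call. = FALSE)
  }

  qx <- qr(X)
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  df_residual <- n - p
  # a residual sum of squares at rounding level is a perfect fit: treat the
  # noise variance as zero and score coefficients by magnitude, so that the
  # noiseless limit prunes numerically-zero abilities exactly
  tss <- sum((y - mean(y))^2)
  if (rss <= 1e-20 * max(tss, 1)) {
    rss <- 0
    sigma2 <- 0
    se <- rep(0, p)
    nonzero <- abs(beta) > 1e-8 * max(abs(beta), 1e-300)
    tstat <- ifelse(nonzero, sign(beta) * Inf, 0)
    p_value <- ifelse(nonzero, 0, 1)
  } else {
    sigma2 <- rss / df_residual
    xtx_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
    tstat <- ifelse(se > 0, beta / se,
                    ifelse(beta == 0, 0, sign(beta) * Inf))
    p_value <- ifelse(is.finite(tstat),
                      2 * stats::pt(-abs(tstat), df_residual),
                      0)
    p_value[se == 0 & beta == 0] <- 1
  }

  structure(
    list(
      target = problem$target,
      estimates = data.frame(
        label = labels$label, type = labels$type, partner = labels$partner,
        estimate = unname(beta), se = se, t = unname(tstat),
        p_value = unname(p_value), stringsAsFactors = FALSE
      ),
      rss = rss, n_samples = n, n_params = p, df_residual = df_residual,
      sigma2 = sigma2,
      aic = aic_score(rss, n, p),
      dropped = dropped
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> target %s: n=%d, p=%d, rss=%.4g, aic=%.4g\n",
              x$target, x$n_samples, x$n_params, x$rss, x$aic))
  print(x$estimates, digits = 4)
  invisible(x)
}

#' Akaike information criterion for a Gaussian least-squares fit
#'
#' Computes `n * ln(RSS / n) + 2p`, the AIC of a Gaussian linear model up to
#' an additive constant. A perfect fit (`RSS = 0`) returns `-Inf` so that it
#' dominates any finite score.
#'
#' @param rss Residual sum of squares (>= 0).
#' @param n Number of samples (> 0).
#' @param p Number of estimated parameters (>= 0).
#' @return AIC value (scalar, possibly `-Inf`).
#' @export
aic_score <- function(rss, n, p) {
  stopifnot(is.numeric(rss), length(rss) == 1L, rss >= 0,
            is.numeric(n), length(n) == 1L, n > 0,
            is.numeric(p), length(p) == 1L, p >= 0)
  if (rss == 0) {
    message("perfect fit (rss = 0): AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * p
}

#' Detect model order by AIC and prune abilities by t-test
#'
#' Backward elimination: the full candidate model is fitted, then the
#' non-intercept regressor with the smallest `|t|` is removed and the model
#' refitted, down to the intercept-only model. Among this nested path the
#' model with minimal AIC is selected (ties go to the smaller model). A final
#' t-test sweep then removes remaining non-intercept regressors with
#' `p >= alpha`, refitting until all survivors are significant; the intercept
#' (basal level) is never pruned. Equal `|t|` ties remove the
#' lexicographically last label, which makes the procedure deterministic.
#'
#' @param problem A `regression_problem`.
#' @param alpha Pruning significance level; default 0.05.
#' @return A `fit_result` for the selected model, with extra fields
#'   `eliminated` (data frame `label`, `reason` in `aic`/`ttest`/`constant`/
#'   `collinear`) and `aic_path` (data frame `step`, `n_regressors`, `aic`,
#'   `removed_label`).
#' @export
detect_order_and_prune <- function(problem, alpha = 0.05) {
  stopifnot(inherits(problem, "regression_problem"))
  stopifnot_scalar_prob(alpha, "alpha")

  fit <- least_squares_fit(problem)
  pre_dropped <- fit$dropped
  current_labels <- fit$estimates$label[fit$estimates$type != "basal"]
  # refits work on the already rank-filtered column set
  problem <- subset_problem(problem, current_labels)
  path <- list(fit)
  removed_seq <- character(0)

  while (length(current_labels) > 0) {
    est <- path[[length(path)]]$estimates
    est <- est[est$type != "basal", , drop = FALSE]
    at_min <- which(abs(est$t) == min(abs(est$t)))
    victim <- max(est$label[at_min])  # lexicographically last on ties
    current_labels <- setdiff(current_labels, victim)
    removed_seq <- c(removed_seq, victim)
    fit_k <- least_squares_fit(subset_problem(problem, current_labels))
    path <- c(path, list(fit_k))
  }

  aics <- vapply(path, `[[`, numeric(1), "aic")
  best_idx <- max(which(aics == min(aics)))  # ties: smallest model
  best <- path[[best_idx]]
  aic_removed <- if (best_idx > 1) removed_seq[seq_len(best_idx - 1)] else character(0)

  eliminated <- rbind(
    pre_dropped,
    if (length(aic_removed)) data.frame(label = aic_removed, reason = "aic",
                                        stringsAsFactors = FALSE)
  )

  # t-test sweep: drop all insignificant survivors, refit, repeat until stable
  final <- best
  repeat {
    est <- final$estimates
    bad <- est$type != "basal" & est$p_value >= alpha
    if (!any(bad)) break
    eliminated <- rbind(eliminated,
                        data.frame(label = est$label[bad], reason = "ttest",
                                   stringsAsFactors = FALSE))
    keep <- est$label[est$type != "basal" & est$p_value < alpha]
    final <- least_squares_fit(subset_problem(problem, keep))
  }

  final$eliminated <- eliminated
  final$aic_path <- data.frame(
    step = seq_along(path) - 1L,
    n_regressors = vapply(path, function(f) sum(f$estimates$type != "basal"),
                          integer(1)),
    aic = aics,
    removed_label = c(NA_character_, removed_seq),
    stringsAsFactors = FALSE
  )
  final$selected_step <- best_idx - 1L
  final
}

#' Identify a genetic-and-epigenetic network from one cohort
#'
#' For every node in the candidate network, builds and prunes both the
#' protein-association problem and the gene-regulatory problem
#' (see [detect_order_and_prune()]), then assembles the surviving abilities
#' and basal levels into an [identified_gen()]. Per-target failures are
#' collected as warnings and the target is skipped; the run fails only if
#' every target fails.
#'
#' @param data A [cohort_dataset()].
#' @param candidates A [candidate_gen()].
#' @param alpha Pruning significance level; default 0.05.
#' @param group Cohort label stored on the result; defaults to the dataset's
#'   single group label when unambiguous.
#' @param ppi_reciprocal Logical; when `TRUE` (default) a protein association
#'   is retained only if it survives pruning in the regressions of *both* of
#'   its endpoints. The association ability is symmetric at the pair level,
#'   and the bilinear design makes a single endpoint's evidence weak: the
#'   response profile enters each of its own product regressors, so a
#'   high-variance target can retain nearly any partner. Requiring reciprocal
#'   significance suppresses such one-sided false positives.
#' @return An [identified_gen()]. Edges carry the fitted ability, the signed
#'   coefficient on the regressor profile (`-c_il` for miRNA edges), SE, t and
#'   p-value; `basal` carries `h_i` (model `"ppi"`) and `k_i` (model `"grn"`)
#'   with SEs and residual variances.
#' @export
identify_gen <- function(data, candidates, alpha = 0.05, group = NULL,
                         ppi_reciprocal = TRUE) {
  stopifnot(inherits(data, "cohort_dataset"),
            inherits(candidates, "candidate_gen"))
  stopifnot_scalar_prob(alpha, "alpha")
  if (is.null(group)) {
    g <- unique(data$sample_groups)
    group <- if (length(g) == 1L) g else NA_character_
  }
  nodes <- intersect(candidates$node_ids, data$node_ids)
  if (!length(nodes)) stop("no candidate nodes present in the data",
                           call. = FALSE)

  edge_rows <- list()
  basal_rows <- list()
  failures <- character(0)

  for (node in nodes) {
    for (model in c("ppi", "grn")) {
      res <- tryCatch({
        problem <- if (model == "ppi") {
          build_ppi_problem(node, data, candidates)
        } else {
          build_grn_problem(node, data, candidates)
        }
        detect_order_and_prune(problem, alpha = alpha)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s/%s: %s", node, model,
                                        conditionMessage(res)))
        next
      }
      est <- res$estimates
      reg <- est[est$type != "basal", , drop = FALSE]
      if (nrow(reg)) {
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          target = node, regulator = reg$partner, type = reg$type,
          ability = reg$estimate,
          signed_coef = ifelse(reg$type == "mirna", -reg$estimate,
                               reg$estimate),
          se = reg$se, t = reg$t, p_value = reg$p_value,
          stringsAsFactors = FALSE
        )
      }
      b <- est[est$type == "basal", , drop = FALSE]
      basal_rows[[length(basal_rows) + 1L]] <- data.frame(
        node = node, model = model, estimate = b$estimate, se = b$se,
        sigma2 = res$sigma2, stringsAsFactors = FALSE
      )
    }
  }

  if (length(failures) == 2L * length(nodes)) {
    stop("identification failed for every target; first error: ",
         failures[1], call. = FALSE)
  }
  if (length(failures)) {
    warning(length(failures), " target model(s) skipped: ",
            paste(utils::head(failures, 5), collapse = "; "),
            if (length(failures) > 5) " ...", call. = FALSE)
  }

  edges <- if (length(edge_rows)) {
    e <- do.call(rbind, edge_rows)
    if (ppi_reciprocal && any(e$type == "ppi")) {
      is_ppi <- e$type == "ppi"
      pair <- paste(pmin(e$target, e$regulator),
                    pmax(e$target, e$regulator), sep = "\r")
      seen_twice <- names(which(table(pair[is_ppi]) == 2L))
      e <- e[!is_ppi | pair %in% seen_twice, , drop = FALSE]
      rownames(e) <- NULL
    }
    e
  } else {
    data.frame(target = character(), regulator = character(),
               type = character(), ability = numeric(),
               signed_coef = numeric(), se = numeric(), t = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  }
  basal <- if (length(basal_rows)) {
    do.call(rbind, basal_rows)
  } else {
    data.frame(node = character(), model = character(), estimate = numeric(),
               se = numeric(), sigma2 = numeric(), stringsAsFactors = FALSE)
  }
  out <- identified_gen(edges, basal,
                        node_ids = nodes,
                        mirna_ids = candidates$mirna_ids,
                        group = group)
  attr(out, "failures") <- failures
  out
}
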