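# regression problem builders, least squares, AIC, order detection

test_that("PPI problems hold product regressors plus a final intercept", {
  y <- rbind(G1 = c(1, 2), G2 = c(3, 4), G3 = c(5, 6))
  d <- make_cohort(y, "a", protein = y)
  cand <- candidate_gen(
    ppi_edges = data.frame(node_a = "G1", node_b = "G2"),
    tf_edges = data.frame(tf = character(), target = character()),
    mirna_edges = data.frame(mirna = character(), target = character()),
    node_ids = c("G1", "G2", "G3"), mirna_ids = character()
  )
  prob <- build_ppi_problem("G1", d, cand)
  expect_equal(unname(prob$design[, "ppi:G2"]), c(3, 8))
  expect_equal(colnames(prob$design), c("ppi:G2", "basal"))
  expect_equal(unname(prob$design[, "basal"]), c(1, 1))

  # no partners -> intercept only
  prob3 <- build_ppi_problem("G3", d, cand)
  expect_equal(colnames(prob3$design), "basal")
})

test_that("PPI design equals an independently composed matrix", {
  set.seed(5)
  y <- matrix(stats::rnorm(4 * 5, 3), 4, 5,
              dimnames = list(c("G1", "G2", "G3", "G4"), NULL))
  d <- make_cohort(y, "a", protein = y)
  cand <- candidate_gen(
    ppi_edges = data.frame(node_a = c("G1", "G1", "G1"),
                           node_b = c("G2", "G3", "G4")),
    tf_edges = data.frame(tf = character(), target = character()),
    mirna_edges = data.frame(mirna = character(), target = character()),
    node_ids = rownames(y), mirna_ids = character()
  )
  prob <- build_ppi_problem("G1", d, cand)
  manual <- cbind(y["G1", ] * y["G2", ], y["G1", ] * y["G3", ],
                  y["G1", ] * y["G4", ], 1)
  expect_equal(unname(prob$design), unname(manual))

  # a partner absent from the expression data is a named error
  cand5 <- candidate_gen(
    ppi_edges = data.frame(node_a = "G1", node_b = "G5"),
    tf_edges = data.frame(tf = character(), target = character()),
    mirna_edges = data.frame(mirna = character(), target = character()),
    node_ids = c(rownames(y), "G5"), mirna_ids = character()
  )
  expect_error(build_ppi_problem("G1", d, cand5), "G5")
})

test_that("GRN problems negate miRNA profiles and order TF columns first", {
  y <- rbind(G1 = c(1, 1, 1), G2 = c(2, 1, 0), G3 = c(0, 1, 2))
  mir <- rbind(M1 = c(2, 5, 1), M2 = c(1, 1, 3))
  d <- make_cohort(y, "a", mirna = mir, protein = y)
  cand <- candidate_gen(
    ppi_edges = data.frame(node_a = character(), node_b = character()),
    tf_edges = data.frame(tf = c("G2", "G3"), target = c("G1", "G1")),
    mirna_edges = data.frame(mirna = c("M1", "M2"), target = c("G1", "G1")),
    node_ids = rownames(y), mirna_ids = rownames(mir)
  )
  prob <- build_grn_problem("G1", d, cand)
  manual <- cbind(y["G2", ], y["G3", ], -mir["M1", ], -mir["M2", ], 1)
  expect_equal(unname(prob$design), unname(manual))
  expect_equal(prob$labels$type, c("tf", "tf", "mirna", "mirna", "basal"))
  expect_equal(unname(prob$design[, "mirna:M1"]), c(-2, -5, -1))
})

test_that("least squares matches closed forms and an independent solver", {
  # response exactly twice a single regressor
  x <- c(1, 2, 3, 4, 5)
  fit <- least_squares_fit(make_problem(cbind("tf:R1" = x), 2 * x))
  expect_equal(fit$estimates$estimate[1], 2)
  expect_equal(fit$rss, 0)
  expect_equal(fit$estimates$p_value[fit$estimates$label == "tf:R1"], 0)

  # intercept-only -> sample mean
  y <- c(4, 6, 11)
  fit0 <- least_squares_fit(make_problem(
    matrix(numeric(), 3, 0), y
  ))
  expect_equal(fit0$estimates$estimate, mean(y))

  # random fixture vs normal equations and vs lm()
  set.seed(6)
  X <- matrix(stats::rnorm(30), 10, 3)
  yy <- stats::rnorm(10)
  prob <- make_problem(X, yy)
  fit3 <- least_squares_fit(prob)
  D <- cbind(X, 1)
  beta_ne <- solve(crossprod(D), crossprod(D, yy))
  expect_lt(max(abs(fit3$estimates$estimate - drop(beta_ne))), 1e-10)
  lf <- summary(stats::lm(yy ~ X))$coefficients
  expect_lt(max(abs(fit3$estimates$se - lf[c(2:4, 1), 2])), 1e-10)
  expect_lt(max(abs(fit3$estimates$p_value - lf[c(2:4, 1), 4])), 1e-10)
})

test_that("degenerate designs are resolved deterministically", {
  set.seed(7)
  x1 <- stats::rnorm(20)
  # constant column collapses into the intercept
  prob_const <- make_problem(cbind("tf:R1" = x1, "tf:R2" = rep(2, 20)),
                             x1 + 1)
  expect_message(fit <- least_squares_fit(prob_const), "constant")
  expect_false("tf:R2" %in% fit$estimates$label)

  # duplicated column: the rightmost of the dependency is dropped
  prob_dup <- make_problem(cbind("tf:R1" = x1, "tf:R2" = x1), x1)
  expect_warning(fit2 <- least_squares_fit(prob_dup), "dependent")
  expect_identical(fit2$dropped$label, "tf:R2")

  # more parameters than samples is an error
  Xbig <- matrix(stats::rnorm(12), 3, 4)
  expect_error(
    suppressWarnings(least_squares_fit(make_problem(Xbig, stats::rnorm(3)))),
    "reduce the candidate set"
  )
})

test_that("AIC follows n*ln(rss/n) + 2p", {
  expect_equal(aic_score(20, 20, 0), 0)
  expect_equal(aic_score(3.7, 20, 5) - aic_score(3.7, 20, 4), 2)
  expect_equal(aic_score(3.7, 20, 4), 20 * log(3.7 / 20) + 8)
  expect_message(expect_identical(aic_score(0, 10, 2), -Inf), "perfect")
})

test_that("backward elimination keeps strong signals and visits a nested path", {
  set.seed(10)
  n <- 100
  X <- matrix(stats::rnorm(n * 6), n, 6)
  colnames(X) <- sprintf("tf:R%02d", 1:6)
  y <- 0.5 * X[, 3] + stats::rnorm(n, sd = 0.1)  # |coef|/sd = 5
  fit <- detect_order_and_prune(make_problem(X, y))
  kept <- fit$estimates$label[fit$estimates$type != "basal"]
  expect_true("tf:R03" %in% kept)
  # the backward path removes one regressor per step
  expect_equal(fit$aic_path$n_regressors, 6:0)
  expect_true(all(fit$estimates$p_value[fit$estimates$type != "basal"] < 0.05))
  # every elimination is recorded with a reason
  expect_true(all(fit$eliminated$reason %in% c("aic", "ttest",
                                               "constant", "collinear")))
  expect_setequal(c(kept, fit$eliminated$label), colnames(X))
})

test_that("estimates are invariant to regressor column order", {
  set.seed(12)
  X <- matrix(stats::rnorm(200), 50, 4)
  colnames(X) <- sprintf("tf:R%02d", 1:4)
  y <- X %*% c(1, 0.5, 0, 0) + stats::rnorm(50, sd = 0.2)
  f1 <- detect_order_and_prune(make_problem(X, drop(y)))
  perm <- c(3, 1, 4, 2)
  f2 <- detect_order_and_prune(make_problem(X[, perm], drop(y)))
  e1 <- f1$estimates[order(f1$estimates$label), ]
  e2 <- f2$estimates[order(f2$estimates$label), ]
  expect_equal(e1$label, e2$label)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
})

test_that("identification with empty candidates returns basal levels only", {
  cfg <- sim_config(n_nodes = 8, n_mirnas = 2, ppi_density = 0,
                    tf_density = 0, mirna_density = 0, seed = 2)
  gt <- generate_ground_truth(cfg)
  d <- simulate_cohort(gt, "young", n = 10)
  cand <- emit_candidate_network(gt, fp_fraction = 0)
  gen <- identify_gen(d, cand)
  expect_equal(nrow(gen$edges), 0L)
  expect_equal(nrow(gen$basal), 16L)  # ppi + grn intercept per node
  # basal estimates are the sample means of the degenerate models
  h_hat <- gen$basal$estimate[gen$basal$model == "ppi"]
  expect_equal(h_hat, unname(rowMeans(d$protein_expr)))
})

test_that("noiseless identification recovers the planted support exactly", {
  cfg <- sim_config(n_nodes = 50, n_mirnas = 10, seed = 19)
  gt <- generate_ground_truth(cfg)
  gt$noise_sd <- 0
  cand <- emit_candidate_network(gt, fp_fraction = 0.5)
  d <- simulate_cohort(gt, "elderly", n = 60, mode = "regression_faithful")
  gen <- suppressMessages(suppressWarnings(identify_gen(d, cand)))
  expect_setequal(identified_support(gen), true_support(gt))
})

test_that("recovered regulatory abilities sit within three standard errors", {
  errs <- c(); ses <- c()
  for (s in 1:3) {
    cfg <- sim_config(n_nodes = 40, n_mirnas = 10, seed = 100 + s)
    gt <- generate_ground_truth(cfg)
    cand <- emit_candidate_network(gt, fp_fraction = 0.5)
    d <- simulate_cohort(gt, "elderly", n = 146,
                         mode = "regression_faithful")
    gen <- suppressMessages(suppressWarnings(identify_gen(d, cand)))
    tf_hat <- gen$edges[gen$edges$type == "tf", ]
    key_hat <- paste(tf_hat$regulator, tf_hat$target)
    key_true <- paste(gt$tf_reg$tf, gt$tf_reg$target)
    shared <- intersect(key_hat, key_true)
    errs <- c(errs, abs(tf_hat$ability[match(shared, key_hat)] -
                          gt$tf_reg$ability[match(shared, key_true)]))
    ses <- c(ses, tf_hat$se[match(shared, key_hat)])
  }
  expect_gt(length(errs), 10)
  expect_lt(mean(errs), 3 * mean(ses))
})
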