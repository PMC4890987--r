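# synthetic-data generator: ground truth, candidate emission, forward model

test_that("zero edge density yields empty ability maps with basal levels", {
  gt <- toy_gt(n_nodes = 10, n_mirnas = 3)
  expect_equal(nrow(gt$ppi), 0)
  expect_equal(nrow(gt$tf_reg), 0)
  expect_equal(nrow(gt$mirna_reg), 0)
  expect_length(gt$basal_protein, 10)
  expect_equal(dim(gt$basal_gene), c(10L, 2L))
  expect_true(all(is.finite(gt$basal_protein)))
})

test_that("generation, candidate emission and simulation are seed-deterministic", {
  cfg <- sim_config(n_nodes = 30, n_mirnas = 6, seed = 11)
  expect_identical(generate_ground_truth(cfg), generate_ground_truth(cfg))
  gt <- generate_ground_truth(cfg)
  expect_identical(emit_candidate_network(gt), emit_candidate_network(gt))
  expect_identical(simulate_cohort(gt, "young"), simulate_cohort(gt, "young"))
  expect_identical(
    simulate_cohort(gt, "elderly", mode = "regression_faithful"),
    simulate_cohort(gt, "elderly", mode = "regression_faithful")
  )
})

test_that("ground-truth structure respects configured invariants", {
  cfg <- sim_config(n_nodes = 60, n_mirnas = 12, seed = 13)
  gt <- generate_ground_truth(cfg)
  ids <- gt$node_ids
  expect_true(all(c(gt$ppi$node_a, gt$ppi$node_b, gt$tf_reg$target) %in% ids))
  expect_true(all(gt$tf_reg$tf %in% gt$tf_ids))
  expect_true(all(gt$mirna_reg$mirna %in% gt$mirna_ids))
  # per-target regulator counts within caps
  expect_true(all(table(gt$ppi$node_a) <= cfg$max_ppi_partners))
  expect_true(all(table(gt$ppi$node_b) <= cfg$max_free_ppi_partners))
  expect_true(all(table(gt$tf_reg$target) <= cfg$max_tf_regulators))
  expect_true(all(table(gt$mirna_reg$target) <= cfg$max_mirna_regulators))
  # densities implying counts above caps are rejected
  expect_error(sim_config(n_nodes = 100, mirna_density = 0.5),
               "max_mirna_regulators")
})

test_that("realized edge counts sit in the binomial 99% envelope", {
  cfg <- sim_config(n_nodes = 50, n_mirnas = 10, ppi_density = 0.05,
                    tf_density = 0.05, mirna_density = 0.05,
                    max_ppi_partners = 10, max_free_ppi_partners = 10,
                    max_tf_regulators = 10, max_mirna_regulators = 10,
                    seed = 21)
  gt <- generate_ground_truth(cfg)
  # independent expectation: count eligible pairs by brute force
  half <- floor(50 / 2)
  n_ppi_pairs <- length(gt$solved_half) * length(gt$free_half)
  n_tf_pairs <- sum(vapply(gt$tf_ids, function(tf) {
    sum(gt$node_ids != tf)
  }, numeric(1)))
  n_mir_pairs <- length(gt$mirna_ids) * length(gt$node_ids)
  envelope <- function(npairs, p) {
    npairs * p + c(-1, 1) * stats::qnorm(0.995) * sqrt(npairs * p * (1 - p))
  }
  for (spec in list(list(nrow(gt$ppi), n_ppi_pairs),
                    list(nrow(gt$tf_reg), n_tf_pairs),
                    list(nrow(gt$mirna_reg), n_mir_pairs))) {
    env <- envelope(spec[[2]], 0.05)
    expect_gte(spec[[1]], env[1])
    expect_lte(spec[[1]], env[2])
  }
})

test_that("degenerate model (no edges, vanishing noise) returns basal levels", {
  gt <- toy_gt(n_nodes = 6, n_mirnas = 2)
  gt$noise_sd <- 1e-10
  d <- simulate_cohort(gt, "young", n = 5)
  expect_lt(max(abs(d$protein_expr - gt$basal_protein)), 1e-7)
  expect_lt(max(abs(d$gene_expr - gt$basal_gene[, "young"])), 1e-7)
  expect_true(all(d$mirna_expr > 0))
})

test_that("a single TF regulation propagates exactly into the target", {
  gt <- toy_gt(n_nodes = 4, n_mirnas = 1)
  gt$tf_reg <- data.frame(tf = "G0003", target = "G0001", ability = 1,
                          stringsAsFactors = FALSE)
  gt$noise_sd <- 1e-12
  d <- simulate_cohort(gt, "young", n = 6)
  expect_lt(max(abs(d$gene_expr["G0001", ] -
                      (d$protein_expr["G0003", ] +
                         gt$basal_gene["G0001", "young"]))), 1e-8)
})

test_that("forward-model residual moments match the configured noise", {
  cfg <- sim_config(n_nodes = 30, n_mirnas = 8, seed = 31)
  gt <- generate_ground_truth(cfg)
  d <- simulate_cohort(gt, "young", n = 500, seed = 77,
                       mode = "regression_faithful")
  # direct independent recomputation of the gene-regulatory prediction
  pred <- matrix(gt$basal_gene[, "young"], 30, 500,
                 dimnames = dimnames(d$gene_expr))
  for (r in seq_len(nrow(gt$tf_reg))) {
    pred[gt$tf_reg$target[r], ] <- pred[gt$tf_reg$target[r], ] +
      gt$tf_reg$ability[r] * d$protein_expr[gt$tf_reg$tf[r], ]
  }
  for (r in seq_len(nrow(gt$mirna_reg))) {
    pred[gt$mirna_reg$target[r], ] <- pred[gt$mirna_reg$target[r], ] -
      gt$mirna_reg$ability[r] * d$mirna_expr[gt$mirna_reg$mirna[r], ]
  }
  res <- as.vector(d$gene_expr - pred)
  n_tot <- length(res)
  expect_lt(abs(mean(res)), 3 * gt$noise_sd / sqrt(n_tot))
  expect_lt(abs(stats::var(res) - gt$noise_sd^2),
            3 * gt$noise_sd^2 * sqrt(2 / (n_tot - 1)))
})

test_that("candidate emission adds the requested decoys and keeps all true edges", {
  cfg <- sim_config(n_nodes = 60, n_mirnas = 15, seed = 41)
  gt <- generate_ground_truth(cfg)

  cand0 <- emit_candidate_network(gt, fp_fraction = 0)
  expect_setequal(paste(cand0$ppi_edges$node_a, cand0$ppi_edges$node_b),
                  paste(gt$ppi$node_a, gt$ppi$node_b))
  expect_setequal(paste(cand0$tf_edges$tf, cand0$tf_edges$target),
                  paste(gt$tf_reg$tf, gt$tf_reg$target))
  expect_setequal(paste(cand0$mirna_edges$mirna, cand0$mirna_edges$target),
                  paste(gt$mirna_reg$mirna, gt$mirna_reg$target))

  cand <- emit_candidate_network(gt, fp_fraction = 0.5)
  # fp_fraction 0.5 -> as many decoys as true edges, per type
  expect_equal(nrow(cand$ppi_edges), 2L * nrow(gt$ppi))
  expect_equal(nrow(cand$tf_edges), 2L * nrow(gt$tf_reg))
  expect_equal(nrow(cand$mirna_edges), 2L * nrow(gt$mirna_reg))
  # superset property and no duplicated edges, by set arithmetic
  key <- function(df) paste(df[[1]], df[[2]])
  expect_true(all(key(gt$ppi) %in% key(cand$ppi_edges)))
  expect_true(all(key(gt$tf_reg) %in% key(cand$tf_edges)))
  expect_true(all(key(gt$mirna_reg) %in% key(cand$mirna_edges)))
  expect_equal(anyDuplicated(key(cand$ppi_edges)), 0L)
  expect_equal(anyDuplicated(key(cand$tf_edges)), 0L)
  expect_equal(anyDuplicated(key(cand$mirna_edges)), 0L)
})

test_that("ill-conditioned abilities are rejected by the stability bound", {
  gt <- toy_gt(n_nodes = 4, n_mirnas = 1)
  # place the denominator 1 - a * y_j near zero for the solved node
  a_bad <- 1 / unname(gt$basal_protein["G0003"])
  gt$ppi <- data.frame(node_a = "G0001", node_b = "G0003", ability = a_bad,
                       stringsAsFactors = FALSE)
  expect_error(simulate_cohort(gt, "young", n = 50, seed = 5,
                               mode = "regression_faithful"),
               "stability bound")
  expect_error(simulate_cohort(gt, "young", n = 50, seed = 5,
                               mode = "fixed_point"),
               "stability bound")
})
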