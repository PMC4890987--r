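# shared fixture builders: everything is generated in code at test time

# ground truth with no edges and no planted shifts, ready for injection
toy_gt <- function(n_nodes = 4, n_mirnas = 2, seed = 1, ...) {
  cfg <- sim_config(n_nodes = n_nodes, n_mirnas = n_mirnas,
                    ppi_density = 0, tf_density = 0, mirna_density = 0,
                    meth_fraction = 0, de_fraction = 0, seed = seed, ...)
  generate_ground_truth(cfg)
}

# wrap a raw regressor matrix (no intercept) into a regression problem
make_problem <- function(X, y, types = NULL, target = "T1") {
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("tf:R%02d", seq_len(p))
  if (is.null(types)) types <- rep("tf", p)
  design <- cbind(X, basal = rep(1, nrow(X)))
  regression_problem(
    target, y, design,
    data.frame(label = colnames(design),
               type = c(types, "basal"),
               partner = c(sub("^[a-z]+:", "", colnames(X)), NA_character_),
               stringsAsFactors = FALSE)
  )
}

# cohort dataset from bare matrices (protein == gene unless given)
make_cohort <- function(expr, group, mirna = NULL, protein = NULL) {
  n <- ncol(expr)
  samples <- sprintf("%s_%03d", group, seq_len(n))
  colnames(expr) <- samples
  if (is.null(protein)) protein <- expr
  colnames(protein) <- samples
  if (is.null(mirna)) {
    mirna <- matrix(numeric(), nrow = 0, ncol = n,
                    dimnames = list(character(), samples))
  } else {
    colnames(mirna) <- samples
  }
  cohort_dataset(protein, expr, mirna,
                 stats::setNames(rep(group, n), samples))
}

# canonical edge keys: PPI pairs are unordered
canon_key <- function(type, from, to) {
  ifelse(type == "ppi",
         paste(type, pmin(from, to), pmax(from, to)),
         paste(type, from, to))
}

true_support <- function(gt) {
  unique(c(
    if (nrow(gt$ppi)) paste("ppi", pmin(gt$ppi$node_a, gt$ppi$node_b),
                            pmax(gt$ppi$node_a, gt$ppi$node_b)),
    if (nrow(gt$tf_reg)) paste("tf", gt$tf_reg$tf, gt$tf_reg$target),
    if (nrow(gt$mirna_reg)) paste("mirna", gt$mirna_reg$mirna,
                                  gt$mirna_reg$target)
  ))
}

identified_support <- function(gen) {
  unique(canon_key(gen$edges$type, gen$edges$regulator, gen$edges$target))
}

# synthetic identified network (abilities set directly, no fitting)
make_identified <- function(edges, node_ids, mirna_ids = character(),
                            group = "A") {
  k <- nrow(edges)
  edges$signed_coef <- ifelse(edges$type == "mirna", -edges$ability,
                              edges$ability)
  edges$se <- rep(0.01, k)
  edges$t <- edges$ability / 0.01
  edges$p_value <- rep(1e-4, k)
  basal <- data.frame(node = rep(node_ids, 2),
                      model = rep(c("ppi", "grn"), each = length(node_ids)),
                      estimate = 1, se = 0.1, sigma2 = 0.01,
                      stringsAsFactors = FALSE)
  identified_gen(edges, basal, node_ids, mirna_ids, group = group)
}
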