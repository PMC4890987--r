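#' Simulation configuration for synthetic GEN studies
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' emulate the study conditions the pipeline targets: two unequal cohorts
#' (30 young vs 146 elderly samples), a sparse true network buried in a
#' candidate network with false-positive edges, group-specific basal-level
#' shifts on a subset of genes (DNA-methylation surrogates) and a subset of
#' differentially expressed genes.
#'
#' PPI pairs are drawn across a fixed bipartition of the node set (first half
#' vs second half). This keeps the bilinear association model identifiable in
#' the regression-faithful simulation mode (see [simulate_cohort()]): one side
#' of every association can be given freely varying profiles while the other
#' side satisfies the model exactly.
#'
#' @param n_nodes Number of protein/gene nodes `N`.
#' @param n_mirnas Number of miRNAs `O`.
#' @param groups Character vector of group labels; the first group is the
#'   reference, later groups receive the planted methylation and expression
#'   shifts.
#' @param n_samples Integer vector of per-group sample counts (recycled
#'   against `groups`).
#' @param tf_fraction Fraction of nodes designated as TFs (drawn from the
#'   free half of the bipartition so TF regressors vary across samples).
#' @param ppi_density,tf_density,mirna_density Per-eligible-pair edge
#'   probabilities for the three edge types.
#' @param max_ppi_partners,max_tf_regulators,max_mirna_regulators Hard caps on
#'   per-target regulator counts; configurations whose expected counts exceed
#'   a cap are rejected.
#' @param max_free_ppi_partners Cap on the PPI degree of free-half nodes
#'   (default 1). With a single association per free node, each free node's
#'   own bilinear regression involves one genuine partner, which keeps the
#'   regression-faithful data interpretable from both endpoints of a pair.
#' @param ppi_ability_range,tf_ability_range,mirna_ability_range Magnitude
#'   ranges for the drawn abilities `a_ij`, `b_ij`, `c_il`. PPI and TF
#'   abilities get random signs; miRNA repression abilities are positive
#'   (repression enters the model as `-c_il * mir_l`).
#' @param basal_protein_range,basal_gene_range Uniform ranges for basal levels
#'   `h_i` and `k_i`.
#' @param meth_fraction,meth_shift Fraction of nodes given a group-specific
#'   basal-level (`k_i`) shift, and the shift magnitude (expression units).
#' @param de_fraction,de_shift Fraction of nodes given a planted group mean
#'   shift in gene expression, and its magnitude.
#' @param noise_sd Residual standard deviation of the model noises `v_i`,
#'   `w_i`; must be positive.
#' @param mirna_log_mean,mirna_log_sd Log-normal parameters for miRNA
#'   profiles (expression-like positive values).
#' @param profile_sd Sample-to-sample standard deviation of the freely drawn
#'   protein profiles in regression-faithful simulation.
#' @param fp_fraction Default decoy fraction for [emit_candidate_network()]:
#'   the fraction of candidate edges that are false positives.
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_nodes = 100L,
                       n_mirnas = 20L,
                       groups = c("young", "elderly"),
                       n_samples = c(30L, 146L),
                       tf_fraction = 0.2,
                       ppi_density = 0.02,
                       tf_density = 0.02,
                       mirna_density = 0.05,
                       max_ppi_partners = 4L,
                       max_free_ppi_partners = 1L,
                       max_tf_regulators = 4L,
                       max_mirna_regulators = 4L,
                       ppi_ability_range = c(0.01, 0.025),
                       tf_ability_range = c(0.3, 1),
                       mirna_ability_range = c(0.3, 1),
                       basal_protein_range = c(2, 4),
                       basal_gene_range = c(1, 3),
                       meth_fraction = 0.1,
                       meth_shift = 0.5,
                       de_fraction = 0.1,
                       de_shift = 0.3,
                       noise_sd = 0.1,
                       mirna_log_mean = 0,
                       mirna_log_sd = 0.4,
                       profile_sd = 1.2,
                       fp_fraction = 0.5,
                       seed = 1L) {
  n_nodes <- stopifnot_count(n_nodes, "n_nodes", min = 2L)
  n_mirnas <- stopifnot_count(n_mirnas, "n_mirnas", min = 0L)
  seed <- stopifnot_count(seed, "seed", min = 0L)
  if (length(groups) < 1L || anyDuplicated(groups)) {
    stop("`groups` must be distinct labels", call. = FALSE)
  }
  n_samples <- rep_len(as.integer(n_samples), length(groups))
  if (any(n_samples < 2L)) stop("each group needs >= 2 samples", call. = FALSE)
  names(n_samples) <- groups
  for (nm in c("ppi_density", "tf_density", "mirna_density")) {
    stopifnot_scalar_prob(get(nm), nm, open_left = FALSE)
  }
  stopifnot_scalar_prob(fp_fraction, "fp_fraction", open_left = FALSE)
  stopifnot_scalar_prob(tf_fraction, "tf_fraction", open_left = FALSE)
  if (!(is.numeric(noise_sd) && noise_sd > 0)) {
    stop("`noise_sd` must be > 0", call. = FALSE)
  }
  for (nm in c("ppi_ability_range", "tf_ability_range", "mirna_ability_range",
               "basal_protein_range", "basal_gene_range")) {
    r <- get(nm)
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("`%s` must be a finite increasing pair", nm), call. = FALSE)
    }
  }

  half <- floor(n_nodes / 2)
  n_tfs <- max(0L, round(tf_fraction * n_nodes))
  if (ppi_density * (n_nodes - half) > max_ppi_partners) {
    stop("`ppi_density` implies expected partner counts above ",
         "`max_ppi_partners`; lower the density or raise the cap",
         call. = FALSE)
  }
  if (ppi_density * half > max_free_ppi_partners) {
    stop("`ppi_density` implies expected free-half partner counts above ",
         "`max_free_ppi_partners`; lower the density or raise the cap",
         call. = FALSE)
  }
  if (tf_density * n_tfs > max_tf_regulators) {
    stop("`tf_density` implies expected TF regulator counts above ",
         "`max_tf_regulators`", call. = FALSE)
  }
  if (mirna_density * n_mirnas > max_mirna_regulators) {
    stop("`mirna_density` implies expected miRNA regulator counts above ",
         "`max_mirna_regulators`", call. = FALSE)
  }

  structure(
    list(
      n_nodes = n_nodes, n_mirnas = n_mirnas,
      groups = groups, n_samples = n_samples,
      tf_fraction = tf_fraction,
      ppi_density = ppi_density, tf_density = tf_density,
      mirna_density = mirna_density,
      max_ppi_partners = as.integer(max_ppi_partners),
      max_free_ppi_partners = as.integer(max_free_ppi_partners),
      max_tf_regulators = as.integer(max_tf_regulators),
      max_mirna_regulators = as.integer(max_mirna_regulators),
      ppi_ability_range = ppi_ability_range,
      tf_ability_range = tf_ability_range,
      mirna_ability_range = mirna_ability_range,
      basal_protein_range = basal_protein_range,
      basal_gene_range = basal_gene_range,
      meth_fraction = meth_fraction, meth_shift = meth_shift,
      de_fraction = de_fraction, de_shift = de_shift,
      noise_sd = noise_sd,
      mirna_log_mean = mirna_log_mean, mirna_log_sd = mirna_log_sd,
      profile_sd = profile_sd,
      fp_fraction = fp_fraction,
      seed = seed
    ),
    class = "sim_config"
  )
}

# cap per-node edge counts deterministically: scan edges in order and keep an
# edge only while both endpoints are under their cap
cap_edges <- function(df, count_cols, cap) {
  if (!nrow(df)) return(df)
  counts <- new.env(parent = emptyenv())
  keep <- logical(nrow(df))
  for (r in seq_len(nrow(df))) {
    keys <- as.character(unlist(df[r, count_cols, drop = FALSE]))
    vals <- vapply(keys, function(k) {
      if (is.null(counts[[k]])) 0L else counts[[k]]
    }, integer(1))
    if (all(vals < cap)) {
      keep[r] <- TRUE
      for (k in keys) counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  df[keep, , drop = FALSE]
}

#' Generate a ground-truth genetic-and-epigenetic network
#'
#' Draws a sparse true network — symmetric protein-association pairs with
#' abilities `a_ij`, TF regulations `b_ij`, miRNA repressions `c_il` — plus
#' basal levels (`h_i`; group-specific `k_i` encoding DNA-methylation
#' surrogates) and a planted set of differentially expressed nodes. Edges are
#' Bernoulli draws at the configured densities; per-node regulator counts are
#' capped at the configured maxima (excess edges are dropped
#' deterministically, which is rare at admissible densities).
#'
#' @param config A [sim_config()].
#' @return An object of class `gen_ground_truth`: node/miRNA/TF ids, ability
#'   tables `ppi` (`node_a`, `node_b`, `ability`), `tf_reg`
#'   (`tf`, `target`, `ability`), `mirna_reg` (`mirna`, `target`, `ability`),
#'   `basal_protein` (named vector `h_i`), `basal_gene` (nodes x groups matrix
#'   of `k_i`), `meth_nodes`, `de_nodes`, `noise_sd` and the config.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    N <- config$n_nodes
    O <- config$n_mirnas
    node_ids <- sprintf("G%04d", seq_len(N))
    mirna_ids <- if (O > 0) sprintf("MIR%03d", seq_len(O)) else character()
    half <- floor(N / 2)
    solved_half <- node_ids[seq_len(half)]
    free_half <- node_ids[(half + 1):N]
    n_tfs <- min(length(free_half), max(0L, round(config$tf_fraction * N)))
    tf_ids <- sort(sample(free_half, n_tfs))

    draw_sign <- function(k) sample(c(-1, 1), k, replace = TRUE)
    draw_mag <- function(k, range) stats::runif(k, range[1], range[2])

    # PPI pairs across the bipartition
    pairs <- expand.grid(node_a = solved_half, node_b = free_half,
                         stringsAsFactors = FALSE)
    take <- stats::runif(nrow(pairs)) < config$ppi_density
    ppi <- pairs[take, , drop = FALSE]
    ppi <- cap_edges(ppi, "node_a", config$max_ppi_partners)
    # by default each free-half node carries at most one true association, so
    # its own bilinear regression stays interpretable (see ?sim_config)
    ppi <- cap_edges(ppi, "node_b", config$max_free_ppi_partners)
    ppi$ability <- draw_sign(nrow(ppi)) *
      draw_mag(nrow(ppi), config$ppi_ability_range)
    rownames(ppi) <- NULL

    # TF -> target regulations
    tf_pairs <- expand.grid(tf = tf_ids, target = node_ids,
                            stringsAsFactors = FALSE)
    tf_pairs <- tf_pairs[tf_pairs$tf != tf_pairs$target, , drop = FALSE]
    take <- stats::runif(nrow(tf_pairs)) < config$tf_density
    tf_reg <- tf_pairs[take, , drop = FALSE]
    tf_reg <- cap_edges(tf_reg, "target", config$max_tf_regulators)
    tf_reg$ability <- draw_sign(nrow(tf_reg)) *
      draw_mag(nrow(tf_reg), config$tf_ability_range)
    rownames(tf_reg) <- NULL

    # miRNA -> target repressions (positive abilities, Eq-style sign kept by
    # the model: repression enters as -c_il * mir_l)
    mir_pairs <- expand.grid(mirna = mirna_ids, target = node_ids,
                             stringsAsFactors = FALSE)
    take <- stats::runif(nrow(mir_pairs)) < config$mirna_density
    mirna_reg <- mir_pairs[take, , drop = FALSE]
    mirna_reg <- cap_edges(mirna_reg, "target", config$max_mirna_regulators)
    mirna_reg$ability <- draw_mag(nrow(mirna_reg), config$mirna_ability_range)
    rownames(mirna_reg) <- NULL

    basal_protein <- stats::setNames(
      draw_mag(N, config$basal_protein_range), node_ids)
    k_base <- draw_mag(N, config$basal_gene_range)
    basal_gene <- matrix(k_base, nrow = N, ncol = length(config$groups),
                         dimnames = list(node_ids, config$groups))
    n_meth <- round(config$meth_fraction * N)
    meth_nodes <- if (n_meth > 0) sort(sample(node_ids, n_meth)) else character()
    if (length(config$groups) > 1L && length(meth_nodes)) {
      basal_gene[meth_nodes, -1L] <-
        basal_gene[meth_nodes, -1L] + config$meth_shift
    }
    n_de <- round(config$de_fraction * N)
    de_nodes <- if (n_de > 0) sort(sample(node_ids, n_de)) else character()

    structure(
      list(
        node_ids = node_ids, mirna_ids = mirna_ids, tf_ids = tf_ids,
        solved_half = solved_half, free_half = free_half,
        ppi = ppi, tf_reg = tf_reg, mirna_reg = mirna_reg,
        basal_protein = basal_protein, basal_gene = basal_gene,
        meth_nodes = meth_nodes, de_nodes = de_nodes,
        noise_sd = config$noise_sd,
        config = config
      ),
      class = "gen_ground_truth"
    )
  })
}

#' @export
print.gen_ground_truth <- function(x, ...) {
  cat("<gen_ground_truth>\n")
  cat(sprintf("  nodes: %d (%d TFs), miRNAs: %d\n",
              length(x$node_ids), length(x$tf_ids), length(x$mirna_ids)))
  cat(sprintf("  true edges: %d ppi, %d tf, %d mirna\n",
              nrow(x$ppi), nrow(x$tf_reg), nrow(x$mirna_reg)))
  cat(sprintf("  methylation-shift nodes: %d, DE nodes: %d\n",
              length(x$meth_nodes), length(x$de_nodes)))
  invisible(x)
}

sample_decoys <- function(n_decoy, pool_a, pool_b, taken_keys,
                          unordered = FALSE, forbid_equal = TRUE) {
  # rejection-sample unique (a, b) pairs not among `taken_keys`
  if (n_decoy == 0L) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  seen <- taken_keys
  out_a <- character(0)
  out_b <- character(0)
  tries <- 0L
  while (length(out_a) < n_decoy && tries < 10000L) {
    tries <- tries + 1L
    need <- n_decoy - length(out_a)
    a <- sample(pool_a, 2L * need + 10L, replace = TRUE)
    b <- sample(pool_b, 2L * need + 10L, replace = TRUE)
    if (unordered) {
      lo <- pmin(a, b); hi <- pmax(a, b)
      a <- lo; b <- hi
    }
    ok <- if (forbid_equal) a != b else rep(TRUE, length(a))
    key <- paste(a, b, sep = "\r")
    ok <- ok & !(key %in% seen) & !duplicated(key)
    if (any(ok)) {
      take <- which(ok)[seq_len(min(need, sum(ok)))]
      out_a <- c(out_a, a[take])
      out_b <- c(out_b, b[take])
      seen <- c(seen, key[take])
    }
  }
  if (length(out_a) < n_decoy) {
    stop("could not place the requested number of decoy edges; ",
         "the edge universe is too saturated", call. = FALSE)
  }
  data.frame(a = out_a, b = out_b, stringsAsFactors = FALSE)
}

#' Emit a candidate network containing the true edges plus decoys
#'
#' Stands in for database-derived candidate networks, which contain edges from
#' many experimental conditions and hence false positives relative to any one
#' cohort. All true edges are always included; decoy edges that never
#' duplicate a true edge are added so that the requested fraction of the
#' candidate set is false.
#'
#' @param gt A [generate_ground_truth()] result.
#' @param fp_fraction Fraction of candidate edges (per edge type) that are
#'   decoys, in `[0, 1)`; defaults to the generator config.
#' @param seed Integer seed; defaults to the generator seed + 1.
#' @return A [candidate_gen()] whose edge sets are supersets of the true
#'   edges.
#' @export
emit_candidate_network <- function(gt, fp_fraction = gt$config$fp_fraction,
                                   seed = gt$config$seed + 1L) {
  stopifnot(inherits(gt, "gen_ground_truth"))
  stopifnot_scalar_prob(fp_fraction, "fp_fraction", open_left = FALSE)
  with_seed(seed, {
    n_decoy <- function(n_true) {
      if (n_true == 0L) 0L else round(fp_fraction / (1 - fp_fraction) * n_true)
    }

    # decoy PPI pairs come from the same bipartite eligible universe as the
    # true pairs, like database false positives drawn among plausible pairs
    ppi_true <- gt$ppi[c("node_a", "node_b")]
    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
    ppi_dec <- sample_decoys(n_decoy(nrow(ppi_true)), gt$solved_half,
                             gt$free_half,
                             key(ppi_true$node_a, ppi_true$node_b),
                             unordered = TRUE)
    ppi_edges <- rbind(ppi_true,
                       stats::setNames(ppi_dec, c("node_a", "node_b")))

    tf_true <- gt$tf_reg[c("tf", "target")]
    tf_dec <- sample_decoys(n_decoy(nrow(tf_true)), gt$tf_ids, gt$node_ids,
                            paste(tf_true$tf, tf_true$target, sep = "\r"))
    tf_edges <- rbind(tf_true, stats::setNames(tf_dec, c("tf", "target")))

    mir_true <- gt$mirna_reg[c("mirna", "target")]
    mir_dec <- sample_decoys(n_decoy(nrow(mir_true)), gt$mirna_ids,
                             gt$node_ids,
                             paste(mir_true$mirna, mir_true$target, sep = "\r"),
                             forbid_equal = FALSE)
    mirna_edges <- rbind(mir_true,
                         stats::setNames(mir_dec, c("mirna", "target")))

    candidate_gen(ppi_edges, tf_edges, mirna_edges,
                  node_ids = gt$node_ids, mirna_ids = gt$mirna_ids,
                  tf_ids = gt$tf_ids)
  })
}

#' Forward-simulate one cohort from a ground-truth network
#'
#' Generates miRNA profiles (i.i.d. log-normal), protein profiles `y_i(n)`
#' satisfying the bilinear association model and gene profiles
#' `x_i(n) = sum_j b_ij y_j(n) - sum_l c_il mir_l(n) + k_i + w_i(n)` with
#' Gaussian noise. Group-specific basal levels `k_i` and planted
#' differential-expression shifts are applied for non-reference groups.
#'
#' Two schemes realize the association model, which is a consistency relation
#' rather than a generative one:
#'
#' * `"fixed_point"` rearranges it to
#'   `y_i = (h_i + v_i) / (1 - sum_j a_ij y_j)` and iterates Gauss-Seidel
#'   passes (at most 100, tolerance 1e-8) from `y = h`. Draws where any
#'   denominator satisfies `|1 - sum_j a_ij y_j| < 0.2` are rejected with an
#'   error, which signals ill-conditioned abilities.
#' * `"regression_faithful"` draws the free half of the node bipartition as
#'   `h_j` plus `N(0, profile_sd^2)` sample effects and sets each partnered
#'   node of the solved half by the solved form against those free profiles,
#'   under the same conditioning bound. Each solved target's association
#'   equation then holds exactly with freely varying regressors, which is the
#'   regime least-squares identification assumes; use this mode for parameter
#'   and support recovery studies.
#'
#' @param gt A [generate_ground_truth()] result.
#' @param group Group label (must be a column of `gt$basal_gene`).
#' @param n Number of samples; defaults to the configured size for `group`.
#' @param seed Integer seed; defaults to a group-specific offset of the
#'   generator seed.
#' @param mode Simulation scheme, see above.
#' @return A [cohort_dataset()].
#' @export
simulate_cohort <- function(gt, group, n = NULL, seed = NULL,
                            mode = c("fixed_point", "regression_faithful")) {
  stopifnot(inherits(gt, "gen_ground_truth"))
  mode <- match.arg(mode)
  groups <- colnames(gt$basal_gene)
  if (!group %in% groups) {
    stop("`group` has no basal-level entry: ", group, call. = FALSE)
  }
  if (is.null(n)) n <- gt$config$n_samples[[group]]
  n <- stopifnot_count(n, "n", min = 2L)
  if (is.null(seed)) seed <- gt$config$seed + 100L * match(group, groups)

  N <- length(gt$node_ids)
  O <- length(gt$mirna_ids)
  cfg <- gt$config

  with_seed(seed, {
    sample_ids <- sprintf("%s_%03d", group, seq_len(n))
    mir <- matrix(stats::rlnorm(O * n, cfg$mirna_log_mean, cfg$mirna_log_sd),
                  nrow = O, ncol = n,
                  dimnames = list(gt$mirna_ids, sample_ids))

    v <- matrix(stats::rnorm(N * n, 0, gt$noise_sd), nrow = N,
                dimnames = list(gt$node_ids, sample_ids))
    h <- gt$basal_protein

    partners <- split(
      c(gt$ppi$node_b, gt$ppi$node_a),
      c(gt$ppi$node_a, gt$ppi$node_b)
    )
    abilities <- split(
      c(gt$ppi$ability, gt$ppi$ability),
      c(gt$ppi$node_a, gt$ppi$node_b)
    )

    denom_for <- function(i, y) {
      js <- partners[[i]]
      if (is.null(js)) return(rep(1, n))
      1 - drop(crossprod(matrix(abilities[[i]], ncol = 1),
                         y[js, , drop = FALSE]))
    }

    if (mode == "fixed_point") {
      y <- matrix(h, nrow = N, ncol = n, dimnames = list(gt$node_ids, sample_ids))
      y <- y + v  # partnerless nodes keep h + v; partnered rows are overwritten
      targets <- intersect(gt$node_ids, names(partners))
      if (length(targets)) {
        for (pass in seq_len(100L)) {
          delta <- 0
          for (i in targets) {
            den <- denom_for(i, y)
            yi <- (h[[i]] + v[i, ]) / den
            delta <- max(delta, max(abs(yi - y[i, ])))
            y[i, ] <- yi
          }
          if (delta < 1e-8) break
        }
        bad <- vapply(targets, function(i) min(abs(denom_for(i, y))),
                      numeric(1))
        if (any(bad < 0.2)) {
          stop("fixed-point stability bound violated (|1 - sum a_ij y_j| < ",
               "0.2) for node(s): ",
               paste(targets[bad < 0.2], collapse = ", "),
               "; the drawn abilities are ill-conditioned", call. = FALSE)
        }
      }
    } else {
      e <- matrix(stats::rnorm(N * n, 0, cfg$profile_sd), nrow = N,
                  dimnames = list(gt$node_ids, sample_ids))
      y <- matrix(h, nrow = N, ncol = n,
                  dimnames = list(gt$node_ids, sample_ids)) + e
      # solved-half nodes satisfy their association model: partnered ones via
      # the solved form, partnerless ones as basal level plus model noise
      no_partner <- setdiff(gt$solved_half, names(partners))
      y[no_partner, ] <- matrix(h[no_partner], nrow = length(no_partner),
                                ncol = n) + v[no_partner, , drop = FALSE]
      solved <- intersect(gt$solved_half, names(partners))
      for (i in solved) {
        den <- denom_for(i, y)
        if (min(abs(den)) < 0.2) {
          stop("fixed-point stability bound violated (|1 - sum a_ij y_j| < ",
               "0.2) for node ", i, call. = FALSE)
        }
        y[i, ] <- (h[[i]] + v[i, ]) / den
      }
    }

    # gene-regulatory layer
    w <- matrix(stats::rnorm(N * n, 0, gt$noise_sd), nrow = N,
                dimnames = list(gt$node_ids, sample_ids))
    k <- gt$basal_gene[, group]
    x <- matrix(k, nrow = N, ncol = n,
                dimnames = list(gt$node_ids, sample_ids)) + w
    if (nrow(gt$tf_reg)) {
      for (r in seq_len(nrow(gt$tf_reg))) {
        x[gt$tf_reg$target[r], ] <- x[gt$tf_reg$target[r], ] +
          gt$tf_reg$ability[r] * y[gt$tf_reg$tf[r], ]
      }
    }
    if (nrow(gt$mirna_reg)) {
      for (r in seq_len(nrow(gt$mirna_reg))) {
        x[gt$mirna_reg$target[r], ] <- x[gt$mirna_reg$target[r], ] -
          gt$mirna_reg$ability[r] * mir[gt$mirna_reg$mirna[r], ]
      }
    }
    if (length(gt$de_nodes) && match(group, groups) > 1L) {
      x[gt$de_nodes, ] <- x[gt$de_nodes, ] + cfg$de_shift
    }

    cohort_dataset(
      protein_expr = y, gene_expr = x, mirna_expr = mir,
      sample_groups = stats::setNames(rep(group, n), sample_ids)
    )
  })
}
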