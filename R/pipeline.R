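#' Validate and normalize a pipeline run configuration
#'
#' Accepts a YAML file path or an equivalent nested list and returns a typed,
#' defaulted `run_config`. Exactly one of `simulation` (synthetic-data block,
#' keys matching [sim_config()] arguments plus `mode`) or `input` (paths to
#' cohort datasets written by [write_cohort_dataset()] and a candidate edge
#' list) must be present. Unknown keys are rejected by name.
#'
#' Recognized top-level keys and defaults:
#' * `simulation` / `input` — exactly one required.
#' * `alphas` — `pool`, `prune`, `methylation`, `de`; all default 0.05.
#' * `energy` — PNP energy proportion, default 0.85.
#' * `thresholds` — either `quantile: <prob>` (default, 0.9) or one
#'   `th1`/`th2`/`th3` triple per cohort label.
#' * `seed` — integer, default 1.
#' * `output_dir` — default a fresh temporary directory.
#'
#' @param x Path to a YAML file, or a list.
#' @return An object of class `run_config`.
#' @export
validate_config <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x, call. = FALSE)
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("config must be a YAML file or a list", call. = FALSE)

  known <- c("simulation", "input", "alphas", "energy", "thresholds",
             "seed", "output_dir")
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has_sim <- !is.null(x$simulation)
  has_input <- !is.null(x$input)
  if (has_sim == has_input) {
    stop("config must contain exactly one of `simulation` or `input`",
         call. = FALSE)
  }

  seed <- stopifnot_count(if (is.null(x$seed)) 1L else x$seed, "seed",
                          min = 0L)

  if (has_sim) {
    sim <- x$simulation
    mode <- sim$mode %||% "fixed_point"
    if (!mode %in% c("fixed_point", "regression_faithful")) {
      stop("simulation `mode` must be fixed_point or regression_faithful",
           call. = FALSE)
    }
    sim$mode <- NULL
    bad <- setdiff(names(sim), names(formals(sim_config)))
    if (length(bad)) {
      stop("unknown simulation key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(sim$seed)) sim$seed <- seed
    sim_cfg <- do.call(sim_config, sim)
    groups <- sim_cfg$groups
    input <- NULL
  } else {
    input <- x$input
    need <- c("dir", "cohorts", "edges")
    missing_keys <- setdiff(need, names(input))
    if (length(missing_keys)) {
      stop("input block missing required key(s): ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(names(input), need)
    if (length(bad)) {
      stop("unknown input key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    groups <- as.character(input$cohorts)
    if (length(groups) < 2L) {
      stop("`input$cohorts` needs at least two cohort prefixes",
           call. = FALSE)
    }
    sim_cfg <- NULL
    mode <- NULL
  }

  alphas <- x$alphas %||% list()
  bad <- setdiff(names(alphas), c("pool", "prune", "methylation", "de"))
  if (length(bad)) {
    stop("unknown alphas key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  alphas <- list(
    pool = alphas$pool %||% 0.05,
    prune = alphas$prune %||% 0.05,
    methylation = alphas$methylation %||% 0.05,
    de = alphas$de %||% 0.05
  )
  for (nm in names(alphas)) {
    stopifnot_scalar_prob(alphas[[nm]], paste0("alphas$", nm))
  }

  energy <- x$energy %||% 0.85
  stopifnot_scalar_prob(energy, "energy", open_left = TRUE,
                        open_right = FALSE)

  thresholds <- x$thresholds %||% list(quantile = 0.9)
  if (!is.null(thresholds$quantile)) {
    if (length(thresholds) != 1L) {
      stop("`thresholds` must be either a quantile or per-cohort triples, ",
           "not both", call. = FALSE)
    }
    stopifnot_scalar_prob(thresholds$quantile, "thresholds$quantile")
  } else {
    missing_groups <- setdiff(groups, names(thresholds))
    if (length(missing_groups)) {
      stop("thresholds missing for cohort(s): ",
           paste(missing_groups, collapse = ", "), call. = FALSE)
    }
    for (g in groups) {
      tg <- thresholds[[g]]
      if (!all(c("th1", "th2", "th3") %in% names(tg))) {
        stop("thresholds for cohort ", g, " must name th1, th2, th3",
             call. = FALSE)
      }
    }
  }

  structure(
    list(
      simulation = sim_cfg, sim_mode = mode, input = input,
      groups = groups, alphas = alphas, energy = energy,
      thresholds = thresholds, seed = seed,
      output_dir = x$output_dir %||% tempfile("coregen_run_")
    ),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full GEN analysis pipeline
#'
#' Executes simulate (or load) -> pool -> identify -> PNP -> compare for each
#' cohort, writing every intermediate artifact as delimited text under the
#' configured output directory plus a YAML manifest with stage bookkeeping
#' (pool size, edge counts before/after pruning, projection dimension M, core
#' sizes) and MD5 checksums of all artifacts. Reruns with the same
#' configuration and seed produce bit-identical artifacts. A stage failure
#' aborts the run with the stage name.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @return The manifest, invisibly (also written to
#'   `<output_dir>/manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stages_done <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  groups <- config$groups

  # stage 1: simulate or load --------------------------------------------
  stage_data <- run_stage("simulate", {
    if (!is.null(config$simulation)) {
      gt <- generate_ground_truth(config$simulation)
      candidates <- emit_candidate_network(gt)
      datasets <- lapply(groups, function(g) {
        simulate_cohort(gt, g, mode = config$sim_mode)
      })
      names(datasets) <- groups
      sim_dir <- file.path(out, "simulate")
      for (g in groups) write_cohort_dataset(datasets[[g]], sim_dir, g)
      write_edge_list(candidates, file.path(sim_dir, "candidate_edges.tsv"))
      write_ground_truth(gt, sim_dir)
      list(datasets = datasets, edges = as_edge_table(candidates))
    } else {
      datasets <- lapply(groups, function(g) {
        read_cohort_dataset(config$input$dir, g)
      })
      names(datasets) <- groups
      list(datasets = datasets,
           edges = read_edge_list(config$input$edges))
    }
  })
  datasets <- stage_data$datasets
  raw_edges <- stage_data$edges
  counts$samples <- lapply(datasets, function(d) ncol(d$gene_expr))
  counts$candidate_edges_raw <- nrow(raw_edges)
  stages_done <- c(stages_done, "simulate")

  # stage 2: protein pool + candidate assembly ---------------------------
  cg <- run_stage("pool", {
    pool <- select_protein_pool(datasets, alpha = config$alphas$pool)
    pool_dir <- file.path(out, "pool")
    dir.create(pool_dir, showWarnings = FALSE, recursive = TRUE)
    anova_tab <- attr(pool, "anova")
    write_tsv_full(anova_tab, file.path(pool_dir, "pool_anova.tsv"))
    writeLines(pool, file.path(pool_dir, "pool.txt"))
    cg <- assemble_candidate_gen(pool, raw_edges)
    write_edge_list(cg, file.path(pool_dir, "candidate_edges_pooled.tsv"))
    cg
  })
  counts$pool_size <- length(cg$node_ids)
  counts$candidate_edges_pooled <- nrow(cg$ppi_edges) + nrow(cg$tf_edges) +
    nrow(cg$mirna_edges)
  stages_done <- c(stages_done, "pool")

  # stage 3: identification ----------------------------------------------
  gens <- run_stage("identify", {
    id_dir <- file.path(out, "identify")
    gens <- lapply(groups, function(g) {
      gen <- identify_gen(datasets[[g]], cg, alpha = config$alphas$prune,
                          group = g)
      write_identified_gen(gen, id_dir, g)
      gen
    })
    names(gens) <- groups
    gens
  })
  counts$identified_edges <- lapply(gens, function(g) nrow(g$edges))
  stages_done <- c(stages_done, "identify")

  # stage 4: principal network projection ---------------------------------
  cores <- run_stage("pnp", {
    pnp_dir <- file.path(out, "pnp")
    dir.create(pnp_dir, showWarnings = FALSE, recursive = TRUE)
    cores <- lapply(groups, function(g) {
      nm <- build_network_matrix(gens[[g]])
      pnp <- project_and_score(pnp_decompose(nm, energy = config$energy))
      counts$pnp_M[[g]] <<- pnp$M
      th <- if (!is.null(config$thresholds$quantile)) {
        quantile_thresholds(pnp, prob = config$thresholds$quantile)
      } else {
        config$thresholds[[g]]
      }
      core <- extract_core(pnp, th$th1, th$th2, th$th3, gen = gens[[g]])
      write_tsv_full(pnp_components_table(pnp),
                     file.path(pnp_dir, paste0(g, "_components.tsv")))
      write_tsv_full(core$scores,
                     file.path(pnp_dir, paste0(g, "_scores.tsv")))
      write_tsv_full(core$core_edges,
                     file.path(pnp_dir, paste0(g, "_core_edges.tsv")))
      writeLines(c(core$core_nodes, core$core_mirnas),
                 file.path(pnp_dir, paste0(g, "_core_nodes.txt")))
      core
    })
    names(cores) <- groups
    cores
  })
  counts$core_nodes <- lapply(cores, function(cc) length(cc$core_nodes))
  counts$core_mirnas <- lapply(cores, function(cc) length(cc$core_mirnas))
  stages_done <- c(stages_done, "pnp")

  # stage 5: comparison ----------------------------------------------------
  cmp_counts <- run_stage("compare", {
    g1 <- groups[1]; g2 <- groups[2]
    cmp_dir <- file.path(out, "compare")
    dir.create(cmp_dir, showWarnings = FALSE, recursive = TRUE)
    cmp <- compare_core_gens(cores[[g1]], cores[[g2]], labels = c(g1, g2))
    membership <- data.frame(
      id = c(cmp$common_nodes, cmp$specific_nodes_a, cmp$specific_nodes_b,
             cmp$common_mirnas, cmp$specific_mirnas_a, cmp$specific_mirnas_b),
      kind = c(rep("node", length(cmp$common_nodes) +
                     length(cmp$specific_nodes_a) +
                     length(cmp$specific_nodes_b)),
               rep("mirna", length(cmp$common_mirnas) +
                     length(cmp$specific_mirnas_a) +
                     length(cmp$specific_mirnas_b))),
      membership = c(rep("common", length(cmp$common_nodes)),
                     rep(paste0("specific_", g1), length(cmp$specific_nodes_a)),
                     rep(paste0("specific_", g2), length(cmp$specific_nodes_b)),
                     rep("common", length(cmp$common_mirnas)),
                     rep(paste0("specific_", g1), length(cmp$specific_mirnas_a)),
                     rep(paste0("specific_", g2), length(cmp$specific_mirnas_b))),
      stringsAsFactors = FALSE
    )
    write_tsv_full(membership, file.path(cmp_dir, "core_membership.tsv"))
    write_tsv_full(cmp$common_edges, file.path(cmp_dir, "common_edges.tsv"))
    write_tsv_full(cmp$specific_edges_a,
                   file.path(cmp_dir, paste0("specific_edges_", g1, ".tsv")))
    write_tsv_full(cmp$specific_edges_b,
                   file.path(cmp_dir, paste0("specific_edges_", g2, ".tsv")))
    meth <- flag_methylation_candidates(gens[[g1]], gens[[g2]],
                                        alpha = config$alphas$methylation)
    write_tsv_full(meth, file.path(cmp_dir, "methylation_candidates.tsv"))
    de <- flag_differential_expression(datasets[[g1]], datasets[[g2]],
                                       alpha = config$alphas$de)
    write_tsv_full(de, file.path(cmp_dir, "differential_expression.tsv"))
    list(common_core_nodes = length(cmp$common_nodes),
         methylation_flags = sum(meth$flagged),
         de_flags = sum(de$flagged))
  })
  counts <- c(counts, cmp_counts)
  stages_done <- c(stages_done, "compare")

  # manifest ---------------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.yaml"]
  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- substring(names(checksums), nchar(out) + 2L)

  cfg_for_hash <- config
  cfg_for_hash$output_dir <- NULL
  hash_file <- tempfile()
  yaml::write_yaml(unclass_recursive(cfg_for_hash), hash_file)
  config_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  manifest <- list(
    package = "coregen",
    version = as.character(utils::packageVersion("coregen")),
    seed = config$seed,
    config_hash = config_hash,
    stages = stages_done,
    counts = counts,
    checksums = checksums
  )
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else if (is.function(x)) {
    NULL
  } else {
    x
  }
}
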