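# network matrix assembly, SVD projection, core extraction

test_that("the network matrix places abilities in the documented blocks", {
  nodes <- c("G1", "G2")
  mirnas <- "M1"
  # empty network -> all-zero matrix of shape (2N+O) x N
  empty <- make_identified(
    data.frame(target = character(), regulator = character(),
               type = character(), ability = numeric(),
               stringsAsFactors = FALSE),
    nodes, mirnas
  )
  H0 <- build_network_matrix(empty)
  expect_equal(dim(H0$H), c(5L, 2L))
  expect_true(all(H0$H == 0))

  # single TF ability b for target 2 regulated by node 2's TF row
  gen <- make_identified(
    data.frame(target = "G1", regulator = "G2", type = "tf", ability = 0.5,
               stringsAsFactors = FALSE),
    nodes, mirnas
  )
  H <- build_network_matrix(gen)$H
  expect_equal(sum(H != 0), 1L)
  expect_equal(H[4, 1], 0.5)  # TF row of node 2, column of target 1

  # miRNA entries carry the negated repression ability
  gen_m <- make_identified(
    data.frame(target = "G2", regulator = "M1", type = "mirna",
               ability = 0.7, stringsAsFactors = FALSE),
    nodes, mirnas
  )
  expect_equal(build_network_matrix(gen_m)$H[5, 2], -0.7)

  # duplicate (regulator, target, type) entries are an error
  dup <- make_identified(
    data.frame(target = c("G1", "G1"), regulator = c("G2", "G2"),
               type = c("tf", "tf"), ability = c(0.5, 0.2),
               stringsAsFactors = FALSE),
    nodes, mirnas
  )
  expect_error(build_network_matrix(dup), "duplicate")
})

test_that("random sparse networks reproduce a brute-force triple loop", {
  set.seed(14)
  nodes <- sprintf("G%02d", 1:12)
  mirnas <- sprintf("M%02d", 1:4)
  N <- 12L; O <- 4L
  e <- rbind(
    data.frame(target = sample(nodes, 10, TRUE),
               regulator = sample(nodes, 10, TRUE), type = "ppi",
               stringsAsFactors = FALSE),
    data.frame(target = sample(nodes, 8, TRUE),
               regulator = sample(nodes, 8, TRUE), type = "tf",
               stringsAsFactors = FALSE),
    data.frame(target = sample(nodes, 6, TRUE),
               regulator = sample(mirnas, 6, TRUE), type = "mirna",
               stringsAsFactors = FALSE)
  )
  e <- e[e$target != e$regulator | e$type == "mirna", ]
  e <- e[!duplicated(e[c("target", "regulator", "type")]), ]
  e$ability <- stats::runif(nrow(e), -1, 1)
  gen <- make_identified(e, nodes, mirnas)
  H <- build_network_matrix(gen)$H

  H_brute <- matrix(0, 2 * N + O, N)
  for (r in seq_len(nrow(e))) {
    i <- match(e$target[r], nodes)
    if (e$type[r] == "ppi") {
      H_brute[match(e$regulator[r], nodes), i] <- e$ability[r]
    } else if (e$type[r] == "tf") {
      H_brute[N + match(e$regulator[r], nodes), i] <- e$ability[r]
    } else {
      H_brute[2 * N + match(e$regulator[r], mirnas), i] <- -e$ability[r]
    }
  }
  expect_equal(unname(H), H_brute)
})

test_that("eigen expression fractions and M follow the energy rule", {
  # diagonal 3, 1 embedded: E = (0.9, 0.1), M = 1
  gen <- make_identified(
    data.frame(target = c("G1", "G2"), regulator = c("G1", "G2"),
               type = "tf", ability = c(3, 1), stringsAsFactors = FALSE),
    c("G1", "G2"), character()
  )
  pnp <- pnp_decompose(build_network_matrix(gen))
  expect_equal(pnp$d, c(3, 1))
  expect_equal(pnp$E, c(0.9, 0.1))
  expect_equal(pnp$M, 1L)

  # ten equal singular values: cumulative energy reaches 0.85 at m = 9
  H10 <- diag(10)
  pnp10 <- pnp_decompose(H10)
  expect_equal(pnp10$E, rep(0.1, 10))
  expect_equal(pnp10$M, 9L)

  # an all-zero matrix cannot be decomposed
  expect_error(pnp_decompose(matrix(0, 3, 2)), "all zero|zero")
})

test_that("decomposition agrees with an independent eigendecomposition", {
  set.seed(15)
  H <- matrix(stats::rnorm(28 * 10), 28, 10)
  pnp <- pnp_decompose(H, energy = 0.85)
  ev <- sort(eigen(crossprod(H), symmetric = TRUE)$values, decreasing = TRUE)
  expect_lt(max(abs(pnp$d^2 - ev)), 1e-8)
  expect_lt(abs(sum(pnp$E) - 1), 1e-12)
  # V is orthonormal, so projecting onto all N components reproduces H
  expect_lt(max(abs(H %*% pnp$V %*% t(pnp$V) - H)), 1e-8)
})

test_that("projection scores and distances match a brute-force double loop", {
  set.seed(16)
  H <- matrix(stats::rnorm(20 * 8), 20, 8)
  H[7, ] <- 0  # an all-zero row must get distance zero
  pnp <- project_and_score(pnp_decompose(H, energy = 0.85))
  D_brute <- numeric(20)
  for (k in 1:20) {
    s2 <- 0
    for (m in seq_len(pnp$M)) {
      s2 <- s2 + sum(H[k, ] * pnp$V[, m])^2
    }
    D_brute[k] <- sqrt(s2)
  }
  expect_lt(max(abs(pnp$D - D_brute)), 1e-10)
  expect_equal(unname(pnp$D[7]), 0)

  # with full energy the distance is the row norm (Parseval)
  pnp_full <- project_and_score(pnp_decompose(H, energy = 1.0))
  expect_equal(pnp_full$M, 8L)
  expect_lt(max(abs(pnp_full$D - sqrt(rowSums(H^2)))), 1e-10)

  # distances are nondecreasing in M
  expect_true(all(pnp_full$D - pnp$D >= -1e-12))
})

test_that("core extraction thresholds by row class and is monotone", {
  set.seed(17)
  nodes <- sprintf("G%02d", 1:10)
  mirnas <- sprintf("M%02d", 1:3)
  e <- data.frame(
    target = sample(nodes, 15, TRUE),
    regulator = c(sample(nodes, 10, TRUE), sample(mirnas, 5, TRUE)),
    type = c(rep("tf", 10), rep("mirna", 5)),
    stringsAsFactors = FALSE
  )
  e <- e[!duplicated(e[c("target", "regulator", "type")]), ]
  e$ability <- stats::runif(nrow(e), 0.2, 1)
  gen <- make_identified(e, nodes, mirnas)
  pnp <- project_and_score(pnp_decompose(build_network_matrix(gen)))

  # zero thresholds at full energy: every node with a nonzero row is core
  # (rows carry regulator profiles, so nonzero rows belong to the regulators)
  pnp1 <- project_and_score(pnp_decompose(build_network_matrix(gen),
                                          energy = 1.0))
  all_core <- extract_core(pnp1, 0, 0, 0, gen = gen)
  expect_setequal(all_core$core_nodes, unique(e$regulator[e$type == "tf"]))
  expect_setequal(all_core$core_mirnas, unique(e$regulator[e$type == "mirna"]))

  # thresholds above the maximum distance: empty core
  hi <- max(pnp$D) * 1.01
  none <- extract_core(pnp, hi, hi, hi)
  expect_length(none$core_nodes, 0)
  expect_length(none$core_mirnas, 0)

  # lowering any threshold never removes a core node
  mid <- extract_core(pnp, stats::median(pnp$D), 0.2, 0.1)
  low <- extract_core(pnp, stats::median(pnp$D) / 2, 0.1, 0.05)
  expect_true(all(mid$core_nodes %in% low$core_nodes))
  expect_true(all(mid$core_mirnas %in% low$core_mirnas))

  # induced core subnetwork keeps only edges between core members
  expect_true(all(all_core$core_edges$target %in% all_core$core_nodes))
})

test_that("node relabelling permutes rows but leaves distances attached", {
  set.seed(18)
  nodes <- sprintf("G%02d", 1:8)
  e <- data.frame(target = sample(nodes, 12, TRUE),
                  regulator = sample(nodes, 12, TRUE), type = "tf",
                  stringsAsFactors = FALSE)
  e <- e[e$target != e$regulator, ]
  e <- e[!duplicated(e[c("target", "regulator")]), ]
  e$ability <- stats::runif(nrow(e), -1, 1)
  gen1 <- make_identified(e, nodes, character())
  perm <- sample(nodes)
  gen2 <- make_identified(e, perm, character())
  d1 <- project_and_score(pnp_decompose(build_network_matrix(gen1)))$scores
  d2 <- project_and_score(pnp_decompose(build_network_matrix(gen2)))$scores
  key <- function(s) stats::setNames(s$distance, paste(s$class, s$id))
  k1 <- key(d1); k2 <- key(d2)
  expect_equal(k1[sort(names(k1))], k2[sort(names(k2))], tolerance = 1e-10)
})

test_that("published per-cohort thresholds are available as constants", {
  th <- pnp_published_thresholds()
  elderly <- th[th$cohort == "elderly", ]
  expect_equal(unlist(elderly[c("th1", "th2", "th3")], use.names = FALSE),
               c(0.6, 0.35, 0.03))
  expect_equal(nrow(th), 4L)
})

test_that("regulators with tenfold abilities dominate the projection ranks", {
  set.seed(20)
  ok <- 0L
  runs <- 20L
  for (r in seq_len(runs)) {
    nodes <- sprintf("G%03d", 1:150)
    regs <- sample(nodes, 80)
    e <- do.call(rbind, lapply(regs, function(rg) {
      data.frame(target = sample(setdiff(nodes, rg), 4), regulator = rg,
                 type = "tf", stringsAsFactors = FALSE)
    }))
    e$ability <- stats::runif(nrow(e), 0.1, 0.3) *
      sample(c(-1, 1), nrow(e), TRUE)
    big5 <- sample(regs, 5)
    e$ability[e$regulator %in% big5] <- 10 * e$ability[e$regulator %in% big5]
    gen <- make_identified(e, nodes, character())
    pnp <- project_and_score(pnp_decompose(build_network_matrix(gen)))
    sc <- pnp$scores[pnp$scores$class == "tf", ]
    top5 <- sc$id[order(-sc$distance)][1:5]
    if (setequal(top5, big5)) ok <- ok + 1L
  }
  expect_gte(ok, runs - 1L)
})
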