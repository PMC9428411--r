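# Helper: build a diff_modules object directly from log-scores, to exercise
# the driver-extraction rule on hand-constructed cases.
make_diff_modules <- function(log_scores, types, modules) {
  nodes <- names(log_scores)
  structure(
    list(labels = stats::setNames(modules, nodes),
         scores = stats::setNames(exp(log_scores), nodes),
         floored = stats::setNames(rep(FALSE, length(nodes)), nodes),
         node_type = stats::setNames(types, nodes),
         d_total = NA_real_, n_modules = length(unique(modules)),
         baseline = "female", perturbed = "male", bias = "male-biased",
         eps = 1e-12),
    class = "diff_modules"
  )
}

test_that("with perturbed = baseline, D equals Barber Q for any partition", {
  for (seed in 1:8) {
    g <- random_small_graph(4, 7, seed = seed)
    nodes <- c(g$tf_ids, g$gene_ids)
    set.seed(seed + 100)
    part <- stats::setNames(sample(1:3, length(nodes), replace = TRUE), nodes)
    d <- differential_modularity_score(g, g, part)
    q <- bipartite_modularity(g, part)
    expect_lt(abs(d - q), 1e-12)
  }
})

test_that("densifying a module raises D under the true partition", {
  base_w <- two_block_graph()$w
  base_w[1, 3] <- base_w[3, 1] <- 0.5        # cross-module weight
  g <- bipartite_graph(base_w)
  pert_w <- base_w
  pert_w[1:2, 1:2] <- 2 * pert_w[1:2, 1:2]   # double block 1 only
  pert <- bipartite_graph(pert_w)
  part <- two_block_partition()
  d_pert <- differential_modularity_score(pert, g, part)
  d_same <- differential_modularity_score(g, g, part)
  expect_gt(d_pert, d_same)

  # a community holding only TFs contributes nothing
  part2 <- part
  part2[c("t1", "t2")] <- 3
  d2 <- differential_modularity_score(pert, g, part2)
  part3 <- part
  part3[c("t1", "t2")] <- 4
  expect_equal(d2, differential_modularity_score(pert, g, part3))
})

test_that("identical networks return near-baseline structure with D = Q", {
  cfg <- small_study_config(seed = 30)
  sim <- simulate_regulatory_prior(cfg)
  w <- diffgrn:::.motif_matrix(sim$motif, sort(unique(sim$motif$source)),
                               sprintf("G%04d", 1:200))
  g <- bipartite_graph(w)
  base_part <- maximize_modularity(g)
  dm <- find_differential_modules(g, g, baseline_partition = base_part)
  expect_equal(dm$d_total,
               bipartite_modularity(g, stats::setNames(
                 as.integer(sub("M", "", dm$labels)), names(dm$labels))),
               tolerance = 1e-12)
  ari <- mclust::adjustedRandIndex(dm$labels[names(base_part$labels)],
                                   base_part$labels)
  expect_gte(ari, 0.9)
})

test_that("the optimizer never worsens the initialization's D", {
  cfg <- small_study_config(seed = 31)
  sim <- simulate_study(cfg)
  pre <- preprocess_expression(sim$expression)
  x <- pre$expression
  motif <- suppressMessages(filter_canonical(sim$motif, rownames(x$values)))
  sexv <- x$sample_meta$sex
  nm <- infer_network(motif, sim$ppi,
                      diffgrn:::subset_expr(x, samples = which(sexv == "male")))
  nf <- infer_network(motif, sim$ppi,
                      diffgrn:::subset_expr(x, samples = which(sexv == "female")))
  gm <- suppressMessages(positive_projection(nm))
  gf <- suppressMessages(positive_projection(nf))
  pf <- maximize_modularity(gf)
  dm <- suppressMessages(
    find_differential_modules(gm, gf, baseline_partition = pf))
  d_init <- suppressMessages(
    differential_modularity_score(gm, gf, pf$labels))
  expect_gte(dm$d_total, d_init - 1e-12)

  # the reported D is reproduced by independent re-evaluation of the partition
  labs <- stats::setNames(as.integer(sub("M", "", dm$labels)), names(dm$labels))
  d_check <- suppressMessages(differential_modularity_score(gm, gf, labs))
  expect_equal(dm$d_total, d_check, tolerance = 1e-12)
})

test_that("dual-baseline runs are labeled correctly and are asymmetric", {
  cfg <- small_study_config(seed = 32)
  sim <- simulate_study(cfg)
  pre <- preprocess_expression(sim$expression)
  x <- pre$expression
  motif <- suppressMessages(filter_canonical(sim$motif, rownames(x$values)))
  sexv <- x$sample_meta$sex
  nm <- infer_network(motif, sim$ppi,
                      diffgrn:::subset_expr(x, samples = which(sexv == "male")),
                      condition = "male")
  nf <- infer_network(motif, sim$ppi,
                      diffgrn:::subset_expr(x, samples = which(sexv == "female")),
                      condition = "female")
  dual <- suppressMessages(run_dual_baseline(nm, nf))
  expect_equal(dual$female_baseline$baseline, "female")
  expect_equal(dual$female_baseline$bias, "male-biased")
  expect_equal(dual$male_baseline$baseline, "male")
  expect_equal(dual$male_baseline$bias, "female-biased")
  common <- intersect(names(dual$female_baseline$labels),
                      names(dual$male_baseline$labels))
  ari <- mclust::adjustedRandIndex(dual$female_baseline$labels[common],
                                   dual$male_baseline$labels[common])
  expect_lt(ari, 1) # swapping baselines changes the module set
})

test_that("the driver rule matches the hand-computed IQR example", {
  # module A: logScores {-3.0, -3.1, -3.2, -2.0}; only the -2.0 TF clears
  # median + 1.5 * IQR
  logs <- c(a1 = -3.0, a2 = -3.1, a3 = -3.2, a4 = -2.0,
            g1 = -5.0, g2 = -5.1, g3 = -5.2)
  dm <- make_diff_modules(logs,
                          types = c(rep("TF", 4), rep("gene", 3)),
                          modules = c(rep("M1", 4), rep("M1", 3)))
  dr <- extract_drivers(dm)
  expect_identical(dr$node[dr$selected], "a4")
  med <- median(logs[1:4])
  iqr <- IQR(logs[1:4])
  expect_true(logs["a4"] > med + 1.5 * iqr)
  expect_true(all(logs[1:3] <= med + 1.5 * iqr))

  # all-equal scores: IQR 0 and nothing strictly exceeds the median
  dm0 <- make_diff_modules(stats::setNames(rep(-3, 6), letters[1:6]),
                           types = rep(c("TF", "gene"), each = 3),
                           modules = rep("M1", 6))
  expect_false(any(extract_drivers(dm0)$selected))
})

test_that("driver selection is scale-equivariant", {
  set.seed(33)
  logs <- stats::setNames(rnorm(20, -3, 0.6), paste0("n", 1:20))
  types <- rep(c("TF", "gene"), 10)
  dm <- make_diff_modules(logs, types, rep(c("M1", "M2"), each = 10))
  sel1 <- extract_drivers(dm)$node[extract_drivers(dm)$selected]
  dm_scaled <- dm
  dm_scaled$scores <- dm$scores * 37.5
  dr2 <- extract_drivers(dm_scaled)
  expect_setequal(dr2$node[dr2$selected], sel1)
  expect_equal(sort(dr2$log_score), unname(sort(logs + log(37.5))),
               tolerance = 1e-12)
})

test_that("modules with fewer than 3 nodes of a type are not tested", {
  logs <- c(t1 = -1, t2 = -4, g1 = -5, g2 = -5.5, g3 = -6, g4 = -2)
  dm <- make_diff_modules(logs, types = c("TF", "TF", rep("gene", 4)),
                          modules = rep("M1", 6))
  expect_message(dr <- extract_drivers(dm), "not tested")
  expect_false(any(dr$tested[dr$type == "TF"]))
  expect_true(all(dr$tested[dr$type == "gene"]))
})

test_that("shared top TFs are the intersection of selected sets", {
  mk <- function(sel_nodes, all_nodes) {
    structure(data.frame(node = all_nodes, type = "TF",
                         selected = all_nodes %in% sel_nodes,
                         stringsAsFactors = FALSE),
              class = c("driver_set", "data.frame"))
  }
  a <- mk(c("t1", "t2"), paste0("t", 1:5))
  b <- mk(c("t2", "t3"), paste0("t", 1:5))
  expect_identical(shared_top_tfs(a, b), "t2")
  expect_identical(shared_top_tfs(a, mk(character(0), "t9")), character(0))
  expect_identical(shared_top_tfs(a, a), c("t1", "t2"))
})
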