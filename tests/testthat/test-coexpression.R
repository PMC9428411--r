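test_that("raising the soft-threshold power never increases adjacency", {
  set.seed(1)
  for (rep in 1:5) {
    x <- tiny_expr(30, 15, seed = rep)
    n1 <- coexpression_network(x, beta = 2)
    n2 <- coexpression_network(x, beta = 5)
    off <- upper.tri(n1$adjacency)
    expect_true(all(n2$adjacency[off] <= n1$adjacency[off] + 1e-12))
  }
})

test_that("TOM is in [0,1] and equals 1 for identical connected neighborhoods", {
  set.seed(2)
  x <- tiny_expr(25, 12, seed = 3)
  net <- coexpression_network(x, beta = 6)
  expect_true(all(net$tom >= -1e-12 & net$tom <= 1 + 1e-12))
  expect_true(all(diag(net$tom) == 1))

  # binary fixture: nodes 1 and 2 adjacent with identical neighborhoods
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 1] <- 1
  a[1, 3:5] <- a[3:5, 1] <- 1
  a[2, 3:5] <- a[3:5, 2] <- 1
  tom <- diffgrn:::.tom(a)
  expect_equal(tom[1, 2], 1)
})

test_that("soft-threshold selection follows the stated tie-break and fallback rules", {
  # block-identity similarity: degenerate degrees fit trivially, smallest beta wins
  sim <- kronecker(diag(2), matrix(1, 30, 30))
  dimnames(sim) <- list(sprintf("g%02d", 1:60), sprintf("g%02d", 1:60))
  b <- select_soft_threshold(sim)
  expect_equal(as.integer(b), 1L)

  expect_equal(as.integer(select_soft_threshold(sim, betas = 6)), 6L)

  small <- sim[1:20, 1:20]
  expect_warning(b2 <- select_soft_threshold(small), "50")
  expect_equal(as.integer(b2), 6L)
})

test_that("hub-structured modular similarity attains a scale-free fit of at least 0.8", {
  # modules with a loading spectrum (hubs + peripheral genes): degrees follow
  # a power-law-like profile, the regime the scale-free criterion targets
  set.seed(12)
  n_per <- 50
  sim <- matrix(abs(rnorm(150 * 150, sd = 0.03)), 150, 150)
  for (m in 0:2) {
    idx <- m * n_per + seq_len(n_per)
    l <- runif(n_per, 0.3, 0.95)
    sim[idx, idx] <- outer(l, l)
  }
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 1
  dimnames(sim) <- list(sprintf("g%03d", 1:150), sprintf("g%03d", 1:150))
  beta <- select_soft_threshold(sim)
  expect_identical(attr(beta, "criterion"), "first_above_cut")
  adj <- sim^as.integer(beta)
  diag(adj) <- 0
  expect_gte(independent_scale_free_r2(colSums(adj)), 0.8)
})

test_that("planted blocks are recovered as modules with high ARI", {
  cfg <- sim_config(n_genes = 210, n_tfs = 20,
                    n_samples_male = 50, n_samples_female = 50,
                    n_modules = 3, module_sizes = rep(50, 3),
                    tfs_per_community = c(6, 7, 7),
                    within_module_corr = 0.7, n_batches = 1,
                    frac_low_variance = 0, seed = 13)
  sim <- simulate_expression(cfg)
  net <- coexpression_network(sim$expression, beta = 6)
  mods <- detect_modules(net, min_size = 10)
  expect_equal(length(mods$sizes), 3L)
  truth <- ifelse(sim$truth$module == 0, "bg", paste0("m", sim$truth$module))
  detected <- mods$labels[names(sim$truth$module)]
  ari <- mclust::adjustedRandIndex(truth, detected)
  expect_gte(ari, 0.9)
  # internal ARI agrees with the external implementation
  expect_equal(diffgrn:::adjusted_rand_index(truth, detected), ari,
               tolerance = 1e-12)
})

test_that("pure noise leaves almost all genes unassigned", {
  set.seed(14)
  x <- tiny_expr(values = matrix(rnorm(120 * 60), 120, 60))
  net <- coexpression_network(x)
  mods <- detect_modules(net, min_size = 10)
  expect_gte(mean(mods$labels == "unassigned"), 0.9)
})

test_that("a minimum size above every block leaves all genes unassigned", {
  cfg <- sim_config(n_genes = 100, n_tfs = 20,
                    n_samples_male = 30, n_samples_female = 30,
                    n_modules = 2, module_sizes = c(30, 30),
                    tfs_per_community = c(10, 10),
                    within_module_corr = 0.7, n_batches = 1,
                    frac_low_variance = 0, seed = 15)
  sim <- simulate_expression(cfg)
  net <- coexpression_network(sim$expression)
  mods <- detect_modules(net, min_size = 50)
  expect_true(all(mods$labels == "unassigned"))
})

test_that("module detection does not depend on gene input order", {
  cfg <- sim_config(n_genes = 120, n_tfs = 20,
                    n_samples_male = 30, n_samples_female = 30,
                    n_modules = 2, module_sizes = c(40, 40),
                    tfs_per_community = c(10, 10),
                    within_module_corr = 0.7, n_batches = 1,
                    frac_low_variance = 0, seed = 16)
  sim <- simulate_expression(cfg)
  x <- sim$expression
  set.seed(17)
  perm <- sample(nrow(x$values))
  xp <- expression_matrix(x$values[perm, ], x$sample_meta, x$gene_meta)
  m1 <- detect_modules(coexpression_network(x, beta = 6), min_size = 10)
  m2 <- detect_modules(coexpression_network(xp, beta = 6), min_size = 10)
  expect_identical(m1$labels[sort(names(m1$labels))],
                   m2$labels[sort(names(m2$labels))])
})

test_that("hub labels come from per-module degree rankings in both networks", {
  cfg <- sim_config(n_genes = 100, n_tfs = 20,
                    n_samples_male = 30, n_samples_female = 30,
                    n_modules = 2, module_sizes = c(40, 40),
                    tfs_per_community = c(10, 10),
                    within_module_corr = 0.7, n_batches = 1,
                    frac_low_variance = 0, seed = 18)
  sim <- simulate_expression(cfg)
  net <- coexpression_network(sim$expression, beta = 6)
  mods <- detect_modules(net, min_size = 10)
  m1_genes <- names(mods$labels)[mods$labels == "CM1"]

  # star PPI inside CM1: first gene interacts with every other member
  star <- edge_list(data.frame(source = m1_genes[1], target = m1_genes[-1]),
                    mode = "unipartite_ppi")
  hubs <- label_hubs(net, mods, star, k = 3)
  center <- hubs[hubs$gene == m1_genes[1], ]
  expect_equal(center$degree_ppi, length(m1_genes) - 1L)
  expect_true(center$hub_label %in% c("ppi", "both"))
  leaves <- hubs[hubs$gene %in% m1_genes[-1], ]
  expect_true(all(leaves$degree_ppi == 1L))

  # a module smaller than k yields at most its own size in hubs
  small_mod <- names(mods$sizes)[which.min(mods$sizes)]
  members <- names(mods$labels)[mods$labels == small_mod]
  hubs2 <- label_hubs(net, mods, star, k = 1000)
  labeled <- hubs2$hub_label[hubs2$gene %in% members]
  expect_lte(sum(labeled != "none"), length(members))
})
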