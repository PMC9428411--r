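test_that("a fixed seed reproduces the full study bundle exactly", {
  cfg <- small_study_config(seed = 5)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(as.data.frame(a$motif), as.data.frame(b$motif))
  expect_identical(as.data.frame(a$ppi), as.data.frame(b$ppi))
  expect_identical(a$truth$truth_male, b$truth$truth_male)
})

test_that("planted modules reach the target within-module correlation", {
  cfg <- sim_config(n_genes = 250, n_tfs = 20,
                    n_samples_male = 50, n_samples_female = 50,
                    n_modules = 3, module_sizes = rep(50, 3),
                    tfs_per_community = c(6, 7, 7),
                    within_module_corr = 0.6, activity_shift = 0,
                    n_batches = 1, frac_low_variance = 0, seed = 2)
  sim <- simulate_expression(cfg)
  for (m in 1:3) {
    genes <- names(sim$truth$module)[sim$truth$module == m]
    cr <- cor(t(sim$expression$values[genes, ]))
    expect_lt(abs(mean(cr[upper.tri(cr)]) - 0.6), 0.1)
  }
})

test_that("zero correlation target makes modules indistinguishable from noise", {
  cfg <- sim_config(n_genes = 150, n_tfs = 20,
                    n_samples_male = 50, n_samples_female = 50,
                    n_modules = 2, module_sizes = c(40, 40),
                    tfs_per_community = c(10, 10),
                    within_module_corr = 0, activity_shift = 0,
                    n_batches = 1, frac_low_variance = 0, seed = 3)
  sim <- simulate_expression(cfg)
  genes <- names(sim$truth$module)[sim$truth$module == 1]
  cr <- cor(t(sim$expression$values[genes, ]))
  expect_lt(mean(abs(cr[upper.tri(cr)])), 0.1)
})

test_that("sex-active modules shift the designated sex upward", {
  cfg <- sim_config(n_genes = 150, n_tfs = 20,
                    n_samples_male = 70, n_samples_female = 50,
                    n_modules = 2, module_sizes = c(40, 40),
                    tfs_per_community = c(10, 10),
                    activity_shift = 1.0, sex_active_modules = 1,
                    sex_active_sex = "female", n_batches = 1,
                    frac_low_variance = 0, seed = 4)
  sim <- simulate_expression(cfg)
  x <- sim$expression
  z <- (x$values - rowMeans(x$values)) / apply(x$values, 1, sd)
  genes <- names(sim$truth$module)[sim$truth$module == 1]
  f_mean <- mean(z[genes, x$sample_meta$sex == "female"])
  m_mean <- mean(z[genes, x$sample_meta$sex == "male"])
  expect_gt(f_mean, m_mean)
  expect_gt(f_mean, 0)
  expect_lt(m_mean, 0)
})

test_that("low-variance genes land below the 0.1 variance threshold", {
  cfg <- small_study_config(seed = 6, frac_low_variance = 0.2)
  sim <- simulate_study(cfg)
  v <- apply(sim$expression$values[sim$truth$low_variance, ], 1, var)
  expect_true(all(v < 0.1))
  expect_length(sim$truth$low_variance, round(0.2 * 200))
})

test_that("rewiring swaps exactly floor(frac * |E1|) edges between sex truths", {
  cfg <- sim_config(n_genes = 100, n_tfs = 20,
                    n_samples_male = 10, n_samples_female = 10,
                    n_modules = 4, module_sizes = rep(25, 4),
                    tfs_per_community = rep(5, 4),
                    rewired_fraction = 0.5, frac_low_variance = 0, seed = 7)
  p <- simulate_regulatory_prior(cfg)
  key <- function(d) paste(d$tf, d$gene)
  e1 <- sum(p$truth$tf_community[p$truth$truth_female$tf] == 1 &
              p$truth$gene_community[p$truth$truth_female$gene] == 1)
  k <- floor(0.5 * e1)
  expect_equal(length(setdiff(key(p$truth$truth_male), key(p$truth$truth_female))), k)
  expect_equal(length(setdiff(key(p$truth$truth_female), key(p$truth$truth_male))), k)
  expect_equal(nrow(p$truth$rewired_edges), k)
  # swapped-in targets live in the destination community
  expect_true(all(p$truth$gene_community[p$truth$rewired_edges$new_gene] ==
                    cfg$rewire_destination))

  cfg0 <- sim_config(n_genes = 100, n_tfs = 20,
                     n_samples_male = 10, n_samples_female = 10,
                     n_modules = 4, module_sizes = rep(25, 4),
                     tfs_per_community = rep(5, 4),
                     rewired_fraction = 0, frac_low_variance = 0, seed = 7)
  p0 <- simulate_regulatory_prior(cfg0)
  expect_identical(p0$truth$truth_male, p0$truth$truth_female)
  expect_length(p0$truth$driver_tfs, 0)
})

test_that("PPI edges are enriched within communities", {
  cfg <- sim_config(n_genes = 200, n_tfs = 40,
                    n_samples_male = 10, n_samples_female = 10,
                    n_modules = 4, module_sizes = rep(50, 4),
                    tfs_per_community = rep(10, 4),
                    frac_low_variance = 0, seed = 8)
  p <- simulate_regulatory_prior(cfg)
  comm <- p$truth$tf_community
  same <- comm[p$ppi$source] == comm[p$ppi$target]
  n_tf_per <- table(comm)
  pairs_within <- sum(choose(n_tf_per, 2))
  pairs_between <- choose(length(comm), 2) - pairs_within
  rate_within <- sum(same) / pairs_within
  rate_between <- sum(!same) / pairs_between
  expect_gt(rate_within, rate_between)
})

test_that("an injected outlier sample is shifted by the configured amount", {
  cfg <- small_study_config(seed = 9, add_outlier = TRUE, outlier_shift = 8)
  sim <- simulate_study(cfg)
  out <- sim$truth$outlier_sample
  expect_false(is.null(out))
  x <- sim$expression$values
  others <- setdiff(colnames(x), out)
  normal_genes <- setdiff(rownames(x), sim$truth$low_variance)
  shift <- mean(x[normal_genes, out]) - mean(x[normal_genes, others])
  expect_equal(shift, 8, tolerance = 0.5)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(within_module_corr = 1), "infeasible")
  expect_error(sim_config(module_sizes = c(500, 200, 10, 10)), "exceeds")
  expect_error(sim_config(rewired_fraction = 1.2), "rewired_fraction")
  expect_error(sim_config(tfs_per_community = c(10, 10, 10, 11)),
               "tfs_per_community")
})
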