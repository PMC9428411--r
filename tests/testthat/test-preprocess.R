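test_that("variance filter is strict: a gene at exactly the threshold is kept", {
  d <- sqrt(0.1)
  vals <- rbind(
    g_low  = c(-d, d, 0) / sqrt(2),  # variance 0.05
    g_edge = c(-d, d, 0),            # variance exactly 0.1
    g_high = c(-d, d, 0) * sqrt(2)   # variance 0.2
  )
  colnames(vals) <- paste0("s", 1:3)
  x <- tiny_expr(values = vals)
  stopifnot(var(vals[2, ]) == 0.1) # fixture really sits on the boundary
  out <- filter_low_variance(x, threshold = 0.1)
  expect_identical(rownames(out$expression$values), c("g_edge", "g_high"))
  expect_identical(out$report$removed_low_variance, "g_low")
})

test_that("variance filter with threshold 0 is the identity and is idempotent", {
  x <- tiny_expr(10, 6, seed = 2)
  expect_expr_equal(filter_low_variance(x, 0)$expression, x)
  once <- filter_low_variance(x, 0.8)$expression
  twice <- filter_low_variance(once, 0.8)$expression
  expect_expr_equal(once, twice)
})

test_that("variance filter removes close to the planted low-variance fraction", {
  cfg <- small_study_config(seed = 10, frac_low_variance = 0.3,
                            module_sizes = c(30L, 30L, 30L, 30L))
  sim <- simulate_study(cfg)
  out <- filter_low_variance(sim$expression, 0.1)
  frac_removed <- length(out$report$removed_low_variance) /
    nrow(sim$expression$values)
  expect_equal(frac_removed, 0.3, tolerance = 0.05)
})

test_that("sex-chromosome genes are removed under normalized labels", {
  x <- tiny_expr(5, 6, seed = 3)
  gm <- data.frame(gene_id = rownames(x$values),
                   chromosome = c("1", "chrX", "7", "X", "y"),
                   stringsAsFactors = FALSE)
  out <- remove_sex_chromosome_genes(x, gm)
  expect_identical(rownames(out$expression$values),
                   rownames(x$values)[c(1, 3)])
  expect_setequal(out$report$removed_sex_chromosome,
                  rownames(x$values)[c(2, 4, 5)])

  expect_warning(out2 <- remove_sex_chromosome_genes(x, gene_meta = NULL),
                 "annotation")
  expect_expr_equal(out2$expression, x)
})

test_that("a globally shifted sample is flagged as the only outlier", {
  set.seed(4)
  v <- matrix(rnorm(100 * 20), 100, 20)
  v[, 7] <- v[, 7] + 8
  x <- tiny_expr(values = v)
  expect_identical(detect_outlier_samples(x, cut_sd = 3), "s07")
  expect_identical(detect_outlier_samples(x, cut_sd = Inf), character(0))
})

test_that("iid samples are rarely flagged as outliers", {
  clean <- vapply(1:40, function(seed) {
    set.seed(seed)
    x <- tiny_expr(values = matrix(rnorm(80 * 25), 80, 25))
    length(detect_outlier_samples(x, cut_sd = 3)) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("batch adjustment recovers planted offsets and protects sex", {
  set.seed(5)
  n_g <- 60; n_s <- 40
  v <- matrix(rnorm(n_g * n_s), n_g, n_s)
  sex <- rep(c("male", "female"), each = n_s / 2)
  batch <- rep_len(c("B1", "B2"), n_s)            # balanced across sexes
  v[, batch == "B1"] <- v[, batch == "B1"] + 1
  v[, batch == "B2"] <- v[, batch == "B2"] - 1
  v[1, sex == "female"] <- v[1, sex == "female"] + 0.5
  rownames(v) <- sprintf("g%02d", 1:n_g); colnames(v) <- sprintf("s%02d", 1:n_s)
  x <- expression_matrix(v, data.frame(sample_id = colnames(v), sex = sex,
                                       batch = batch))
  adj <- adjust_batch(x)$expression$values
  batch_gap <- rowMeans(adj[, batch == "B1"]) - rowMeans(adj[, batch == "B2"])
  expect_lt(max(abs(batch_gap)), 0.01)
  sex_effect <- mean(adj[1, sex == "female"]) - mean(adj[1, sex == "male"])
  raw_effect <- mean(v[1, sex == "female"]) - mean(v[1, sex == "male"])
  expect_equal(sex_effect, raw_effect, tolerance = 0.05)
})

test_that("single batch is the identity; a sex-confounded batch errors", {
  x <- tiny_expr(10, 8, seed = 6)
  x$sample_meta$batch <- "B1"
  out <- adjust_batch(x)
  expect_false(out$report$batch_adjusted)
  expect_expr_equal(out$expression, x)

  x$sample_meta$batch <- ifelse(x$sample_meta$sex == "male", "B1", "B2")
  expect_error(adjust_batch(x), "confounded")
})

test_that("the preprocessing chain applies stages in the stated order", {
  cfg <- small_study_config(seed = 11, add_outlier = TRUE)
  sim <- simulate_study(cfg)
  res <- preprocess_expression(sim$expression)
  expect_identical(res$report$order,
                   c("variance_filter", "sex_chromosome_removal",
                     "outlier_removal", "batch_adjustment"))
  expect_identical(res$report$removed_outliers, sim$truth$outlier_sample)
  # the outlier inflates some low-variance genes past the cut (the filter
  # runs first), but nothing outside the planted low-variance set is removed
  expect_true(all(res$report$removed_low_variance %in% sim$truth$low_variance))
  expect_true(res$report$batch_adjusted)
  expect_equal(res$report$n_samples_out, res$report$n_samples_in - 1)
})
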