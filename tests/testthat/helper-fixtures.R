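# Fixture builders and independent oracles shared across tests.

# Small expression matrix with both sexes annotated.
tiny_expr <- function(n_genes = 6, n_samples = 8, seed = 1, values = NULL) {
  set.seed(seed)
  v <- if (is.null(values)) {
    matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  } else {
    values
  }
  n_genes <- nrow(v); n_samples <- ncol(v)
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%02d", seq_len(n_genes))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%02d", seq_len(n_samples))
  meta <- data.frame(
    sample_id = colnames(v),
    sex = rep_len(c("male", "female"), n_samples),
    batch = rep_len(c("B1", "B2"), n_samples),
    stringsAsFactors = FALSE
  )
  expression_matrix(v, meta)
}

# The two-block bipartite fixture: two disjoint fully connected 2 TF x 2 gene
# blocks with unit weights. True partition has Q = 0.5.
two_block_graph <- function() {
  w <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("g", 1:4)))
  w[1:2, 1:2] <- 1
  w[3:4, 3:4] <- 1
  bipartite_graph(w)
}

two_block_partition <- function() {
  stats::setNames(c(1, 1, 2, 2, 1, 1, 2, 2),
                  c(paste0("t", 1:4), paste0("g", 1:4)))
}

# Random small bipartite graph with strictly positive total weight.
random_small_graph <- function(n_tf, n_gene, seed, density = 0.6) {
  set.seed(seed)
  repeat {
    w <- matrix(round(runif(n_tf * n_gene), 3) *
                  (runif(n_tf * n_gene) < density),
                n_tf, n_gene,
                dimnames = list(paste0("t", seq_len(n_tf)),
                                paste0("g", seq_len(n_gene))))
    if (sum(w) > 0) return(bipartite_graph(w))
  }
}

# All set partitions of n elements as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- vector("list", 0)
  rec <- function(labels, maxl) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible(NULL))
    }
    for (l in seq_len(maxl + 1L)) rec(c(labels, l), max(maxl, l))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive-search maximum Barber modularity (independent oracle).
exhaustive_max_q <- function(graph) {
  nodes <- c(graph$tf_ids, graph$gene_ids)
  best <- -Inf
  for (p in all_partitions(length(nodes))) {
    q <- bipartite_modularity(graph, stats::setNames(p, nodes))
    if (q > best) best <- q
  }
  best
}

# Independent scale-free fit: regression of log10 frequency on log10 degree.
independent_scale_free_r2 <- function(k, n_bins = 10) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- as.vector(table(bin))
  mk <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(mk)
  fit <- lm(log10(freq[ok]) ~ log10(mk[ok]))
  summary(fit)$r.squared
}

# Desk-scale simulation config used by several integration tests.
small_study_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 200L, n_tfs = 20L,
         n_samples_male = 25L, n_samples_female = 20L,
         module_sizes = c(40L, 30L, 40L, 40L),
         tfs_per_community = c(3L, 3L, 7L, 7L),
         seed = seed),
    list(...)
  )
  do.call(sim_config, args)
}

expect_expr_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tolerance)
  expect_identical(rownames(a$values), rownames(b$values))
  expect_identical(colnames(a$values), colnames(b$values))
}
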