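# Expression preprocessing: low-variance gene filter, sex-chromosome gene
# removal, hierarchical-clustering outlier detection and additive batch
# adjustment. The pipeline applies the stages in that fixed order.

#' Remove genes with low expression variance
#'
#' Drops genes whose sample variance is strictly smaller than `threshold`
#' (a gene with variance exactly at the threshold is kept). Gene order is
#' preserved.
#'
#' @param x An [expression_matrix()].
#' @param threshold Variance threshold; default 0.1, the conventional cut for
#'   variance-stabilized RNA-seq ahead of co-expression analysis.
#' @return List with `expression` (filtered) and `report` (a
#'   `preprocess_report` fragment listing removed genes).
#' @export
filter_low_variance <- function(x, threshold = 0.1) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2) stopf("need at least 2 samples")
  v <- row_vars(x$values)
  keep <- v >= threshold
  if (!any(keep)) stopf("variance filter at %g removed every gene", threshold)
  removed <- rownames(x$values)[!keep]
  out <- subset_expr(x, genes = which(keep))
  list(
    expression = out,
    report = list(removed_low_variance = removed, variance_threshold = threshold)
  )
}

# Normalize chromosome labels: strip a leading "chr", uppercase.
.norm_chrom <- function(chr) toupper(sub("^chr", "", as.character(chr)))

#' Remove genes on the sex chromosomes
#'
#' Genes annotated to chromosome X or Y are removed so autosomal signal
#' dominates downstream networks. Labels are normalized before matching, so
#' `"chrX"`, `"X"` and `"x"` are all treated as X. Genes with no annotation
#' are kept, with a warning.
#'
#' @param x An [expression_matrix()].
#' @param gene_meta Optional annotation data frame (`gene_id`/row names +
#'   `chromosome`); defaults to the annotation stored in `x`.
#' @return List with `expression` and `report` (removed gene ids).
#' @export
remove_sex_chromosome_genes <- function(x, gene_meta = x$gene_meta) {
  stopifnot(inherits(x, "expr_matrix"))
  genes <- rownames(x$values)
  if (is.null(gene_meta)) {
    warnf("no chromosome annotation available; keeping all %d genes",
          length(genes))
    return(list(expression = x,
                report = list(removed_sex_chromosome = character(0))))
  }
  gene_meta <- .key_by(gene_meta, "gene_id")
  chrom <- .norm_chrom(gene_meta[genes, "chromosome"])
  unannotated <- is.na(chrom)
  if (any(unannotated)) {
    warnf("%d gene(s) without chromosome annotation kept", sum(unannotated))
  }
  drop <- !unannotated & chrom %in% c("X", "Y")
  out <- if (any(drop)) subset_expr(x, genes = which(!drop)) else x
  list(expression = out,
       report = list(removed_sex_chromosome = genes[drop]))
}

#' Detect outlier samples by hierarchical clustering
#'
#' Samples are clustered by average-linkage hierarchical clustering of their
#' Euclidean expression distances. A sample is flagged when the height at
#' which it first merges into the tree exceeds the mean of all merge heights
#' by more than `cut_sd` standard deviations -- i.e. it only joins the bulk
#' of the samples at an anomalously late stage.
#'
#' @param x An [expression_matrix()].
#' @param cut_sd Outlier cut in SD units of the merge-height distribution.
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(x, cut_sd = 3) {
  stopifnot(inherits(x, "expr_matrix"))
  n <- ncol(x$values)
  if (n < 3) stopf("need at least 3 samples")
  hc <- stats::hclust(stats::dist(t(x$values)), method = "average")
  # first-merge height of each leaf
  first_height <- numeric(n)
  for (k in seq_len(nrow(hc$merge))) {
    leaves <- -hc$merge[k, ][hc$merge[k, ] < 0]
    first_height[leaves] <- hc$height[k]
  }
  cut <- mean(hc$height) + cut_sd * stats::sd(hc$height)
  if (!is.finite(cut)) return(character(0))
  colnames(x$values)[first_height > cut]
}

#' Remove additive batch effects, protecting the sex effect
#'
#' Per gene, fits the least-squares additive model
#' `expression ~ sex + batch` and subtracts the fitted batch terms
#' (re-centered to mean zero), leaving the sex effect untouched. Delegates to
#' `limma::removeBatchEffect()` with a sex design matrix -- the standard
#' remove-batch-effect contract.
#'
#' @param x An [expression_matrix()] whose `sample_meta` has a `batch` column.
#' @return List with `expression` (adjusted) and `report`.
#' @export
adjust_batch <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  meta <- x$sample_meta
  if (!"batch" %in% names(meta)) stopf("sample metadata has no `batch` column")
  batch <- factor(meta$batch)
  if (nlevels(batch) < 2) {
    return(list(expression = x, report = list(batch_adjusted = FALSE)))
  }
  sex <- factor(meta$sex)
  tab <- table(batch, sex)
  single_sex_batches <- rowSums(tab > 0) == 1
  batches_per_sex <- colSums(tab > 0)
  if (any(single_sex_batches) && all(batches_per_sex <= 1)) {
    stopf("batch is confounded with sex; cannot adjust")
  }
  design <- stats::model.matrix(~sex)
  adj <- limma::removeBatchEffect(x$values, batch = batch, design = design)
  out <- expression_matrix(adj, meta, x$gene_meta)
  list(expression = out, report = list(batch_adjusted = TRUE))
}

#' Run the full preprocessing chain
#'
#' Applies, in order: low-variance gene filter, sex-chromosome gene removal,
#' outlier-sample removal and batch adjustment, and assembles a
#' machine-readable report of what was removed at each step.
#'
#' @param x An [expression_matrix()].
#' @param variance_threshold Variance cut for [filter_low_variance()].
#' @param outlier_cut_sd Cut for [detect_outlier_samples()].
#' @param gene_meta Optional chromosome annotation overriding `x$gene_meta`.
#' @return List with `expression` and `report` (class `preprocess_report`).
#' @export
preprocess_expression <- function(x, variance_threshold = 0.1,
                                  outlier_cut_sd = 3, gene_meta = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  n_genes_in <- nrow(x$values)
  n_samples_in <- ncol(x$values)

  s1 <- filter_low_variance(x, variance_threshold)
  s2 <- remove_sex_chromosome_genes(
    s1$expression,
    gene_meta = if (is.null(gene_meta)) s1$expression$gene_meta else gene_meta
  )
  outliers <- detect_outlier_samples(s2$expression, cut_sd = outlier_cut_sd)
  x3 <- if (length(outliers)) {
    subset_expr(s2$expression,
                samples = setdiff(colnames(s2$expression$values), outliers))
  } else {
    s2$expression
  }
  s4 <- adjust_batch(x3)

  report <- structure(
    list(
      n_genes_in = n_genes_in, n_genes_out = nrow(s4$expression$values),
      n_samples_in = n_samples_in, n_samples_out = ncol(s4$expression$values),
      removed_low_variance = s1$report$removed_low_variance,
      removed_sex_chromosome = s2$report$removed_sex_chromosome,
      removed_outliers = outliers,
      batch_adjusted = s4$report$batch_adjusted,
      variance_threshold = variance_threshold,
      order = c("variance_filter", "sex_chromosome_removal",
                "outlier_removal", "batch_adjustment")
    ),
    class = "preprocess_report"
  )
  list(expression = s4$expression, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("preprocess: %d -> %d genes, %d -> %d samples\n",
              x$n_genes_in, x$n_genes_out, x$n_samples_in, x$n_samples_out))
  cat(sprintf("  low variance: %d | sex chromosome: %d | outliers: %d | batch adjusted: %s\n",
              length(x$removed_low_variance), length(x$removed_sex_chromosome),
              length(x$removed_outliers), x$batch_adjusted))
  invisible(x)
}
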