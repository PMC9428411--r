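# Module activity scoring: per-class gene rankings from sample z-scores, and
# a weighted Kolmogorov-Smirnov enrichment of each co-expression module in
# each class ranking, normalized against a gene-label permutation null.

#' Per-class gene ranking statistics
#'
#' Z-scores every gene across all samples, then summarizes each gene within a
#' class as the mean z over that class's samples. Because z-scores are
#' centered across all samples, a gene elevated in one class necessarily has
#' a negative statistic in the other.
#'
#' @param x An [expression_matrix()] (preprocessed).
#' @param class_labels Optional vector of class labels per sample; defaults
#'   to the stored sex annotation.
#' @return A numeric matrix, genes x classes, of mean class z-scores. The
#'   per-class ranking is by decreasing statistic.
#' @export
class_rank_statistic <- function(x, class_labels = x$sample_meta$sex) {
  stopifnot(inherits(x, "expr_matrix"))
  classes <- sort(unique(as.character(class_labels)))
  if (length(classes) < 2) stopf("need at least two classes")
  vals <- x$values
  mu <- rowMeans(vals)
  sd <- sqrt(row_vars(vals))
  zero <- sd == 0
  if (any(zero)) {
    warnf("%d zero-variance gene(s): z-scores set to 0", sum(zero))
    sd[zero] <- 1
  }
  z <- (vals - mu) / sd
  z[zero, ] <- 0
  stat <- vapply(classes, function(cl) {
    rowMeans(z[, class_labels == cl, drop = FALSE])
  }, numeric(nrow(vals)))
  rownames(stat) <- rownames(vals)
  stat
}

# Weighted (exponent 1) Kolmogorov-Smirnov enrichment score of the genes at
# positions `hit_idx` of a ranking whose statistics, sorted decreasingly, are
# `stats_sorted`. Returns the signed maximal deviation of the running sum.
.es_weighted_ks <- function(stats_sorted, hit_idx) {
  n <- length(stats_sorted)
  hits <- logical(n)
  hits[hit_idx] <- TRUE
  w <- abs(stats_sorted)
  w_hit <- sum(w[hits])
  if (w_hit == 0) w[hits] <- w_hit <- 1 # all-zero stats: unweighted steps
  p_hit <- cumsum(ifelse(hits, w, 0)) / w_hit
  p_miss <- cumsum(!hits) / (n - sum(hits))
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' GSEA-style module activity with a gene-permutation null
#'
#' For each module and each class ranking, computes the weighted
#' Kolmogorov-Smirnov enrichment score (weight exponent 1) of the module's
#' genes, and normalizes it against `n_perm` random gene sets of the same
#' size: `NES = ES / mean(|ES*|)` over permutation scores of matching sign,
#' with an empirical p-value carrying a +1 pseudocount. A module is flagged
#' `sex_different` when its absolute NES exceeds `nes_cut` in at least one
#' class; its direction is the class with the largest (signed) NES.
#'
#' @param ranking Gene x class statistic matrix from [class_rank_statistic()].
#' @param modules A [detect_modules()] result, or a named list of gene-id
#'   vectors.
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Integer seed for the permutation null.
#' @param nes_cut Absolute NES threshold for the sex-different flag
#'   (default 2).
#' @param min_genes Modules with fewer ranked genes are skipped (default 5).
#' @return Data frame of class `activity_result`: one row per (module,
#'   class) with `es`, `nes`, `perm_p`, `sex_different`, `direction`.
#' @export
gsea_module_activity <- function(ranking, modules, n_perm = 1000, seed = 1,
                                 nes_cut = 2, min_genes = 5) {
  sets <- if (inherits(modules, "module_assignment")) {
    labs <- modules$labels[modules$labels != "unassigned"]
    split(names(labs), labs)
  } else {
    modules
  }
  classes <- colnames(ranking)
  genes <- rownames(ranking)

  rows <- list()
  with_seed(seed, {
    for (mod in names(sets)) {
      members <- intersect(sets[[mod]], genes)
      if (length(members) < min_genes) {
        message(sprintf("module %s has %d ranked gene(s) (< %d): skipped",
                        mod, length(members), min_genes))
        next
      }
      m <- length(members)
      res <- lapply(classes, function(cl) {
        ord <- order(ranking[, cl], decreasing = TRUE)
        stats_sorted <- ranking[ord, cl]
        hit_idx <- match(members, genes[ord])
        es <- .es_weighted_ks(stats_sorted, hit_idx)
        perm <- vapply(seq_len(n_perm), function(i) {
          .es_weighted_ks(stats_sorted, sample.int(length(genes), m))
        }, numeric(1))
        same <- perm[sign(perm) == sign(es)]
        nes <- if (length(same)) es / mean(abs(same)) else 0
        p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
        c(es = es, nes = nes, p = p)
      })
      nes_vec <- vapply(res, `[[`, numeric(1), "nes")
      flagged <- max(abs(nes_vec)) > nes_cut
      direction <- if (flagged) classes[which.max(nes_vec)] else "none"
      for (i in seq_along(classes)) {
        rows[[length(rows) + 1]] <- data.frame(
          module = mod, class = classes[i], n_genes = m,
          es = res[[i]][["es"]], nes = res[[i]][["nes"]],
          perm_p = res[[i]][["p"]],
          sex_different = flagged, direction = direction,
          stringsAsFactors = FALSE
        )
      }
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(module = character(0), class = character(0),
               n_genes = integer(0), es = numeric(0), nes = numeric(0),
               perm_p = numeric(0), sex_different = logical(0),
               direction = character(0))
  }
  structure(out, class = c("activity_result", "data.frame"),
            nes_cut = nes_cut)
}
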