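# Condition-specific regulatory network inference by message passing over a
# motif prior, TF-TF PPI and gene co-expression. Edge weights are on a
# z-score-like scale and may be negative; downstream community detection uses
# the positive part as interaction evidence.

#' Restrict a motif prior to canonical TF-gene edges
#'
#' Keeps edges whose target gene is present in the expression matrix, and
#' (under canonical-only mode) drops edges whose target is itself a TF of the
#' motif set, so the network stays strictly bipartite TF -> gene.
#'
#' @param motif A bipartite `edge_list`.
#' @param expression_genes Character vector of genes with expression data.
#' @param canonical_only Drop TF-as-target edges (default `TRUE`).
#' @return Filtered `edge_list`; dropped counts are reported via `message()`.
#' @export
filter_canonical <- function(motif, expression_genes, canonical_only = TRUE) {
  stopifnot(inherits(motif, "edge_list"))
  tfs <- unique(motif$source)
  keep <- motif$target %in% expression_genes
  n_absent <- sum(!keep)
  n_tf_target <- 0L
  if (canonical_only) {
    tf_target <- motif$target %in% tfs
    n_tf_target <- sum(tf_target & keep)
    keep <- keep & !tf_target
  }
  message(sprintf(
    "motif filter: %d edge(s) to genes absent from expression, %d TF-as-target edge(s) dropped; %d retained",
    n_absent, n_tf_target, sum(keep)
  ))
  if (!any(keep)) stopf("no motif edges left after filtering")
  out <- motif[keep, ]
  attr(out, "mode") <- attr(motif, "mode")
  class(out) <- class(motif)
  out
}

#' Row/column z-score normalization of a network matrix
#'
#' Each entry is replaced by `(z_row + z_col) / sqrt(2)`, where `z_row` and
#' `z_col` are the entry's z-scores within its row and its column. A row or
#' column with zero spread contributes the overall matrix z-score scaled by
#' `1/sqrt(2)` instead.
#'
#' @param m Finite numeric matrix.
#' @return Matrix of the same shape.
#' @export
normalize_network <- function(m) {
  if (!all(is.finite(m))) stopf("matrix must be finite")
  mu_all <- mean(m)
  sd_all <- stats::sd(as.vector(m))
  z_all <- if (is.na(sd_all) || sd_all == 0) {
    matrix(0, nrow(m), ncol(m))
  } else {
    (m - mu_all) / sd_all
  }
  n_r <- ncol(m)
  mu_r <- rowMeans(m)
  sd_r <- sqrt(pmax(rowSums((m - mu_r)^2) / (n_r - 1), 0))
  z_r <- (m - mu_r) / sd_r
  deg_r <- !is.finite(sd_r) | sd_r == 0
  if (any(deg_r)) z_r[deg_r, ] <- z_all[deg_r, ] / sqrt(2)

  n_c <- nrow(m)
  mu_c <- colMeans(m)
  sd_c <- sqrt(pmax(colSums((t(t(m) - mu_c))^2) / (n_c - 1), 0))
  z_c <- t((t(m) - mu_c) / sd_c)
  deg_c <- !is.finite(sd_c) | sd_c == 0
  if (any(deg_c)) z_c[, deg_c] <- z_all[, deg_c] / sqrt(2)

  out <- (z_r + z_c) / sqrt(2)
  dimnames(out) <- dimnames(m)
  out
}

# Continuous Tanimoto similarity between the rows of x (a x k) and the
# columns of y (k x b): <x_i, y_j> / sqrt(||x_i||^2 + ||y_j||^2 - |<x_i,y_j>|).
.tanimoto <- function(x, y) {
  num <- x %*% y
  den <- sqrt(outer(rowSums(x^2), colSums(y^2), `+`) - abs(num))
  out <- num / den
  out[!is.finite(out)] <- 0
  out
}

# Dense edge-weight matrix (TFs x genes) from a bipartite edge list over
# fixed id spaces.
.motif_matrix <- function(motif, tf_ids, gene_ids) {
  w <- matrix(0, length(tf_ids), length(gene_ids),
              dimnames = list(tf_ids, gene_ids))
  keep <- motif$source %in% tf_ids & motif$target %in% gene_ids
  e <- motif[keep, ]
  w[cbind(match(e$source, tf_ids), match(e$target, gene_ids))] <- e$weight
  w
}

# Symmetric TF x TF matrix from a unipartite PPI edge list, unit diagonal.
.ppi_matrix <- function(ppi, tf_ids) {
  p <- matrix(0, length(tf_ids), length(tf_ids),
              dimnames = list(tf_ids, tf_ids))
  keep <- ppi$source %in% tf_ids & ppi$target %in% tf_ids
  e <- ppi[keep, ]
  if (nrow(e)) {
    i <- match(e$source, tf_ids); j <- match(e$target, tf_ids)
    p[cbind(i, j)] <- e$weight
    p[cbind(j, i)] <- e$weight
  }
  diag(p) <- 1
  p
}

#' Infer a condition-specific regulatory network by message passing
#'
#' Starting from the z-normalized motif prior `W`, PPI `P` and co-expression
#' `C` (Pearson correlation of the supplied expression subset), iterates:
#' responsibility `R = T(P, W)`, availability `A = T(W, C)` with the
#' continuous Tanimoto similarity, then `W <- (1 - alpha) W + alpha (R + A)/2`.
#' `P` and `C` move analogously toward the co-regulation similarity
#' `T(W, t(W))` and co-targeting similarity `T(t(W), W)` of the current `W`,
#' with the updated diagonal damped to each row's maximum off-diagonal value
#' so self-similarity cannot dominate. Iteration stops when the mean absolute
#' change of `W` drops below `tol`.
#'
#' @param motif Bipartite motif prior `edge_list` (ideally already passed
#'   through [filter_canonical()]).
#' @param ppi Unipartite TF-TF `edge_list`.
#' @param expression_subset [expression_matrix()] restricted to one
#'   condition's samples.
#' @param alpha Update rate in `[0, 1]`; `alpha = 0` returns the normalized
#'   prior unchanged.
#' @param tol Convergence tolerance on mean `|delta W|`.
#' @param max_iter Iteration cap.
#' @param condition Label stored on the result (e.g. `"male"`).
#' @return Object of class `grn`: `tf_ids`, `gene_ids`, `w` (TFs x genes,
#'   z-score-like scale), `condition`, `alpha`, `n_iterations`, `converged`,
#'   `delta` (per-iteration mean absolute change).
#' @export
infer_network <- function(motif, ppi, expression_subset, alpha = 0.1,
                          tol = 1e-3, max_iter = 200, condition = NA_character_) {
  stopifnot(inherits(motif, "edge_list"),
            inherits(expression_subset, "expr_matrix"))
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  gene_ids <- rownames(expression_subset$values)
  tf_ids <- sort(unique(motif$source))
  if (!any(motif$target %in% gene_ids)) {
    stopf("motif targets and expression genes do not overlap")
  }

  w <- normalize_network(.motif_matrix(motif, tf_ids, gene_ids))
  p <- normalize_network(.ppi_matrix(ppi, tf_ids))
  cc <- stats::cor(t(expression_subset$values))
  cc[is.na(cc)] <- 0
  cc <- normalize_network(cc)

  # Replace the diagonal of a similarity update by the off-diagonal row SD
  # scaled by the matrix dimension and a factor growing with the iteration:
  # the inflating self-similarity enters later Tanimoto denominators and
  # keeps the message-passing gain bounded.
  damp_diag <- function(s, step) {
    n <- nrow(s)
    off_sum <- rowSums(s) - diag(s)
    off_ss <- rowSums(s^2) - diag(s)^2
    mu <- off_sum / (n - 1)
    sd_off <- sqrt(pmax(off_ss / (n - 1) - mu^2, 0))
    diag(s) <- sd_off * n * exp(2 * alpha * step)
    s
  }

  delta <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  if (alpha > 0) {
    for (it in seq_len(max_iter)) {
      r <- .tanimoto(p, w)
      a <- .tanimoto(w, cc)
      w_new <- (1 - alpha) * w + alpha * (r + a) / 2
      d <- mean(abs(w_new - w))
      delta <- c(delta, d)
      w <- w_new
      n_iter <- it
      if (d < tol) { converged <- TRUE; break }
      p_upd <- damp_diag(.tanimoto(w, t(w)), it - 1L)
      c_upd <- damp_diag(.tanimoto(t(w), w), it - 1L)
      p <- (1 - alpha) * p + alpha * p_upd
      cc <- (1 - alpha) * cc + alpha * c_upd
    }
  } else {
    converged <- TRUE
    n_iter <- 1L
  }

  structure(
    list(tf_ids = tf_ids, gene_ids = gene_ids, w = w,
         condition = condition, alpha = alpha,
         n_iterations = n_iter, converged = converged, delta = delta),
    class = "grn"
  )
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf(
    "grn (%s): %d TFs x %d genes; %d iteration(s), %sconverged\n",
    ifelse(is.na(x$condition), "unlabeled", x$condition),
    length(x$tf_ids), length(x$gene_ids), x$n_iterations,
    ifelse(x$converged, "", "NOT ")
  ))
  invisible(x)
}

#' Write a regulatory network as dense and long-format TSV
#'
#' @param net A `grn`.
#' @param dense_path Output TSV of the TFs x genes weight matrix.
#' @param long_path Optional long-format (tf, gene, weight) TSV.
#' @export
write_grn <- function(net, dense_path, long_path = NULL) {
  out <- data.frame(tf = net$tf_ids, stringsAsFactors = FALSE)
  for (j in seq_along(net$gene_ids)) {
    out[[net$gene_ids[j]]] <- fmt_num(net$w[, j])
  }
  utils::write.table(out, dense_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(long_path)) {
    long <- data.frame(
      tf = rep(net$tf_ids, times = length(net$gene_ids)),
      gene = rep(net$gene_ids, each = length(net$tf_ids)),
      weight = fmt_num(as.vector(net$w)), stringsAsFactors = FALSE
    )
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dense_path)
}
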