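# Soft-thresholded co-expression network, topological overlap, module
# detection by average-linkage clustering with a fixed dissimilarity cut, and
# hub labeling against a PPI network.

#' Scale-free fit statistic of a degree distribution
#'
#' Bins the weighted degrees, regresses log10(frequency) on log10(mean bin
#' degree), and returns the signed R-squared (negated when the slope is
#' positive, since scale-free topology requires a decreasing fit). Degenerate
#' distributions with fewer than three informative bins fit any power law
#' trivially and score 1.
#' @noRd
.scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[is.finite(k)]
  if (length(unique(round(k, 10))) < 3) return(1)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  mean_k <- vapply(seq_len(n_bins), function(b) mean(k[as.integer(bin) == b]),
                   numeric(1))
  ok <- freq > 0 & mean_k > 0
  if (sum(ok) < 3) return(1)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  if (is.na(slope)) return(1)
  -sign(slope) * r2
}

#' Select the soft-thresholding power
#'
#' Returns the smallest power `beta` for which the adjacency
#' `|r|^beta` degree distribution attains scale-free fit R-squared >= `r2_cut`;
#' if none qualifies, the power with the maximum fit is returned.
#'
#' @param similarity Symmetric matrix of absolute correlations.
#' @param betas Candidate powers (default 1..20).
#' @param r2_cut Scale-free fit target (default 0.8).
#' @return Integer power, with attributes `r2` (fit at the chosen power) and
#'   `criterion` (`"first_above_cut"` or `"max_r2"`).
#' @export
select_soft_threshold <- function(similarity, betas = 1:20, r2_cut = 0.8) {
  n <- nrow(similarity)
  if (n < 50) {
    warnf("fewer than 50 genes: soft threshold forced to 6")
    return(structure(6L, r2 = NA_real_, criterion = "forced_small_n"))
  }
  sim <- similarity
  diag(sim) <- 0
  r2 <- vapply(betas, function(b) .scale_free_r2(colSums(sim^b)), numeric(1))
  above <- which(r2 >= r2_cut)
  if (length(above)) {
    pick <- above[1]
    criterion <- "first_above_cut"
  } else {
    pick <- which.max(r2)
    criterion <- "max_r2"
  }
  structure(as.integer(betas[pick]), r2 = r2[pick], criterion = criterion)
}

#' Build a soft-thresholded co-expression network
#'
#' Computes the unsigned similarity `|Pearson r|` between genes, raises it to
#' the chosen soft-threshold power to get the adjacency, and derives the
#' topological overlap matrix (TOM).
#'
#' @param x An [expression_matrix()] (genes x samples), already preprocessed.
#' @param beta Soft-threshold power; `NULL` (default) selects it with
#'   [select_soft_threshold()].
#' @param betas Candidate powers when `beta` is `NULL`.
#' @return List of class `coexpression_network` with `gene_ids`, `similarity`,
#'   `beta`, `r2`, `adjacency` (zero diagonal) and `tom`.
#' @export
coexpression_network <- function(x, beta = NULL, betas = 1:20) {
  stopifnot(inherits(x, "expr_matrix"))
  sim <- abs(stats::cor(t(x$values)))
  sim[is.na(sim)] <- 0 # zero-variance genes are uncorrelated with everything
  r2 <- NA_real_
  if (is.null(beta)) {
    beta <- select_soft_threshold(sim, betas = betas)
    r2 <- attr(beta, "r2")
  }
  beta <- as.integer(beta)
  if (beta < 1) stopf("beta must be >= 1")
  adj <- sim^beta
  diag(adj) <- 0
  tom <- .tom(adj)
  structure(
    list(gene_ids = rownames(x$values), similarity = sim, beta = beta,
         r2 = r2, adjacency = adj, tom = tom),
    class = "coexpression_network"
  )
}

# Unsigned topological overlap of a (zero-diagonal) adjacency matrix.
.tom <- function(adj) {
  l <- adj %*% adj
  k <- colSums(adj)
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  tom
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, beta = %d (scale-free R2 = %s)\n",
              length(x$gene_ids), x$beta,
              ifelse(is.na(x$r2), "n/a", sprintf("%.3f", x$r2))))
  invisible(x)
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity `1 - TOM`
#' with a fixed cut: genes joining the tree only above `cut_height` stay
#' apart, clusters below `min_size` are left unassigned, and modules are
#' renumbered CM1, CM2, ... by decreasing size. Genes are processed in
#' lexicographic id order so the partition does not depend on input order.
#'
#' @param network A [coexpression_network()].
#' @param min_size Minimum module size (30 at full scale; use 10 for
#'   desk-scale data).
#' @param cut_height Absolute dissimilarity cut on the `1 - TOM` scale.
#' @return List of class `module_assignment` with `labels` (gene ->
#'   `"CM<k>"` or `"unassigned"`) and `sizes`.
#' @export
detect_modules <- function(network, min_size = 30, cut_height = 0.99) {
  stopifnot(inherits(network, "coexpression_network"))
  ord <- order(network$gene_ids)
  genes <- network$gene_ids[ord]
  diss <- 1 - network$tom[ord, ord]
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  labels <- rep("unassigned", length(genes))
  names(labels) <- genes
  if (length(keep)) {
    keep_sizes <- sizes[keep]
    # renumber by decreasing size; ties by first gene id in the cluster
    first_gene <- vapply(keep, function(k) genes[cl == k][1], character(1))
    ord2 <- order(-as.integer(keep_sizes), first_gene)
    for (i in seq_along(ord2)) {
      labels[cl == as.integer(keep[ord2[i]])] <- paste0("CM", i)
    }
  }
  labels <- labels[network$gene_ids] # restore input order
  out_sizes <- table(labels[labels != "unassigned"])
  structure(list(labels = labels, sizes = out_sizes,
                 min_size = min_size, cut_height = cut_height),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("module_assignment: %d modules, %d genes unassigned\n",
              length(x$sizes), sum(x$labels == "unassigned")))
  invisible(x)
}

#' Label hub genes in co-expression and PPI networks
#'
#' Within each module, the top-`k` genes by weighted within-module
#' co-expression degree are co-expression hubs, and the top-`k` by PPI degree
#' (edges among module members) are PPI hubs; genes topping both lists are
#' labeled `"both"`. Modules smaller than `k` simply rank all their members.
#'
#' @param network A [coexpression_network()].
#' @param modules A [detect_modules()] result.
#' @param ppi A unipartite `edge_list` of protein-protein interactions.
#' @param k Number of hubs per module and network (default 10).
#' @return Data frame with `gene`, `module`, `degree_coexpression`,
#'   `degree_ppi`, `hub_label`.
#' @export
label_hubs <- function(network, modules, ppi, k = 10) {
  stopifnot(inherits(network, "coexpression_network"),
            inherits(modules, "module_assignment"))
  genes <- network$gene_ids
  labels <- modules$labels[genes]
  adj <- network$adjacency

  ppi_deg_in <- function(members) {
    sub <- ppi[ppi$source %in% members & ppi$target %in% members, ]
    deg <- integer(length(members))
    names(deg) <- members
    if (nrow(sub)) {
      t1 <- table(factor(sub$source, levels = members))
      t2 <- table(factor(sub$target, levels = members))
      deg <- as.integer(t1 + t2)
      names(deg) <- members
    }
    deg
  }

  out <- data.frame(gene = genes, module = labels,
                    degree_coexpression = 0, degree_ppi = 0L,
                    hub_label = "none", stringsAsFactors = FALSE)
  for (m in names(modules$sizes)) {
    members <- genes[labels == m]
    idx <- match(members, genes)
    cdeg <- colSums(adj[idx, idx, drop = FALSE])
    pdeg <- ppi_deg_in(members)
    out$degree_coexpression[idx] <- cdeg
    out$degree_ppi[idx] <- pdeg
    kk <- min(k, length(members))
    chub <- members[order(-cdeg, members)][seq_len(kk)]
    phub <- members[order(-pdeg, members)][seq_len(kk)]
    phub <- phub[pdeg[match(phub, members)] > 0] # a hub needs interactions
    lab <- ifelse(members %in% chub & members %in% phub, "both",
                  ifelse(members %in% chub, "coexpression",
                         ifelse(members %in% phub, "ppi", "none")))
    out$hub_label[idx] <- lab
  }
  rownames(out) <- NULL
  out
}
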