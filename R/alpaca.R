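# Differential modularity: compare a "perturbed" condition network against a
# "baseline" network by scoring the observed within-module weight of the
# perturbed network against the baseline's configuration-model expectation,
# find the node partition maximizing that score, and extract driver TFs and
# genes whose log-scale contributions stand out from their module.

# Zero-pad two positive bipartite graphs onto the union of their node sets.
.harmonize_graphs <- function(a, b) {
  tfs <- sort(unique(c(a$tf_ids, b$tf_ids)))
  genes <- sort(unique(c(a$gene_ids, b$gene_ids)))
  n_missing <- (length(tfs) - length(a$tf_ids)) +
    (length(tfs) - length(b$tf_ids)) +
    (length(genes) - length(a$gene_ids)) +
    (length(genes) - length(b$gene_ids))
  if (n_missing > 0) {
    message(sprintf(
      "%d node slot(s) present in only one network treated as degree 0", n_missing))
  }
  pad <- function(g) {
    w <- matrix(0, length(tfs), length(genes), dimnames = list(tfs, genes))
    w[g$tf_ids, g$gene_ids] <- g$w
    bipartite_graph(w)
  }
  list(a = pad(a), b = pad(b))
}

#' Differential modularity of a partition
#'
#' `D = sum over same-community TF i, gene j of
#' [w_ij^pert / m_pert - k_i^base d_j^base / m_base^2]`: the observed
#' within-module weight fraction of the perturbed network minus the baseline
#' configuration-model expectation. With `perturbed = baseline` this equals
#' the Barber bipartite modularity of that network under the same partition.
#' Nodes present in only one network are treated as degree 0 in the other.
#'
#' @param perturbed,baseline `bipartite_graph`s (positive projections).
#' @param partition Named node -> community labels covering both graphs'
#'   nodes.
#' @return The differential modularity score `D`.
#' @export
differential_modularity_score <- function(perturbed, baseline, partition) {
  h <- .harmonize_graphs(perturbed, baseline)
  labs <- if (inherits(partition, "bipartite_partition")) {
    partition$labels
  } else {
    partition
  }
  ct <- labs[h$a$tf_ids]
  cg <- labs[h$a$gene_ids]
  if (anyNA(ct) || anyNA(cg)) stopf("partition must cover every node")
  .diff_modularity(h$a$w, h$a$m_w, rowSums(h$b$w), colSums(h$b$w), h$b$m_w,
                   ct, cg)
}

#' Find differential modules between two condition networks
#'
#' Initializes from the baseline network's own community partition and
#' maximizes the differential modularity `D` with the same deterministic move
#' engine used for Barber modularity (alternating assignment, single-node
#' moves, community merges), so the result never scores below its
#' initialization. Per-node scores are each node's within-module differential
#' contribution, floored at `eps` so the log transform used for driver
#' extraction is defined; floored nodes are never selectable as drivers.
#'
#' @param perturbed,baseline `bipartite_graph`s (positive projections of the
#'   two condition networks).
#' @param baseline_partition Optional precomputed [maximize_modularity()]
#'   partition of `baseline`; computed if missing.
#' @param baseline_label,perturbed_label Condition names (e.g. `"female"`,
#'   `"male"`); modules are biased toward the perturbed condition.
#' @param eps Floor applied to non-positive node scores (default `1e-12`).
#' @param max_sweeps Optimizer sweep cap.
#' @return Object of class `diff_modules`: `labels` (node -> `"M<k>"`, by
#'   decreasing module size), `scores` (per-node differential contribution,
#'   floored), `node_type`, `d_total`, `baseline`, `perturbed`, `bias`.
#' @export
find_differential_modules <- function(perturbed, baseline,
                                      baseline_partition = NULL,
                                      baseline_label = "baseline",
                                      perturbed_label = "perturbed",
                                      eps = 1e-12, max_sweeps = 50) {
  h <- .harmonize_graphs(perturbed, baseline)
  wp <- h$a$w; m_p <- h$a$m_w
  kb <- rowSums(h$b$w); db <- colSums(h$b$w); m_b <- h$b$m_w
  if (is.null(baseline_partition)) {
    baseline_partition <- maximize_modularity(h$b)
  }
  init <- baseline_partition$labels
  missing <- setdiff(c(h$a$tf_ids, h$a$gene_ids), names(init))
  if (length(missing)) {
    init <- c(init, stats::setNames(
      seq.int(max(init) + 1L, length.out = length(missing)), missing))
  }
  res <- .optimize_bipartite(wp, m_p, kb, db, m_b,
                             as.character(init[h$a$tf_ids]),
                             as.character(init[h$a$gene_ids]),
                             max_sweeps)
  part <- .finish_partition(h$a, res)

  ct <- part$labels[h$a$tf_ids]
  cg <- part$labels[h$a$gene_ids]
  n_lab <- max(part$labels)
  mg <- matrix(0, length(cg), n_lab); mg[cbind(seq_along(cg), cg)] <- 1
  mt <- matrix(0, length(ct), n_lab); mt[cbind(seq_along(ct), ct)] <- 1
  d_l <- as.vector(t(mg) %*% db)
  k_l <- as.vector(t(mt) %*% kb)
  s_tf <- (wp %*% mg)[cbind(seq_along(ct), ct)] / m_p - kb * d_l[ct] / m_b^2
  s_g <- (t(wp) %*% mt)[cbind(seq_along(cg), cg)] / m_p - db * k_l[cg] / m_b^2
  scores <- c(s_tf, s_g)
  names(scores) <- c(h$a$tf_ids, h$a$gene_ids)
  floored <- scores < eps
  scores[floored] <- eps

  labels <- paste0("M", part$labels)
  names(labels) <- names(part$labels)
  structure(
    list(labels = labels, scores = scores, floored = floored,
         node_type = part$node_type, d_total = res$score,
         n_modules = part$n_communities,
         baseline = baseline_label, perturbed = perturbed_label,
         bias = paste0(perturbed_label, "-biased"), eps = eps),
    class = "diff_modules"
  )
}

#' @export
print.diff_modules <- function(x, ...) {
  cat(sprintf(
    "diff_modules (%s baseline, %s): %d modules over %d nodes, D = %.4f\n",
    x$baseline, x$bias, x$n_modules, length(x$labels), x$d_total
  ))
  invisible(x)
}

#' Run differential-modularity analysis in both directions
#'
#' The dual-baseline design: with the female network as baseline, modules
#' capture where the male network is denser than expected (male-biased), and
#' vice versa. Both directions are always reported because the two
#' comparisons are not symmetric.
#'
#' @param male_net,female_net `grn` objects on identical node spaces.
#' @param ... Passed to [find_differential_modules()].
#' @return List with `female_baseline` (male-biased modules) and
#'   `male_baseline` (female-biased modules).
#' @export
run_dual_baseline <- function(male_net, female_net, ...) {
  male_g <- positive_projection(male_net)
  female_g <- positive_projection(female_net)
  list(
    female_baseline = find_differential_modules(
      male_g, female_g, baseline_label = "female", perturbed_label = "male", ...),
    male_baseline = find_differential_modules(
      female_g, male_g, baseline_label = "male", perturbed_label = "female", ...)
  )
}

#' Log-scale transform of differential modularity scores
#'
#' Natural log of the raw per-node score, with non-positive scores floored at
#' `eps` first so the transform is always defined.
#'
#' @param score Numeric vector of raw differential modularity scores.
#' @param eps Floor for non-positive scores.
#' @return `log(pmax(score, eps))`.
#' @export
driver_log_score <- function(score, eps = 1e-12) {
  log(pmax(score, eps))
}

#' Extract driver TFs and genes from differential modules
#'
#' Scores are moved to the natural-log scale; the interquartile range is
#' computed separately for TFs and for genes over the whole network (the two
#' node types live on different scales in a bipartite network), while the
#' reference median is each node's own module median (within node type). A
#' node is selected when its log score exceeds that module median by more
#' than `k_tf` (TFs) or `k_gene` (genes) times the type's IQR. Modules with
#' fewer than 3 nodes of a type are not tested for that type.
#'
#' @param modules A `diff_modules` result.
#' @param k_tf,k_gene IQR multipliers (defaults 1.5 and 3).
#' @param iqr_scope `"global"` (default; IQR per node type over the whole
#'   network) or `"module"` (IQR within each module).
#' @return Data frame of class `driver_set`, sorted by decreasing score:
#'   columns `node`, `score`, `type`, `module`, `log_score`, `tested`,
#'   `selected`.
#' @export
extract_drivers <- function(modules, k_tf = 1.5, k_gene = 3,
                            iqr_scope = c("global", "module")) {
  stopifnot(inherits(modules, "diff_modules"))
  iqr_scope <- match.arg(iqr_scope)
  nodes <- names(modules$labels)
  type <- modules$node_type[nodes]
  s <- modules$scores[nodes]
  x <- driver_log_score(s, eps = modules$eps)
  mod <- modules$labels[nodes]
  k_type <- c(TF = k_tf, gene = k_gene)

  iqr_global <- vapply(c("TF", "gene"), function(tp) {
    stats::IQR(x[type == tp])
  }, numeric(1))

  tested <- logical(length(nodes))
  selected <- logical(length(nodes))
  for (m in unique(mod)) {
    for (tp in c("TF", "gene")) {
      idx <- which(mod == m & type == tp)
      if (length(idx) < 3) {
        if (length(idx)) {
          message(sprintf("module %s has %d %s node(s) (< 3): not tested",
                          m, length(idx), tp))
        }
        next
      }
      med <- stats::median(x[idx])
      iqr <- if (iqr_scope == "global") iqr_global[[tp]] else stats::IQR(x[idx])
      tested[idx] <- TRUE
      selected[idx] <- x[idx] > med + k_type[[tp]] * iqr
    }
  }
  # floored nodes carry no real contribution and are never drivers
  selected[modules$floored[nodes]] <- FALSE

  out <- data.frame(node = nodes, score = unname(s), type = unname(type),
                    module = unname(mod), log_score = unname(x),
                    tested = tested, selected = selected,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$node), ]
  rownames(out) <- NULL
  structure(out, class = c("driver_set", "data.frame"),
            k_tf = k_tf, k_gene = k_gene, iqr_scope = iqr_scope,
            bias = modules$bias, baseline = modules$baseline)
}

#' Top TFs shared between the two baseline directions
#'
#' @param drivers_a,drivers_b `driver_set` data frames.
#' @return Character vector: TFs selected in both.
#' @export
shared_top_tfs <- function(drivers_a, drivers_b) {
  sel <- function(d) d$node[d$type == "TF" & d$selected]
  sort(intersect(sel(drivers_a), sel(drivers_b)))
}

#' Write differential modules and driver calls to TSV
#' @param drivers A `driver_set`.
#' @param path Output TSV with columns IDs, Score, Type, Membership,
#'   logScore, selected.
#' @export
write_drivers <- function(drivers, path) {
  out <- data.frame(IDs = drivers$node, Score = fmt_num(drivers$score),
                    Type = drivers$type, Membership = drivers$module,
                    logScore = fmt_num(drivers$log_score),
                    selected = drivers$selected, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
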