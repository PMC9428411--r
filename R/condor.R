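# Bipartite TF-gene community structure by Barber modularity maximization:
# positive-edge projection of an inferred network, modularity evaluation, and
# a deterministic BRIM-style optimizer (alternating label assignment plus
# single-node moves and community merges). No randomness: initialization and
# tie-breaks are fixed, so partitions are reproducible without seeds.

#' Project a regulatory network onto its positive edges
#'
#' Positive edge weights are interpreted as evidence for a TF-gene
#' interaction; non-positive entries are dropped, as are nodes left without
#' any positive edge.
#'
#' @param net A `grn` from [infer_network()], or a list with `tf_ids`,
#'   `gene_ids` and a TFs x genes weight matrix `w`.
#' @return Object of class `bipartite_graph`: `tf_ids`, `gene_ids`, `w`
#'   (non-negative TFs x genes matrix), `m_w` (total weight).
#' @export
positive_projection <- function(net) {
  w <- net$w
  w[w <= 0] <- 0
  keep_tf <- rowSums(w) > 0
  keep_gene <- colSums(w) > 0
  if (!any(keep_tf) || !any(keep_gene)) {
    stopf("no positive edges: cannot build a bipartite graph")
  }
  n_drop <- sum(!keep_tf) + sum(!keep_gene)
  if (n_drop > 0) {
    message(sprintf("positive projection dropped %d node(s) without positive edges",
                    n_drop))
  }
  w <- w[keep_tf, keep_gene, drop = FALSE]
  bipartite_graph(w)
}

#' Construct a weighted bipartite graph from a TFs x genes matrix
#' @param w Non-negative numeric matrix with TF row names and gene column
#'   names.
#' @return A `bipartite_graph`.
#' @export
bipartite_graph <- function(w) {
  stopifnot(is.matrix(w), all(w >= 0), sum(w) > 0)
  if (is.null(rownames(w)) || is.null(colnames(w))) {
    stopf("weight matrix needs TF row names and gene column names")
  }
  structure(list(tf_ids = rownames(w), gene_ids = colnames(w),
                 w = w, m_w = sum(w)),
            class = "bipartite_graph")
}

#' Barber bipartite modularity of a partition
#'
#' `Q = (1/m) * sum_ij [w_ij - k_i d_j / m] * delta(c_i, c_j)` with `k`, `d`
#' the weighted TF and gene degrees and `m` the total edge weight.
#'
#' @param graph A `bipartite_graph`.
#' @param partition Named community labels covering `c(tf_ids, gene_ids)`
#'   (a `bipartite_partition` or a named vector).
#' @return Modularity Q in `[-1, 1]`.
#' @export
bipartite_modularity <- function(graph, partition) {
  labs <- if (inherits(partition, "bipartite_partition")) {
    partition$labels
  } else {
    partition
  }
  ct <- labs[graph$tf_ids]
  cg <- labs[graph$gene_ids]
  if (anyNA(ct) || anyNA(cg)) stopf("partition must cover every graph node")
  .diff_modularity(graph$w, graph$m_w,
                   rowSums(graph$w), colSums(graph$w), graph$m_w,
                   ct, cg)
}

# D = sum over same-community (i, j) of [wp_ij / m_p - kb_i db_j / m_b^2].
# With the perturbed and baseline graphs equal this is Barber modularity.
.diff_modularity <- function(wp, m_p, kb, db, m_b, ct, cg) {
  labels <- unique(c(ct, cg))
  total <- 0
  for (l in labels) {
    ti <- ct == l
    gj <- cg == l
    if (!any(ti) || !any(gj)) next
    total <- total + sum(wp[ti, gj, drop = FALSE]) / m_p -
      sum(kb[ti]) * sum(db[gj]) / m_b^2
  }
  total
}

# Core alternating-assignment engine shared by Barber-modularity optimization
# and differential-modularity optimization. Maximizes
#   sum_same_community [ wp_ij / m_p - kb_i db_j / m_b^2 ]
# via (1) BRIM-style alternating TF/gene label assignment, (2) sequential
# single-node best moves, (3) greedy community merges. Deterministic; ties go
# to the smallest label index.
.optimize_bipartite <- function(wp, m_p, kb, db, m_b, init_tf, init_gene,
                                max_sweeps = 50) {
  ct <- as.integer(factor(init_tf, levels = unique(c(init_tf, init_gene))))
  cg <- as.integer(factor(init_gene, levels = unique(c(init_tf, init_gene))))
  score <- function() .diff_modularity(wp, m_p, kb, db, m_b, ct, cg)

  memb <- function(lab, n_lab) {
    m <- matrix(0, length(lab), n_lab)
    m[cbind(seq_along(lab), lab)] <- 1
    m
  }
  relabel <- function() {
    f <- factor(c(ct, cg))
    ct <<- as.integer(f[seq_along(ct)])
    cg <<- as.integer(f[seq_along(cg) + length(ct)])
  }

  best_score <- -Inf
  repeat { # cycle assignment, node moves and merges until Q stabilizes

  # phase 1: alternating sweeps
  for (sweep in seq_len(max_sweeps)) {
    relabel()
    n_lab <- max(ct, cg)
    d_l <- as.vector(t(memb(cg, n_lab)) %*% db)   # baseline gene degree per label
    gain_tf <- wp %*% memb(cg, n_lab) / m_p - outer(kb, d_l) / m_b^2
    new_ct <- max.col(gain_tf, ties.method = "first")
    k_l <- as.vector(t(memb(new_ct, n_lab)) %*% kb)
    gain_g <- t(wp) %*% memb(new_ct, n_lab) / m_p - outer(db, k_l) / m_b^2
    new_cg <- max.col(gain_g, ties.method = "first")
    changed <- any(new_ct != ct) || any(new_cg != cg)
    ct <- new_ct
    cg <- new_cg
    if (!changed) break
  }

  # phase 2: sequential single-node moves (allow opening a fresh label)
  repeat {
    relabel()
    improved <- FALSE
    n_lab <- max(c(ct, cg)) + 1L # one spare empty label
    mg <- memb(cg, n_lab)
    d_l <- as.vector(t(mg) %*% db)
    w_tf_l <- wp %*% mg
    for (i in seq_along(ct)) {
      gains <- w_tf_l[i, ] / m_p - kb[i] * d_l / m_b^2
      best <- which.max(gains)
      if (gains[best] > gains[ct[i]] + 1e-13) {
        ct[i] <- best
        improved <- TRUE
      }
    }
    mt <- memb(ct, n_lab)
    k_l <- as.vector(t(mt) %*% kb)
    w_g_l <- t(wp) %*% mt
    for (j in seq_along(cg)) {
      gains <- w_g_l[j, ] / m_p - db[j] * k_l / m_b^2
      best <- which.max(gains)
      if (gains[best] > gains[cg[j]] + 1e-13) {
        cg[j] <- best
        improved <- TRUE
      }
    }
    if (!improved) break
  }

  # phase 3: greedy community merges
  repeat {
    relabel()
    n_lab <- max(c(ct, cg))
    if (n_lab < 2) break
    w_lab <- t(memb(ct, n_lab)) %*% wp %*% memb(cg, n_lab)
    k_lab <- numeric(n_lab); d_lab <- numeric(n_lab)
    for (l in seq_len(n_lab)) {
      k_lab[l] <- sum(kb[ct == l]); d_lab[l] <- sum(db[cg == l])
    }
    best_gain <- 0; best_pair <- NULL
    for (a in seq_len(n_lab - 1)) {
      for (b in (a + 1):n_lab) {
        gain <- (w_lab[a, b] + w_lab[b, a]) / m_p -
          (k_lab[a] * d_lab[b] + k_lab[b] * d_lab[a]) / m_b^2
        if (gain > best_gain + 1e-13) {
          best_gain <- gain; best_pair <- c(a, b)
        }
      }
    }
    if (is.null(best_pair)) break
    ct[ct == best_pair[2]] <- best_pair[1]
    cg[cg == best_pair[2]] <- best_pair[1]
  }

  s <- score()
  if (s <= best_score + 1e-13) break
  best_score <- s
  } # outer cycle

  relabel()
  list(ct = ct, cg = cg, score = score())
}

# Restricted-growth enumeration of all set partitions of n elements.
.rg_partitions <- function(n) {
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

# Exact maximization over gene-side partitions for small gene sides: given
# gene labels, each TF's optimal community follows independently in closed
# form (a TF-only community contributes zero), so enumerating gene partitions
# yields the global optimum.
.exact_bipartite <- function(wp, m_p, kb, db, m_b) {
  n_g <- ncol(wp)
  best <- NULL
  for (cg in .rg_partitions(n_g)) {
    n_lab <- max(cg)
    mg <- matrix(0, n_g, n_lab)
    mg[cbind(seq_len(n_g), cg)] <- 1
    d_l <- as.vector(t(mg) %*% db)
    gains <- wp %*% mg / m_p - outer(kb, d_l) / m_b^2
    per_tf <- apply(gains, 1, max)
    score <- sum(pmax(per_tf, 0))
    if (is.null(best) || score > best$score + 1e-15) {
      ct <- max.col(gains, ties.method = "first")
      lone <- per_tf < 0 # better off alone in an empty community
      if (any(lone)) ct[lone] <- n_lab + seq_len(sum(lone))
      best <- list(ct = ct, cg = cg, score = score)
    }
  }
  best
}

# Deterministic synchronous label propagation on a similarity matrix; used to
# seed the gene-side labels from the gene-gene co-targeting projection.
.label_propagation_init <- function(s, max_sweeps = 15) {
  n <- nrow(s)
  diag(s) <- 0
  lab <- seq_len(n)
  prev <- NULL
  for (sweep in seq_len(max_sweeps)) {
    u <- sort(unique(lab))
    m <- matrix(0, n, length(u))
    m[cbind(seq_len(n), match(lab, u))] <- 1
    votes <- s %*% m
    new <- u[max.col(votes, ties.method = "first")]
    no_nb <- rowSums(s) == 0
    new[no_nb] <- lab[no_nb]
    if (identical(new, lab) || identical(new, prev)) { lab <- new; break }
    prev <- lab
    lab <- new
  }
  lab
}

#' Maximize Barber bipartite modularity
#'
#' Gene labels are seeded by label propagation on the gene-gene co-targeting
#' projection, then refined by alternating TF/gene assignment, single-node
#' moves and community merges. Deterministic (smallest-label tie-breaks), so
#' repeated runs agree without a seed. Community labels are renumbered by
#' decreasing community size.
#'
#' @param graph A `bipartite_graph`.
#' @param max_sweeps Cap on alternating sweeps (default 50).
#' @return Object of class `bipartite_partition`: `labels` (named node ->
#'   integer community), `node_type`, `q`, `n_communities`, `m_w`.
#' @export
maximize_modularity <- function(graph, max_sweeps = 50) {
  stopifnot(inherits(graph, "bipartite_graph"))
  w <- graph$w
  kb <- rowSums(w)
  db <- colSums(w)
  proj <- crossprod(w) # gene-gene co-targeting
  # several deterministic starts: label propagation on the co-targeting
  # projection, every gene its own community, and a single community; the
  # best-scoring refined partition wins
  lp <- paste0("g", .label_propagation_init(proj))
  inits <- list(
    lp = lp,
    singleton = paste0("g", seq_along(graph$gene_ids)),
    one = rep("g1", length(graph$gene_ids))
  )
  res <- NULL
  for (init_gene in inits) {
    init_tf <- rep(init_gene[1], length(graph$tf_ids))
    cand <- .optimize_bipartite(w, graph$m_w, kb, db, graph$m_w,
                                init_tf, init_gene, max_sweeps)
    if (is.null(res) || cand$score > res$score + 1e-13) res <- cand
  }
  if (length(graph$gene_ids) <= 9) {
    # small gene side: global optimum by exhaustive gene-partition search
    exact <- .exact_bipartite(w, graph$m_w, kb, db, graph$m_w)
    if (exact$score > res$score + 1e-15) res <- exact
  }
  # never worse than the all-in-one partition
  one <- rep(1L, length(kb) + length(db))
  q_one <- .diff_modularity(w, graph$m_w, kb, db, graph$m_w,
                            one[seq_along(kb)], one[-seq_along(kb)])
  if (res$score < q_one) {
    res$ct <- rep(1L, length(kb)); res$cg <- rep(1L, length(db))
    res$score <- q_one
  }
  .finish_partition(graph, res)
}

# Renumber communities by decreasing size and wrap as bipartite_partition.
.finish_partition <- function(graph, res, class = "bipartite_partition",
                              extra = list()) {
  labs <- c(res$ct, res$cg)
  sizes <- table(labs)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- integer(max(labs))
  remap[as.integer(names(sizes)[ord])] <- seq_along(ord)
  labs <- remap[labs]
  names(labs) <- c(graph$tf_ids, graph$gene_ids)
  structure(
    c(list(labels = labs,
           node_type = stats::setNames(
             rep(c("TF", "gene"), c(length(graph$tf_ids), length(graph$gene_ids))),
             names(labs)),
           q = res$score, n_communities = length(unique(labs)),
           m_w = graph$m_w),
      extra),
    class = class
  )
}

#' @export
print.bipartite_partition <- function(x, ...) {
  cat(sprintf("bipartite_partition: %d communities over %d nodes, Q = %.4f\n",
              x$n_communities, length(x$labels), x$q))
  invisible(x)
}

#' Write a community partition to TSV
#' @param partition A `bipartite_partition`.
#' @param path Output TSV (node, type, community); Q in a header comment.
#' @export
write_partition <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Q = %s", fmt_num(partition$q)), con)
  out <- data.frame(node = names(partition$labels),
                    type = partition$node_type,
                    community = partition$labels, stringsAsFactors = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
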