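# Gene-set enrichment of modules: hypergeometric over-representation analysis
# and a permutation test (MSET-style) drawing random same-size gene sets from
# the background. Fold enrichment is observed overlap over the analytic
# expectation; p-values are BH-adjusted within each (method, collection)
# family.

# Normalize a module specification to a named list of gene-id vectors.
.as_module_sets <- function(modules) {
  if (inherits(modules, "module_assignment")) {
    labs <- modules$labels[modules$labels != "unassigned"]
    return(split(names(labs), labs))
  }
  if (inherits(modules, "diff_modules")) {
    genes <- names(modules$labels)[modules$node_type == "gene"]
    return(split(genes, modules$labels[genes]))
  }
  if (is.list(modules)) return(modules)
  stopf("unsupported module specification")
}

.as_collection <- function(collection) {
  if (inherits(collection, "gene_sets")) {
    return(lapply(unclass(collection), `[[`, "members"))
  }
  collection
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each (module, gene set) overlap against
#' the background universe. Sets are intersected with the background first;
#' sets below `min_set` genes (after intersection) are dropped. BH adjustment
#' runs across all tested pairs of the collection.
#'
#' @param modules Module gene sets: a [detect_modules()] result, a
#'   `diff_modules` result (its gene members), or a named list.
#' @param collection A `gene_sets` collection or named list of gene-id
#'   vectors.
#' @param background Character vector: the gene universe (must contain all
#'   module genes).
#' @param min_set Minimum (background-intersected) set size to test. The
#'   conventional defaults are 10 for co-expression modules and 6 (i.e.
#'   strictly more than 5 genes) for differential modules.
#' @param alpha Significance threshold applied to the BH-adjusted p.
#' @return Data frame of class `enrichment_result`: one row per tested pair
#'   with counts, `fold_enrichment`, `p`, `p_adj`, `significant`, `method`.
#' @export
ora <- function(modules, collection, background, min_set = 10, alpha = 0.0005) {
  mods <- .as_module_sets(modules)
  sets <- .as_collection(collection)
  background <- unique(background)
  if (!length(background)) stopf("empty background")
  stray <- setdiff(unique(unlist(mods)), background)
  if (length(stray)) {
    stopf("module gene(s) missing from background: %s",
          paste(utils::head(stray, 3), collapse = ", "))
  }
  n_bg <- length(background)

  rows <- list()
  for (set_name in names(sets)) {
    members <- intersect(unique(sets[[set_name]]), background)
    if (length(members) < min_set) {
      if (!length(members)) {
        message(sprintf("gene set %s disjoint from background: dropped", set_name))
      }
      next
    }
    for (mod in names(mods)) {
      mg <- intersect(unique(mods[[mod]]), background)
      o <- length(intersect(mg, members))
      expected <- length(mg) * length(members) / n_bg
      p <- stats::phyper(o - 1, length(members), n_bg - length(members),
                         length(mg), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, gene_set = set_name,
        n_module = length(mg), n_set = length(members), n_background = n_bg,
        overlap = o,
        fold_enrichment = if (expected > 0) o / expected else NA_real_,
        p = p, stringsAsFactors = FALSE
      )
    }
  }
  .finish_enrichment(rows, method = "ora", alpha = alpha)
}

#' Permutation (MSET-style) gene-set enrichment
#'
#' Compares the observed overlap between a module and a target set against
#' `n_perm` random draws of the same module size from the background, without
#' replacement. The empirical p carries a +1 pseudocount so it is never zero;
#' fold enrichment uses the analytic expectation
#' `n_module * n_set / n_background`.
#'
#' @param module_genes Character vector of module genes (subset of
#'   `background`).
#' @param target_set Character vector of target genes (intersected with the
#'   background).
#' @param background Character vector: the gene universe (e.g. all network
#'   genes).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return One-row data frame with counts, `fold_enrichment`, empirical `p`,
#'   `method = "mset"`.
#' @export
mset <- function(module_genes, target_set, background, n_perm = 10000,
                 seed = 1) {
  background <- unique(background)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% background)) {
    stopf("module genes must be contained in the background")
  }
  if (length(module_genes) > length(background)) {
    stopf("module larger than background")
  }
  target <- intersect(unique(target_set), background)
  n_bg <- length(background)
  n_mod <- length(module_genes)
  n_set <- length(target)
  o <- length(intersect(module_genes, target))

  in_target <- background %in% target
  perm_ge <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      sum(in_target[sample.int(n_bg, n_mod)]) >= o
    }, numeric(1)))
  })
  p <- (1 + perm_ge) / (1 + n_perm)
  expected <- n_mod * n_set / n_bg
  data.frame(
    module = NA_character_, gene_set = NA_character_,
    n_module = n_mod, n_set = n_set, n_background = n_bg, overlap = o,
    fold_enrichment = if (expected > 0) o / expected else NA_real_,
    p = p, method = "mset", n_perm = n_perm, stringsAsFactors = FALSE
  )
}

#' MSET enrichment of every module against every set of a collection
#'
#' Runs [mset()] per (module, gene set) pair and BH-adjusts the empirical
#' p-values across the collection.
#'
#' @inheritParams ora
#' @param n_perm,seed Passed to [mset()]; each pair uses a seed derived from
#'   `seed` so results do not depend on iteration order.
#' @param min_set Minimum background-intersected set size to test.
#' @return `enrichment_result` data frame.
#' @export
mset_collection <- function(modules, collection, background, n_perm = 10000,
                            seed = 1, min_set = 1, alpha = 0.05) {
  mods <- .as_module_sets(modules)
  sets <- .as_collection(collection)
  background <- unique(background)
  rows <- list()
  i <- 0L
  for (set_name in names(sets)) {
    members <- intersect(unique(sets[[set_name]]), background)
    if (length(members) < min_set) next
    for (mod in names(mods)) {
      i <- i + 1L
      r <- mset(intersect(unique(mods[[mod]]), background), members,
                background, n_perm = n_perm, seed = derive_seed(seed, i))
      r$module <- mod
      r$gene_set <- set_name
      rows[[length(rows) + 1]] <- r
    }
  }
  .finish_enrichment(rows, method = "mset", alpha = alpha)
}

.finish_enrichment <- function(rows, method, alpha) {
  out <- if (length(rows)) {
    out <- do.call(rbind, rows)
    out$method <- method
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj < alpha
    out
  } else {
    data.frame(module = character(0), gene_set = character(0),
               n_module = integer(0), n_set = integer(0),
               n_background = integer(0), overlap = integer(0),
               fold_enrichment = numeric(0), p = numeric(0),
               method = character(0), p_adj = numeric(0),
               significant = logical(0))
  }
  structure(out, class = c("enrichment_result", "data.frame"), alpha = alpha)
}
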