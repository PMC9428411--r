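# End-to-end orchestration: preprocess -> co-expression modules -> module
# activity -> per-sex network inference -> per-sex communities ->
# dual-baseline differential modularity -> drivers -> enrichment, with a
# machine-readable run summary. Stages derive their seeds from one master
# seed, so a rerun with the same inputs and seed is byte-identical.

#' Run the full differential regulatory network pipeline
#'
#' @param expression An [expression_matrix()] (raw; preprocessing is applied
#'   here).
#' @param motif Bipartite motif prior `edge_list`.
#' @param ppi Unipartite TF-TF `edge_list`.
#' @param gene_sets Optional `gene_sets` collection for enrichment of the
#'   differential modules.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param variance_threshold,outlier_cut_sd Preprocessing parameters.
#' @param beta Soft-threshold power. The default 6 is the conventional power
#'   for unsigned networks; set `NULL` to select the smallest power reaching
#'   a scale-free fit (appropriate when the data's degree spectrum is
#'   hub-like).
#' @param min_module_size Minimum co-expression module size.
#' @param nes_cut,n_perm_activity Module-activity parameters.
#' @param alpha,tol,max_iter Network-inference parameters.
#' @param k_tf,k_gene Driver-extraction IQR multipliers.
#' @param n_perm_mset Permutations for the MSET stage.
#' @param run_coexpression,run_activity,run_enrichment Stage toggles.
#' @param outdir Optional directory; when given, every stage's tables plus a
#'   JSON run summary are written there.
#' @return List of class `diffgrn_run` with each stage's results and the
#'   `summary` list.
#' @export
run_pipeline <- function(expression, motif, ppi, gene_sets = NULL,
                         seed = 1,
                         variance_threshold = 0.1, outlier_cut_sd = 3,
                         beta = 6, min_module_size = 30,
                         nes_cut = 2, n_perm_activity = 1000,
                         alpha = 0.1, tol = 1e-3, max_iter = 200,
                         k_tf = 1.5, k_gene = 3, n_perm_mset = 10000,
                         run_coexpression = TRUE, run_activity = TRUE,
                         run_enrichment = !is.null(gene_sets),
                         outdir = NULL) {
  t0 <- Sys.time()
  params <- list(
    seed = seed, variance_threshold = variance_threshold,
    outlier_cut_sd = outlier_cut_sd, beta = beta,
    min_module_size = min_module_size, nes_cut = nes_cut,
    n_perm_activity = n_perm_activity, alpha = alpha, tol = tol,
    max_iter = max_iter, k_tf = k_tf, k_gene = k_gene,
    n_perm_mset = n_perm_mset, run_coexpression = run_coexpression,
    run_activity = run_activity, run_enrichment = run_enrichment
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  pre <- stage("preprocess", preprocess_expression(
    expression, variance_threshold = variance_threshold,
    outlier_cut_sd = outlier_cut_sd))
  x <- pre$expression

  net <- modules <- activity <- NULL
  if (run_coexpression) {
    net <- stage("coexpression", coexpression_network(x, beta = beta))
    modules <- stage("coexpression", detect_modules(net, min_size = min_module_size))
    if (run_activity) {
      ranking <- stage("module_activity", class_rank_statistic(x))
      activity <- stage("module_activity", gsea_module_activity(
        ranking, modules, n_perm = n_perm_activity,
        seed = derive_seed(seed, 2L), nes_cut = nes_cut))
    }
  }

  motif_f <- stage("grn_inference",
                   filter_canonical(motif, rownames(x$values)))
  sex <- x$sample_meta$sex
  nets <- stage("grn_inference", list(
    male = infer_network(motif_f, ppi, subset_expr(x, samples = which(sex == "male")),
                         alpha = alpha, tol = tol, max_iter = max_iter,
                         condition = "male"),
    female = infer_network(motif_f, ppi, subset_expr(x, samples = which(sex == "female")),
                           alpha = alpha, tol = tol, max_iter = max_iter,
                           condition = "female")
  ))

  graphs <- stage("bipartite_communities", list(
    male = positive_projection(nets$male),
    female = positive_projection(nets$female)
  ))
  partitions <- stage("bipartite_communities", list(
    male = maximize_modularity(graphs$male),
    female = maximize_modularity(graphs$female)
  ))

  diff <- stage("differential_modularity",
                run_dual_baseline(nets$male, nets$female))
  drivers <- stage("drivers", list(
    male_biased = extract_drivers(diff$female_baseline, k_tf = k_tf, k_gene = k_gene),
    female_biased = extract_drivers(diff$male_baseline, k_tf = k_tf, k_gene = k_gene)
  ))
  shared <- shared_top_tfs(drivers$male_biased, drivers$female_biased)

  enrichment <- NULL
  if (run_enrichment && !is.null(gene_sets)) {
    background <- rownames(x$values)
    enrichment <- stage("enrichment", list(
      male_biased = mset_collection(diff$female_baseline, gene_sets, background,
                                    n_perm = n_perm_mset,
                                    seed = derive_seed(seed, 3L), alpha = 0.05),
      female_biased = mset_collection(diff$male_baseline, gene_sets, background,
                                      n_perm = n_perm_mset,
                                      seed = derive_seed(seed, 4L), alpha = 0.05)
    ))
  }

  summary <- list(
    params = params,
    preprocess = list(
      n_genes_in = pre$report$n_genes_in, n_genes_out = pre$report$n_genes_out,
      n_samples_in = pre$report$n_samples_in,
      n_samples_out = pre$report$n_samples_out,
      removed_outliers = pre$report$removed_outliers
    ),
    coexpression = if (!is.null(net)) {
      list(beta = net$beta, r2 = net$r2,
           n_modules = length(modules$sizes),
           n_unassigned = sum(modules$labels == "unassigned"))
    },
    networks = lapply(nets, function(n) {
      list(condition = n$condition, n_tfs = length(n$tf_ids),
           n_genes = length(n$gene_ids), n_iterations = n$n_iterations,
           converged = n$converged)
    }),
    communities = lapply(partitions, function(p) {
      list(n_communities = p$n_communities, q = p$q)
    }),
    differential = lapply(diff, function(d) {
      list(baseline = d$baseline, bias = d$bias,
           n_modules = d$n_modules, d_total = d$d_total)
    }),
    n_shared_top_tfs = length(shared),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  run <- structure(
    list(preprocess = pre, coexpression = net, modules = modules,
         activity = activity, networks = nets, partitions = partitions,
         differential = diff, drivers = drivers, shared_top_tfs = shared,
         enrichment = enrichment, summary = summary),
    class = "diffgrn_run"
  )
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.diffgrn_run <- function(x, ...) {
  s <- x$summary
  cat("diffgrn_run\n")
  cat(sprintf("  preprocess: %d -> %d genes, %d -> %d samples\n",
              s$preprocess$n_genes_in, s$preprocess$n_genes_out,
              s$preprocess$n_samples_in, s$preprocess$n_samples_out))
  if (!is.null(s$coexpression)) {
    cat(sprintf("  coexpression: %d modules (beta %d)\n",
                s$coexpression$n_modules, s$coexpression$beta))
  }
  cat(sprintf("  differential: %d male-biased / %d female-biased modules, %d shared top TFs\n",
              s$differential$female_baseline$n_modules,
              s$differential$male_baseline$n_modules, s$n_shared_top_tfs))
  invisible(x)
}

#' Write every stage of a pipeline run to a directory
#'
#' @param run A `diffgrn_run`.
#' @param outdir Output directory (created if needed). Tables are TSV; the
#'   run summary is JSON.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_expression(run$preprocess$expression, p("expression_preprocessed.tsv"),
                   p("sample_meta.tsv"))
  if (!is.null(run$modules)) {
    utils::write.table(
      data.frame(gene = names(run$modules$labels),
                 module = run$modules$labels, stringsAsFactors = FALSE),
      p("coexpression_modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  if (!is.null(run$activity)) {
    act <- as.data.frame(run$activity)
    act$es <- fmt_num(act$es); act$nes <- fmt_num(act$nes)
    act$perm_p <- fmt_num(act$perm_p)
    utils::write.table(act, p("module_activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (cond in names(run$networks)) {
    write_grn(run$networks[[cond]], p(sprintf("grn_%s.tsv", cond)))
    write_partition(run$partitions[[cond]], p(sprintf("communities_%s.tsv", cond)))
  }
  write_drivers(run$drivers$male_biased, p("drivers_male_biased.tsv"))
  write_drivers(run$drivers$female_biased, p("drivers_female_biased.tsv"))
  writeLines(run$shared_top_tfs, p("shared_top_tfs.txt"))
  if (!is.null(run$enrichment)) {
    for (dir in names(run$enrichment)) {
      e <- as.data.frame(run$enrichment[[dir]])
      e$fold_enrichment <- fmt_num(e$fold_enrichment)
      e$p <- fmt_num(e$p); e$p_adj <- fmt_num(e$p_adj)
      utils::write.table(e, p(sprintf("enrichment_%s.tsv", dir)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(run$summary, p("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(outdir)
}
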