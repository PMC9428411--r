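# Synthetic-data generator. Emulates the statistical structure the analysis
# assumes: two sample classes of unequal size, batch structure, a gene
# variance spectrum including sub-0.1-variance genes, planted correlated gene
# blocks, a sparse bipartite motif prior with TF-gene communities, TF-TF PPI
# homophily, and sex-specific regulatory rewiring inside one community. The
# ground truth it returns is sufficient to score every downstream stage
# (module recovery, driver recall, enrichment hits) without re-deriving
# structure.

#' Simulation configuration
#'
#' All knobs of the synthetic generators, validated once. Expression is
#' simulated on a log-like (variance-stabilized) scale, so noise is Gaussian
#' and per-gene variances are ~1 for informative genes.
#'
#' @param n_genes,n_tfs Number of genes / transcription factors.
#' @param n_samples_male,n_samples_female Class sizes (defaults mirror a
#'   70/50 male/female cohort scaled to desk size).
#' @param n_modules Number of planted modules (co-expression blocks, and
#'   equally TF-gene communities in the regulatory prior).
#' @param module_sizes Integer vector of genes per module; must sum to at
#'   most `n_genes`.
#' @param tfs_per_community Integer vector of TFs per community (summing to
#'   `n_tfs`); `NULL` splits TFs evenly. The default makes the rewired
#'   community TF-poor and the destination community TF-rich, so planted
#'   drivers are a minority of their differential module's TFs -- the regime
#'   in which an IQR-based driver rule is meaningful.
#' @param within_module_corr Target mean pairwise correlation inside a
#'   planted module, in `[0, 1)`.
#' @param activity_shift Mean expression shift (in per-gene SD units) applied
#'   to sex-active modules in the designated sex.
#' @param sex_active_modules Indices of modules receiving the activity shift.
#' @param sex_active_sex Sex in which those modules are shifted up.
#' @param n_batches,batch_sd Number of batches and SD of the additive
#'   per-gene, per-batch offsets.
#' @param frac_low_variance Fraction of all genes forced to total variance
#'   below 0.1 (drawn from the unstructured background genes).
#' @param rewired_fraction Fraction of the rewired community's prior TF-gene
#'   edges whose targets are swapped to the destination community in the
#'   rewired sex's truth network.
#' @param rewired_in_prior If `TRUE` (default) the swapped-in edges are part
#'   of the motif prior: the motif map is sequence-based and sex-agnostic, so
#'   binding sites used by only one sex still appear in it.
#' @param rewired_community,rewire_destination Community whose edges are
#'   rewired and the community receiving the swapped targets.
#' @param rewired_sex Sex whose truth network carries the rewiring.
#' @param motif_within,motif_between,motif_background Edge probabilities of
#'   the bipartite motif prior: TF-gene pairs within a community, across
#'   communities, and from any TF to background genes.
#' @param ppi_within,ppi_between TF-TF PPI edge probabilities for pairs
#'   sharing / not sharing a community.
#' @param tf_coherence Fraction (in `(0, 1]`) of each TF's activity variance
#'   carried by its community factor; the rest is TF-specific. Low values
#'   make genes respond to their *individual* regulators, which is what lets
#'   sex-specific rewiring reshape the co-expression structure; high values
#'   make communities behave as single blocks and wash out per-TF signal.
#' @param add_outlier If `TRUE`, the last sample gets a global shift of
#'   `outlier_shift` SD on every gene.
#' @param outlier_shift Size of the planted outlier shift, in SD units.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 600L, n_tfs = 40L,
                       n_samples_male = 40L, n_samples_female = 30L,
                       n_modules = 4L,
                       module_sizes = if (n_modules == 4L) {
                         c(120L, 80L, 110L, 110L)
                       } else {
                         rep(floor(0.7 * n_genes / n_modules), n_modules)
                       },
                       tfs_per_community = NULL,
                       within_module_corr = 0.75,
                       activity_shift = 1.0,
                       sex_active_modules = 1L, sex_active_sex = "female",
                       n_batches = 2L, batch_sd = 0.3,
                       frac_low_variance = 0.25,
                       rewired_fraction = 0.5, rewired_in_prior = TRUE,
                       rewired_community = 1L, rewire_destination = 2L,
                       rewired_sex = "male",
                       motif_within = 0.6, motif_between = 0.02,
                       motif_background = 0.02,
                       ppi_within = 0.5, ppi_between = 0.05,
                       tf_coherence = 0.35,
                       add_outlier = FALSE, outlier_shift = 8,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
    n_samples_male = as.integer(n_samples_male),
    n_samples_female = as.integer(n_samples_female),
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    tfs_per_community = if (!is.null(tfs_per_community)) {
      as.integer(tfs_per_community)
    } else if (n_modules == 4L && n_tfs == 40L) {
      c(5L, 5L, 15L, 15L)
    } else {
      tabulate(sort(rep_len(seq_len(as.integer(n_modules)), as.integer(n_tfs))),
               nbins = as.integer(n_modules))
    },
    within_module_corr = within_module_corr,
    activity_shift = activity_shift,
    sex_active_modules = as.integer(sex_active_modules),
    sex_active_sex = match.arg(sex_active_sex, c("male", "female")),
    n_batches = as.integer(n_batches), batch_sd = batch_sd,
    frac_low_variance = frac_low_variance,
    rewired_fraction = rewired_fraction,
    rewired_in_prior = isTRUE(rewired_in_prior),
    rewired_community = as.integer(rewired_community),
    rewire_destination = as.integer(rewire_destination),
    rewired_sex = match.arg(rewired_sex, c("male", "female")),
    motif_within = motif_within, motif_between = motif_between,
    motif_background = motif_background,
    ppi_within = ppi_within, ppi_between = ppi_between,
    tf_coherence = tf_coherence,
    add_outlier = isTRUE(add_outlier), outlier_shift = outlier_shift,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_genes < 1 || n_tfs < 1) stopf("need positive n_genes and n_tfs")
    if (n_samples_male < 1 || n_samples_female < 1) {
      stopf("both sample classes must be non-empty")
    }
    if (length(module_sizes) != n_modules) {
      stopf("module_sizes must have n_modules entries")
    }
    if (sum(module_sizes) > n_genes) {
      stopf("sum(module_sizes) exceeds n_genes")
    }
    if (length(tfs_per_community) != n_modules ||
        sum(tfs_per_community) != n_tfs || any(tfs_per_community < 1)) {
      stopf("tfs_per_community must be %d positive counts summing to n_tfs",
            n_modules)
    }
    if (within_module_corr < 0 || within_module_corr >= 1) {
      stopf("within_module_corr must be in [0, 1): %g is infeasible",
            within_module_corr)
    }
    if (frac_low_variance < 0 || frac_low_variance >= 1) {
      stopf("frac_low_variance must be in [0, 1)")
    }
    if (rewired_fraction < 0 || rewired_fraction > 1) {
      stopf("rewired_fraction must be in [0, 1]")
    }
    for (p in c(motif_within, motif_between, motif_background,
                ppi_within, ppi_between)) {
      if (p < 0 || p > 1) stopf("edge probabilities must be in [0, 1]")
    }
    if (rewired_community > n_modules || rewire_destination > n_modules) {
      stopf("rewired_community / rewire_destination out of range")
    }
    if (n_modules > 1 && rewired_community == rewire_destination) {
      stopf("rewire_destination must differ from rewired_community")
    }
    if (tf_coherence <= 0 || tf_coherence > 1) {
      stopf("tf_coherence must be in (0, 1]")
    }
    if (n_batches < 1) stopf("need at least one batch")
  })
  structure(cfg, class = "sim_config")
}

# Shared sample layout: ids, sex, batch (balanced within sex), age.
.sim_samples <- function(cfg) {
  n <- cfg$n_samples_male + cfg$n_samples_female
  sex <- c(rep("male", cfg$n_samples_male), rep("female", cfg$n_samples_female))
  ids <- c(sprintf("M%03d", seq_len(cfg$n_samples_male)),
           sprintf("F%03d", seq_len(cfg$n_samples_female)))
  batch <- unlist(lapply(c(cfg$n_samples_male, cfg$n_samples_female),
                         function(k) {
                           rep_len(paste0("B", seq_len(cfg$n_batches)), k)
                         }))
  data.frame(sample_id = ids, sex = sex, batch = batch,
             age_pcw = round(stats::runif(n, 12, 19), 2),
             stringsAsFactors = FALSE)
}

.gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))
.tf_ids <- function(cfg) sprintf("TF%03d", seq_len(cfg$n_tfs))

# Gene -> planted module (0 = background); modules occupy leading genes.
.gene_modules <- function(cfg) {
  mod <- integer(cfg$n_genes)
  at <- 1L
  for (m in seq_len(cfg$n_modules)) {
    mod[at:(at + cfg$module_sizes[m] - 1L)] <- m
    at <- at + cfg$module_sizes[m]
  }
  names(mod) <- .gene_ids(cfg)
  mod
}

# Assemble the expression matrix from a per-sample signal matrix (genes x
# samples, already standardized per gene) shared by both generators: mixes
# signal and noise to hit the correlation target, applies sex-activity
# shifts, low-variance scaling, batch offsets and the optional outlier.
.assemble_expression <- function(cfg, samples, signal, modules) {
  n_g <- cfg$n_genes
  n_s <- nrow(samples)
  rho <- cfg$within_module_corr
  noise <- matrix(stats::rnorm(n_g * n_s), n_g, n_s)
  has_signal <- rowSums(signal != 0) > 0
  x <- sqrt(rho) * signal + sqrt(1 - rho) * noise
  x[!has_signal, ] <- noise[!has_signal, ]

  # sub-0.1-variance genes come from the unstructured background
  background <- which(modules == 0 & !has_signal)
  n_low <- round(cfg$frac_low_variance * n_g)
  if (n_low > length(background)) {
    stopf("frac_low_variance requires %d background genes; only %d available",
          n_low, length(background))
  }
  low_idx <- background[seq_len(n_low)]
  scale_g <- rep(1, n_g)
  if (n_low > 0) scale_g[low_idx] <- stats::runif(n_low, 0.10, 0.25)
  x <- x * scale_g

  # sex-activity shift, in per-gene SD units
  active_cols <- samples$sex == cfg$sex_active_sex
  for (m in cfg$sex_active_modules) {
    rows <- modules == m
    x[rows, active_cols] <- x[rows, active_cols] +
      cfg$activity_shift * scale_g[rows]
  }

  # additive per-gene, per-batch offsets (scaled so low-variance genes stay low)
  if (cfg$n_batches > 1 && cfg$batch_sd > 0) {
    offsets <- matrix(stats::rnorm(n_g * cfg$n_batches, sd = cfg$batch_sd),
                      n_g, cfg$n_batches)
    bidx <- match(samples$batch, paste0("B", seq_len(cfg$n_batches)))
    x <- x + offsets[, bidx] * scale_g
  }

  outlier <- NULL
  if (cfg$add_outlier) {
    x[, n_s] <- x[, n_s] + cfg$outlier_shift * scale_g
    outlier <- samples$sample_id[n_s]
  }

  rownames(x) <- .gene_ids(cfg)
  colnames(x) <- samples$sample_id
  gm <- data.frame(gene_id = rownames(x),
                   chromosome = as.character(rep_len(1:22, n_g)),
                   stringsAsFactors = FALSE)
  list(
    expression = expression_matrix(x, samples, gm),
    low_variance = rownames(x)[low_idx],
    outlier_sample = outlier
  )
}

#' Simulate an expression matrix with planted co-expression modules
#'
#' Latent-factor model: each planted module has one standard-normal factor
#' per sample, and its genes load on it so the mean within-module pairwise
#' correlation is approximately `within_module_corr`. Sex-active modules are
#' shifted by `activity_shift` SD in the designated sex; batch offsets are
#' additive Gaussian; a fraction of background genes is scaled below 0.1
#' total variance.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (an [expression_matrix()]) and `truth`
#'   (planted module map, sex-active modules, low-variance genes, outlier).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    samples <- .sim_samples(config)
    modules <- .gene_modules(config)
    n_s <- nrow(samples)
    factors <- matrix(stats::rnorm(config$n_modules * n_s),
                      config$n_modules, n_s)
    signal <- matrix(0, config$n_genes, n_s)
    for (m in seq_len(config$n_modules)) {
      signal[modules == m, ] <- matrix(rep(factors[m, ], sum(modules == m)),
                                       ncol = n_s, byrow = TRUE)
    }
    parts <- .assemble_expression(config, samples, signal, modules)
    list(
      expression = parts$expression,
      truth = list(
        module = modules,
        sex_active = data.frame(module = config$sex_active_modules,
                                sex = config$sex_active_sex,
                                shift = config$activity_shift),
        low_variance = parts$low_variance,
        outlier_sample = parts$outlier_sample
      )
    )
  })
}

#' Simulate a motif prior, PPI network and sex-specific truth networks
#'
#' The motif prior is a bipartite TF-gene graph with planted communities
#' (dense within, sparse between). The PPI connects TFs in the same community
#' with higher probability. The per-sex truth networks are the within-
#' community edges, except that in the rewired sex a fraction of the rewired
#' community's edges have their targets swapped to genes of the destination
#' community -- a coordinated regulatory program shift that defines which
#' correlations each sex's expression carries.
#'
#' @param config A [sim_config()].
#' @return List with `motif` and `ppi` (both [edge_list()]) and `truth`
#'   (per-sex truth edge data frames, community maps, rewired edges, planted
#'   driver TFs and the perturbed community's node membership).
#' @export
simulate_regulatory_prior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .sim_prior_impl(config))
}

.sim_prior_impl <- function(cfg) {
  tfs <- .tf_ids(cfg)
  genes <- .gene_ids(cfg)
  gene_comm <- .gene_modules(cfg)
  tf_comm <- rep(seq_len(cfg$n_modules), cfg$tfs_per_community)
  names(tf_comm) <- tfs

  # Bernoulli bipartite prior with community-dependent rates
  p <- matrix(cfg$motif_between, cfg$n_tfs, cfg$n_genes,
              dimnames = list(tfs, genes))
  p[, gene_comm == 0] <- cfg$motif_background
  for (c in seq_len(cfg$n_modules)) {
    p[tf_comm == c, gene_comm == c] <- cfg$motif_within
  }
  draw <- matrix(stats::runif(length(p)), nrow(p), ncol(p)) < p
  idx <- which(draw, arr.ind = TRUE)
  motif <- edge_list(data.frame(source = tfs[idx[, 1]],
                                target = genes[idx[, 2]], weight = 1,
                                stringsAsFactors = FALSE),
                     mode = "bipartite_tf_gene")

  # truth networks: within-community edges only
  within <- idx[tf_comm[idx[, 1]] == gene_comm[idx[, 2]] &
                  gene_comm[idx[, 2]] != 0, , drop = FALSE]
  base <- data.frame(tf = tfs[within[, 1]], gene = genes[within[, 2]],
                     stringsAsFactors = FALSE)

  rc <- cfg$rewired_community
  in_rc <- tf_comm[base$tf] == rc & gene_comm[base$gene] == rc
  e_rc <- which(in_rc)
  k <- floor(cfg$rewired_fraction * length(e_rc))
  rewired <- base
  swap <- integer(0)
  if (k > 0) {
    swap <- sort(sample(e_rc, k))
    dest_genes <- sample(genes[gene_comm == cfg$rewire_destination])
    if (!length(dest_genes)) stopf("destination community has no genes")
    # Concentrated retargeting: the r-th swapped edge of each rewired TF goes
    # to the r-th destination gene, so each receiving gene gains one edge
    # from (almost) every rewired TF -- a coordinated dual-regulation program
    # rather than diffuse noise. This is what makes the rewiring visible in
    # the perturbed sex's co-expression.
    existing <- paste(rewired$tf, rewired$gene)
    rank_in_tf <- stats::ave(seq_along(swap), rewired$tf[swap],
                             FUN = seq_along)
    if (max(rank_in_tf) > length(dest_genes)) {
      stopf("rewired_fraction too high: %d swapped edges per TF exceed the %d destination genes",
            max(rank_in_tf), length(dest_genes))
    }
    new_targets <- dest_genes[rank_in_tf]
    clash <- paste(rewired$tf[swap], new_targets) %in% existing
    for (i in which(clash)) {
      free <- dest_genes[!(paste(rewired$tf[swap[i]], dest_genes) %in% existing)]
      if (!length(free)) {
        stopf("rewired_fraction too high: no free targets left for %s",
              rewired$tf[swap[i]])
      }
      new_targets[i] <- free[1]
      existing <- c(existing, paste(rewired$tf[swap[i]], new_targets[i]))
    }
    rewired$gene[swap] <- new_targets
  }
  if (cfg$rewired_sex == "male") {
    truth_male <- rewired; truth_female <- base
  } else {
    truth_male <- base; truth_female <- rewired
  }

  # The motif map is sequence-based and sex-agnostic: it contains the binding
  # sites of BOTH sexes' realized networks. Rewiring changes which prior
  # edges are used per sex, not which sites exist, so the swapped-in edges
  # are appended to the prior (the swapped-out ones are already there).
  if (k > 0 && isTRUE(cfg$rewired_in_prior)) {
    new_edges <- data.frame(source = rewired$tf[swap],
                            target = rewired$gene[swap], weight = 1,
                            stringsAsFactors = FALSE)
    have <- paste(motif$source, motif$target)
    new_edges <- new_edges[!(paste(new_edges$source, new_edges$target) %in% have), ]
    if (nrow(new_edges)) {
      motif <- edge_list(rbind(as.data.frame(motif), new_edges),
                         mode = "bipartite_tf_gene")
    }
  }

  # PPI with community homophily (unordered TF pairs)
  pairs <- which(upper.tri(matrix(0, cfg$n_tfs, cfg$n_tfs)), arr.ind = TRUE)
  same <- tf_comm[pairs[, 1]] == tf_comm[pairs[, 2]]
  keep <- stats::runif(nrow(pairs)) <
    ifelse(same, cfg$ppi_within, cfg$ppi_between)
  ppi <- edge_list(data.frame(source = tfs[pairs[keep, 1]],
                              target = tfs[pairs[keep, 2]], weight = 1,
                              stringsAsFactors = FALSE),
                   mode = "unipartite_ppi")

  driver_tfs <- sort(unique(base$tf[swap]))
  perturbed <- if (cfg$rewired_sex == "male") truth_male else truth_female
  rc_tfs <- tfs[tf_comm == rc]
  membership <- sort(unique(c(
    rc_tfs, perturbed$gene[perturbed$tf %in% rc_tfs]
  )))

  list(
    motif = motif, ppi = ppi,
    truth = list(
      tf_community = tf_comm, gene_community = gene_comm,
      truth_male = truth_male, truth_female = truth_female,
      rewired_edges = if (k > 0) {
        data.frame(tf = base$tf[swap], old_gene = base$gene[swap],
                   new_gene = rewired$gene[swap], stringsAsFactors = FALSE)
      } else {
        data.frame(tf = character(0), old_gene = character(0),
                   new_gene = character(0))
      },
      driver_tfs = driver_tfs,
      rewired_community = rc,
      rewire_destination = cfg$rewire_destination,
      rewired_sex = cfg$rewired_sex,
      perturbed_membership = membership
    )
  )
}

#' Simulate a full study: prior, PPI and truth-driven expression
#'
#' Generates the regulatory prior with [simulate_regulatory_prior()], then
#' simulates expression in which each gene responds to the mean activity of
#' its regulators *in the sample's sex-specific truth network*: TF activity
#' is its community factor plus idiosyncratic noise, so sex-specific rewiring
#' changes which genes co-respond between sexes. This is the end-to-end
#' fixture: planted communities are recoverable from the prior, rewired
#' structure from the per-sex expression, and planted drivers by
#' differential-modularity analysis.
#'
#' @param config A [sim_config()].
#' @return List of class `diffgrn_sim` with `expression`, `motif`, `ppi`,
#'   `truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prior <- simulate_regulatory_prior(config)
  with_seed(derive_seed(config$seed, 1L), {
    samples <- .sim_samples(config)
    n_s <- nrow(samples)
    genes <- .gene_ids(config)
    tfs <- .tf_ids(config)
    tf_comm <- prior$truth$tf_community
    gene_comm <- prior$truth$gene_community

    factors <- matrix(stats::rnorm(config$n_modules * n_s),
                      config$n_modules, n_s)
    coh <- config$tf_coherence
    activity <- sqrt(coh) * factors[tf_comm, , drop = FALSE] +
      sqrt(1 - coh) * matrix(stats::rnorm(config$n_tfs * n_s),
                             config$n_tfs, n_s)
    rownames(activity) <- tfs

    # mean regulator activity per gene, using the sample's sex truth network
    reg_signal <- function(truth, cols) {
      inc <- matrix(0, config$n_genes, config$n_tfs,
                    dimnames = list(genes, tfs))
      inc[cbind(truth$gene, truth$tf)] <- 1
      n_reg <- rowSums(inc)
      sig <- inc %*% activity[, cols, drop = FALSE]
      sig[n_reg > 0, ] <- sig[n_reg > 0, ] / n_reg[n_reg > 0]
      sig
    }
    signal <- matrix(0, config$n_genes, n_s)
    male_cols <- which(samples$sex == "male")
    female_cols <- which(samples$sex == "female")
    signal[, male_cols] <- reg_signal(prior$truth$truth_male, male_cols)
    signal[, female_cols] <- reg_signal(prior$truth$truth_female, female_cols)

    # standardize regulated genes' signal rows so the rho mixing applies
    regulated <- rowSums(signal != 0) > 0
    if (any(regulated)) {
      s <- signal[regulated, , drop = FALSE]
      mu <- rowMeans(s)
      sd <- sqrt(row_vars(s))
      sd[sd == 0] <- 1
      signal[regulated, ] <- (s - mu) / sd
    }

    parts <- .assemble_expression(config, samples, signal, gene_comm)
    structure(
      list(
        expression = parts$expression,
        motif = prior$motif,
        ppi = prior$ppi,
        truth = c(prior$truth, list(
          module = gene_comm,
          sex_active = data.frame(module = config$sex_active_modules,
                                  sex = config$sex_active_sex,
                                  shift = config$activity_shift),
          low_variance = parts$low_variance,
          outlier_sample = parts$outlier_sample
        ))
      ),
      class = "diffgrn_sim"
    )
  })
}

#' @export
print.diffgrn_sim <- function(x, ...) {
  cat(sprintf(
    "diffgrn_sim: %d genes x %d samples; %d TFs; motif %d edges; ppi %d edges\n",
    nrow(x$expression$values), ncol(x$expression$values),
    length(x$truth$tf_community), nrow(x$motif), nrow(x$ppi)
  ))
  cat(sprintf("  rewired community %d -> %d (%s truth), %d planted driver TFs\n",
              x$truth$rewired_community, x$truth$rewire_destination,
              x$truth$rewired_sex, length(x$truth$driver_tfs)))
  invisible(x)
}
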