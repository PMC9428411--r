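# Readers and writers for the pipeline's external formats: expression TSV with
# sample metadata, gene annotation TSV, edge-list TSV (bipartite TF-gene or
# unipartite PPI) and GMT gene-set collections. TSV is the canonical dialect:
# UTF-8, tab separated, '.' decimal. Numeric values are written with 15
# significant digits so write -> read round-trips are stable well beyond the
# 12 digits the pipeline guarantees.

#' Construct an expression matrix object
#'
#' Bundles a genes x samples numeric matrix with per-sample metadata (sex,
#' batch, age) and optional per-gene metadata (chromosome). This is the
#' container every pipeline stage consumes.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   row and column names. Expression is assumed to be on a log-like,
#'   variance-stabilized scale.
#' @param sample_meta Data frame with one row per sample. Must contain a
#'   `sex` column with values `"male"`/`"female"`; `batch` and `age_pcw`
#'   are carried along when present. Row names (or a `sample_id` column)
#'   must match the matrix column names.
#' @param gene_meta Optional data frame keyed by gene id (row names or a
#'   `gene_id` column) carrying a `chromosome` column.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `sample_meta`, `gene_meta`.
#' @export
expression_matrix <- function(values, sample_meta, gene_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stopf("duplicate gene id: '%s'", dup)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stopf("duplicate sample id: '%s'", dup)
  }
  if (!all(is.finite(values))) stopf("expression values must be finite")
  sample_meta <- .key_by(sample_meta, "sample_id")
  missing <- setdiff(colnames(values), rownames(sample_meta))
  if (length(missing)) {
    stopf("samples missing from metadata: %s", paste(missing, collapse = ", "))
  }
  sample_meta <- sample_meta[colnames(values), , drop = FALSE]
  if (!"sex" %in% names(sample_meta) || anyNA(sample_meta$sex)) {
    stopf("every sample needs a sex label in `sample_meta$sex`")
  }
  bad <- setdiff(unique(as.character(sample_meta$sex)), c("male", "female"))
  if (length(bad)) stopf("unknown sex label(s): %s", paste(bad, collapse = ", "))
  if (!is.null(gene_meta)) {
    gene_meta <- .key_by(gene_meta, "gene_id")
    gene_meta <- gene_meta[intersect(rownames(values), rownames(gene_meta)), ,
                           drop = FALSE]
  }
  structure(
    list(values = values, sample_meta = sample_meta, gene_meta = gene_meta),
    class = "expr_matrix"
  )
}

# Move an id column into row names if the frame is not already keyed.
.key_by <- function(df, id_col) {
  df <- as.data.frame(df)
  if (id_col %in% names(df)) {
    ids <- as.character(df[[id_col]])
    if (anyDuplicated(ids)) {
      stopf("duplicate %s: '%s'", id_col, ids[duplicated(ids)][1])
    }
    rownames(df) <- ids
    df[[id_col]] <- NULL
  }
  df
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "expr_matrix: %d genes x %d samples (%d male, %d female)\n",
    nrow(x$values), ncol(x$values),
    sum(x$sample_meta$sex == "male"), sum(x$sample_meta$sex == "female")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Subset an expr_matrix by gene and/or sample ids or indices.
subset_expr <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  gm <- x$gene_meta
  if (!is.null(gm)) gm <- gm[intersect(rownames(v), rownames(gm)), , drop = FALSE]
  expression_matrix(v, x$sample_meta[colnames(v), , drop = FALSE], gm)
}

#' Read an expression matrix and its sample metadata
#'
#' @param path TSV with a header of sample ids and gene ids in the first
#'   column.
#' @param meta_path TSV keyed by `sample_id` with at least a `sex` column.
#' @param gene_meta_path Optional TSV with columns `gene_id`, `chromosome`.
#' @return An [expression_matrix()] with file order preserved.
#' @export
read_expression <- function(path, meta_path, gene_meta_path = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = NA)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene id in '%s': '%s'", path,
          gene_ids[duplicated(gene_ids)][1])
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  gm <- NULL
  if (!is.null(gene_meta_path)) gm <- read_gene_annotation(gene_meta_path)
  expression_matrix(values, meta, gm)
}

#' Write an expression matrix (and its metadata) to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV for the matrix.
#' @param meta_path Optional output TSV for the sample metadata.
#' @export
write_expression <- function(x, path, meta_path = NULL) {
  vals <- x$values
  out <- data.frame(gene_id = rownames(vals), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(vals))) out[[colnames(vals)[j]]] <- fmt_num(vals[, j])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- cbind(sample_id = rownames(x$sample_meta), x$sample_meta)
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a gene chromosome annotation table
#'
#' @param path TSV with columns `gene_id` and `chromosome`.
#' @return Data frame keyed by gene id.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chromosome") %in% names(tab))) {
    stopf("'%s' must have columns gene_id and chromosome", path)
  }
  .key_by(tab, "gene_id")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, fields `name`, `description`, then members,
#' all tab separated. Duplicate members within a line are collapsed.
#'
#' @param path GMT file.
#' @return A named list of class `gene_sets`; each element has `description`
#'   and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("GMT line %d has %d field(s); need name, description and members",
            i, length(fields))
    }
    nm <- fields[1]
    if (nm %in% names(sets)) stopf("duplicate gene-set name '%s'", nm)
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stopf("GMT line %d ('%s') has no members", i, nm)
    sets[[nm]] <- list(description = fields[2], members = members)
  }
  structure(sets, class = "gene_sets")
}

#' Write a gene-set collection to GMT
#' @param sets A `gene_sets` list as returned by [read_gmt()].
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Union several gene sets into one merged set
#'
#' Explicit union operation for joined motif collections (e.g. merging all
#' estrogen-receptor motif target sets into a single `ER_TARGETS` set).
#'
#' @param sets A `gene_sets` collection.
#' @param names Names of the sets to merge.
#' @param new_name Name of the merged set.
#' @param description Description for the merged set.
#' @return A `gene_sets` collection containing the single merged set.
#' @export
gmt_union <- function(sets, names, new_name,
                      description = paste("union of", length(names), "sets")) {
  missing <- setdiff(names, base::names(sets))
  if (length(missing)) {
    stopf("gene set(s) not found: %s", paste(missing, collapse = ", "))
  }
  members <- unique(unlist(lapply(sets[names], `[[`, "members"),
                           use.names = FALSE))
  out <- list()
  out[[new_name]] <- list(description = description, members = members)
  structure(out, class = "gene_sets")
}

#' Read an edge-list TSV
#'
#' Two or three tab-separated columns: source, target and optional weight
#' (defaulting to 1). Duplicate source-target rows have their weights summed,
#' with a warning.
#'
#' @param path Edge-list TSV (with header `source`, `target`[, `weight`], or
#'   headerless).
#' @param mode `"bipartite_tf_gene"` (sources are TFs, targets genes; no
#'   self-loops allowed) or `"unipartite_ppi"`.
#' @return A data frame of class `edge_list` with columns `source`, `target`,
#'   `weight` and attribute `mode`.
#' @export
read_edge_list <- function(path, mode = c("bipartite_tf_gene", "unipartite_ppi")) {
  mode <- match.arg(mode)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^source\t", first)
  tab <- utils::read.delim(path, header = has_header, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2 || ncol(tab) > 3) {
    stopf("edge list '%s' must have 2 or 3 columns", path)
  }
  if (ncol(tab) == 2) tab[[3]] <- 1
  names(tab) <- c("source", "target", "weight")
  edge_list(tab, mode = mode)
}

#' Construct an edge list object
#'
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `weight` (default 1).
#' @param mode Edge-list mode; see [read_edge_list()].
#' @return A data frame of class `edge_list`.
#' @export
edge_list <- function(edges, mode = c("bipartite_tf_gene", "unipartite_ppi")) {
  mode <- match.arg(mode)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  edges <- edges[, c("source", "target", "weight")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  if (!all(is.finite(edges$weight))) stopf("edge weights must be finite")
  if (mode == "bipartite_tf_gene" && any(edges$source == edges$target)) {
    stopf("self-loop in bipartite edge list: '%s'",
          edges$source[edges$source == edges$target][1])
  }
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    w <- rowsum(edges$weight, key, reorder = FALSE)
    keep <- !duplicated(key)
    edges <- edges[keep, ]
    edges$weight <- as.numeric(w[match(key[keep], rownames(w)), 1])
    warnf("%d duplicate edge row(s): weights summed", n_dup)
  }
  rownames(edges) <- NULL
  structure(edges, class = c("edge_list", "data.frame"), mode = mode)
}

#' Write an edge list to TSV
#' @param edges An `edge_list`.
#' @param path Output file.
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(source = edges$source, target = edges$target,
                    weight = fmt_num(edges$weight), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
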