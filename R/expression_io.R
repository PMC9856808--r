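#' Construct and validate an expression matrix
#'
#' An `ExpressionMatrix` is a dense non-negative numeric matrix of abundance
#' values (FPKM/RSEM/RPM-like, unlogged) with unique gene identifiers as row
#' names and unique sample identifiers as column names.  All pipeline stages
#' take this container as input; validation happens at construction so
#' downstream code can rely on the invariants.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return a validated matrix of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required")
  }
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

validate_expression_matrix <- function(values) {
  if (nrow(values) < 2L || ncol(values) < 2L) {
    stop("expression matrix needs at least 2 genes and 2 samples")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stop("duplicate gene identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) stop("duplicate sample identifier(s): ",
                        paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "non-finite or negative expression value at gene '%s', sample '%s'",
      rownames(values)[i[1L]], colnames(values)[i[2L]]))
  }
  invisible(values)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expected dialect: tab-separated, UTF-8, header row of sample identifiers,
#' first column named `gene_id` holding the gene identifiers (the transposed
#' layout is accepted via `orientation = "samples_rows"`).  Values must be
#' numeric, finite and non-negative; missing values are a hard error because
#' no downstream stage defines an imputation rule.
#'
#' @param path file path.
#' @param orientation `"genes_rows"` (default) or `"samples_rows"`.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expression TSV needs an id column plus data")
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate identifier(s) in first column: ",
                        paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals))
  bad <- union(bad, which(is.na(vals)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(vals))
    stop(sprintf("non-numeric or missing cell at row %d ('%s'), column '%s'",
                 i[1L], ids[i[1L]], colnames(vals)[i[2L]]))
  }
  neg <- which(num < 0)
  if (length(neg)) {
    i <- arrayInd(neg[1L], dim(vals))
    stop(sprintf("negative value at row %d ('%s'), column '%s'",
                 i[1L], ids[i[1L]], colnames(vals)[i[2L]]))
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  if (orientation == "samples_rows") num <- t(num)
  expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' Full-precision output (17 significant digits) so that a read/write
#' round-trip is value-identical.
#'
#' @param expr an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  validate_expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr),
                   format(unclass(expr), digits = 17, trim = TRUE,
                          scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(expr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' Two tab-separated columns, `sample_id` and `entity` (the cohort label,
#' e.g. a TCGA study code).  Sample identifiers must be unique.
#'
#' @param path file path.
#' @return data.frame with columns `sample_id`, `entity`.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (!all(c("sample_id", "entity") %in% colnames(df))) {
    stop("annotation TSV must have columns 'sample_id' and 'entity'")
  }
  df <- df[, c("sample_id", "entity")]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id(s): ",
                        paste(unique(dup), collapse = ", "))
  df
}

#' @rdname read_sample_annotation
#' @param ann annotation data.frame.
#' @export
write_sample_annotation <- function(ann, path) {
  stopifnot(all(c("sample_id", "entity") %in% colnames(ann)))
  write.table(ann[, c("sample_id", "entity")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix with its annotation and filter small entities
#'
#' Takes the intersection of the matrix and annotation sample sets, then
#' drops every entity with fewer than `min_entity_size` samples (the bound
#' is inclusive: an entity with exactly `min_entity_size` samples is kept).
#' Removed entities are reported via [message()].
#'
#' @param expr an [expression_matrix()].
#' @param ann annotation data.frame (`sample_id`, `entity`).
#' @param min_entity_size minimum per-entity sample count, default 60.
#' @return list with elements `expr` and `ann`, aligned and filtered.
#' @export
align_cohort <- function(expr, ann, min_entity_size = 60L) {
  validate_expression_matrix(expr)
  stopifnot(min_entity_size >= 1L)
  common <- intersect(colnames(expr), ann$sample_id)
  if (!length(common)) stop("no overlap between matrix and annotation samples")
  ann <- ann[match(common, ann$sample_id), , drop = FALSE]
  sizes <- table(ann$entity)
  keep_entities <- names(sizes)[sizes >= min_entity_size]
  dropped <- setdiff(names(sizes), keep_entities)
  if (length(dropped)) {
    message("align_cohort: removed entities below size ", min_entity_size,
            ": ", paste(sprintf("%s (n=%d)", dropped, sizes[dropped]),
                        collapse = ", "))
  }
  keep <- ann$entity %in% keep_entities
  ann <- ann[keep, , drop = FALSE]
  if (nrow(ann) < 2L) stop("fewer than 2 samples retained after filtering")
  expr <- expression_matrix(unclass(expr)[, ann$sample_id, drop = FALSE])
  rownames(ann) <- NULL
  list(expr = expr, ann = ann)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard tab-separated GMT: one set per line, fields
#' `name TAB description TAB member...`.  Duplicate members within a set are
#' dropped.  Returns a named list of `list(description =, genes =)`.
#'
#' @param path file path.
#' @return a `GeneSetCollection`: named list of sets.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(fields)))
    }
    name <- fields[1L]
    if (!is.null(sets[[name]])) stop("duplicate set name: ", name)
    sets[[name]] <- list(description = fields[2L],
                         genes = unique(fields[-(1:2)]))
  }
  structure(sets, class = "GeneSetCollection")
}

#' @rdname read_gmt
#' @param sets a gene-set collection as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
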