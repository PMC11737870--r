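#' Validate a count matrix
#'
#' Enforces the shape contract used throughout the package: an integer-valued,
#' non-negative matrix with unique gene row names and unique column names.
#'
#' @param values numeric matrix, genes x columns.
#' @param what label used in error messages.
#' @return the validated matrix (storage mode integer), invisibly usable.
#' @keywords internal
validate_count_matrix <- function(values, what = "count matrix") {
  if (!is.matrix(values)) stop(what, ": values must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop(what, ": gene (row) and column names are required")
  }
  if (anyDuplicated(rownames(values))) {
    stop(what, ": duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop(what, ": duplicate column ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (anyNA(values)) stop(what, ": missing values are not allowed")
  if (!is.numeric(values)) stop(what, ": values must be numeric counts")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("%s: negative count %s at gene '%s', column '%s'",
                 what, values[neg[1, 1], neg[1, 2]],
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]))
  }
  if (any(values != round(values))) {
    bad <- which(values != round(values), arr.ind = TRUE)[1, ]
    stop(sprintf("%s: non-integer count at gene '%s', column '%s'",
                 what, rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  storage.mode(values) <- "integer"
  values
}

#' Read a gene x column count matrix
#'
#' Two on-disk dialects are supported: a TSV with a header row of column ids
#' and gene ids in the first column, and MatrixMarket (`.mtx`) with sibling
#' label files `<stem>.genes.txt` and `<stem>.cols.txt` (one id per line).
#'
#' @param path path to the matrix file.
#' @param format `"tsv"` or `"mtx"`.
#' @param layer_tag `"umi"` (single-cell UMIs) or `"reads"` (bulk).
#' @return integer matrix (genes x columns) with dimnames and a `layer_tag`
#'   attribute, validated against the count-matrix contract.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"), layer_tag = c("umi", "reads")) {
  format <- match.arg(format)
  layer_tag <- match.arg(layer_tag)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, header = TRUE, check.names = FALSE,
                        stringsAsFactors = FALSE, comment.char = ""),
      error = function(e) stop("malformed TSV '", path, "': ", conditionMessage(e))
    )
    if (ncol(df) < 2) stop("malformed TSV '", path, "': need a gene-id column plus >=1 data column")
    gene_ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(values)) {
      bad <- which(is.na(suppressWarnings(apply(values, 2, as.numeric))), arr.ind = TRUE)
      stop("malformed TSV '", path, "': non-numeric entry near data line ",
           if (length(bad)) bad[1] + 1L else "?")
    }
    rownames(values) <- gene_ids
  } else {
    stem <- sub("\\.mtx$", "", path)
    gene_file <- paste0(stem, ".genes.txt")
    col_file <- paste0(stem, ".cols.txt")
    if (!file.exists(gene_file)) stop("missing MTX gene label file: ", gene_file)
    if (!file.exists(col_file)) stop("missing MTX column label file: ", col_file)
    values <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(gene_file)
    col_ids <- readLines(col_file)
    if (length(gene_ids) != nrow(values)) {
      stop("gene label file has ", length(gene_ids), " ids but matrix has ", nrow(values), " rows")
    }
    if (length(col_ids) != ncol(values)) {
      stop("column label file has ", length(col_ids), " ids but matrix has ", ncol(values), " columns")
    }
    dimnames(values) <- list(gene_ids, col_ids)
  }
  values <- validate_count_matrix(values, what = paste0("count matrix '", path, "'"))
  attr(values, "layer_tag") <- layer_tag
  values
}

#' Write a count matrix in the TSV or MTX dialect
#'
#' @param values integer matrix with dimnames (genes x columns).
#' @param path output path; for MTX, `<stem>.genes.txt` / `<stem>.cols.txt`
#'   are written beside it.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(values, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  values <- validate_count_matrix(values)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(values), values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(values, sparse = TRUE), path)
    writeLines(rownames(values), paste0(stem, ".genes.txt"))
    writeLines(colnames(values), paste0(stem, ".cols.txt"))
  }
  invisible(path)
}

#' Read sample/cell metadata
#'
#' TSV with at least a `column_id` column; `condition`, `timepoint_days`,
#' `replicate`, `population` are recognised when present, any further columns
#' are carried along untouched.
#'
#' @param path TSV path.
#' @return data.frame with one row per column id.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.delim(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"column_id" %in% names(md)) stop("metadata '", path, "' lacks a 'column_id' column")
  if (anyDuplicated(md$column_id)) {
    stop("metadata '", path, "': duplicated column_id: ",
         paste(unique(md$column_id[duplicated(md$column_id)]), collapse = ", "))
  }
  md
}

#' Check that metadata covers a matrix
#' @param values matrix with column names.
#' @param metadata data.frame with `column_id`.
#' @return the metadata rows reordered to match the matrix columns.
#' @keywords internal
align_metadata <- function(values, metadata) {
  missing <- setdiff(colnames(values), metadata$column_id)
  if (length(missing)) {
    stop("metadata is missing rows for columns: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  metadata[match(colnames(values), metadata$column_id), , drop = FALSE]
}

#' Read a GMT gene-set collection
#'
#' One set per line: set name, description, then member gene ids, all
#' tab-separated. Duplicated genes within a line are removed with a warning;
#' the description field is ignored.
#'
#' @param path GMT file path.
#' @param source_tag label recorded on the collection; defaults to the file name.
#' @return object of class `gene_set_collection`: a list with `sets` (named
#'   list of character vectors) and `source_tag`.
#' @export
read_gene_sets <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("gene-set file '", path, "' is empty")
    return(gene_set_collection(list(), source_tag))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3) {
      stop("malformed GMT '", path, "' line ", i, ": expected >=3 tab-separated fields")
    }
    name <- fields[[1]]
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("GMT '", path, "' line ", i, " ('", name, "'): duplicated gene ids removed")
      genes <- unique(genes)
    }
    if (name %in% names(sets)) stop("malformed GMT '", path, "': duplicated set name '", name, "'")
    sets[[name]] <- genes
  }
  gene_set_collection(sets, source_tag)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (each non-empty, unique genes).
#' @param source_tag provenance label.
#' @return `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, source_tag = "custom") {
  stopifnot(is.list(sets))
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) stop("all gene sets must be named")
    empty <- names(sets)[vapply(sets, length, 1L) == 0]
    if (length(empty)) stop("empty gene sets: ", paste(empty, collapse = ", "))
    dup <- names(sets)[vapply(sets, anyDuplicated, 1L) > 0]
    if (length(dup)) stop("duplicated gene ids within sets: ", paste(dup, collapse = ", "))
  }
  structure(list(sets = sets, source_tag = source_tag), class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection (", x$source_tag, "): ", length(x$sets), " sets\n", sep = "")
  invisible(x)
}

#' Default splenic myeloid marker table
#'
#' Literature-standard mouse markers for the six splenic CD11b+ populations
#' the single-cell analysis distinguishes (classical and non-classical
#' monocytes, immature/mature cDC2, neutrophils, NK cells).
#'
#' @return data.frame with columns `type` and `gene`.
#' @export
default_markers <- function() {
  path <- system.file("extdata", "splenic_myeloid_markers.tsv", package = "trainomics")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Default cell-cycle gene list
#'
#' Proliferation genes excluded before variable-gene selection.
#'
#' @return character vector of mouse gene symbols.
#' @export
default_cell_cycle_genes <- function() {
  readLines(system.file("extdata", "cell_cycle_genes.txt", package = "trainomics"))
}
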