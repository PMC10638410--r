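#' Multi-sample single-cell dataset container
#'
#' Holds a log-normalized expression matrix (genes x cells), the cell-to-
#' sample assignment, a low-dimensional cell embedding (cells x D, e.g. top
#' PCs of harmonized data) and the sample-level design matrix. All components
#' are aligned by cell id; the design matrix has a leading intercept column
#' of ones and one row per sample.
#'
#' @param expression genes x cells numeric matrix (dense or sparse) with
#'   dimnames. Missing values are rejected: imputation is upstream.
#' @param sample_of_cell character/factor of sample labels, one per cell
#'   (named by cell id, or aligned to the expression columns).
#' @param embedding optional cells x D numeric matrix (rownames = cell ids).
#' @param sample_design optional samples x (V+1) numeric matrix with leading
#'   intercept column; defaults to intercept-only.
#' @return object of class `msd`.
#' @export
multisample_dataset <- function(expression, sample_of_cell, embedding = NULL,
                                sample_design = NULL) {
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression must have gene (row) and cell (column) names")
  cells <- colnames(expression)
  if (anyDuplicated(cells)) stop("duplicate cell_ids in expression")
  if (anyDuplicated(rownames(expression))) stop("duplicate gene_ids")
  if (inherits(expression, "sparseMatrix")) {
    if (anyNA(expression@x)) stop("missing expression values are disallowed")
  } else if (anyNA(expression)) {
    stop("missing expression values are disallowed")
  }
  if (!is.null(names(sample_of_cell))) {
    if (!all(cells %in% names(sample_of_cell)))
      stop("sample_of_cell does not cover all cells")
    sample_of_cell <- sample_of_cell[cells]
  } else if (length(sample_of_cell) != length(cells)) {
    stop("sample_of_cell length does not match cell count")
  }
  sample_of_cell <- stats::setNames(factor(as.character(sample_of_cell)), cells)
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (is.null(rownames(embedding))) {
      if (nrow(embedding) != length(cells))
        stop("embedding rows do not align with cells")
      rownames(embedding) <- cells
    } else {
      if (!all(cells %in% rownames(embedding)))
        stop("embedding rows do not align with cells")
      embedding <- embedding[cells, , drop = FALSE]
    }
    if (anyNA(embedding)) stop("missing embedding values are disallowed")
  }
  samples <- levels(sample_of_cell)
  if (is.null(sample_design)) {
    sample_design <- matrix(1, length(samples), 1L,
                            dimnames = list(samples, "intercept"))
  } else {
    sample_design <- as.matrix(sample_design)
    if (!is.numeric(sample_design)) stop("sample_design must be numeric")
    if (is.null(rownames(sample_design)))
      stop("sample_design must have sample rownames")
    missing_s <- setdiff(samples, rownames(sample_design))
    if (length(missing_s))
      stop("design missing sample(s): ", paste(missing_s, collapse = ", "))
    sample_design <- sample_design[samples, , drop = FALSE]
    if (any(sample_design[, 1L] != 1))
      stop("first design column must be an all-ones intercept")
  }
  ds <- list(expression = expression, cell_ids = cells,
             gene_ids = rownames(expression), sample_of_cell = sample_of_cell,
             embedding = embedding, sample_design = sample_design,
             backing = "memory")
  class(ds) <- "msd"
  ds
}

#' @export
print.msd <- function(x, ...) {
  cat(sprintf(
    "msd dataset: %d genes x %d cells, %d samples, %s-backed\n",
    length(x$gene_ids), length(x$cell_ids),
    nlevels(x$sample_of_cell), x$backing))
  cat(sprintf("  design: %d column(s): %s\n", ncol(x$sample_design),
              paste(colnames(x$sample_design), collapse = ", ")))
  invisible(x)
}

n_samples <- function(ds) nlevels(ds$sample_of_cell)

# Expression rows for selected genes as a dense matrix (streams from HDF5
# when disk-backed).
get_expression <- function(ds, genes = NULL) {
  if (ds$backing == "disk") {
    idx <- if (is.null(genes)) seq_along(ds$gene_ids)
           else match(genes, ds$gene_ids)
    if (anyNA(idx)) stop("unknown gene id")
    out <- rhdf5::h5read(ds$h5_path, "expression",
                         index = list(idx, NULL))
    dimnames(out) <- list(ds$gene_ids[idx], ds$cell_ids)
    return(out)
  }
  m <- if (is.null(genes)) ds$expression else ds$expression[genes, , drop = FALSE]
  as.matrix(m)
}

# ---- loading ----------------------------------------------------------------

read_expression_any <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    gf <- sub("\\.mtx$", ".genes.txt", path, ignore.case = TRUE)
    cf <- sub("\\.mtx$", ".cells.txt", path, ignore.case = TRUE)
    if (!file.exists(gf) || !file.exists(cf))
      stop("MTX sidecar files not found: expected ", gf, " and ", cf)
    rn <- readLines(gf); cn <- readLines(cf)
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("MTX dimensions do not match sidecar id files")
    dimnames(m) <- list(rn, cn)
    m
  } else if (grepl("\\.(h5|hdf5)$", path, ignore.case = TRUE)) {
    m <- rhdf5::h5read(path, "expression")
    dimnames(m) <- list(as.character(rhdf5::h5read(path, "gene_ids")),
                        as.character(rhdf5::h5read(path, "cell_ids")))
    m
  } else {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    as.matrix(df)
  }
}

# Expand categorical covariates to dummy columns (reference level =
# lexicographically first) and prepend the intercept.
build_design <- function(df) {
  stopifnot("sample" %in% colnames(df))
  samples <- as.character(df$sample)
  if (anyDuplicated(samples)) stop("duplicate sample rows in design table")
  covs <- df[setdiff(colnames(df), "sample")]
  out <- list(intercept = rep(1, nrow(df)))
  for (nm in colnames(covs)) {
    v <- covs[[nm]]
    if (is.numeric(v)) {
      out[[nm]] <- v
    } else {
      v <- as.character(v)
      if (anyNA(v)) stop("non-numeric design cells: NA in ", nm)
      lev <- sort(unique(v))
      for (l in lev[-1L]) out[[paste0(nm, "_", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, out)
  rownames(X) <- samples
  if (anyNA(X)) stop("non-numeric value in design table")
  X
}

#' Load a multi-sample dataset from files
#'
#' Reads the expression matrix (MTX triplet with `.genes.txt`/`.cells.txt`
#' sidecars, dense CSV with gene rownames, or HDF5 with datasets
#' `expression`, `gene_ids`, `cell_ids`), the cell metadata TSV (columns
#' `cell`, `sample`), an optional embedding CSV (rownames = cell ids) and an
#' optional sample design TSV (column `sample` plus covariates; categorical
#' covariates are expanded to dummy columns with the lexicographically first
#' level as reference). Cells present in the expression matrix but absent
#' from the metadata are dropped (count logged).
#'
#' With `backing_mode = "disk"` and an HDF5 expression file, the matrix is
#' left on disk and streamed gene-by-gene.
#'
#' @param expression_path,metadata_path,embedding_path,design_path file paths
#'   (`embedding_path`, `design_path` may be `NULL`).
#' @param backing_mode "memory" or "disk".
#' @return an [multisample_dataset()] object.
#' @export
load_dataset <- function(expression_path, metadata_path,
                         embedding_path = NULL, design_path = NULL,
                         backing_mode = c("memory", "disk")) {
  backing_mode <- match.arg(backing_mode)
  meta <- utils::read.delim(metadata_path, colClasses = "character")
  if (!all(c("cell", "sample") %in% colnames(meta)))
    stop("metadata must have columns 'cell' and 'sample'")
  if (anyDuplicated(meta$cell)) stop("duplicate cell_ids in metadata")
  if (backing_mode == "disk") {
    if (!grepl("\\.(h5|hdf5)$", expression_path, ignore.case = TRUE))
      stop("disk backing requires an HDF5 expression file")
    gene_ids <- as.character(rhdf5::h5read(expression_path, "gene_ids"))
    cell_ids <- as.character(rhdf5::h5read(expression_path, "cell_ids"))
    keep <- cell_ids %in% meta$cell
    if (!all(keep))
      stop("disk backing requires metadata covering all cells; ",
           sum(!keep), " uncovered")
    expr <- NULL
  } else {
    expr <- read_expression_any(expression_path)
    keep <- colnames(expr) %in% meta$cell
    if (any(!keep)) {
      td_log("dropping %d cells absent from metadata", sum(!keep))
      expr <- expr[, keep, drop = FALSE]
    }
    if (ncol(expr) == 0L) stop("no cells shared between expression and metadata")
    cell_ids <- colnames(expr)
    gene_ids <- rownames(expr)
  }
  sample_of_cell <- stats::setNames(meta$sample, meta$cell)[cell_ids]
  embedding <- NULL
  if (!is.null(embedding_path)) {
    embedding <- as.matrix(utils::read.csv(embedding_path, row.names = 1L,
                                           check.names = FALSE))
    if (!all(cell_ids %in% rownames(embedding)))
      stop("embedding does not cover all cells (alignment error)")
    embedding <- embedding[cell_ids, , drop = FALSE]
  }
  design <- NULL
  if (!is.null(design_path)) {
    ddf <- utils::read.delim(design_path, check.names = FALSE)
    design <- build_design(ddf)
  }
  if (backing_mode == "disk") {
    # validate alignment on a stub, then swap in the on-disk payload
    stub <- matrix(0, 1, length(cell_ids),
                   dimnames = list("stub", cell_ids))
    ds <- multisample_dataset(stub, sample_of_cell, embedding, design)
    ds$expression <- NULL
    ds$gene_ids <- gene_ids
    ds$h5_path <- normalizePath(expression_path)
    ds$backing <- "disk"
    return(ds)
  }
  multisample_dataset(expr, sample_of_cell, embedding, design)
}

#' Write a dataset to a directory of plain files
#'
#' Writes expression (`expression.csv` or `expression.h5`), metadata
#' (`cells.tsv`), embedding (`embedding.csv`) and design (`design.tsv`).
#'
#' @param ds an `msd` dataset.
#' @param dir output directory (created if needed).
#' @param format "csv" or "h5" for the expression matrix.
#' @return invisibly, the directory.
#' @export
write_dataset <- function(ds, dir, format = c("csv", "h5")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- get_expression(ds)
  if (format == "csv") {
    utils::write.csv(as.data.frame(expr),
                     file.path(dir, "expression.csv"))
  } else {
    h5 <- file.path(dir, "expression.h5")
    if (file.exists(h5)) file.remove(h5)
    rhdf5::h5createFile(h5)
    rhdf5::h5write(unname(expr), h5, "expression")
    rhdf5::h5write(rownames(expr), h5, "gene_ids")
    rhdf5::h5write(colnames(expr), h5, "cell_ids")
    rhdf5::h5closeAll()
  }
  utils::write.table(
    data.frame(cell = ds$cell_ids,
               sample = as.character(ds$sample_of_cell)),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ds$embedding))
    utils::write.csv(as.data.frame(ds$embedding),
                     file.path(dir, "embedding.csv"))
  utils::write.table(
    cbind(data.frame(sample = rownames(ds$sample_design)),
          as.data.frame(ds$sample_design)),
    file.path(dir, "design.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

# ---- result tables ----------------------------------------------------------

PVAL_FLOOR_LABEL <- "<2.22e-308"

#' Write a result table as TSV
#'
#' Writes any tabular test result with a stable column order. P-values below
#' the double-precision floor are serialized as `"<2.22e-308"`, mirroring
#' the convention of reporting such p-values as smaller than the precision
#' lower bound.
#'
#' @param results data.frame of results.
#' @param path output file path.
#' @export
write_result_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  pcols <- grep("^(p|p_value|pval|p_.*)$", colnames(out), value = TRUE)
  for (pc in pcols) {
    v <- out[[pc]]
    if (is.numeric(v)) {
      tiny <- !is.na(v) & v < .Machine$double.xmin
      if (any(tiny)) {
        v <- format(v, digits = 17)
        v[tiny] <- PVAL_FLOOR_LABEL
        out[[pc]] <- v
      }
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#' @param path TSV path.
#' @return data.frame with `"<2.22e-308"` entries restored as 0.
#' @export
read_result_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  for (nm in colnames(df)) {
    v <- df[[nm]]
    if (is.character(v) && any(v == PVAL_FLOOR_LABEL, na.rm = TRUE)) {
      v[v == PVAL_FLOOR_LABEL] <- "0"
      df[[nm]] <- as.numeric(v)
    }
  }
  df
}
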