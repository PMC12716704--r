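#' Construct a spatial transcriptomics dataset
#'
#' Bundles a cells-by-genes expression matrix with per-cell spatial
#' coordinates. Rows of `expr` and `coords` are aligned by position: row i of
#' the expression matrix and row i of the coordinate matrix describe the same
#' cell.
#'
#' @param expr numeric N x G matrix of nonnegative expression values
#'   (cells in rows, genes in columns).
#' @param coords numeric N x 2 matrix of spatial positions (x, y).
#' @param gene_names character vector of length G; unique gene symbols.
#'   Defaults to the column names of `expr`.
#' @param cell_ids character vector of length N; unique cell identifiers.
#'   Defaults to row names of `expr` or `cell_1..cell_N`.
#' @param labels optional character vector of length N with cluster or
#'   annotation labels.
#' @return An object of class `spatial_dataset` with elements `expr`,
#'   `coords`, `gene_names`, `cell_ids`, `labels`.
#' @export
spatial_dataset <- function(expr, coords, gene_names = colnames(expr),
                            cell_ids = rownames(expr), labels = NULL) {
  expr <- as.matrix(expr)
  coords <- as.matrix(coords)
  storage.mode(expr) <- "double"
  storage.mode(coords) <- "double"
  n <- nrow(expr); g <- ncol(expr)
  if (n < 2L) stop("need at least 2 cells, got ", n)
  if (g < 2L) stop("need at least 2 genes, got ", g)
  if (nrow(coords) != n) {
    stop("row count mismatch: expression has ", n,
         " cells but coordinates have ", nrow(coords))
  }
  if (ncol(coords) != 2L) stop("coords must have exactly 2 columns (x, y)")
  if (anyNA(expr) || any(!is.finite(expr))) stop("expression contains NaN/Inf")
  if (anyNA(coords) || any(!is.finite(coords))) stop("coords contain NaN/Inf")
  if (is.null(gene_names)) gene_names <- paste0("gene_", seq_len(g))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  gene_names <- as.character(gene_names)
  cell_ids <- as.character(cell_ids)
  if (length(gene_names) != g) stop("gene_names length != G")
  if (length(cell_ids) != n) stop("cell_ids length != N")
  if (anyDuplicated(gene_names)) stop("gene_names must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length != N")
  }
  dimnames(expr) <- list(cell_ids, gene_names)
  dimnames(coords) <- list(cell_ids, c("x", "y"))
  structure(list(expr = expr, coords = coords, gene_names = gene_names,
                 cell_ids = cell_ids, labels = labels),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", nrow(x$expr), "cells x", ncol(x$expr), "genes",
      if (!is.null(x$labels))
        paste0("(", length(unique(x$labels)), " labelled groups)"
        ) else "(unlabelled)", "\n")
  invisible(x)
}

#' Read a spatial dataset from files
#'
#' Reads an expression matrix (dense CSV with a header of gene names, or a
#' MatrixMarket file with `.rows`/`.cols` sidecar files listing cell ids and
#' gene names) together with a coordinate CSV with columns `x`, `y` and an
#' optional `cell_id` column. Rows are matched by position; when both files
#' carry cell ids the ids are cross-checked.
#'
#' @param expr_path path to the expression file.
#' @param coords_path path to the coordinate CSV.
#' @param format `"csv"` (dense, header = genes, optional first `cell_id`
#'   column) or `"mtx"` (MatrixMarket triplet with `<path>.rows` and
#'   `<path>.cols` sidecars).
#' @param labels_path optional path to a single-column CSV of cluster labels.
#' @return A [spatial_dataset()]. Expression values are returned exactly as
#'   stored; normalization is a separate explicit step
#'   ([normalize_expression()]).
#' @export
read_dataset <- function(expr_path, coords_path, format = c("csv", "mtx"),
                         labels_path = NULL) {
  format <- match.arg(format)
  for (p in c(expr_path, coords_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  if (format == "csv") {
    tab <- utils::read.csv(expr_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    cell_ids <- NULL
    if (ncol(tab) >= 1L && identical(names(tab)[1L], "cell_id")) {
      cell_ids <- as.character(tab[[1L]])
      tab <- tab[, -1L, drop = FALSE]
    }
    bad <- which(!vapply(tab, is.numeric, TRUE))
    if (length(bad)) {
      col <- bad[1L]
      row <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1L]
      stop("non-numeric expression value in column '", names(tab)[col],
           "', row ", row)
    }
    expr <- as.matrix(tab)
    gene_names <- colnames(expr)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(expr)))
  } else {
    m <- Matrix::readMM(expr_path)
    rows_path <- paste0(expr_path, ".rows")
    cols_path <- paste0(expr_path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path)) {
      stop("MTX sidecar files missing: expected ", rows_path, " and ",
           cols_path)
    }
    cell_ids <- readLines(rows_path)
    gene_names <- readLines(cols_path)
    expr <- as.matrix(m)
    if (length(cell_ids) != nrow(expr) || length(gene_names) != ncol(expr)) {
      stop("MTX sidecar lengths do not match matrix dimensions")
    }
  }
  co <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(co))) {
    stop("coordinate file must have columns 'x' and 'y'; found: ",
         paste(names(co), collapse = ", "))
  }
  if (nrow(co) != nrow(expr)) {
    stop("row count mismatch: expression has ", nrow(expr),
         " cells but coordinates have ", nrow(co))
  }
  if ("cell_id" %in% names(co) && !is.null(cell_ids) &&
      !all(as.character(co$cell_id) == cell_ids)) {
    stop("cell ids in coordinate file disagree with expression rows")
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    labels <- as.character(lab[[ncol(lab)]])
  }
  spatial_dataset(expr, cbind(x = co$x, y = co$y), gene_names = gene_names,
                  cell_ids = cell_ids, labels = labels)
}

#' Write a spatial dataset to files
#'
#' Inverse of [read_dataset()]; values round-trip within floating-point
#' printing precision for CSV and exactly for MTX.
#'
#' @param ds a [spatial_dataset()].
#' @param dir output directory, created if missing.
#' @param format `"csv"` or `"mtx"`.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_dataset <- function(ds, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coords_path <- file.path(dir, "coords.csv")
  co <- data.frame(cell_id = ds$cell_ids, x = ds$coords[, 1L],
                   y = ds$coords[, 2L])
  utils::write.csv(co, coords_path, row.names = FALSE, quote = FALSE)
  if (format == "csv") {
    expr_path <- file.path(dir, "expression.csv")
    df <- data.frame(cell_id = ds$cell_ids,
                     format(ds$expr, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE)
    names(df) <- c("cell_id", ds$gene_names)
    utils::write.csv(df, expr_path, row.names = FALSE, quote = FALSE)
  } else {
    expr_path <- file.path(dir, "expression.mtx")
    Matrix::writeMM(Matrix::Matrix(ds$expr, sparse = TRUE), expr_path)
    writeLines(ds$cell_ids, paste0(expr_path, ".rows"))
    writeLines(ds$gene_names, paste0(expr_path, ".cols"))
  }
  out <- list(expr = expr_path, coords = coords_path)
  if (!is.null(ds$labels)) {
    labels_path <- file.path(dir, "labels.csv")
    utils::write.csv(data.frame(cell_id = ds$cell_ids, label = ds$labels),
                     labels_path, row.names = FALSE, quote = FALSE)
    out$labels <- labels_path
  }
  invisible(out)
}

#' Construct a ligand-receptor pair database
#'
#' @param ligand,receptor character vectors of gene symbols of equal length.
#' @return An object of class `lr_db`: a data frame with columns `ligand`,
#'   `receptor`, duplicates removed, order preserved.
#' @export
lr_db <- function(ligand, receptor) {
  ligand <- as.character(ligand); receptor <- as.character(receptor)
  stopifnot(length(ligand) == length(receptor))
  if (any(!nzchar(ligand)) || any(!nzchar(receptor))) {
    stop("ligand/receptor symbols must be nonempty")
  }
  keep <- !duplicated(paste0(ligand, "\r", receptor))
  structure(data.frame(ligand = ligand[keep], receptor = receptor[keep],
                       stringsAsFactors = FALSE),
            class = c("lr_db", "data.frame"))
}

#' Read a ligand-receptor pair list
#'
#' Expects a TSV with header columns `ligand` and `receptor` (further columns
#' are ignored), as exported from curated databases such as CellTalkDB.
#' Pairs referencing genes absent from a particular dataset are kept here and
#' filtered where the database is used.
#'
#' @param path path to the TSV file.
#' @return An `lr_db` (see [lr_db()]); may hold zero rows.
#' @export
read_lr_db <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab))) {
    stop("LR file must have columns 'ligand' and 'receptor'; found: ",
         paste(names(tab), collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(structure(data.frame(ligand = character(), receptor = character(),
                                stringsAsFactors = FALSE),
                     class = c("lr_db", "data.frame")))
  }
  lr_db(tab$ligand, tab$receptor)
}

#' Write a ligand-receptor pair list
#' @param db an `lr_db`.
#' @param path output TSV path.
#' @export
write_lr_db <- function(db, path) {
  utils::write.table(as.data.frame(db)[, c("ligand", "receptor")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize an expression matrix
#'
#' @param expr numeric N x G matrix.
#' @param mode one of:
#'   * `library_size_log1p`: scale each cell to the median library size,
#'     then `log1p`; the default preprocessing for model input features.
#'   * `minmax_per_gene`: map each gene column to `[0, 1]`; constant columns
#'     map to all zeros (keeps downstream kernels finite).
#'   * `zscore_per_gene`: center and scale each column to mean 0, sd 1;
#'     constant columns map to all zeros.
#' @return Matrix of the same shape.
#' @export
normalize_expression <- function(expr,
                                 mode = c("library_size_log1p",
                                          "minmax_per_gene",
                                          "zscore_per_gene")) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  switch(mode,
    library_size_log1p = {
      if (any(expr < 0)) stop("library-size normalization needs nonnegative input")
      lib <- rowSums(expr)
      lib[lib == 0] <- 1
      log1p(expr / lib * stats::median(rowSums(expr)))
    },
    minmax_per_gene = {
      lo <- apply(expr, 2L, min)
      hi <- apply(expr, 2L, max)
      rng <- hi - lo
      rng[rng == 0] <- 1  # constant column -> zeros
      sweep(sweep(expr, 2L, lo), 2L, rng, "/")
    },
    zscore_per_gene = {
      mu <- colMeans(expr)
      sd <- apply(expr, 2L, stats::sd)
      sd[sd == 0 | is.na(sd)] <- Inf  # constant column -> zeros
      sweep(sweep(expr, 2L, mu), 2L, sd, "/")
    })
}
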