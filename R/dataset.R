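#' Expression dataset container
#'
#' A lightweight container for a cells-by-genes expression matrix with per-cell
#' metadata. Cells are always rows and genes columns; a dataset carries a raw
#' `counts` layer and/or a log-normalized `lognorm` layer, an ordered gene
#' list, and a `cell_meta` data frame with at least a `study` column (the batch
#' / study-of-origin label used as the model condition) and optionally a
#' `cell_type` column.
#'
#' @param counts optional cells x genes matrix of non-negative integers
#'   (dense or `Matrix` sparse).
#' @param lognorm optional cells x genes matrix of non-negative reals.
#' @param genes character vector of gene identifiers (column names). If
#'   missing, taken from the column names of the supplied layer.
#' @param cell_meta data frame with one row per cell; must contain a `study`
#'   column. A `cell_id` column is added from row names when absent.
#' @param active which layer subsequent modelling should use; defaults to
#'   `"lognorm"` when present, else `"counts"`.
#'
#' @return an object of class `sc_dataset` with elements `counts`, `lognorm`,
#'   `genes`, `cell_meta`, `active`, and `studies` (the study registry, in
#'   order of first appearance).
#' @export
sc_dataset <- function(counts = NULL, lognorm = NULL, genes = NULL,
                       cell_meta = NULL, active = NULL) {
  if (is.null(counts) && is.null(lognorm))
    stop("at least one of `counts` or `lognorm` must be supplied")
  layer <- if (!is.null(counts)) counts else lognorm
  n_cells <- nrow(layer)
  n_genes <- ncol(layer)
  if (is.null(genes)) genes <- colnames(layer)
  if (is.null(genes)) genes <- paste0("gene", seq_len(n_genes))
  genes <- as.character(genes)
  if (length(genes) != n_genes)
    stop("`genes` length (", length(genes), ") does not match matrix columns (",
         n_genes, ")")
  if (anyDuplicated(genes)) {
    warning("duplicate gene identifiers; keeping first occurrence of each")
    keep <- !duplicated(genes)
    genes <- genes[keep]
    if (!is.null(counts)) counts <- counts[, keep, drop = FALSE]
    if (!is.null(lognorm)) lognorm <- lognorm[, keep, drop = FALSE]
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = paste0("cell", seq_len(n_cells)),
                            study = rep("study1", n_cells),
                            stringsAsFactors = FALSE)
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (nrow(cell_meta) != n_cells)
    stop("`cell_meta` rows (", nrow(cell_meta),
         ") do not match matrix rows (", n_cells, ")")
  if (is.null(cell_meta$study))
    stop("`cell_meta` must contain a `study` column")
  cell_meta$study <- as.character(cell_meta$study)
  if (is.null(cell_meta$cell_id)) {
    ids <- rownames(cell_meta)
    if (is.null(ids) || identical(ids, as.character(seq_len(n_cells))))
      ids <- paste0("cell", seq_len(n_cells))
    cell_meta$cell_id <- ids
  }
  cell_meta$cell_id <- as.character(cell_meta$cell_id)
  if (anyDuplicated(cell_meta$cell_id))
    stop("duplicate cell barcodes in metadata")
  if (!is.null(cell_meta$cell_type))
    cell_meta$cell_type <- as.character(cell_meta$cell_type)

  prep <- function(m, check_int = FALSE) {
    if (is.null(m)) return(NULL)
    if (!inherits(m, "Matrix")) m <- Matrix::Matrix(as.matrix(m), sparse = TRUE)
    m <- methods::as(m, "CsparseMatrix")
    v <- m@x
    if (length(v) && min(v) < 0) stop("expression values must be non-negative")
    if (check_int && length(v) && any(abs(v - round(v)) > 1e-8))
      stop("counts layer contains non-integer values")
    dimnames(m) <- list(cell_meta$cell_id, genes)
    m
  }
  counts <- prep(counts, check_int = TRUE)
  lognorm <- prep(lognorm)
  if (is.null(active)) active <- if (!is.null(lognorm)) "lognorm" else "counts"
  active <- match.arg(active, c("counts", "lognorm"))
  if (is.null(switch(active, counts = counts, lognorm = lognorm)))
    stop("active layer '", active, "' is not present")

  structure(list(counts = counts, lognorm = lognorm, genes = genes,
                 cell_meta = cell_meta, active = active,
                 studies = unique(cell_meta$study)),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("sc_dataset: ", n_cells(x), " cells x ", length(x$genes), " genes\n",
      sep = "")
  cat("  layers: ", paste(c("counts", "lognorm")[
    c(!is.null(x$counts), !is.null(x$lognorm))], collapse = ", "),
    " (active: ", x$active, ")\n", sep = "")
  cat("  studies: ", paste(x$studies, collapse = ", "), "\n", sep = "")
  if (!is.null(x$cell_meta$cell_type))
    cat("  cell types: ", paste(unique(x$cell_meta$cell_type), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) c(n_cells(x), length(x$genes))

#' Number of cells in a dataset
#' @param ds an `sc_dataset`.
#' @return integer cell count.
#' @export
n_cells <- function(ds) nrow(ds$cell_meta)

#' Active expression layer as a matrix
#' @param ds an `sc_dataset`.
#' @param layer `"counts"`, `"lognorm"`, or `NULL` for the active layer.
#' @param dense return a base dense matrix?
#' @return the requested layer.
#' @export
get_layer <- function(ds, layer = NULL, dense = FALSE) {
  if (is.null(layer)) layer <- ds$active
  m <- switch(layer, counts = ds$counts, lognorm = ds$lognorm,
              stop("unknown layer '", layer, "'"))
  if (is.null(m)) stop("layer '", layer, "' is not present")
  if (dense) as.matrix(m) else m
}

#' Subset a dataset by cells
#' @param ds an `sc_dataset`.
#' @param cells integer or logical index over cells.
#' @return the subset `sc_dataset` (same genes, same layers).
#' @export
subset_cells <- function(ds, cells) {
  meta <- ds$cell_meta[cells, , drop = FALSE]
  if (anyDuplicated(meta$cell_id))  # repeated selection keeps ids unique
    meta$cell_id <- make.unique(meta$cell_id)
  sc_dataset(counts = if (!is.null(ds$counts)) ds$counts[cells, , drop = FALSE],
             lognorm = if (!is.null(ds$lognorm)) ds$lognorm[cells, , drop = FALSE],
             genes = ds$genes,
             cell_meta = meta,
             active = ds$active)
}

# -- readers / writers --------------------------------------------------------

#' Read an expression dataset
#'
#' Supported formats: `mtx_dir` (a directory with `matrix.mtx` in genes x cells
#' Matrix Market orientation, `genes.tsv`, `barcodes.tsv` and an optional
#' `metadata.tsv` with columns `cell_id`, `study`, `cell_type`), `csv` (a
#' directory with `matrix.csv`, cells as rows / genes as header columns / first
#' column cell ids, plus optional `metadata.csv`), and `h5ad` (AnnData file,
#' converted through the bundled Python helper; `X` is taken as the counts
#' layer when integer-valued, else as lognorm).
#'
#' @param path file or directory path.
#' @param format one of `"mtx_dir"`, `"h5ad"`, `"csv"`; guessed from `path`
#'   when `NULL`.
#' @param layer which layer the main matrix represents, `"counts"` (default)
#'   or `"lognorm"`.
#' @return an [sc_dataset].
#' @export
read_dataset <- function(path, format = NULL, layer = c("counts", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(format)) {
    format <- if (grepl("\\.h5ad$", path)) "h5ad" else {
      if (!dir.exists(path)) stop("path does not exist: ", path)
      if (file.exists(file.path(path, "matrix.mtx"))) "mtx_dir" else "csv"
    }
  }
  format <- match.arg(format, c("mtx_dir", "h5ad", "csv"))
  switch(format,
         mtx_dir = read_mtx_dir(path, layer),
         csv = read_csv_dir(path, layer),
         h5ad = read_h5ad(path))
}

read_mtx_dir <- function(path, layer) {
  need <- file.path(path, c("matrix.mtx", "genes.tsv", "barcodes.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing file: ", miss[[1]])
  m <- Matrix::t(Matrix::readMM(file.path(path, "matrix.mtx")))  # -> cells x genes
  genes <- readLines(file.path(path, "genes.tsv"))
  genes <- vapply(strsplit(genes, "\t"), `[[`, "", 1L)
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  meta_path <- file.path(path, "metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = barcodes, study = "study1", stringsAsFactors = FALSE)
  }
  if (is.null(meta$cell_id)) meta$cell_id <- barcodes
  args <- list(genes = genes, cell_meta = meta)
  args[[layer]] <- m
  do.call(sc_dataset, args)
}

read_csv_dir <- function(path, layer) {
  mp <- file.path(path, "matrix.csv")
  if (!file.exists(mp)) stop("missing file: ", mp)
  tab <- utils::read.csv(mp, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  meta_path <- file.path(path, "metadata.csv")
  meta <- if (file.exists(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = ids, study = "study1", stringsAsFactors = FALSE)
  }
  if (is.null(meta$cell_id)) meta$cell_id <- ids
  args <- list(genes = colnames(m), cell_meta = meta)
  args[[layer]] <- m
  do.call(sc_dataset, args)
}

#' Write a dataset to disk
#'
#' @param ds an [sc_dataset].
#' @param path output directory (for `mtx_dir`/`csv`) or `.h5ad` file path.
#' @param format `"mtx_dir"`, `"csv"` or `"h5ad"`.
#' @param layer which layer to write as the main matrix.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("mtx_dir", "csv", "h5ad"),
                          layer = NULL) {
  format <- match.arg(format)
  if (is.null(layer)) layer <- ds$active
  m <- get_layer(ds, layer)
  meta <- ds$cell_meta
  if (format == "h5ad") return(write_h5ad(ds, path, layer))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx_dir") {
    Matrix::writeMM(Matrix::t(m), file.path(path, "matrix.mtx"))
    writeLines(ds$genes, file.path(path, "genes.tsv"))
    writeLines(meta$cell_id, file.path(path, "barcodes.tsv"))
    utils::write.table(meta, file.path(path, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    dm <- as.matrix(m)
    out <- data.frame(cell_id = meta$cell_id, dm, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(out) <- c("cell_id", ds$genes)
    utils::write.csv(out, file.path(path, "matrix.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(meta, file.path(path, "metadata.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

h5ad_bridge <- function() {
  system.file("python", "h5ad_bridge.py", package = "scgraft", mustWork = TRUE)
}

read_h5ad <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  tmp <- tempfile("h5ad_import_")
  status <- system2("python", c(h5ad_bridge(), "export", shQuote(path),
                                shQuote(tmp)), stdout = TRUE, stderr = TRUE)
  if (!dir.exists(tmp))
    stop("h5ad conversion failed: ", paste(status, collapse = "\n"))
  layer <- readLines(file.path(tmp, "layer.txt"))[1]
  on.exit(unlink(tmp, recursive = TRUE))
  read_mtx_dir(tmp, layer)
}

write_h5ad <- function(ds, path, layer) {
  tmp <- tempfile("h5ad_export_")
  write_dataset(ds, tmp, format = "mtx_dir", layer = layer)
  writeLines(layer, file.path(tmp, "layer.txt"))
  status <- system2("python", c(h5ad_bridge(), "import", shQuote(tmp),
                                shQuote(path)), stdout = TRUE, stderr = TRUE)
  unlink(tmp, recursive = TRUE)
  if (!file.exists(path))
    stop("h5ad conversion failed: ", paste(status, collapse = "\n"))
  invisible(path)
}

# -- normalization / gene selection / alignment -------------------------------

#' Library-size normalization and log transform
#'
#' Scales each cell's counts to a common total (`target_sum`, default 10,000)
#' and applies `log(1 + x)`; the result is stored in the `lognorm` layer and
#' the counts layer is retained.
#'
#' @param ds an [sc_dataset] with a counts layer.
#' @param target_sum per-cell total after scaling.
#' @return the dataset with a `lognorm` layer (active layer set to lognorm).
#' @export
normalize_lognorm <- function(ds, target_sum = 1e4) {
  stopifnot(target_sum > 0)
  counts <- get_layer(ds, "counts")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("cells with zero total count at indices: ",
         paste(utils::head(which(totals == 0), 10), collapse = ", "))
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% counts
  ln <- scaled
  ln@x <- log1p(ln@x)
  sc_dataset(counts = counts, lognorm = ln, genes = ds$genes,
             cell_meta = ds$cell_meta, active = "lognorm")
}

#' Select highly variable genes
#'
#' Ranks genes by dispersion of the log-normalized layer, normalized within
#' bins of mean expression (genes are binned by mean, and dispersions z-scored
#' within each bin, so the selection is not dominated by expression level).
#' Ties broken by gene order; selection is deterministic.
#'
#' @param ds an [sc_dataset] with a lognorm layer.
#' @param n_top number of genes to keep.
#' @param n_bins number of mean-expression bins for dispersion normalization.
#' @return the dataset restricted to the selected genes, in original order.
#' @export
select_hvg <- function(ds, n_top, n_bins = 20) {
  ln <- get_layer(ds, "lognorm")
  G <- ncol(ln)
  if (n_top > G) stop("n_top (", n_top, ") exceeds gene count (", G, ")")
  mu <- Matrix::colMeans(ln)
  ex2 <- Matrix::colMeans(ln^2)
  v <- pmax(ex2 - mu^2, 0) * n_cells(ds) / max(1, n_cells(ds) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1))),
              include.lowest = TRUE)
  norm_disp <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 2) next
    m <- mean(disp[idx]); s <- stats::sd(disp[idx])
    norm_disp[idx] <- if (s > 0) (disp[idx] - m) / s else 0
  }
  ord <- order(norm_disp, decreasing = TRUE)
  keep <- sort(ord[seq_len(n_top)])
  sc_dataset(counts = if (!is.null(ds$counts)) ds$counts[, keep, drop = FALSE],
             lognorm = ln[, keep, drop = FALSE],
             genes = ds$genes[keep], cell_meta = ds$cell_meta,
             active = ds$active)
}

#' Align a query dataset to a reference gene list
#'
#' The output has exactly `reference_genes` in reference order: shared genes
#' carry the query values, reference genes missing from the query become
#' all-zero columns, and query-only genes are dropped. The fraction of
#' zero-filled genes is attached as attribute `zero_filled_fraction`.
#'
#' @param query an [sc_dataset].
#' @param reference_genes character vector of reference gene identifiers.
#' @return the aligned dataset.
#' @export
align_genes <- function(query, reference_genes) {
  reference_genes <- as.character(reference_genes)
  shared <- intersect(reference_genes, query$genes)
  if (length(shared) == 0)
    stop("no overlap between query genes and reference gene list")
  n <- n_cells(query)
  G <- length(reference_genes)
  remap <- function(m) {
    if (is.null(m)) return(NULL)
    out <- Matrix::Matrix(0, n, G, sparse = TRUE)
    pos <- match(shared, reference_genes)
    out[, pos] <- m[, match(shared, query$genes), drop = FALSE]
    out
  }
  res <- sc_dataset(counts = remap(query$counts), lognorm = remap(query$lognorm),
                    genes = reference_genes, cell_meta = query$cell_meta,
                    active = query$active)
  attr(res, "zero_filled_fraction") <- 1 - length(shared) / G
  attr(res, "zero_filled_genes") <- setdiff(reference_genes, shared)
  res
}
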