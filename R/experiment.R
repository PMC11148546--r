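#' Construct an experiment matrix
#'
#' Container for a sorted-sample scRNA-seq experiment: sparse UMI counts
#' (genes x cells) with per-cell design metadata and per-gene annotation.
#'
#' @param counts sparse or dense nonnegative integer matrix, genes in rows,
#'   cells in columns. Row names are gene symbols, column names barcodes.
#' @param cell_meta data.frame with one row per cell: columns `barcode`,
#'   `sample_id`, `genotype` ("Control"/"KO"), `reporter`
#'   ("positive"/"negative"), `time` ("early"/"late"), `sex` ("F"/"M").
#' @param gene_meta data.frame with one row per gene: columns `symbol` and
#'   logical `is_mito`. If missing, mitochondrial genes are flagged by the
#'   mouse "mt-" symbol prefix.
#' @return an object of class `tt_experiment`.
#' @export
tt_experiment <- function(counts, cell_meta, gene_meta = NULL) {
  counts <- as_dgc(counts)
  if (min(counts@x %||% 0) < 0) stop("counts must be nonnegative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  if (is.null(rownames(counts))) stop("counts must carry gene symbols as rownames")
  if (is.null(colnames(counts))) stop("counts must carry barcodes as colnames")
  if (anyDuplicated(colnames(counts))) stop("cell barcodes must be unique")
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(symbol = rownames(counts),
                            is_mito = startsWith(rownames(counts), "mt-"),
                            stringsAsFactors = FALSE)
  }
  stopifnot(nrow(gene_meta) == nrow(counts), nrow(cell_meta) == ncol(counts))
  cell_meta <- as.data.frame(cell_meta)
  req <- c("barcode", "sample_id", "genotype", "reporter", "time", "sex")
  miss <- setdiff(req, names(cell_meta))
  if (length(miss)) stop("cell_meta lacks columns: ", paste(miss, collapse = ", "))
  if (!all(cell_meta$barcode == colnames(counts)))
    stop("cell_meta$barcode must match counts colnames in order")
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "tt_experiment")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# general numeric sparse (dgCMatrix) from dense or any Matrix class
as_dgc <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x) * 1, sparse = TRUE)
  methods::as(methods::as(methods::as(x, "dMatrix"),
                          "generalMatrix"), "CsparseMatrix")
}

#' @export
print.tt_experiment <- function(x, ...) {
  cat(sprintf("tt_experiment: %d genes x %d cells, %d samples\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id))))
  invisible(x)
}

#' @export
dim.tt_experiment <- function(x) dim(x$counts)

#' Subset an experiment to a set of cells
#' @param x a `tt_experiment`
#' @param cells logical, integer or barcode character index over cells
#' @return a `tt_experiment` restricted to those cells
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "tt_experiment"))
  if (is.character(cells)) cells <- match(cells, colnames(x$counts))
  tt_experiment(x$counts[, cells, drop = FALSE],
                x$cell_meta[cells, , drop = FALSE], x$gene_meta)
}

# condition label "<genotype>_<reporter>_<time>" used in per-condition summaries
condition_of <- function(cell_meta) {
  paste(cell_meta$genotype, cell_meta$reporter, cell_meta$time, sep = "_")
}

# log2 fold change of group means on de-logged normalized expression,
# with a small pseudo-mean for stability
log2fc_means <- function(m1, m2, pseudo = 1e-9) {
  log2((m1 + pseudo) / (m2 + pseudo))
}

# row variances of a sparse/dense matrix with the n-1 denominator
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("need at least 2 columns for a variance")
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  (ex2 - mu^2) * n / (n - 1)
}

# run code under a local RNG state: seeds reproducibly without
# disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
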