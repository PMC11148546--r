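#' Write an experiment as 10x-style triplet files
#'
#' One directory per sample containing `matrix.mtx` (MatrixMarket coordinate
#' integer, genes x cells), `features.tsv` (id, symbol) and `barcodes.tsv`,
#' plus a top-level `samples.tsv` sample sheet. Round-trips losslessly
#' through [read_tenx()].
#'
#' @param exp a [tt_experiment()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of sample directories written.
#' @export
write_tenx <- function(exp, dir) {
  stopifnot(inherits(exp, "tt_experiment"))
  if (ncol(exp$counts) == 0) stop("experiment has no cells; refusing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  sheet <- unique(exp$cell_meta[, c("sample_id", "genotype", "reporter", "time", "sex")])
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- character(0)
  for (sid in sheet$sample_id) {
    idx <- which(exp$cell_meta$sample_id == sid)
    if (length(idx) == 0) stop("sample with zero cells: ", sid)
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    m <- exp$counts[, idx, drop = FALSE]
    Matrix::writeMM(m, file.path(sdir, "matrix.mtx"))
    utils::write.table(
      data.frame(id = exp$gene_meta$symbol, symbol = exp$gene_meta$symbol),
      file.path(sdir, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    writeLines(exp$cell_meta$barcode[idx], file.path(sdir, "barcodes.tsv"))
    out <- c(out, sdir)
  }
  invisible(out)
}

#' Read 10x-style triplet matrices into one experiment
#'
#' Reads per-sample MatrixMarket triplets listed in a sample sheet,
#' validates dimensions, concatenates, and disambiguates barcodes that are
#' duplicated across samples by a deterministic `-<sample_id>` suffix.
#'
#' @param dir directory containing one subdirectory per sample.
#' @param sample_sheet data.frame (or path to a TSV) with columns
#'   `sample_id`, `genotype`, `reporter`, `time`, `sex`. Defaults to
#'   `<dir>/samples.tsv`.
#' @return a [tt_experiment()].
#' @export
read_tenx <- function(dir, sample_sheet = NULL) {
  if (is.null(sample_sheet)) sample_sheet <- file.path(dir, "samples.tsv")
  if (is.character(sample_sheet))
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  sheet <- as.data.frame(sample_sheet)
  blocks <- list(); metas <- list(); feat_ref <- NULL
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    sdir <- file.path(dir, sid)
    if (!dir.exists(sdir)) stop("sample in sheet without files: ", sid)
    m <- as_dgc(Matrix::readMM(file.path(sdir, "matrix.mtx")))
    feats <- utils::read.delim(file.path(sdir, "features.tsv"), header = FALSE,
                               stringsAsFactors = FALSE)
    bcs <- readLines(file.path(sdir, "barcodes.tsv"))
    if (nrow(feats) != nrow(m))
      stop(sprintf("%s: matrix declares %d genes but features.tsv has %d",
                   sid, nrow(m), nrow(feats)))
    if (length(bcs) != ncol(m))
      stop(sprintf("%s: matrix declares %d cells but barcodes.tsv has %d",
                   sid, ncol(m), length(bcs)))
    if (is.null(feat_ref)) feat_ref <- feats[[2]]
    else if (!identical(feat_ref, feats[[2]]))
      stop("feature lists differ between samples")
    rownames(m) <- feats[[2]]
    colnames(m) <- bcs
    blocks[[sid]] <- m
    meta <- sheet[rep(i, ncol(m)), , drop = FALSE]
    meta$barcode <- bcs
    metas[[sid]] <- meta
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  dup <- duplicated(meta$barcode) | duplicated(meta$barcode, fromLast = TRUE)
  meta$barcode[dup] <- paste0(meta$barcode[dup], "-", meta$sample_id[dup])
  if (anyDuplicated(meta$barcode)) stop("barcodes remain duplicated within a sample")
  colnames(counts) <- meta$barcode
  tt_experiment(counts, meta[, c("barcode", "sample_id", "genotype",
                                 "reporter", "time", "sex")])
}
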