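#' Cell-level quality filters
#'
#' Keeps exactly the cells with detected genes > `min_genes`, mitochondrial
#' read fraction < `max_mito`, and detected genes < `median_mult` x the
#' median detected genes of that cell's sample (median computed on the
#' pre-filter cells). All three bounds are strict.
#'
#' @param exp a [tt_experiment()] with `is_mito` flags set.
#' @param min_genes minimum detected genes (exclusive); default 200.
#' @param max_mito maximum mitochondrial fraction (exclusive); default 0.5.
#' @param median_mult upper detected-gene bound as a multiple of the
#'   per-sample pre-filter median (exclusive); default 3.
#' @return list with `experiment` (filtered) and `report`: per-sample
#'   cells_in, cells_out, removals attributed to each rule (a cell can
#'   count against several), median detected genes, and the thresholds.
#' @export
filter_cells <- function(exp, min_genes = 200, max_mito = 0.5, median_mult = 3) {
  stopifnot(inherits(exp, "tt_experiment"))
  detected <- Matrix::colSums(exp$counts > 0)
  total <- Matrix::colSums(exp$counts)
  mito <- Matrix::colSums(exp$counts[exp$gene_meta$is_mito, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 0)
  sample_id <- exp$cell_meta$sample_id
  med <- tapply(detected, sample_id, stats::median)
  cap <- median_mult * med[sample_id]
  pass_min <- detected > min_genes
  pass_mito <- mito_frac < max_mito
  pass_cap <- detected < cap
  keep <- pass_min & pass_mito & pass_cap
  report <- do.call(rbind, lapply(unique(sample_id), function(s) {
    i <- sample_id == s
    data.frame(sample_id = s,
               cells_in = sum(i),
               cells_out = sum(keep[i]),
               removed_by_min_genes = sum(!pass_min[i]),
               removed_by_mito = sum(!pass_mito[i]),
               removed_by_max_genes = sum(!pass_cap[i]),
               median_detected = unname(med[s]),
               max_genes_threshold = unname(median_mult * med[s]),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  empty <- report$sample_id[report$cells_out == 0]
  if (length(empty))
    warning("samples with zero cells after filtering: ", paste(empty, collapse = ", "))
  list(experiment = subset_cells(exp, which(keep)), report = report)
}
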