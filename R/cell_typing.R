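#' Module-score parameters
#'
#' @param n_bins expression bins for control-gene matching; default 100.
#' @param n_ctrl_per_bin control genes sampled per module gene; default 50.
#' @param seed seed for control-gene sampling (recorded so scores are
#'   reproducible).
#' @return a `tt_score_params` list.
#' @export
module_score_params <- function(n_bins = 100L, n_ctrl_per_bin = 50L, seed = 0L) {
  stopifnot(n_bins >= 1, n_ctrl_per_bin >= 1)
  structure(list(n_bins = as.integer(n_bins),
                 n_ctrl_per_bin = as.integer(n_ctrl_per_bin),
                 seed = as.integer(seed)),
            class = "tt_score_params")
}

#' Gene-module score per cell
#'
#' Expression-matched control scoring: all genes are binned into `n_bins`
#' equal-frequency bins by average normalized expression across the scored
#' cells; for each module gene, `n_ctrl_per_bin` control genes are sampled
#' without replacement from its bin (module genes excluded); the score of a
#' cell is the mean normalized expression over the module genes minus the
#' mean over the pooled (deduplicated) control genes. Module genes not
#' detected in any cell are excluded before scoring. If the module covers
#' every detected gene the control pool is empty and the score falls back
#' to mean(module) minus the grand mean over all genes, flagged degenerate.
#'
#' @param norm a `tt_norm`.
#' @param genes character vector of module gene symbols.
#' @param params a [module_score_params()].
#' @param cells optional cell index; bins and scores are computed over
#'   these cells only (default all).
#' @param name module name used in error messages.
#' @return numeric per-cell score, named by barcode; attributes
#'   `control_genes` and `degenerate`.
#' @export
module_score <- function(norm, genes, params = module_score_params(),
                         cells = NULL, name = "module") {
  x <- norm$lognorm
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  detected <- rownames(x)[Matrix::rowSums(x != 0) > 0]
  set <- intersect(genes, detected)
  if (length(set) == 0)
    stop("module '", name, "' has no detected genes")
  avg <- Matrix::rowMeans(x[detected, , drop = FALSE])
  nb <- min(params$n_bins, length(detected))
  bin <- ceiling(nb * rank(avg, ties.method = "first") / length(detected))
  names(bin) <- detected
  pool_by_bin <- split(setdiff(detected, set), bin[setdiff(detected, set)])
  degenerate <- length(unlist(pool_by_bin)) == 0
  if (degenerate) {
    score <- Matrix::colMeans(x[set, , drop = FALSE]) - Matrix::colMeans(x)
    ctrl <- character(0)
  } else {
    ctrl <- with_seed(params$seed, {
      picks <- lapply(set, function(g) {
        pool <- pool_by_bin[[as.character(bin[g])]]
        if (is.null(pool) || length(pool) == 0) return(character(0))
        if (length(pool) <= params$n_ctrl_per_bin) pool
        else sample(pool, params$n_ctrl_per_bin)
      })
      unique(unlist(picks))
    })
    if (length(ctrl) == 0) {
      score <- Matrix::colMeans(x[set, , drop = FALSE]) - Matrix::colMeans(x)
      degenerate <- TRUE
    } else {
      score <- Matrix::colMeans(x[set, , drop = FALSE]) -
        Matrix::colMeans(x[ctrl, , drop = FALSE])
    }
  }
  structure(score, control_genes = ctrl, degenerate = degenerate)
}

#' Score a table of marker modules
#'
#' @param norm a `tt_norm`.
#' @param modules data.frame with columns `module`, `type`, `sex`, `gene`
#'   (see [truth_marker_modules()] or [read_marker_modules()]).
#' @param params a [module_score_params()].
#' @param cells optional cell index.
#' @return list with `scores` (cells x modules matrix) and `meta`
#'   (module, type, sex).
#' @export
score_modules <- function(norm, modules, params = module_score_params(),
                          cells = NULL) {
  meta <- unique(modules[, c("module", "type", "sex")])
  if (anyDuplicated(meta$module)) stop("module names must be unique")
  sc <- vapply(meta$module, function(m) {
    as.numeric(module_score(norm, modules$gene[modules$module == m],
                            params, cells, name = m))
  }, numeric(if (is.null(cells)) ncol(norm$lognorm) else length(cells)))
  bc <- colnames(norm$lognorm)
  rownames(sc) <- if (is.null(cells)) bc else bc[cells]
  list(scores = sc, meta = meta)
}

#' Assign cell types by highest module score
#'
#' Each cell is assigned the type of its highest-scoring eligible module.
#' Eligibility honors sex restriction: a module with `sex` "F" or "M" is
#' scored only for cells of that sex (the sex-specific PT S2/S3 modules);
#' modules with `sex` "any" are eligible for all cells. Exact ties break
#' deterministically to the lexicographically first module name; tied cells
#' are reported in the `ties` attribute.
#'
#' @param scored output of [score_modules()].
#' @param sex per-cell sex vector aligned with the score rows.
#' @return data.frame `barcode`, `assigned_type`, `assigned_module`,
#'   `score`, with attribute `ties`.
#' @export
assign_types <- function(scored, sex) {
  sc <- scored$scores; meta <- scored$meta
  stopifnot(length(sex) == nrow(sc))
  ord <- order(meta$module)                # lexicographic tie-break order
  sc <- sc[, ord, drop = FALSE]; meta <- meta[ord, ]
  n <- nrow(sc)
  assigned <- integer(n); tied <- logical(n)
  for (s in unique(sex)) {
    el <- which(meta$sex == "any" | meta$sex == s)
    if (length(el) == 0) stop("cells of sex '", s, "' have no eligible modules")
    rows <- which(sex == s)
    sub <- sc[rows, el, drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    tied[rows] <- rowSums(sub == sub[cbind(seq_len(nrow(sub)), best)]) > 1
    assigned[rows] <- el[best]
  }
  out <- data.frame(barcode = rownames(sc),
                    assigned_type = meta$type[assigned],
                    assigned_module = meta$module[assigned],
                    score = sc[cbind(seq_len(n), assigned)],
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- out$barcode[tied]
  out
}

#' Derive marker genes from labelled reference cells
#'
#' For each type, markers are the genes with log2-fold change (mean
#' de-logged normalized expression, that type versus all other cells
#' pooled) > `log2fc_min`, expressed in > `pct_in_min` of the type's cells,
#' and in < `pct_out_max` of the other cells. All bounds strict.
#'
#' @param norm a `tt_norm`.
#' @param types per-cell type labels aligned with the columns of `norm`.
#' @param log2fc_min,pct_in_min,pct_out_max the three marker rules;
#'   defaults 1.0, 0.5, 0.2.
#' @param pseudo pseudo-mean for the fold change; default 1e-9.
#' @return named list of character vectors, one per type (empty modules are
#'   kept, flagged by a warning, and should be treated as ineligible).
#' @export
derive_markers <- function(norm, types, log2fc_min = 1.0, pct_in_min = 0.5,
                           pct_out_max = 0.2, pseudo = 1e-9) {
  x <- norm$lognorm
  stopifnot(length(types) == ncol(x))
  ex <- x; ex@x <- expm1(ex@x)
  det <- x; det@x <- as.numeric(det@x > 0)
  lev <- sort(unique(types))
  ind <- Matrix::sparseMatrix(i = seq_along(types), j = match(types, lev),
                              x = 1, dims = c(length(types), length(lev)))
  n_in <- Matrix::colSums(ind)
  mean_in <- as.matrix(ex %*% ind) %*% diag(1 / n_in, length(lev))
  pct_in <- as.matrix(det %*% ind) %*% diag(1 / n_in, length(lev))
  tot_mean <- Matrix::rowSums(ex) ; tot_pct <- Matrix::rowSums(det)
  out <- stats::setNames(vector("list", length(lev)), lev)
  for (j in seq_along(lev)) {
    n_out <- ncol(x) - n_in[j]
    if (n_out == 0) { out[[j]] <- character(0); next }
    mean_out <- (tot_mean - mean_in[, j] * n_in[j]) / n_out
    pct_out <- (tot_pct - pct_in[, j] * n_in[j]) / n_out
    fc <- log2fc_means(mean_in[, j], mean_out, pseudo)
    hit <- fc > log2fc_min & pct_in[, j] > pct_in_min & pct_out < pct_out_max
    out[[j]] <- rownames(x)[hit]
  }
  empty <- names(out)[lengths(out) == 0]
  if (length(empty))
    warning("types with no derived markers (ineligible modules): ",
            paste(empty, collapse = ", "))
  out
}

#' Read / write marker-module tables
#'
#' Marker modules as TSV with columns `module`, `type`, `sex`, `gene`
#' (`sex` optional; defaults to "any").
#'
#' @param path TSV path.
#' @return data.frame with the four columns.
#' @export
read_marker_modules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$sex)) df$sex <- "any"
  if (is.null(df$type)) df$type <- df$module
  df[, c("module", "type", "sex", "gene")]
}

#' @rdname read_marker_modules
#' @param modules data.frame as returned by [truth_marker_modules()].
#' @export
write_marker_modules <- function(modules, path) {
  utils::write.table(modules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
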