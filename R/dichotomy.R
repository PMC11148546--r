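#' Dichotomy-detection parameters
#'
#' @param n_var variable genes correlated; default 1,200.
#' @param linkage hclust linkage on distance 1 - rho; default "complete".
#' @param cut_k number of dendrogram clusters cut; default 8.
#' @param min_module_size smallest gene cluster considered; default 20.
#' @param class_A_threshold Module A score above which a PT cell is Class A
#'   (strict); default 0.15.
#' @param seed seed for the module scoring step.
#' @return a `tt_dichotomy_params` list.
#' @export
dichotomy_params <- function(n_var = 1200L, linkage = "complete", cut_k = 8L,
                             min_module_size = 20L, class_A_threshold = 0.15,
                             refine_frac = 0.5, seed = 0L) {
  stopifnot(cut_k >= 2, refine_frac >= 0, refine_frac <= 1)
  structure(as.list(environment()), class = "tt_dichotomy_params")
}

#' Most variable genes over proximal tubule cells
#'
#' The `n` genes of largest sample variance (n-1 denominator) of normalized
#' log expression across the given PT cells; constant genes are excluded,
#' ties break by symbol.
#'
#' @param norm a `tt_norm`.
#' @param pt_cells index of PT cells.
#' @param n genes to return; default 1,200.
#' @return character vector of gene symbols.
#' @export
top_variable_genes_pt <- function(norm, pt_cells, n = 1200) {
  if (length(pt_cells) < 2) stop("need at least 2 PT cells")
  x <- norm$lognorm[, pt_cells, drop = FALSE]
  if (n > nrow(x)) stop("n exceeds number of genes")
  v <- row_vars(x)
  keep <- v > 0
  v <- v[keep]
  sym <- rownames(x)[keep]
  if (n > length(sym)) stop("fewer than n nonconstant genes")
  sym[order(-v, sym)][seq_len(n)]
}

#' Pairwise Spearman correlation matrix
#'
#' Spearman coefficients (average ranks for ties) between every pair of the
#' given genes across cells. Zero-variance genes get correlation 0 to all
#' others (flagged) and 1 on the diagonal.
#'
#' @param norm a `tt_norm`.
#' @param genes gene symbols to correlate.
#' @param cells optional cell index (default all cells in `norm`).
#' @return symmetric correlation matrix with attribute `flagged_constant`.
#' @export
spearman_matrix <- function(norm, genes, cells = NULL) {
  x <- norm$lognorm[genes, , drop = FALSE]
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  if (ncol(x) < 3) stop("need at least 3 cells")
  xm <- as.matrix(x)
  r <- apply(xm, 1, rank)                  # cells x genes, average ranks
  sd0 <- apply(r, 2, stats::sd) == 0
  rc <- scale(r)                           # center + unit SD columns
  rc[, sd0] <- 0
  rho <- crossprod(rc) / (nrow(r) - 1)
  rho[sd0, ] <- 0; rho[, sd0] <- 0
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- list(genes, genes)
  attr(rho, "flagged_constant") <- genes[sd0]
  rho
}

#' Detect the anticorrelated gene-module pair
#'
#' Hierarchically clusters genes on distance 1 - rho, cuts the tree at
#' `cut_k`, and among the resulting gene clusters of at least
#' `min_module_size` genes selects the pair with the most negative mean
#' cross-correlation. If no pair has mean cross-correlation < 0 the result
#' is an explicit "no dichotomy detected". The larger module is named A
#' unless `anchor_A` genes are supplied, in which case the module with the
#' greater anchor overlap is A.
#'
#' @param rho correlation matrix from [spearman_matrix()].
#' @param params a [dichotomy_params()].
#' @param anchor_A optional exemplar genes anchoring the "A" label.
#' @return a `tt_dichotomy` list: `detected`, `module_A`, `module_B`,
#'   `mean_cross_rho`, `mean_within_A`, `mean_within_B`, `cut` (full cutree
#'   assignment), `hclust`.
#' @export
detect_anticorrelated_modules <- function(rho, params = dichotomy_params(),
                                          anchor_A = NULL) {
  stopifnot(nrow(rho) == ncol(rho))
  hc <- stats::hclust(stats::as.dist(1 - rho), method = params$linkage)
  k <- min(params$cut_k, nrow(rho))
  cut <- stats::cutree(hc, k = k)
  sizes <- table(cut)
  big <- as.integer(names(sizes)[sizes >= params$min_module_size])
  no_result <- function() structure(
    list(detected = FALSE, module_A = character(0), module_B = character(0),
         mean_cross_rho = NA_real_, mean_within_A = NA_real_,
         mean_within_B = NA_real_, cut = cut, hclust = hc),
    class = "tt_dichotomy")
  if (length(big) < 2) return(no_result())
  pairs <- utils::combn(big, 2)
  cross <- apply(pairs, 2, function(pq) {
    mean(rho[cut == pq[1], cut == pq[2], drop = FALSE])
  })
  best <- which.min(cross)
  if (cross[best] >= 0) return(no_result())
  p <- pairs[1, best]; q <- pairs[2, best]
  gp <- rownames(rho)[cut == p]; gq <- rownames(rho)[cut == q]
  # refine: membership requires anticorrelation with the opposing set
  # (automates the visual curation of the correlation-heatmap blocks).
  # Iterated to a fixed point: a gene stays iff its mean correlation with
  # the current opposing module is at least refine_frac times as negative
  # as the current pair mean; bystander genes the dendrogram glued onto a
  # block dilute the pair mean at first, so the bound tightens as they
  # drop out
  if (params$refine_frac > 0) {
    gp2 <- gp; gq2 <- gq
    for (it in 1:25) {
      bound <- params$refine_frac * mean(rho[gp2, gq2, drop = FALSE])
      np <- gp[rowMeans(rho[gp, gq2, drop = FALSE]) < bound]
      nq <- gq[rowMeans(rho[gq, gp2, drop = FALSE]) < bound]
      if (length(np) < params$min_module_size ||
          length(nq) < params$min_module_size) break
      done <- setequal(np, gp2) && setequal(nq, gq2)
      gp2 <- np; gq2 <- nq
      if (done) break
    }
    if (length(gp2) >= params$min_module_size &&
        length(gq2) >= params$min_module_size) { gp <- gp2; gq <- gq2 }
  }
  swap <- if (!is.null(anchor_A))
    length(intersect(gq, anchor_A)) > length(intersect(gp, anchor_A))
  else length(gq) > length(gp)
  if (swap) { tmp <- gp; gp <- gq; gq <- tmp }
  within <- function(g) {
    m <- rho[g, g, drop = FALSE]
    mean(m[upper.tri(m)])
  }
  structure(list(detected = TRUE, module_A = gp, module_B = gq,
                 mean_cross_rho = cross[best],
                 mean_within_A = within(gp), mean_within_B = within(gq),
                 cut = cut, hclust = hc),
            class = "tt_dichotomy")
}

#' Classify PT cells into Class A and Class B
#'
#' Scores PT cells for Module A and Module B with expression-matched
#' controls ([module_score()]); a PT cell is Class A iff its Module A score
#' is strictly greater than the threshold, otherwise Class B. Non-PT cells
#' are never assigned a class.
#'
#' @param norm a `tt_norm`.
#' @param module_A,module_B gene vectors from
#'   [detect_anticorrelated_modules()].
#' @param pt_cells index of PT cells.
#' @param params a [dichotomy_params()] (threshold and scoring seed).
#' @param score_params a [module_score_params()]; defaults to 100 bins /
#'   50 controls with the dichotomy seed.
#' @return data.frame `barcode`, `score_A`, `score_B`, `pt_class` for the
#'   PT cells only.
#' @export
classify_pt_cells <- function(norm, module_A, module_B, pt_cells,
                              params = dichotomy_params(),
                              score_params = NULL) {
  if (is.null(score_params))
    score_params <- module_score_params(seed = params$seed)
  sA <- module_score(norm, module_A, score_params, pt_cells, name = "Module A")
  sB <- module_score(norm, module_B, score_params, pt_cells, name = "Module B")
  data.frame(barcode = colnames(norm$lognorm)[pt_cells],
             score_A = as.numeric(sA), score_B = as.numeric(sB),
             pt_class = ifelse(as.numeric(sA) > params$class_A_threshold, "A", "B"),
             stringsAsFactors = FALSE)
}
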