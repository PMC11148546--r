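#' Log-normalize UMI counts
#'
#' Per cell: `lognorm[g,c] = ln(1 + S * counts[g,c] / libsize[c])` with
#' scale factor `S`. A zero-count cell maps to an all-zero column.
#'
#' @param exp a [tt_experiment()] (normally QC-filtered).
#' @param scale_factor `S`; default 10,000.
#' @return a `tt_norm` list: sparse `lognorm` (genes x cells),
#'   `scale_factor`, and the cell/gene metadata carried over.
#' @export
lognormalize <- function(exp, scale_factor = 1e4) {
  stopifnot(inherits(exp, "tt_experiment"))
  libsize <- Matrix::colSums(exp$counts)
  scl <- ifelse(libsize > 0, scale_factor / libsize, 0)
  ln <- exp$counts %*% Matrix::Diagonal(x = scl)
  ln@x <- log1p(ln@x)
  dimnames(ln) <- dimnames(exp$counts)
  structure(list(lognorm = as_dgc(ln),
                 scale_factor = scale_factor,
                 cell_meta = exp$cell_meta, gene_meta = exp$gene_meta),
            class = "tt_norm")
}

#' Highly variable genes
#'
#' The `n` genes with the largest variance (n-1 denominator) of normalized
#' log expression across cells; ties broken deterministically by symbol.
#'
#' @param norm a `tt_norm`.
#' @param n number of genes to keep.
#' @param cells optional cell subset over which to compute variances.
#' @return character vector of gene symbols, most variable first.
#' @export
select_hvg <- function(norm, n = 2000, cells = NULL) {
  x <- norm$lognorm
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  if (n > nrow(x)) stop("n exceeds number of genes")
  v <- row_vars(x)
  ord <- order(-v, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Per-sex standardization of selected genes
#'
#' Standardizes each gene to mean 0 / SD 1 within each sex separately, then
#' recombines. Removes additive and multiplicative per-gene sex offsets by
#' construction; stands in for anchor-based integration across sexes.
#'
#' @param norm a `tt_norm` with `sex` in its cell metadata.
#' @param genes genes to scale (typically [select_hvg()] output).
#' @return `norm` with a dense `scaled` matrix (genes x cells) and `hvg`.
#' @export
sex_correct_scale <- function(norm, genes) {
  sex <- norm$cell_meta$sex
  x <- as.matrix(norm$lognorm[genes, , drop = FALSE])
  out <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (s in unique(sex)) {
    j <- which(sex == s)
    if (length(j) < 2) stop("sex stratum with fewer than 2 cells: ", s)
    xs <- x[, j, drop = FALSE]
    mu <- rowMeans(xs)
    sd <- sqrt(pmax(rowSums((xs - mu)^2) / (length(j) - 1), 0))
    sd[sd == 0] <- 1   # constant gene within the stratum stays at 0
    out[, j] <- (xs - mu) / sd
  }
  norm$scaled <- out
  norm$hvg <- genes
  norm
}

#' Clustering parameters
#'
#' @param n_hvg variable genes used for scaling/PCA; default 2,000.
#' @param n_pcs principal components; default 30.
#' @param resolution Louvain modularity resolution; default 1.
#' @param knn_k neighbors for the SNN graph; default 20.
#' @param snn_prune minimum Jaccard edge weight retained; default 1/15.
#' @param embedding 2-D embedding for visualization only: "pca" (first two
#'   PCs), "umap" (requires uwot), or "none".
#' @param seed seed for PCA initialization and Louvain.
#' @return a `tt_clust_params` list.
#' @export
clustering_params <- function(n_hvg = 2000, n_pcs = 30, resolution = 1,
                              knn_k = 20, snn_prune = 1 / 15,
                              embedding = "pca", seed = 0L) {
  stopifnot(resolution > 0, n_pcs >= 1, knn_k >= 1)
  structure(as.list(environment()), class = "tt_clust_params")
}

#' PCA, shared-nearest-neighbor graph, and Louvain clustering
#'
#' Computes the top principal components of the scaled matrix, an exact
#' k-nearest-neighbor graph on them, SNN edge weights as the Jaccard index
#' of neighbor sets, and Louvain communities at the configured resolution.
#' The 2-D embedding is for visualization only; no downstream logic reads it.
#'
#' @param norm a `tt_norm` with `scaled` set (see [sex_correct_scale()]).
#' @param params a [clustering_params()].
#' @return a `tt_clust` list: `pcs` (cells x n_pcs), `cluster` (integer ids
#'   contiguous from 0, ordered by decreasing size), `embedding`, `params`.
#' @export
pca_cluster_embed <- function(norm, params = clustering_params()) {
  if (is.null(norm$scaled)) stop("run sex_correct_scale() first")
  x <- t(norm$scaled)                      # cells x genes
  n_cells <- nrow(x)
  if (n_cells <= params$n_pcs) stop("fewer cells than requested PCs")
  n_pcs <- min(params$n_pcs, ncol(x))
  with_seed(params$seed, {
    if (n_pcs < min(dim(x)) / 3) {
      pc <- irlba::prcomp_irlba(x, n = n_pcs, center = TRUE, scale. = FALSE)
      pcs <- pc$x
    } else {
      pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
      pcs <- pc$x[, seq_len(n_pcs), drop = FALSE]
    }
    rownames(pcs) <- rownames(x)
    snn <- snn_graph(pcs, k = params$knn_k, prune = params$snn_prune)
    cl <- igraph::cluster_louvain(snn, resolution = params$resolution)
    memb <- igraph::membership(cl)
    # contiguous ids from 0, largest community first
    sizes <- sort(table(memb), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
    cluster <- unname(relabel[as.character(memb)])
    emb <- switch(params$embedding,
      pca = pcs[, 1:2, drop = FALSE],
      umap = {
        if (!requireNamespace("uwot", quietly = TRUE))
          stop("embedding = 'umap' requires the uwot package")
        uwot::umap(pcs, n_threads = 1)
      },
      none = NULL,
      stop("unknown embedding: ", params$embedding))
    structure(list(pcs = pcs, cluster = cluster, embedding = emb,
                   params = params, snn = snn),
              class = "tt_clust")
  })
}

# exact kNN -> SNN Jaccard graph (weighted, undirected, pruned)
snn_graph <- function(pcs, k = 20, prune = 1 / 15) {
  n <- nrow(pcs)
  kk <- min(k + 1, n)                      # neighbor set includes self
  nn <- RANN::nn2(pcs, k = kk)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = kk),
                              j = as.vector(t(nn$nn.idx)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * kk - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
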