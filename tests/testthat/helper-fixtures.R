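# shared fixtures; heavyweight runs are cached so several test files can
# reuse the same default synthetic experiment and pipeline result

.tt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.tt_cache[[key]])) .tt_cache[[key]] <- force(expr)
  .tt_cache[[key]]
}

# full study-design run at default scale (16 samples x 750 cells, 2,000 genes)
default_run <- function(seed = 0L) {
  cached(paste0("run", seed), run_pipeline(pipeline_config(seed = seed)))
}

# reduced-size config for fast pipeline-level tests
small_config <- function(seed = 1L, cells = 150L) {
  pipeline_config(
    seed = seed,
    sim = sim_config(seed = seed, cells_per_sample = cells, n_genes = 700L),
    clustering = clustering_params(n_hvg = 700, n_pcs = 15, knn_k = 15,
                                   seed = seed + 1L),
    dichotomy = dichotomy_params(n_var = 450, seed = seed + 3L),
    ptlike_clustering = clustering_params(n_hvg = 700, n_pcs = 15, knn_k = 15,
                                          seed = seed + 6L))
}

# toy experiment with hand-controlled detected-gene counts per cell:
# cell j expresses the first detected[j] non-mito genes once; mito counts
# are added on top so the mito fraction is mito_frac[j]
toy_qc_experiment <- function(detected, mito_frac = rep(0, length(detected)),
                              n_genes = max(detected) + 10,
                              sample_id = rep("s1", length(detected))) {
  n <- length(detected)
  counts <- matrix(0L, n_genes + 1, n)
  for (j in seq_len(n)) {
    counts[seq_len(detected[j]), j] <- 1L
    if (mito_frac[j] > 0) {
      # one mito gene carrying mito_frac of the cell's reads
      counts[n_genes + 1, j] <- as.integer(round(
        mito_frac[j] / (1 - mito_frac[j]) * detected[j]))
      counts[1, j] <- counts[1, j]  # keep detected count unchanged
    }
  }
  rownames(counts) <- c(sprintf("Gene%04d", seq_len(n_genes)), "mt-Sim01")
  colnames(counts) <- sprintf("cell%03d", seq_len(n))
  tt_experiment(counts, data.frame(
    barcode = colnames(counts), sample_id = sample_id,
    genotype = "Control", reporter = "positive", time = "early", sex = "F",
    stringsAsFactors = FALSE))
}

# minimal tt_norm around a dense lognorm matrix (genes x cells)
toy_norm <- function(lognorm, sex = NULL) {
  ln <- Matrix::Matrix(lognorm * 1, sparse = TRUE)
  meta <- data.frame(barcode = colnames(lognorm),
                     sample_id = "s1", genotype = "Control",
                     reporter = "positive", time = "early",
                     sex = sex %||% rep("F", ncol(lognorm)),
                     stringsAsFactors = FALSE)
  structure(list(lognorm = ln, scale_factor = 1e4, cell_meta = meta,
                 gene_meta = data.frame(symbol = rownames(lognorm),
                                        is_mito = FALSE)),
            class = "tt_norm")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# independent running-sum enrichment oracle: direct position-by-position
# walk down the ranking (used to cross-check the analytic implementation)
naive_gsea_es <- function(s, hit_positions) {
  n <- length(s)
  hits <- seq_len(n) %in% hit_positions
  w <- abs(s); nr <- sum(w[hits])
  inc <- ifelse(hits, if (nr > 0) w / nr else 1 / sum(hits), 0)
  dec <- ifelse(hits, 0, 1 / (n - sum(hits)))
  running <- cumsum(inc - dec)
  mx <- max(running); mn <- min(running)
  if (mx >= -mn) mx else mn      # magnitude ties resolve positive
}

# exhaustive two-sided Wilcoxon oracle: enumerate every group-1 assignment
# and measure extremity by distance of U from its null mean
enum_wilcox_p <- function(v1, v2) {
  v <- c(v1, v2); n1 <- length(v1)
  r <- rank(v)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(v), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(v2) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

de_toy <- function(v1, v2) {
  # shift to positive values (rank statistics are shift-invariant) so the
  # de-logged fold change stays defined
  sh <- min(c(v1, v2)) - 0.1
  ln <- rbind(g1 = c(v1, v2) - sh)
  colnames(ln) <- sprintf("c%02d", seq_along(ln[1, ]))
  wilcoxon_de(toy_norm(ln), seq_along(v1), length(v1) + seq_along(v2))
}


make_block_rho <- function(within = 0.8, cross = -0.8, block = 5, noise = 0) {
  n <- 2 * block + noise
  rho <- diag(n)
  a <- seq_len(block); b <- block + seq_len(block)
  rho[a, a] <- within; rho[b, b] <- within
  rho[a, b] <- cross; rho[b, a] <- cross
  diag(rho) <- 1
  dimnames(rho) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  rho
}

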