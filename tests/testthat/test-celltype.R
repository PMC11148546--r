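# 20-gene / 2-bin fixture: bins split by average expression; every bin pool
# is smaller than n_ctrl_per_bin, so the control set is the full pool and
# the expected score is computable by hand
test_that("module score equals the hand-computed set-minus-controls mean", {
  set.seed(5)
  n_cells <- 12
  ln <- rbind(
    matrix(runif(10 * n_cells, 0, 0.5), 10),   # low-expression bin
    matrix(runif(10 * n_cells, 2, 3), 10))     # high-expression bin
  dimnames(ln) <- list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:n_cells))
  norm <- toy_norm(ln)
  module <- c("g03", "g15")                     # one gene from each bin
  params <- module_score_params(n_bins = 2, n_ctrl_per_bin = 50, seed = 1)
  sc <- module_score(norm, module, params)
  avg <- rowMeans(ln)
  bin <- ceiling(2 * rank(avg, ties.method = "first") / 20)
  ctrl <- setdiff(names(bin)[bin %in% bin[module]], module)
  expected <- colMeans(ln[module, ]) - colMeans(ln[ctrl, ])
  expect_equal(as.numeric(sc), as.numeric(expected), tolerance = 1e-12)
  expect_setequal(attr(sc, "control_genes"), ctrl)
})

test_that("module scores are invariant to a constant shift of the matrix", {
  set.seed(6)
  ln <- matrix(runif(40 * 15, 0, 2), 40, 15,
               dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:15)))
  norm <- toy_norm(ln)
  module <- c("g01", "g22", "g37")
  params <- module_score_params(n_bins = 4, n_ctrl_per_bin = 3, seed = 2)
  base <- as.numeric(module_score(norm, module, params))
  for (shift in runif(100, -5, 5)) {
    shifted <- toy_norm(ln + shift)
    expect_equal(as.numeric(module_score(shifted, module, params)), base,
                 tolerance = 1e-9)
  }
})

test_that("degenerate and empty modules are handled as pinned", {
  ln <- matrix(1, 5, 4, dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:4)))
  norm <- toy_norm(ln)
  # all genes constant and equal: score 0 for every cell
  sc <- module_score(norm, c("g1", "g2"), module_score_params(n_bins = 2))
  expect_equal(as.numeric(sc), rep(0, 4))
  # module covering all genes: fallback to set mean minus grand mean, flagged
  sc_all <- module_score(norm, rownames(ln), module_score_params())
  expect_true(attr(sc_all, "degenerate"))
  expect_equal(as.numeric(sc_all), rep(0, 4))
  expect_error(module_score(norm, c("nope1", "nope2"),
                            name = "Missing module"), "Missing module")
})

test_that("undetected module genes are excluded before scoring", {
  set.seed(7)
  ln <- matrix(runif(30 * 10, 0.1, 2), 30, 10,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
  ln[30, ] <- 0                                  # undetected gene
  norm <- toy_norm(ln)
  params <- module_score_params(n_bins = 3, n_ctrl_per_bin = 4, seed = 3)
  with_g30 <- module_score(norm, c("g01", "g05", "g30"), params)
  without <- module_score(norm, c("g01", "g05"), params)
  expect_equal(as.numeric(with_g30), as.numeric(without), tolerance = 1e-12)
})

test_that("type assignment takes the argmax with deterministic tie-breaks and sex eligibility", {
  scores <- matrix(c(0.5, 0.1, 0.2,
                     0.3, 0.3, 0.1), nrow = 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("T1", "T2", "T3")))
  meta <- data.frame(module = c("T1", "T2", "T3"),
                     type = c("T1", "T2", "T3"), sex = "any")
  ann <- assign_types(list(scores = scores, meta = meta), sex = c("F", "M"))
  expect_equal(ann$assigned_type, c("T1", "T1"))   # tie resolves to first name
  expect_equal(attr(ann, "ties"), "c2")

  meta_sex <- data.frame(module = c("S2 (F)", "S2 (M)", "Other"),
                         type = c("PT S2", "PT S2", "Other"),
                         sex = c("F", "M", "any"))
  sc <- matrix(c(0.9, 0.8, 0.1,
                 0.9, 0.8, 0.1), nrow = 2, byrow = TRUE,
               dimnames = list(c("c1", "c2"), meta_sex$module))
  ann2 <- assign_types(list(scores = sc, meta = meta_sex), sex = c("F", "M"))
  expect_equal(ann2$assigned_module, c("S2 (F)", "S2 (M)"))
  expect_error(assign_types(list(scores = sc[, 1, drop = FALSE],
                                 meta = meta_sex[1, ]), sex = c("F", "M")),
               "no eligible")
})

test_that("marker rules are strict on all three thresholds", {
  # 10 cells of type T, 10 others; counts scaled so normalization is benign
  ln <- matrix(0, 3, 20, dimnames = list(c("gA", "gB", "gC"),
                                         sprintf("c%02d", 1:20)))
  ln["gA", 1:10] <- 2          # 100% in T, 0% out, large fc -> marker
  ln["gB", 1:5] <- 2           # exactly 50% in T -> excluded (strict >)
  ln["gC", ] <- 1              # no fold change -> excluded
  norm <- toy_norm(ln)
  mk <- suppressWarnings(derive_markers(norm, rep(c("T", "other"), each = 10)))
  expect_equal(mk$T, "gA")
})

test_that("module scores track the reference single-cell toolkit implementation", {
  # control genes are sampled, so scores agree up to the control draw:
  # require near-perfect correlation, not identity
  sim <- simulate_experiment(sim_config(seed = 5L, cells_per_sample = 60L,
                                        n_genes = 700L))
  norm <- lognormalize(sim$experiment)
  mods <- truth_marker_modules(sim$truth)
  genes <- mods$gene[mods$module == "PT S1"]
  mine <- module_score(norm, genes,
                       module_score_params(n_bins = 10, n_ctrl_per_bin = 20,
                                           seed = 1))
  so <- suppressWarnings(Seurat::CreateSeuratObject(counts = sim$experiment$counts))
  so <- Seurat::NormalizeData(so, verbose = FALSE)
  so <- suppressWarnings(Seurat::AddModuleScore(so, features = list(genes),
                                                nbin = 10, ctrl = 20, seed = 1,
                                                name = "ms"))
  expect_gt(stats::cor(as.numeric(mine), so$ms1), 0.98)
})

test_that("assignment is invariant to cell order", {
  run <- default_run(0L)
  norm <- run$norm
  scored <- score_modules(norm, run$marker_modules,
                          module_score_params(seed = 2),
                          cells = 1:200)
  ann <- assign_types(scored, norm$cell_meta$sex[1:200])
  perm <- sample(200)
  scored_p <- list(scores = scored$scores[perm, ], meta = scored$meta)
  ann_p <- assign_types(scored_p, norm$cell_meta$sex[1:200][perm])
  expect_equal(ann_p$assigned_type[match(ann$barcode, ann_p$barcode)],
               ann$assigned_type)
})
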