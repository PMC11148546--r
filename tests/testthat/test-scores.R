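toy_ptlike_annotation <- function(cluster, type) {
  data.frame(barcode = sprintf("c%03d", seq_along(cluster)),
             genotype = "KO", reporter = "positive", time = "late",
             cluster = cluster, assigned_type = type,
             stringsAsFactors = FALSE)
}

test_that("PT-cluster rule is strict at 80% and flags non-PT members as PT-like", {
  ann <- toy_ptlike_annotation(rep(0, 10), c(rep("PT S1", 9), "CDIC"))
  res <- identify_pt_like(ann)
  expect_equal(res$pt_clusters, "0")
  expect_equal(sum(res$annotation$is_pt_like), 1)
  expect_equal(res$annotation$is_pt_like[10], TRUE)

  ann80 <- toy_ptlike_annotation(rep(0, 10), c(rep("PT S2", 8), "CDIC", "DCT"))
  expect_warning(res80 <- identify_pt_like(ann80), "no PT clusters")
  expect_length(res80$pt_clusters, 0)
  expect_false(any(res80$annotation$is_pt_like))
})

test_that("PT-like logic equals a brute-force filter over (cluster, type) tables", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 200
    ann <- toy_ptlike_annotation(sample(0:5, n, TRUE),
                                 sample(c("PT S1", "PT S2", "PT S3", "CDIC",
                                          "DCT", "Injured PT"), n, TRUE))
    res <- suppressWarnings(identify_pt_like(ann))
    naive <- logical(n)
    for (cl in unique(ann$cluster)) {
      i <- ann$cluster == cl
      pt <- ann$assigned_type[i] %in% c("PT S1", "PT S2", "PT S3")
      if (mean(pt) > 0.8) naive[i][!pt] <- TRUE
    }
    expect_equal(res$annotation$is_pt_like, naive)
  }
})

test_that("enrichment score matches a naive running-sum walk and stays in [-1, 1]", {
  set.seed(32)
  for (rep in 1:25) {
    n <- 30
    s <- sort(rnorm(n), decreasing = TRUE)
    names(s) <- sprintf("g%02d", 1:n)
    set <- sample(names(s), sample(3:10, 1))
    g <- gsea_preranked(s, set, n_perm = 10, seed = 1)
    expect_equal(g$es, naive_gsea_es(s, which(names(s) %in% set)),
                 tolerance = 1e-12)
    expect_true(abs(g$es) <= 1 + 1e-12)
  }
})

test_that("the enrichment statistic agrees with an independent reference implementation", {
  set.seed(35)
  for (rep in 1:20) {
    n <- sample(20:80, 1)
    s <- sort(rnorm(n), decreasing = TRUE)
    names(s) <- sprintf("g%03d", 1:n)
    pos <- sort(sample(n, sample(3:12, 1)))
    g <- gsea_preranked(s, names(s)[pos], n_perm = 5, seed = 1)
    expect_equal(g$es, fgsea::calcGseaStat(s, pos, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("a set of the top-ranked genes is maximally enriched", {
  s <- sort(rnorm(50, 0, 1), decreasing = TRUE)
  names(s) <- sprintf("g%02d", 1:50)
  g <- gsea_preranked(s, names(s)[1:5], n_perm = 500, seed = 2)
  expect_gt(g$es, 0)
  expect_lte(g$p_perm, 1 / (1 + 500) + 0.01)
  expect_setequal(g$leading_edge, names(s)[1:5])
  # full-ranking set: pinned boundary behavior
  g_full <- gsea_preranked(s, names(s), n_perm = 10, seed = 3)
  expect_equal(g_full$es, 0)
  expect_error(gsea_preranked(s, c("absent1", "absent2"),
                              set_name = "ghost set"), "ghost set")
  expect_error(gsea_preranked(setNames(1:3, c("a", "a", "b")), "a"),
               "duplicate")
})

test_that("exhaustive permutation p equals direct enumeration over all C(10,3) sets", {
  set.seed(33)
  s <- sort(rnorm(10), decreasing = TRUE)
  names(s) <- sprintf("g%02d", 1:10)
  set <- c("g01", "g04", "g09")
  g <- gsea_preranked(s, set, exhaustive = TRUE)
  combos <- utils::combn(10, 3)
  es_all <- apply(combos, 2, function(idx) naive_gsea_es(s, idx))
  es_obs <- naive_gsea_es(s, which(names(s) %in% set))
  same <- sign(es_all) == sign(es_obs)
  # ES magnitudes tie at discrete values across sets; compare with a float
  # tolerance so ties count as exceedances in the oracle too
  p_oracle <- sum(same & abs(es_all) >= abs(es_obs) - 1e-9) / sum(same)
  expect_equal(g$p_perm, p_oracle, tolerance = 1e-12)
  expect_equal(g$n_perm, ncol(combos))
})

test_that("Bonferroni across sets uses the call's family size", {
  s <- sort(rnorm(40), decreasing = TRUE)
  names(s) <- sprintf("g%02d", 1:40)
  sets <- list(top = names(s)[1:5], mid = names(s)[18:22], low = names(s)[36:40])
  res <- gsea_preranked_sets(s, sets, n_perm = 200, seed = 4)
  expect_equal(res$p_adj, pmin(1, res$p_perm * 3))
})

test_that("cells with no expression score zero and cycling proportions are well-behaved", {
  set.seed(34)
  ln <- matrix(runif(40 * 12, 0.2, 2), 40, 12,
               dimnames = list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:12)))
  ln[, 5] <- 0                                 # an all-zero cell
  norm <- toy_norm(ln)
  lists <- list(ccrcc_up_hif = c("g01", "g02", "g03"),
                ccrcc_up_nonhif = c("g10", "g11"))
  sc <- score_ccrcc_modules(norm, lists, module_score_params(n_bins = 4, seed = 5))
  expect_equal(sc$scores$hif_score[5], 0)
  expect_equal(sc$scores$nonhif_score[5], 0)

  counts <- matrix(0L, 3, 6, dimnames = list(c("Mki67", "g1", "g2"),
                                             sprintf("c%d", 1:6)))
  ex <- tt_experiment(counts, data.frame(
    barcode = colnames(counts), sample_id = "s1", genotype = "KO",
    reporter = "positive", time = "early", sex = "F"))
  cyc <- cycling_proportion(ex)
  expect_equal(cyc$by_condition$prop_cycling, 0)
  expect_error(cycling_proportion(ex, marker = "Nope"), "absent")
  counts2 <- counts; counts2["Mki67", 1:2] <- 3L
  ex2 <- tt_experiment(counts2, ex$cell_meta)
  cyc2 <- cycling_proportion(ex2)
  expect_equal(cyc2$by_condition$prop_cycling, 2 / 6)
  perm <- c(4, 2, 6, 1, 3, 5)
  cyc_perm <- cycling_proportion(subset_cells(ex2, perm))
  expect_equal(cyc_perm$by_condition, cyc2$by_condition)
  expect_equal(sum(cyc2$by_condition$n_cells), ncol(counts2))
})

test_that("per-condition summaries conserve cell counts", {
  run <- default_run(0L)
  cyc <- run$scores$cycling$by_condition
  expect_equal(sum(cyc$n_cells), ncol(run$experiment$counts))
  pl <- run$scores$pt_like$proportions
  expect_equal(sum(pl$n_cells),
               sum(run$norm$cell_meta$reporter == "positive"))
  expect_true(all(cyc$prop_cycling >= 0 & cyc$prop_cycling <= 1))
})
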