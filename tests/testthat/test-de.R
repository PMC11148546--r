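test_that("small-sample Wilcoxon p agrees with exhaustive enumeration", {
  set.seed(20)
  for (sizes in list(c(3, 3), c(4, 5), c(5, 5), c(8, 8))) {
    v1 <- rnorm(sizes[1]); v2 <- rnorm(sizes[2]) + 0.5
    p_impl <- de_toy(v1, v2)$p_raw
    expect_equal(p_impl, enum_wilcox_p(v1, v2), tolerance = 1e-9)
    expect_equal(p_impl, stats::wilcox.test(v1, v2)$p.value, tolerance = 1e-12)
  }
})

test_that("the tied/large-sample path reproduces the tie-corrected normal approximation", {
  set.seed(21)
  for (rep in 1:5) {
    v1 <- sample(0:3, 30, TRUE) + 0.0
    v2 <- sample(0:4, 35, TRUE) + 0.0
    p_impl <- de_toy(v1, v2)$p_raw
    # independent recomputation of the approximation
    v <- c(v1, v2); n1 <- 30; n2 <- 35; n <- 65
    r <- rank(v)
    u <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    s2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(s2)
    p_oracle <- min(2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)), 1)
    expect_equal(p_impl, p_oracle, tolerance = 1e-10)
    expect_equal(p_impl,
                 suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE,
                                                     correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("null and equal-mean cases behave as forced by the definitions", {
  d <- de_toy(rep(1, 10), rep(1, 12))   # identical distributions, all tied
  expect_equal(d$p_raw, 1)
  expect_equal(d$regulated, "none")
  expect_equal(d$log2fc, 0)             # equal means give exactly 0
  set.seed(22)
  v <- rnorm(8, 2)
  d2 <- de_toy(v, sample(v))            # same values, permuted
  expect_equal(d2$log2fc, 0, tolerance = 1e-12)
})

test_that("p is invariant under strictly monotone transforms and Bonferroni never shrinks p", {
  set.seed(23)
  v1 <- rexp(15); v2 <- rexp(18) * 1.7
  p_base <- de_toy(v1, v2)$p_raw
  for (f in list(function(x) x^3, function(x) log1p(x), function(x) 10 * x + 2))
    expect_equal(de_toy(f(v1), f(v2))$p_raw, p_base, tolerance = 1e-12)
  run <- cached("de_small", {
    cfg <- sim_config(seed = 30L, cells_per_sample = 80L, n_genes = 600L)
    sim <- simulate_experiment(cfg)
    norm <- lognormalize(sim$experiment)
    meta <- norm$cell_meta
    wilcoxon_de(norm,
                which(meta$genotype == "KO" & meta$reporter == "positive" &
                        meta$time == "early"),
                which(meta$genotype == "Control" & meta$reporter == "positive" &
                        meta$time == "early"))
  })
  expect_true(all(run$p_adj >= run$p_raw - 1e-15))
  expect_true(all(run$log2fc[run$regulated == "up"] > 0.25))
  expect_true(all(run$log2fc[run$regulated == "down"] < -0.25))
})

fake_de <- function(genes, regulated, lfc) {
  data.frame(gene = genes, log2fc = lfc, p_raw = 0, p_adj = 0,
             pct_1 = 0.5, pct_2 = 0.5, regulated = regulated,
             stringsAsFactors = FALSE)
}

test_that("reporter- and time-specificity apply the directional set difference", {
  g <- sprintf("g%d", 1:5)
  pos <- fake_de(g, c("up", "up", "down", "none", "up"), c(1, 1, -1, 0, 1))
  neg <- fake_de(g, c("none", "up", "up", "up", "down"), c(0, 1, 1, 1, -1))
  v <- vhl_regulated_early(pos, neg)
  # up in positives only -> specific; up in both -> excluded;
  # down vs up companions do not cancel; opposite-direction companion keeps it
  expect_equal(v$vhl_specific_early, c("up", "none", "down", "none", "up"))
  t <- time_regulated_ko(pos, neg)
  expect_equal(t$time_specific_ko, v$vhl_specific_early)
  expect_error(vhl_regulated_early(pos, NULL), "required")
  expect_error(vhl_regulated_early(pos, fake_de(g[1:3], rep("none", 3), 0)),
               "different gene sets")
})

test_that("specificity logic matches an independent brute-force filter on random tables", {
  set.seed(24)
  for (rep in 1:20) {
    g <- sprintf("g%d", 1:50)
    rand_de <- function() fake_de(g, sample(c("up", "down", "none"), 50, TRUE),
                                  rnorm(50))
    a <- rand_de(); b <- rand_de()
    v <- vhl_regulated_early(a, b)
    naive <- vapply(seq_along(g), function(i) {
      if (a$regulated[i] == "none") return("none")
      if (a$regulated[i] == b$regulated[i]) return("none")
      a$regulated[i]
    }, character(1))
    expect_equal(v$vhl_specific_early, naive)
  }
})

test_that("identity specificity requires exclusivity and the fold-change margin", {
  g <- sprintf("g%d", 1:4)
  focal <- fake_de(g, c("up", "up", "up", "none"), c(0.5, 0.5, 0.5, 0.5))
  other1 <- fake_de(g, c("none", "up", "none", "none"), c(0.29, 0.1, 0.31, 0))
  other2 <- fake_de(g, c("none", "none", "none", "none"), c(0.1, 0.1, 0.1, 0))
  res <- identity_specific_genes(list(F = focal, O1 = other1, O2 = other2), "F")
  # g1: 0.5 - 0.29 = 0.21 > 0.2 -> specific
  # g2: same-direction regulation elsewhere -> excluded regardless of margin
  # g3: 0.5 - 0.31 = 0.19 < 0.2 -> excluded
  # g4: not regulated in focal
  expect_equal(res$specific, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(identity_specific_genes(list(O1 = other1), "F"), "not among")
})

test_that("specificity rules are recomputable by a naive per-gene loop", {
  set.seed(25)
  g <- sprintf("g%d", 1:40)
  des <- replicate(4, fake_de(g, sample(c("up", "down", "none"), 40, TRUE),
                              round(rnorm(40), 2)), simplify = FALSE)
  names(des) <- c("F", "A", "B", "C")
  res <- identity_specific_genes(des, "F", delta_min = 0.2)
  naive <- vapply(seq_along(g), function(i) {
    d <- des$F$regulated[i]
    if (d == "none") return(FALSE)
    for (o in des[c("A", "B", "C")]) {
      if (o$regulated[i] == d) return(FALSE)
      if (abs(des$F$log2fc[i]) - abs(o$log2fc[i]) <= 0.2) return(FALSE)
    }
    TRUE
  }, logical(1))
  expect_equal(res$specific, naive)
})

test_that("cross-identity PCA reflects profile geometry", {
  set.seed(26)
  base <- rnorm(30)
  lfc <- rbind(I1 = base, I2 = base, I3 = base + rnorm(30, 0, 0.01),
               I4 = -base)
  colnames(lfc) <- sprintf("g%d", 1:30)
  pc <- crossidentity_pca(lfc)
  expect_equal(pc$coords["I1", ], pc$coords["I2", ], tolerance = 1e-10)
  expect_equal(which.max(abs(pc$coords[, 1])), c(I4 = 4L))
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-10)
  expect_error(crossidentity_pca(lfc[1:2, ]), "at least 3")
})

test_that("replicate fold-change concordance is symmetric with unit diagonal and positive", {
  run <- default_run(0L)
  cc <- run$de$concordance
  expect_true(!is.null(cc))
  expect_true(isSymmetric(cc))
  expect_equal(diag(cc), rep(1, nrow(cc)), ignore_attr = TRUE)
  off <- cc[upper.tri(cc)]
  expect_true(all(off > 0.5))
})
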