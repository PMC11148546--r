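#' Select cells by design factors and annotation
#'
#' @param cell_meta per-cell metadata (from a `tt_experiment` / `tt_norm`).
#' @param genotype,reporter,time,sex,sample_id optional design filters.
#' @param identity optional assigned cell type filter (requires `annotation`).
#' @param pt_class optional PT class filter (requires `annotation`).
#' @param annotation optional data.frame with `barcode`, `assigned_type`
#'   and/or `pt_class` columns.
#' @return integer cell indices.
#' @export
select_cells <- function(cell_meta, genotype = NULL, reporter = NULL,
                         time = NULL, sex = NULL, sample_id = NULL,
                         identity = NULL, pt_class = NULL, annotation = NULL) {
  keep <- rep(TRUE, nrow(cell_meta))
  for (f in c("genotype", "reporter", "time", "sex", "sample_id")) {
    v <- get(f)
    if (!is.null(v)) keep <- keep & cell_meta[[f]] %in% v
  }
  if (!is.null(identity) || !is.null(pt_class)) {
    if (is.null(annotation)) stop("identity/pt_class filters need an annotation")
    ann <- annotation[match(cell_meta$barcode, annotation$barcode), ]
    if (!is.null(identity)) {
      at <- ann$assigned_type %||% rep(NA_character_, nrow(cell_meta))
      keep <- keep & !is.na(at) & at %in% identity
    }
    if (!is.null(pt_class)) {
      pc <- ann$pt_class %||% rep(NA_character_, nrow(cell_meta))
      keep <- keep & !is.na(pc) & pc %in% pt_class
    }
  }
  which(keep)
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-sided Wilcoxon rank-sum test per gene on normalized log expression
#' between two disjoint cell groups. Without ties and with both groups at
#' most `exact_max` cells the exact null distribution is used; otherwise
#' the normal approximation with average ranks, tie correction and
#' continuity correction. Fold change is
#' `log2((mean(expm1(x1)) + pseudo) / (mean(expm1(x2)) + pseudo))` on
#' normalized, unscaled expression. P values are Bonferroni-adjusted over
#' the genes tested; a gene is called regulated if |log2FC| >
#' `lfc_threshold` and adjusted p < `p_threshold` (both strict).
#'
#' @param norm a `tt_norm`.
#' @param cells1,cells2 disjoint cell index vectors (group1 vs group2).
#' @param pseudo pseudo-mean in the fold change; 1e-9 by default (set to 1
#'   for the legacy convention).
#' @param lfc_threshold,p_threshold regulation thresholds; defaults 0.25
#'   and 0.01.
#' @param genes optional gene subset to test (default all genes).
#' @param exact_max largest group size for the exact null; default 25.
#' @return a `tt_de` data.frame: `gene`, `log2fc`, `p_raw`, `p_adj`,
#'   `pct_1`, `pct_2`, `regulated` in {"up","down","none"}.
#' @export
wilcoxon_de <- function(norm, cells1, cells2, pseudo = 1e-9,
                        lfc_threshold = 0.25, p_threshold = 0.01,
                        genes = NULL, exact_max = 25) {
  if (length(intersect(cells1, cells2))) stop("groups must be disjoint")
  if (length(cells1) < 1 || length(cells2) < 1) stop("empty group")
  x <- norm$lognorm
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  x1 <- as.matrix(x[, cells1, drop = FALSE])
  x2 <- as.matrix(x[, cells2, drop = FALSE])
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  g <- nrow(x)
  p_raw <- numeric(g)
  for (i in seq_len(g)) {
    v <- c(x1[i, ], x2[i, ])
    r <- rank(v)
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    uv <- unique(v)
    tiesum <- if (length(uv) == n) 0 else {
      tie_tab <- tabulate(match(v, uv))
      sum(tie_tab^3 - tie_tab)
    }
    if (tiesum == 0 && n1 <= exact_max && n2 <= exact_max) {
      p <- if (u > n1 * n2 / 2)
        stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
      else stats::pwilcox(u, n1, n2)
      p_raw[i] <- min(2 * p, 1)
    } else {
      sigma2 <- (n1 * n2 / 12) * ((n + 1) - tiesum / (n * (n - 1)))
      if (sigma2 <= 0) { p_raw[i] <- 1; next }
      z <- u - n1 * n2 / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p_raw[i] <- min(2 * min(stats::pnorm(z),
                              stats::pnorm(z, lower.tail = FALSE)), 1)
    }
  }
  m1 <- rowMeans(expm1(x1)); m2 <- rowMeans(expm1(x2))
  lfc <- log2fc_means(m1, m2, pseudo)
  p_adj <- pmin(1, p_raw * g)
  regulated <- ifelse(p_adj < p_threshold & lfc > lfc_threshold, "up",
                      ifelse(p_adj < p_threshold & lfc < -lfc_threshold,
                             "down", "none"))
  out <- data.frame(gene = rownames(x), log2fc = lfc, p_raw = p_raw,
                    p_adj = p_adj,
                    pct_1 = rowMeans(x1 > 0), pct_2 = rowMeans(x2 > 0),
                    regulated = regulated,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("tt_de", "data.frame")
  out
}

# direction-specific set difference shared by the two contrast schemes:
# regulated in the focal contrast and NOT regulated in the same direction
# in the companion contrast
specific_by_direction <- function(de_focal, de_companion, flag_name) {
  if (!setequal(de_focal$gene, de_companion$gene))
    stop("focal and companion contrasts test different gene sets")
  comp <- de_companion$regulated[match(de_focal$gene, de_companion$gene)]
  specific <- ifelse(de_focal$regulated != "none" & de_focal$regulated != comp,
                     de_focal$regulated, "none")
  out <- data.frame(gene = de_focal$gene,
                    direction_focal = de_focal$regulated,
                    direction_companion = comp,
                    stringsAsFactors = FALSE)
  out[[flag_name]] <- specific
  out
}

#' Genes specifically regulated by Vhl inactivation at the early time point
#'
#' Genes regulated in the reporter-positive KO-vs-Control contrast but not
#' regulated in the same direction in the reporter-negative companion
#' contrast. Sub-threshold same-sign trends in the companion do not
#' exclude a gene.
#'
#' @param de_positive DE result for KO+ vs Control+ (early).
#' @param de_negative DE result for KO- vs Control- (early).
#' @return data.frame with per-gene directions and `vhl_specific_early`.
#' @export
vhl_regulated_early <- function(de_positive, de_negative) {
  if (is.null(de_positive) || is.null(de_negative))
    stop("both reporter contrasts are required")
  specific_by_direction(de_positive, de_negative, "vhl_specific_early")
}

#' Genes regulated over time specifically in Vhl-null cells
#'
#' Genes regulated in KO-positive cells late vs early but not regulated in
#' the same direction in Control-positive cells late vs early.
#'
#' @param de_ko DE result for KO+ late vs early.
#' @param de_control DE result for Control+ late vs early.
#' @return data.frame with per-gene directions and `time_specific_ko`.
#' @export
time_regulated_ko <- function(de_ko, de_control) {
  if (is.null(de_ko) || is.null(de_control))
    stop("both genotype contrasts are required")
  specific_by_direction(de_ko, de_control, "time_specific_ko")
}

#' Identity-specific regulated genes
#'
#' A gene is specific to the focal identity if it is regulated there, is
#' not regulated in the same direction in any other identity, and its
#' |log2FC| exceeds every other identity's |log2FC| by more than
#' `delta_min` (strict). The same rule with a single "other" serves the
#' PT Class A vs Class B scheme.
#'
#' @param de_list named list of `tt_de` results, one per identity that
#'   passed the minimum-cell threshold.
#' @param focal name of the focal identity; must be present in `de_list`.
#' @param delta_min the Delta|log2FC| margin; default 0.2.
#' @return data.frame `gene`, `direction`, `specific` (logical),
#'   `min_delta_abs_log2fc` (the binding margin over other identities).
#' @export
identity_specific_genes <- function(de_list, focal, delta_min = 0.2) {
  if (!focal %in% names(de_list))
    stop("focal identity '", focal, "' not among tested identities")
  others <- de_list[setdiff(names(de_list), focal)]
  if (length(others) == 0) stop("no other identities to compare against")
  def <- de_list[[focal]]
  genes <- def$gene
  dir <- def$regulated
  abs_f <- abs(def$log2fc)
  same_dir_elsewhere <- rep(FALSE, length(genes))
  min_delta <- rep(Inf, length(genes))
  for (de_o in others) {
    idx <- match(genes, de_o$gene)
    if (anyNA(idx)) stop("identities were tested on different gene sets")
    same_dir_elsewhere <- same_dir_elsewhere |
      (de_o$regulated[idx] == dir & dir != "none")
    min_delta <- pmin(min_delta, abs_f - abs(de_o$log2fc[idx]))
  }
  data.frame(gene = genes, direction = dir,
             specific = dir != "none" & !same_dir_elsewhere &
               min_delta > delta_min,
             min_delta_abs_log2fc = min_delta,
             stringsAsFactors = FALSE)
}

#' Cross-identity PCA of fold-change profiles
#'
#' Embeds identities by principal components of their per-gene log2
#' fold-change vectors over the union of regulated genes, after centering
#' and scaling each gene across identities. Genes constant across
#' identities are dropped (they carry no contrast).
#'
#' @param lfc_matrix identities x genes matrix of log2 fold changes.
#' @return list `coords` (identities x PCs), `var_explained` (fractions),
#'   `genes_used`.
#' @export
crossidentity_pca <- function(lfc_matrix) {
  if (nrow(lfc_matrix) < 3) stop("need at least 3 identities")
  v <- apply(lfc_matrix, 2, stats::var)
  keep <- v > 0
  if (!any(keep)) stop("all fold-change columns are constant")
  pc <- stats::prcomp(lfc_matrix[, keep, drop = FALSE],
                      center = TRUE, scale. = TRUE)
  list(coords = pc$x,
       var_explained = pc$sdev^2 / sum(pc$sdev^2),
       genes_used = colnames(lfc_matrix)[keep])
}

#' Fold changes of one group of cells versus another
#'
#' @param norm a `tt_norm`.
#' @param cells1,cells2 cell index vectors.
#' @param genes gene subset (default all).
#' @param pseudo pseudo-mean; default 1e-9.
#' @return named numeric vector of log2 fold changes.
#' @export
log2fc_profile <- function(norm, cells1, cells2, genes = NULL, pseudo = 1e-9) {
  x <- norm$lognorm
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  e <- x; e@x <- expm1(e@x)
  m1 <- Matrix::rowMeans(e[, cells1, drop = FALSE])
  m2 <- Matrix::rowMeans(e[, cells2, drop = FALSE])
  stats::setNames(log2fc_means(m1, m2, pseudo), rownames(x))
}

#' Replicate concordance of Vhl-regulated fold changes
#'
#' For each KO reporter-positive sample at the given time point, computes
#' the log2 fold change of the regulated genes against the pool of
#' sex-matched Control reporter-positive cells, then the Spearman
#' correlation between every pair of per-sample fold-change vectors.
#'
#' @param norm a `tt_norm`.
#' @param regulated_genes genes over which concordance is assessed.
#' @param time time point; default "early".
#' @return symmetric Spearman correlation matrix (KO samples x KO samples).
#' @export
replicate_concordance <- function(norm, regulated_genes, time = "early") {
  if (length(regulated_genes) == 0) stop("no regulated genes supplied")
  meta <- norm$cell_meta
  ko <- meta$genotype == "KO" & meta$reporter == "positive" & meta$time == time
  samples <- unique(meta$sample_id[ko])
  if (length(samples) < 2) stop("need at least 2 KO positive samples")
  profs <- sapply(samples, function(s) {
    cells1 <- which(meta$sample_id == s)
    sx <- meta$sex[cells1[1]]
    cells2 <- which(meta$genotype == "Control" & meta$reporter == "positive" &
                      meta$time == time & meta$sex == sx)
    if (length(cells2) == 0) stop("no sex-matched Control positive cells for ", s)
    log2fc_profile(norm, cells1, cells2, genes = regulated_genes)
  })
  stats::cor(profs, method = "spearman")
}
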