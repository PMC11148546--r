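#' Identify PT-like (de-differentiated) cells
#'
#' Clusters in which strictly more than `pt_cluster_frac` of cells carry a
#' PT type assignment are "PT clusters"; cells inside them that are
#' assigned a non-PT type are PT-like.
#'
#' @param annotation data.frame with per-cell `barcode`, `assigned_type`,
#'   `cluster`, plus `genotype`, `reporter`, `time` for the per-condition
#'   proportions.
#' @param pt_type_names the PT type labels; default S1/S2/S3.
#' @param pt_cluster_frac strict lower bound on the PT fraction of a PT
#'   cluster; default 0.8.
#' @return list: `pt_clusters` (ids), `annotation` with `is_pt_like`
#'   appended, `proportions` per (genotype, reporter, time).
#' @export
identify_pt_like <- function(annotation, pt_type_names = pt_types(),
                             pt_cluster_frac = 0.8) {
  stopifnot(all(c("assigned_type", "cluster") %in% names(annotation)))
  is_pt <- annotation$assigned_type %in% pt_type_names
  frac <- tapply(is_pt, annotation$cluster, mean)
  pt_clusters <- names(frac)[frac > pt_cluster_frac]
  if (length(pt_clusters) == 0)
    warning("no PT clusters found (no cluster exceeds the PT fraction bound)")
  annotation$is_pt_like <- as.character(annotation$cluster) %in% pt_clusters &
    !is_pt
  cond <- condition_of(annotation)
  prop <- do.call(rbind, lapply(split(seq_len(nrow(annotation)), cond),
    function(i) {
      data.frame(condition = cond[i[1]],
                 n_cells = length(i),
                 n_pt_like = sum(annotation$is_pt_like[i]),
                 prop_pt_like = mean(annotation$is_pt_like[i]),
                 stringsAsFactors = FALSE)
    }))
  rownames(prop) <- NULL
  list(pt_clusters = pt_clusters, annotation = annotation, proportions = prop)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score (weight
# exponent 1 on |stat|) for hit positions `pos` in a ranking of length n
# with ranking statistics `s` (sorted decreasing). Returns the signed
# extremum and its position.
gsea_es <- function(s, pos, n) {
  k <- length(pos)
  if (k == n) return(list(es = 0, at = n))     # no miss set: pinned to 0
  pos <- sort(pos)
  w <- abs(s[pos])
  nr <- sum(w)
  if (nr == 0) w <- rep(1, k)                  # all-zero stats: unweighted
  nr <- sum(w)
  hit_cum <- cumsum(w) / nr
  miss_before <- (pos - seq_len(k)) / (n - k)  # misses strictly before each hit
  top <- hit_cum - miss_before                 # running sum right after hit i
  bottom <- c(0, hit_cum[-k]) - miss_before    # right before hit i
  i_max <- which.max(top); i_min <- which.min(bottom)
  # exact magnitude ties resolve to the positive deviation
  if (top[i_max] >= -bottom[i_min])
    list(es = unname(top[i_max]), at = pos[i_max])
  else list(es = unname(bottom[i_min]), at = pos[i_min])
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of a gene set in a
#' ranked list (weight exponent 1 on the absolute ranking statistic), with
#' a gene-set permutation null: `n_perm` random same-size sets, seeded.
#' `NES = ES / mean(|null ES| of matching sign)` and
#' `p_perm = (1 + #(null matching sign and |null| >= |ES|)) / (1 + n_perm)`.
#' With `exhaustive = TRUE` the null enumerates every same-size set and
#' `p_perm` is the exact fraction.
#'
#' @param stats named numeric ranking statistic (e.g. log2 fold changes);
#'   names are genes, no duplicates; sorted internally in decreasing order.
#' @param gene_set character vector; its intersection with the ranking must
#'   be nonempty.
#' @param n_perm permutations; default 1000.
#' @param seed RNG seed for the permutation draw.
#' @param exhaustive enumerate all C(n, k) sets instead of sampling.
#' @param set_name label used in errors and output.
#' @return a `tt_gsea` list: `set_name`, `size`, `es`, `nes`, `p_perm`,
#'   `leading_edge`, `n_perm`, `seed`.
#' @export
gsea_preranked <- function(stats, gene_set, n_perm = 1000L, seed = 0L,
                           exhaustive = FALSE, set_name = "gene_set") {
  if (anyDuplicated(names(stats))) stop("ranking has duplicate genes")
  s <- sort(stats, decreasing = TRUE)
  n <- length(s)
  pos <- which(names(s) %in% gene_set)
  k <- length(pos)
  if (k == 0) stop("gene set '", set_name, "' has no genes in the ranking")
  obs <- gsea_es(s, pos, n)
  es <- obs$es
  null_es <- if (exhaustive) {
    combos <- utils::combn(n, k)
    apply(combos, 2, function(p) gsea_es(s, p, n)$es)
  } else {
    with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) gsea_es(s, sample.int(n, k), n)$es, numeric(1))
    })
  }
  same_sign <- sign(null_es) == sign(es) & sign(es) != 0
  exceed <- same_sign & abs(null_es) >= abs(es)
  # p conditions on the ES sign (null count of the matching sign in the
  # denominator), which is what keeps p uniform under random sets
  p_perm <- if (exhaustive) {
    if (sum(same_sign) == 0) 1 else sum(exceed) / sum(same_sign)
  } else (1 + sum(exceed)) / (1 + sum(same_sign))
  denom <- mean(abs(null_es[same_sign]))
  nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
  le <- if (es >= 0) names(s)[intersect(pos, seq_len(obs$at))]
        else names(s)[intersect(pos, seq(obs$at, n))]
  structure(list(set_name = set_name, size = k, es = es, nes = nes,
                 p_perm = p_perm, leading_edge = le,
                 n_perm = if (exhaustive) length(null_es) else n_perm,
                 seed = seed),
            class = "tt_gsea")
}

#' Enrichment of several gene sets with Bonferroni adjustment
#'
#' @param stats ranking as in [gsea_preranked()].
#' @param sets named list of gene sets; the Bonferroni family is the number
#'   of sets tested in this call.
#' @param ... passed to [gsea_preranked()].
#' @return data.frame set, size, es, nes, p_perm, p_adj.
#' @export
gsea_preranked_sets <- function(stats, sets, ...) {
  res <- lapply(names(sets), function(nm)
    gsea_preranked(stats, sets[[nm]], set_name = nm, ...))
  out <- data.frame(set = names(sets),
                    size = vapply(res, `[[`, numeric(1), "size"),
                    es = vapply(res, `[[`, numeric(1), "es"),
                    nes = vapply(res, `[[`, numeric(1), "nes"),
                    p_perm = vapply(res, `[[`, numeric(1), "p_perm"),
                    stringsAsFactors = FALSE)
  out$p_adj <- pmin(1, out$p_perm * nrow(out))
  out
}

#' Score HIF-target and ccRCC gene modules
#'
#' Scores every cell for the HIF-driven and non-HIF-driven
#' ccRCC-upregulated modules with expression-matched controls, and
#' summarizes per condition (and per PT identity when an annotation is
#' given).
#'
#' @param norm a `tt_norm`.
#' @param lists list with `ccrcc_up_hif` and `ccrcc_up_nonhif` gene vectors
#'   (see [synthetic_gene_lists()]); lists are intersected with detected
#'   genes, an empty intersection is an error.
#' @param params a [module_score_params()].
#' @param annotation optional per-cell annotation with `assigned_type`
#'   (and `pt_class`) for identity-level summaries.
#' @return list `scores` (per-cell data.frame) and `summary` (per
#'   condition x identity: mean, median, IQR of each score).
#' @export
score_ccrcc_modules <- function(norm, lists, params = module_score_params(),
                                annotation = NULL) {
  hif <- module_score(norm, lists$ccrcc_up_hif, params, name = "ccRCC up (HIF)")
  nonhif <- module_score(norm, lists$ccrcc_up_nonhif, params,
                         name = "ccRCC up (non-HIF)")
  meta <- norm$cell_meta
  scores <- data.frame(barcode = meta$barcode,
                       hif_score = as.numeric(hif),
                       nonhif_score = as.numeric(nonhif),
                       condition = condition_of(meta),
                       stringsAsFactors = FALSE)
  scores$identity <- if (!is.null(annotation))
    annotation$assigned_type[match(meta$barcode, annotation$barcode)]
  else NA_character_
  grp <- interaction(scores$condition, scores$identity, drop = TRUE)
  if (is.null(annotation)) grp <- factor(scores$condition)
  summ <- do.call(rbind, lapply(split(seq_len(nrow(scores)), grp), function(i) {
    data.frame(group = as.character(grp[i[1]]), n = length(i),
               hif_mean = mean(scores$hif_score[i]),
               hif_median = stats::median(scores$hif_score[i]),
               hif_iqr = stats::IQR(scores$hif_score[i]),
               nonhif_mean = mean(scores$nonhif_score[i]),
               nonhif_median = stats::median(scores$nonhif_score[i]),
               nonhif_iqr = stats::IQR(scores$nonhif_score[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(scores = scores, summary = summ)
}

#' Proportion of cycling cells
#'
#' Fraction of cells expressing the proliferation marker (raw count
#' strictly greater than `threshold`), per condition and, when an
#' annotation is supplied, per assigned PT identity.
#'
#' @param exp a [tt_experiment()] (raw counts).
#' @param annotation optional per-cell annotation with `assigned_type`.
#' @param marker marker gene symbol; default "Mki67".
#' @param threshold count threshold (strict); default 0.
#' @return list `by_condition` and (optionally) `by_identity` data.frames
#'   with `n_cells`, `n_cycling`, `prop_cycling`.
#' @export
cycling_proportion <- function(exp, annotation = NULL, marker = "Mki67",
                               threshold = 0) {
  if (!marker %in% rownames(exp$counts))
    stop("marker gene absent from the matrix: ", marker)
  expr <- as.numeric(exp$counts[marker, ]) > threshold
  cond <- condition_of(exp$cell_meta)
  tab <- function(idx, split_by) {
    out <- do.call(rbind, lapply(split(idx, split_by), function(i) {
      data.frame(group = as.character(split_by[match(i[1], idx)]),
                 n_cells = length(i),
                 n_cycling = sum(expr[i]), prop_cycling = mean(expr[i]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  res <- list(by_condition = tab(seq_along(expr), factor(cond)))
  if (!is.null(annotation)) {
    ident <- annotation$assigned_type[match(exp$cell_meta$barcode,
                                            annotation$barcode)]
    keep <- which(!is.na(ident) &
                    (ident %in% c(pt_types(), "Injured PT") |
                       startsWith(ident, "PT")))
    res$by_identity <- tab(keep, interaction(cond[keep], ident[keep],
                                             drop = TRUE))
  }
  res
}
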