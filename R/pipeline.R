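#' Pipeline configuration
#'
#' Bundles all stage parameters. Every stage that consumes randomness
#' derives its seed deterministically from the global seed plus a fixed
#' stage offset, so a rerun with the same config reproduces all tables
#' byte-identically.
#'
#' @param seed global seed.
#' @param sim a [sim_config()]; defaults to the study-design defaults with
#'   the global seed.
#' @param input_dir 10x triplet directory to read instead of simulating
#'   (disables the simulate stage).
#' @param marker_modules marker-module table (data.frame or TSV path) when
#'   reading external data; simulated runs default to the planted fixture.
#' @param out_dir optional output directory for TSV tables and a manifest.
#' @param stages named logical toggles: simulate, qc, preprocess, celltype,
#'   ptclass, de, score.
#' @param clustering a [clustering_params()].
#' @param score_params a [module_score_params()].
#' @param dichotomy a [dichotomy_params()].
#' @param de list: `pseudo`, `lfc_threshold`, `p_threshold`, `min_cells`
#'   (strict per-identity bound), `focal_identities`.
#' @param gsea list: `n_perm`, `seed`.
#' @param ptlike_clustering a [clustering_params()] for the
#'   positive-sample clustering behind PT-like detection.
#' @return a `tt_pipeline_config` list.
#' @export
pipeline_config <- function(seed = 0L,
                            sim = NULL,
                            input_dir = NULL,
                            marker_modules = NULL,
                            out_dir = NULL,
                            stages = c(simulate = TRUE, qc = TRUE,
                                       preprocess = TRUE, celltype = TRUE,
                                       ptclass = TRUE, de = TRUE,
                                       score = TRUE),
                            clustering = NULL,
                            score_params = NULL,
                            dichotomy = NULL,
                            de = list(pseudo = 1e-9, lfc_threshold = 0.25,
                                      p_threshold = 0.01, min_cells = 100,
                                      focal_identities = c("CDIC", "PT S3")),
                            gsea = NULL,
                            ptlike_clustering = NULL) {
  seed <- as.integer(seed)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  if (is.null(clustering)) clustering <- clustering_params(seed = seed + 1L)
  if (is.null(score_params)) score_params <- module_score_params(seed = seed + 2L)
  if (is.null(dichotomy)) dichotomy <- dichotomy_params(seed = seed + 3L)
  if (is.null(gsea)) gsea <- list(n_perm = 1000L, seed = seed + 4L)
  if (is.null(ptlike_clustering))
    ptlike_clustering <- clustering_params(seed = seed + 6L)
  defaults <- c(simulate = TRUE, qc = TRUE, preprocess = TRUE,
                celltype = TRUE, ptclass = TRUE, de = TRUE, score = TRUE)
  defaults[names(stages)] <- stages
  if (!is.null(input_dir)) defaults["simulate"] <- FALSE
  structure(list(seed = seed, sim = sim, input_dir = input_dir,
                 marker_modules = marker_modules, out_dir = out_dir,
                 stages = defaults, clustering = clustering,
                 score_params = score_params, dichotomy = dichotomy,
                 de = de, gsea = gsea, ptlike_clustering = ptlike_clustering),
            class = "tt_pipeline_config")
}

#' Run the pipeline end to end
#'
#' Executes simulate (or read) -> qc -> preprocess -> celltype -> ptclass
#' -> de -> score per the config's stage toggles, optionally writing all
#' tables plus a machine-readable run manifest (seeds, parameters,
#' per-stage row counts, output file hashes) to `out_dir`. A stage failure
#' aborts with the failing stage named; outputs written so far are kept.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle: `experiment`, `truth` (synthetic runs),
#'   `qc_report`, `norm`, `clust`, `annotation`, `dichotomy`, `de`,
#'   `scores`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "tt_pipeline_config"))
  res <- list(manifest = list(seed = config$seed, stages = list(),
                              outputs = list()))
  stage <- function(name, enabled, fn) {
    if (!enabled) return(invisible(NULL))
    out <- tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res$manifest$stages[[name]] <<- out$counts
    for (nm in names(out$values)) res[[nm]] <<- out$values[[nm]]
    invisible(NULL)
  }
  on <- config$stages

  stage("simulate", on[["simulate"]], function() {
    sim <- simulate_experiment(config$sim)
    modules <- truth_marker_modules(sim$truth)
    lists <- synthetic_gene_lists(sim$truth, seed = config$seed + 5L)
    list(values = list(experiment = sim$experiment, truth = sim$truth,
                       marker_modules = modules, gene_lists = lists),
         counts = list(cells = ncol(sim$experiment$counts),
                       genes = nrow(sim$experiment$counts)))
  })
  if (!on[["simulate"]]) {
    stage("read", TRUE, function() {
      if (is.null(config$input_dir)) stop("no input_dir and simulate disabled")
      exp <- read_tenx(config$input_dir)
      mm <- config$marker_modules
      if (is.character(mm)) mm <- read_marker_modules(mm)
      if (is.null(mm)) stop("marker_modules required when reading external data")
      list(values = list(experiment = exp, marker_modules = mm),
           counts = list(cells = ncol(exp$counts), genes = nrow(exp$counts)))
    })
  }
  stage("qc", on[["qc"]], function() {
    fc <- filter_cells(res$experiment)
    list(values = list(experiment = fc$experiment, qc_report = fc$report),
         counts = list(cells_kept = ncol(fc$experiment$counts)))
  })
  stage("preprocess", on[["preprocess"]], function() {
    norm <- lognormalize(res$experiment)
    hvg <- select_hvg(norm, min(config$clustering$n_hvg, nrow(norm$lognorm)))
    norm <- sex_correct_scale(norm, hvg)
    clust <- pca_cluster_embed(norm, config$clustering)
    list(values = list(norm = norm, clust = clust),
         counts = list(hvg = length(hvg),
                       clusters = length(unique(clust$cluster))))
  })
  stage("celltype", on[["celltype"]], function() {
    scored <- score_modules(res$norm, res$marker_modules, config$score_params)
    ann <- assign_types(scored, res$norm$cell_meta$sex)
    ann <- cbind(res$norm$cell_meta[, c("sample_id", "genotype", "reporter",
                                        "time", "sex")],
                 ann[, c("barcode", "assigned_type", "assigned_module", "score")])
    ann$cluster <- if (!is.null(res$clust)) res$clust$cluster else NA_integer_
    list(values = list(annotation = ann, module_scores = scored$scores),
         counts = list(types = length(unique(ann$assigned_type))))
  })
  stage("ptclass", on[["ptclass"]], function() {
    ann <- res$annotation
    pt_cells <- which(ann$assigned_type %in% pt_types())
    if (length(pt_cells) < 2) stop("no PT cells to classify")
    # module discovery on PT cells of Control samples, both reporter arms
    disc <- intersect(pt_cells,
                      which(res$norm$cell_meta$genotype == "Control"))
    if (length(disc) < 3) disc <- pt_cells
    vg <- top_variable_genes_pt(res$norm, disc,
                                min(config$dichotomy$n_var, nrow(res$norm$lognorm) - 1))
    rho <- spearman_matrix(res$norm, vg, disc)
    anchors <- if (!is.null(res$truth))
      res$truth$gene$symbol[res$truth$gene$role == "moduleA"] else NULL
    dich <- detect_anticorrelated_modules(rho, config$dichotomy, anchor_A = anchors)
    ann$pt_class <- NA_character_
    if (dich$detected) {
      cls <- classify_pt_cells(res$norm, dich$module_A, dich$module_B,
                               pt_cells, config$dichotomy,
                               module_score_params(seed = config$dichotomy$seed))
      ann$pt_class[pt_cells] <- cls$pt_class
    }
    list(values = list(annotation = ann, dichotomy = dich),
         counts = list(detected = dich$detected,
                       module_A = length(dich$module_A),
                       module_B = length(dich$module_B)))
  })
  stage("de", on[["de"]], function() {
    de <- run_de_stage(res$norm, res$annotation, config$de)
    list(values = list(de = de),
         counts = list(contrasts = length(de$tables),
                       identities_tested = length(de$per_identity)))
  })
  stage("score", on[["score"]], function() {
    sc <- run_score_stage(res, config)
    list(values = list(scores = sc),
         counts = list(pt_clusters = length(sc$pt_like$pt_clusters)))
  })

  res$manifest$parameters <- config_summary(config)
  if (!is.null(config$out_dir)) res <- write_pipeline_outputs(res, config)
  res
}

# the four DE schemes: pooled early contrast + companion, time contrast +
# companion, per-identity DE (> min_cells strictly, each condition),
# identity- and class-specificity, cross-identity PCA, replicate concordance
run_de_stage <- function(norm, ann, p) {
  meta <- norm$cell_meta
  sel <- function(...) select_cells(meta, ..., annotation = ann)
  tables <- list(); skipped <- list()
  de_or_skip <- function(name, c1, c2, min_cells = 1) {
    if (length(c1) <= min_cells || length(c2) <= min_cells) {
      skipped[[name]] <<- sprintf("group sizes %d vs %d (need > %d)",
                                  length(c1), length(c2), min_cells)
      return(NULL)
    }
    tables[[name]] <<- wilcoxon_de(norm, c1, c2, pseudo = p$pseudo,
                                   lfc_threshold = p$lfc_threshold,
                                   p_threshold = p$p_threshold)
    tables[[name]]
  }
  de_pos <- de_or_skip("early_positive",
                       sel(genotype = "KO", reporter = "positive", time = "early"),
                       sel(genotype = "Control", reporter = "positive", time = "early"))
  de_neg <- de_or_skip("early_negative",
                       sel(genotype = "KO", reporter = "negative", time = "early"),
                       sel(genotype = "Control", reporter = "negative", time = "early"))
  vhl <- if (!is.null(de_pos) && !is.null(de_neg))
    vhl_regulated_early(de_pos, de_neg) else NULL
  de_tko <- de_or_skip("time_ko",
                       sel(genotype = "KO", reporter = "positive", time = "late"),
                       sel(genotype = "KO", reporter = "positive", time = "early"))
  de_tctrl <- de_or_skip("time_control",
                         sel(genotype = "Control", reporter = "positive", time = "late"),
                         sel(genotype = "Control", reporter = "positive", time = "early"))
  tsp <- if (!is.null(de_tko) && !is.null(de_tctrl))
    time_regulated_ko(de_tko, de_tctrl) else NULL

  idents <- sort(unique(ann$assigned_type))
  per_identity <- list()
  for (id in idents) {
    c1 <- sel(genotype = "KO", reporter = "positive", time = "early", identity = id)
    c2 <- sel(genotype = "Control", reporter = "positive", time = "early", identity = id)
    d <- de_or_skip(paste0("identity:", id), c1, c2, min_cells = p$min_cells)
    if (!is.null(d)) per_identity[[id]] <- d
  }
  identity_specific <- list()
  for (focal in intersect(p$focal_identities, names(per_identity)))
    identity_specific[[focal]] <- identity_specific_genes(per_identity, focal)

  per_class <- list()
  for (cl in c("A", "B")) {
    c1 <- sel(genotype = "KO", reporter = "positive", time = "early", pt_class = cl)
    c2 <- sel(genotype = "Control", reporter = "positive", time = "early", pt_class = cl)
    d <- de_or_skip(paste0("class:", cl), c1, c2, min_cells = p$min_cells)
    if (!is.null(d)) per_class[[paste("PT Class", cl)]] <- d
  }
  class_specific <- if (length(per_class) == 2)
    identity_specific_genes(per_class, "PT Class A") else NULL

  cross_pca <- NULL
  if (length(per_identity) >= 3) {
    union_genes <- unique(unlist(lapply(per_identity, function(d)
      d$gene[d$regulated != "none"])))
    if (length(union_genes) >= 2) {
      lfc <- t(vapply(per_identity, function(d)
        d$log2fc[match(union_genes, d$gene)], numeric(length(union_genes))))
      colnames(lfc) <- union_genes
      cross_pca <- crossidentity_pca(lfc)
    }
  }
  concordance <- NULL
  if (!is.null(vhl)) {
    reg <- vhl$gene[vhl$vhl_specific_early != "none"]
    n_ko <- length(unique(meta$sample_id[meta$genotype == "KO" &
                                           meta$reporter == "positive" &
                                           meta$time == "early"]))
    if (length(reg) > 0 && n_ko >= 2)
      concordance <- replicate_concordance(norm, reg, time = "early")
  }
  list(tables = tables, skipped = skipped, vhl_specific = vhl,
       time_specific = tsp, per_identity = per_identity,
       identity_specific = identity_specific, per_class = per_class,
       class_specific = class_specific, cross_pca = cross_pca,
       concordance = concordance)
}

run_score_stage <- function(res, config) {
  norm <- res$norm; ann <- res$annotation
  # PT-like detection uses its own clustering of the reporter-positive samples
  pos <- which(norm$cell_meta$reporter == "positive")
  norm_pos <- lognormalize(subset_cells(res$experiment, pos))
  hvg <- select_hvg(norm_pos, min(config$ptlike_clustering$n_hvg,
                                  nrow(norm_pos$lognorm)))
  norm_pos <- sex_correct_scale(norm_pos, hvg)
  clust_pos <- pca_cluster_embed(norm_pos, config$ptlike_clustering)
  ann_pos <- ann[match(norm_pos$cell_meta$barcode, ann$barcode), ]
  ann_pos$cluster <- clust_pos$cluster
  pt_like <- identify_pt_like(ann_pos)

  gsea <- NULL
  de <- res$de
  if (!is.null(de$tables$time_ko) && !is.null(de$vhl_specific)) {
    ranking <- stats::setNames(de$tables$time_ko$log2fc, de$tables$time_ko$gene)
    sets <- list(
      early_upregulated = de$vhl_specific$gene[de$vhl_specific$vhl_specific_early == "up"],
      known_hif_targets = intersect(res$gene_lists$hif_targets, names(ranking)))
    sets <- sets[lengths(lapply(sets, intersect, names(ranking))) > 0]
    if (length(sets))
      gsea <- gsea_preranked_sets(ranking, sets, n_perm = config$gsea$n_perm,
                                  seed = config$gsea$seed)
  }
  ccrcc <- if (!is.null(res$gene_lists))
    score_ccrcc_modules(norm, res$gene_lists, config$score_params, ann) else NULL
  cycling <- cycling_proportion(res$experiment, ann)
  list(pt_like = pt_like, gsea = gsea, ccrcc = ccrcc, cycling = cycling)
}

config_summary <- function(config) {
  list(seed = config$seed,
       clustering = unclass(config$clustering)[c("n_hvg", "n_pcs", "resolution",
                                                 "knn_k", "seed")],
       score_params = unclass(config$score_params),
       dichotomy = unclass(config$dichotomy)[c("n_var", "linkage", "cut_k",
                                               "min_module_size",
                                               "class_A_threshold", "seed")],
       de = config$de, gsea = config$gsea,
       sim = if (!is.null(config$sim))
         unclass(config$sim)[c("seed", "n_samples_per_arm", "cells_per_sample",
                               "n_genes", "frac_class_A",
                               "ptlike_fraction_late_KO",
                               "negative_sort_contamination")])
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- character(0)
  if (!is.null(res$qc_report)) paths <- c(paths, w(res$qc_report, "qc_report.tsv"))
  if (!is.null(res$annotation)) paths <- c(paths, w(res$annotation, "annotation.tsv"))
  if (!is.null(res$dichotomy) && res$dichotomy$detected) {
    mod <- data.frame(gene = c(res$dichotomy$module_A, res$dichotomy$module_B),
                      module = rep(c("A", "B"),
                                   c(length(res$dichotomy$module_A),
                                     length(res$dichotomy$module_B))))
    paths <- c(paths, w(mod, "pt_modules.tsv"))
  }
  for (nm in names(res$de$tables))
    paths <- c(paths, w(res$de$tables[[nm]],
                        paste0("de_", gsub("[^A-Za-z0-9]+", "_", nm), ".tsv")))
  if (!is.null(res$de$vhl_specific))
    paths <- c(paths, w(res$de$vhl_specific, "vhl_specific_early.tsv"))
  if (!is.null(res$de$time_specific))
    paths <- c(paths, w(res$de$time_specific, "time_specific_ko.tsv"))
  if (!is.null(res$scores$gsea)) paths <- c(paths, w(res$scores$gsea, "gsea.tsv"))
  if (!is.null(res$scores$pt_like))
    paths <- c(paths, w(res$scores$pt_like$proportions, "pt_like_proportions.tsv"))
  if (!is.null(res$scores$cycling))
    paths <- c(paths, w(res$scores$cycling$by_condition, "cycling_by_condition.tsv"))
  hashes <- tools::md5sum(paths)
  res$manifest$outputs <- as.list(stats::setNames(unname(hashes), basename(paths)))
  jsonlite::write_json(res$manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res
}
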