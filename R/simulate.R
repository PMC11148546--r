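#' Default renal cell-type composition table
#'
#' Baseline mixture of renal cell types in tdTomato-negative (whole-kidney)
#' and tdTomato-positive (Pax8-restricted tubular epithelium) sorted
#' fractions. Proportions per arm sum to 1. "Injured PT" is a planted
#' de-differentiated state with zero baseline proportion: the generator
#' converts a fraction of late KO-positive PT cells into it.
#'
#' @return data.frame with columns `type`, `prop_negative`, `prop_positive`,
#'   `epithelial` (TRUE for Pax8-targeted tubular epithelium, the
#'   compartment carrying the core Vhl-regulated program), `is_pt`.
#' @export
default_cell_types <- function() {
  tab <- data.frame(
    type = c("PT S1", "PT S2", "PT S3", "LoH DTL", "LoH ATL", "LoH TAL",
             "DCT", "CNT", "CD PC", "CDIC", "Podocyte", "Endothelial",
             "Fibroblast", "Macrophage", "T cell", "Injured PT"),
    prop_negative = c(.10, .10, .10, .03, .03, .08, .05, .04, .05, .05,
                      .05, .12, .10, .06, .04, 0),
    prop_positive = c(.15, .15, .15, .03, .02, .09, .07, .04, .07, .10,
                      .03, .04, .03, .01, .02, 0),
    epithelial = c(rep(TRUE, 10), FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  tab$is_pt <- tab$type %in% c("PT S1", "PT S2", "PT S3")
  tab
}

pt_types <- function() c("PT S1", "PT S2", "PT S3")

#' Simulation configuration
#'
#' Parameters of the chimeric-kidney generator. Defaults realize the study
#' design at desk scale: a 2 (genotype) x 2 (reporter) x 2 (time) x 2 (sex)
#' design with `n_samples_per_arm` replicates, negative-binomial UMI counts
#' (gamma-Poisson, log-normal gene base means), planted cell-type markers,
#' an anticorrelated PT Class A/B module pair, a core + identity-specific
#' Vhl-regulated program in KO-positive epithelium, time-regulated genes,
#' a de-differentiated PT-like subpopulation at the late KO time point,
#' an Mki67 proliferation burst in early KO-positive epithelium,
#' mitochondrial content, a sex-shifted gene set, and imperfect negative
#' sorting (a small fraction of KO-negative cells resampled from the
#' KO-positive generative process).
#'
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config including this seed.
#' @param n_samples_per_arm replicates per design arm (16 arms).
#' @param cells_per_sample cells per sorted sample.
#' @param n_genes total genes, including planted roles.
#' @param cell_type_table as [default_cell_types()].
#' @param n_markers_per_type planted (sex-shared) markers per type.
#' @param marker_log2fc log2 elevation of a marker in its own type.
#' @param pt_module_size_A,pt_module_size_B planted PT module sizes.
#' @param pt_module_log2fc log2 elevation of a module in its own class.
#' @param frac_class_A probability a PT cell is Class A.
#' @param core_regulated list(n_up, log2fc): core program upregulated in all
#'   KO-positive epithelial identities.
#' @param core_late_log2fc additional late-time amplification of the core
#'   program in KO-positive epithelium (the hypoxic program deepens with
#'   time), making the core/HIF sets enriched in the late-vs-early ranking.
#' @param identity_specific_regulated named list, identity -> list(n_genes,
#'   log2fc, direction) of programs regulated only in that identity.
#' @param time_regulated list(n_up, n_down, log2fc): genes regulated late vs
#'   early specifically in KO-positive cells.
#' @param ptlike_fraction_late_KO probability a late KO-positive PT cell
#'   de-differentiates (segment-marker means attenuated >= 50%, injury
#'   markers and Mki67 elevated, Class module program retained).
#' @param mki67_early_KO_boost fold boost of Mki67 mean in early KO-positive
#'   epithelial cells.
#' @param mito_gene_count,mito_fraction_mean mitochondrial gene count and
#'   target mean mitochondrial UMI fraction.
#' @param libsize_lognormal c(mu, sigma) of the per-cell size factor.
#' @param nb_dispersion gamma-Poisson dispersion (variance of the mean-1
#'   gamma multiplier); must be > 0.
#' @param negative_sort_contamination fraction of KO-negative cells drawn
#'   from the KO-positive generative process.
#' @param n_sex_genes,sex_log2fc globally sex-shifted gene set (elevated in
#'   males), exercising the per-sex correction.
#' @param module_activity_sd SD of the per-cell log-normal activity factor
#'   shared by all genes of a PT module (creates within-module correlation).
#' @param n_sex_markers_s2s3 extra sex-restricted markers per sex for each
#'   of PT S2 and PT S3.
#' @return a `tt_sim_config` list.
#' @export
sim_config <- function(seed = 0L,
                       n_samples_per_arm = 1L,
                       cells_per_sample = 750L,
                       n_genes = 2000L,
                       cell_type_table = default_cell_types(),
                       n_markers_per_type = 10L,
                       marker_log2fc = 3.0,
                       pt_module_size_A = 60L,
                       pt_module_size_B = 60L,
                       pt_module_log2fc = 1.2,
                       frac_class_A = 0.5,
                       core_regulated = list(n_up = 30L, log2fc = 1.5),
                       core_late_log2fc = 0.5,
                       identity_specific_regulated = list(
                         "CDIC"  = list(n_genes = 15L, log2fc = 1.5, direction = "up"),
                         "PT S3" = list(n_genes = 15L, log2fc = 1.5, direction = "up")),
                       time_regulated = list(n_up = 25L, n_down = 25L, log2fc = 1.5),
                       ptlike_fraction_late_KO = 0.10,
                       mki67_early_KO_boost = 6,
                       mito_gene_count = 13L,
                       mito_fraction_mean = 0.08,
                       libsize_lognormal = c(mu = 0, sigma = 0.35),
                       nb_dispersion = 0.1,
                       negative_sort_contamination = 0.02,
                       n_sex_genes = 30L,
                       sex_log2fc = 1.0,
                       module_activity_sd = 0.25,
                       n_sex_markers_s2s3 = 2L) {
  cfg <- as.list(environment())
  class(cfg) <- "tt_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  tab <- cfg$cell_type_table
  if (abs(sum(tab$prop_negative) - 1) > 1e-9 ||
      abs(sum(tab$prop_positive) - 1) > 1e-9)
    stop("cell type proportions per arm must sum to 1")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$frac_class_A < 0 || cfg$frac_class_A > 1)
    stop("frac_class_A must lie in [0, 1]")
  if (cfg$negative_sort_contamination < 0 || cfg$negative_sort_contamination >= 1)
    stop("negative_sort_contamination must lie in [0, 1)")
  demand <- n_planted_genes(cfg)
  if (demand >= cfg$n_genes)
    stop(sprintf("gene-role demands (%d) exceed n_genes (%d)", demand, cfg$n_genes))
  invisible(cfg)
}

n_planted_genes <- function(cfg) {
  n_types <- nrow(cfg$cell_type_table)
  spec_n <- sum(vapply(cfg$identity_specific_regulated,
                       function(x) as.integer(x$n_genes), integer(1)))
  n_types * cfg$n_markers_per_type +
    4L * cfg$n_sex_markers_s2s3 +
    cfg$pt_module_size_A + cfg$pt_module_size_B +
    as.integer(cfg$core_regulated$n_up) + spec_n +
    as.integer(cfg$time_regulated$n_up) + as.integer(cfg$time_regulated$n_down) +
    cfg$mito_gene_count + cfg$n_sex_genes + 1L  # + Mki67
}

# assign symbols and roles to the gene panel; returns gene table + index sets
build_gene_panel <- function(cfg) {
  n <- cfg$n_genes
  sym <- sprintf("Gene%04d", seq_len(n))
  sym[seq_len(cfg$mito_gene_count)] <- sprintf("mt-Sim%02d", seq_len(cfg$mito_gene_count))
  role <- rep("null", n)
  role[seq_len(cfg$mito_gene_count)] <- "mito"
  cursor <- cfg$mito_gene_count
  take <- function(k) {
    idx <- cursor + seq_len(k); cursor <<- cursor + k; idx
  }
  i_mki <- take(1L); sym[i_mki] <- "Mki67"; role[i_mki] <- "mki67"
  types <- cfg$cell_type_table$type
  markers <- list()
  for (t in types) {
    idx <- take(cfg$n_markers_per_type)
    role[idx] <- paste0("marker:", t)
    markers[[t]] <- idx
  }
  sex_markers <- list()
  for (t in intersect(c("PT S2", "PT S3"), types)) {
    for (sx in c("F", "M")) {
      idx <- take(cfg$n_sex_markers_s2s3)
      role[idx] <- paste0("marker_sex:", t, ":", sx)
      sex_markers[[paste(t, sx)]] <- idx
    }
  }
  i_modA <- take(cfg$pt_module_size_A); role[i_modA] <- "moduleA"
  i_modB <- take(cfg$pt_module_size_B); role[i_modB] <- "moduleB"
  i_core <- take(as.integer(cfg$core_regulated$n_up)); role[i_core] <- "core_up"
  spec <- list()
  for (id in names(cfg$identity_specific_regulated)) {
    idx <- take(as.integer(cfg$identity_specific_regulated[[id]]$n_genes))
    role[idx] <- paste0("specific:", id)
    spec[[id]] <- idx
  }
  i_tup <- take(as.integer(cfg$time_regulated$n_up)); role[i_tup] <- "time_up"
  i_tdn <- take(as.integer(cfg$time_regulated$n_down)); role[i_tdn] <- "time_down"
  i_sex <- take(cfg$n_sex_genes); role[i_sex] <- "sex"
  list(symbol = sym, role = role,
       mito = seq_len(cfg$mito_gene_count), mki67 = i_mki,
       markers = markers, sex_markers = sex_markers,
       modA = i_modA, modB = i_modB, core = i_core, spec = spec,
       time_up = i_tup, time_down = i_tdn, sex = i_sex)
}

# per-gene base mean counts; planted roles drawn from detectable strata
draw_base_means <- function(cfg, panel) {
  n <- cfg$n_genes
  lam <- pmin(stats::rlnorm(n, meanlog = log(0.5), sdlog = 1.2), 30)
  planted <- panel$role != "null"
  for (t in names(panel$markers)) lam[panel$markers[[t]]] <- stats::runif(cfg$n_markers_per_type, 0.12, 0.20)
  for (k in names(panel$sex_markers)) lam[panel$sex_markers[[k]]] <- stats::runif(length(panel$sex_markers[[k]]), 0.12, 0.20)
  lam[panel$modA] <- stats::runif(length(panel$modA), 0.6, 1.0)
  lam[panel$modB] <- stats::runif(length(panel$modB), 0.6, 1.0)
  for (idx in list(panel$core, panel$time_up, panel$time_down))
    lam[idx] <- stats::runif(length(idx), 0.4, 0.8)
  for (id in names(panel$spec)) lam[panel$spec[[id]]] <- stats::runif(length(panel$spec[[id]]), 0.4, 0.8)
  lam[panel$sex] <- stats::runif(length(panel$sex), 0.3, 0.7)
  lam[panel$mki67] <- 0.12
  # mitochondrial means set to hit the target mean mito fraction
  non_mito_total <- sum(lam[-panel$mito])
  mito_total <- cfg$mito_fraction_mean / (1 - cfg$mito_fraction_mean) * non_mito_total
  w <- stats::runif(length(panel$mito), 0.5, 1.5)
  lam[panel$mito] <- mito_total * w / sum(w)
  lam
}

#' Simulate a chimeric-kidney scRNA-seq experiment
#'
#' Draws one sorted sample per design arm (and replicate), concatenates them,
#' and returns the counts with design metadata plus the planted ground truth
#' used by recovery tests.
#'
#' @param config a [sim_config()].
#' @return list with elements `experiment` (a [tt_experiment()]) and
#'   `truth` (class `tt_truth`: `$cell` per-cell true labels, `$gene`
#'   per-gene role labels).
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    panel <- build_gene_panel(cfg)
    lam <- draw_base_means(cfg, panel)
    # per-gene effect sizes: the stated program log2FC is the center of a
    # +/-40% spread, fixed once per gene (a regulated program spans a range
    # of effect magnitudes, which also gives replicate fold-change vectors
    # their correlatable structure)
    eff <- rep(NA_real_, cfg$n_genes)
    spread <- function(idx, center, lo = 0.6, hi = 1.4)
      center * stats::runif(length(idx), lo, hi)
    eff[panel$core] <- spread(panel$core, cfg$core_regulated$log2fc)
    # identity-specific programs are tested in few-hundred-cell contrasts;
    # their spread stays above the design's Bonferroni detection floor
    for (id in names(cfg$identity_specific_regulated))
      eff[panel$spec[[id]]] <- spread(panel$spec[[id]],
                                      cfg$identity_specific_regulated[[id]]$log2fc,
                                      lo = 0.8)
    eff[panel$time_up] <- spread(panel$time_up, cfg$time_regulated$log2fc)
    eff[panel$time_down] <- spread(panel$time_down, cfg$time_regulated$log2fc)
    arms <- expand.grid(genotype = c("Control", "KO"),
                        reporter = c("positive", "negative"),
                        time = c("early", "late"),
                        sex = c("F", "M"),
                        rep = seq_len(cfg$n_samples_per_arm),
                        stringsAsFactors = FALSE)
    blocks <- vector("list", nrow(arms))
    cells <- vector("list", nrow(arms))
    for (a in seq_len(nrow(arms))) {
      arm <- arms[a, ]
      sid <- sprintf("%s_%s_%s_%s_%d", arm$genotype,
                     substr(arm$reporter, 1, 3), arm$time, arm$sex, arm$rep)
      sim <- simulate_sample(cfg, panel, lam, eff, arm, sid)
      blocks[[a]] <- sim$counts
      cells[[a]] <- sim$cell
    }
    counts <- do.call(cbind, blocks)
    cell <- do.call(rbind, cells)
    rownames(counts) <- panel$symbol
    colnames(counts) <- cell$barcode
    gene_meta <- data.frame(symbol = panel$symbol,
                            is_mito = panel$role == "mito",
                            stringsAsFactors = FALSE)
    exp <- tt_experiment(counts, cell[, c("barcode", "sample_id", "genotype",
                                          "reporter", "time", "sex")], gene_meta)
    truth <- structure(list(
      cell = cell[, c("barcode", "sample_id", "true_type", "true_class",
                      "true_segment", "is_pt_like", "is_cycling",
                      "is_contaminated")],
      gene = data.frame(symbol = panel$symbol, role = panel$role,
                        effect_log2fc = eff, stringsAsFactors = FALSE)),
      class = "tt_truth")
    list(experiment = exp, truth = truth)
  })
}

# one sorted sample: draw types, latent states, means, then NB counts
simulate_sample <- function(cfg, panel, lam, eff, arm, sid) {
  n <- cfg$cells_per_sample
  if (n < 1) stop("cells_per_sample must be >= 1")
  tab <- cfg$cell_type_table
  pos_p <- tab$prop_positive; neg_p <- tab$prop_negative
  positive <- arm$reporter == "positive"
  # imperfect negative sorting: some KO-negative cells are really recombined
  contaminated <- if (!positive && arm$genotype == "KO")
    stats::runif(n) < cfg$negative_sort_contamination else rep(FALSE, n)
  effective_pos <- positive | contaminated
  type <- character(n)
  if (any(effective_pos))
    type[effective_pos] <- sample(tab$type, sum(effective_pos), TRUE, pos_p)
  if (any(!effective_pos))
    type[!effective_pos] <- sample(tab$type, sum(!effective_pos), TRUE, neg_p)
  is_pt <- type %in% pt_types()
  true_class <- rep(NA_character_, n)
  true_class[is_pt] <- ifelse(stats::runif(sum(is_pt)) < cfg$frac_class_A, "A", "B")
  # de-differentiation of late KO-positive PT cells
  ptlike <- is_pt & effective_pos & arm$genotype == "KO" & arm$time == "late" &
    stats::runif(n) < cfg$ptlike_fraction_late_KO
  segment <- type           # original PT segment, kept for marker attenuation
  type[ptlike] <- "Injured PT"
  epi <- tab$epithelial[match(type, tab$type)]
  mki_boost <- effective_pos & arm$genotype == "KO" & arm$time == "early" & epi
  cycling <- mki_boost | ptlike

  sf <- exp(stats::rnorm(n, cfg$libsize_lognormal[["mu"]], cfg$libsize_lognormal[["sigma"]]))
  mu <- outer(lam, sf)

  colmul <- function(rows, cols, f) {
    if (length(rows) && length(cols))
      mu[rows, cols] <<- mu[rows, cols] * rep(f, each = length(rows))
  }
  # per-gene (row-recycled) multiplier across a set of cells
  rowmul <- function(rows, cols, fvec) {
    if (length(rows) && length(cols))
      mu[rows, cols] <<- mu[rows, cols] * fvec
  }
  for (t in unique(type)) {
    idx <- which(type == t & !(t == "Injured PT"))
    colmul(panel$markers[[t]], idx, 2^cfg$marker_log2fc)
  }
  # PT-like cells: injury markers on, own segment markers attenuated >= 50%
  if (any(ptlike)) {
    inj <- which(ptlike)
    # injury program with per-cell intensity variation (keeps the
    # de-differentiated cells a smear toward PT, not a tight island)
    colmul(panel$markers[["Injured PT"]], inj,
           2^cfg$marker_log2fc * exp(stats::rnorm(length(inj), 0, 0.4)))
    atten <- stats::runif(length(inj), 0.15, 0.5)
    for (s in pt_types()) {
      j <- inj[segment[inj] == s]
      if (length(j))
        colmul(panel$markers[[s]], j, 2^cfg$marker_log2fc * atten[match(j, inj)])
    }
    colmul(panel$mki67, inj, 4)
  }
  # sex-restricted S2/S3 markers
  for (t in c("PT S2", "PT S3")) {
    key <- paste(t, arm$sex)
    idx <- which(segment == t)
    colmul(panel$sex_markers[[key]], idx, 2^cfg$marker_log2fc)
  }
  # PT Class A/B: anticorrelated module programs with shared per-cell activity
  pt_or_inj <- which(is_pt)   # includes converted PT-like cells (program retained)
  if (length(pt_or_inj)) {
    actA <- exp(stats::rnorm(length(pt_or_inj), 0, cfg$module_activity_sd))
    actB <- exp(stats::rnorm(length(pt_or_inj), 0, cfg$module_activity_sd))
    isA <- true_class[pt_or_inj] == "A"
    colmul(panel$modA, pt_or_inj, actA * 2^(cfg$pt_module_log2fc * isA))
    colmul(panel$modB, pt_or_inj, actB * 2^(cfg$pt_module_log2fc * !isA))
  }
  # Vhl-regulated programs in recombined (effective-positive) KO cells
  ko_pos <- which(effective_pos & arm$genotype == "KO")
  rowmul(panel$core, ko_pos[epi[ko_pos]], 2^eff[panel$core])
  for (id in names(cfg$identity_specific_regulated)) {
    prog <- cfg$identity_specific_regulated[[id]]
    sgn <- if (identical(prog$direction, "down")) -1 else 1
    rowmul(panel$spec[[id]], ko_pos[type[ko_pos] == id],
           2^(sgn * eff[panel$spec[[id]]]))
  }
  if (arm$time == "late") {
    rowmul(panel$time_up, ko_pos, 2^eff[panel$time_up])
    rowmul(panel$time_down, ko_pos, 2^(-eff[panel$time_down]))
    colmul(panel$core, ko_pos[epi[ko_pos]], 2^cfg$core_late_log2fc)
  }
  colmul(panel$mki67, which(mki_boost), cfg$mki67_early_KO_boost)
  if (arm$sex == "M") colmul(panel$sex, seq_len(n), 2^cfg$sex_log2fc)
  colmul(panel$mito, seq_len(n), exp(stats::rnorm(n, 0, 0.4)))

  counts <- matrix(stats::rpois(length(mu),
                                mu * stats::rgamma(length(mu),
                                                   shape = 1 / cfg$nb_dispersion,
                                                   rate = 1 / cfg$nb_dispersion)),
                   nrow = nrow(mu))
  counts <- as_dgc(counts)
  cell <- data.frame(
    barcode = sprintf("%s-%05d", sid, seq_len(n)),
    sample_id = sid, genotype = arm$genotype, reporter = arm$reporter,
    time = arm$time, sex = arm$sex,
    true_type = type, true_class = true_class,
    true_segment = ifelse(segment %in% pt_types(), segment, NA_character_),
    is_pt_like = ptlike, is_cycling = cycling, is_contaminated = contaminated,
    stringsAsFactors = FALSE)
  cell$true_class[cell$true_type == "Injured PT"] <- NA_character_
  list(counts = counts, cell = cell)
}

#' Planted marker-gene modules from ground truth
#'
#' Builds the fixture marker-module table a synthetic run feeds to
#' [assign_types()]: one module per planted cell type, with sex-restricted
#' variants for PT S2 and PT S3 (sex-shared markers plus that sex's
#' restricted markers), mirroring the use of sex-specific S2/S3 modules.
#'
#' @param truth a `tt_truth` object.
#' @return data.frame with columns `module`, `type`, `sex`, `gene`.
#' @export
truth_marker_modules <- function(truth) {
  g <- truth$gene
  out <- list()
  types <- unique(sub("^marker:", "", g$role[startsWith(g$role, "marker:")]))
  for (t in types) {
    shared <- g$symbol[g$role == paste0("marker:", t)]
    if (t %in% c("PT S2", "PT S3")) {
      for (sx in c("F", "M")) {
        extra <- g$symbol[g$role == paste0("marker_sex:", t, ":", sx)]
        out[[paste(t, sx)]] <- data.frame(
          module = sprintf("%s (%s)", t, sx), type = t, sex = sx,
          gene = c(shared, extra), stringsAsFactors = FALSE)
      }
    } else {
      out[[t]] <- data.frame(module = t, type = t, sex = "any",
                             gene = shared, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Synthetic HIF-target and ccRCC gene lists
#'
#' Fixture lists with the containment structure of the curated annotations
#' (HIF targets; ccRCC-upregulated genes split into HIF and non-HIF driven):
#' the HIF list contains the planted core Vhl-regulated program plus
#' unrelated genes; ccRCC-up-HIF is the core program (a subset of HIF);
#' ccRCC-up-non-HIF is disjoint from the HIF list and contains the planted
#' time-downregulated genes (so its score declines late, as in tumors'
#' non-HIF genes) plus null genes. Synthetic stand-ins, not curated biology.
#'
#' @param truth a `tt_truth`.
#' @param n_extra_hif,n_extra_nonhif null genes padded into each list.
#' @param seed RNG seed for the padding draw.
#' @return list of character vectors `hif_targets`, `ccrcc_up_hif`,
#'   `ccrcc_up_nonhif`.
#' @export
synthetic_gene_lists <- function(truth, n_extra_hif = 40L,
                                 n_extra_nonhif = 15L, seed = 0L) {
  g <- truth$gene
  core <- g$symbol[g$role == "core_up"]
  tdn <- g$symbol[g$role == "time_down"]
  nulls <- g$symbol[g$role == "null"]
  with_seed(seed, {
    pad_hif <- sample(nulls, n_extra_hif)
    pad_non <- sample(setdiff(nulls, pad_hif), n_extra_nonhif)
  })
  list(hif_targets = c(core, pad_hif),
       ccrcc_up_hif = core,
       ccrcc_up_nonhif = c(tdn, pad_non))
}
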