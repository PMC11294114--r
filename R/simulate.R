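# Synthetic study generator.
#
# Emulates the 2x2 genotype-by-treatment mouse design: per-mouse NB gene
# counts with a multiplicative dosage effect on a triplicated segment
# (MMU16/MMU17), optional complete restoration of a rescued subset under
# treatment, genome-wide trans effects, L1 loci placed relative to genes, RNA
# pooling of mice in threes, and behavioural discrimination indices coupled to
# a per-pool expression ratio index. Ground truth is recorded for
# parameter-recovery tests.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_counts()]. Defaults encode
#' the study design being emulated: group sizes 13/17/9/9 mice
#' (TS-t/WT-t/TS-nt/WT-nt), RNA pooled in threes within each
#' (tissue, genotype, treatment) cell, two brain tissues, and a 1.5-fold
#' (3:2 copy-number) expression increase on the triplicated segment.
#'
#' @param n_mice Named integer vector of mice per group; names must be the
#'   four group labels.
#' @param pool_size Mice pooled per RNA sample (default 3).
#' @param tissues Tissues to simulate, subset of `c("CX", "HC")`.
#' @param n_genes,n_l1 Number of gene and L1 features.
#' @param frac_dosage_genes Fraction of genes on the triplicated segment.
#' @param dosage_fold Expression fold-change of dosage genes in trisomic mice
#'   (default 1.5, the naive three-copies-vs-two expectation).
#' @param frac_rescued Fraction of dosage features whose genotype effect is
#'   cancelled in treated trisomic mice.
#' @param rescue_scale Degree of restoration for rescued features (1 =
#'   complete: TS-t mean equals the WT mean).
#' @param trans_effect_sd SD (log2 scale) of genome-wide weak trans genotype
#'   effects on non-dosage genes; 0 disables them.
#' @param frac_strong_trans Fraction of non-dosage genes carrying a strong
#'   trans genotype effect of magnitude `log2(dosage_fold)` with random
#'   sign; these are rescuable like dosage genes, giving the study its
#'   down-regulated (and down-rescued) genes. 0 disables the tier.
#' @param frac_dosage_l1 Fraction of L1 loci with a genotype effect (random
#'   sign, magnitude `log2(dosage_fold)`).
#' @param frac_l1_intragenic,frac_l1_proximal Fractions of L1 loci placed
#'   inside a gene body, respectively within 100 kb of a gene; the remainder
#'   is placed uniformly.
#' @param dispersion_range Range for per-feature NB dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param mean_expression_log_range Range of natural-log per-mouse mean
#'   counts.
#' @param size_factor_sd SD of log-normal per-library depth variation.
#' @param behavior_coupling Slope linking the pool expression ratio index to
#'   DI_4M (DI units per ratio-index unit; negative by default, matching the
#'   observed negative correlation of rescued-gene expression with memory).
#' @param behavior_intercept Baseline DI_4M at ratio index 0.
#' @param di_noise_sd SD of per-mouse DI noise.
#' @param di_baseline_sd SD of the baseline DI (centred at 0).
#' @param total_exploration Total exploration time (seconds) used to
#'   back-solve object exploration times from a DI.
#' @param seed Integer seed recorded in the ground truth.
#' @return A list of class `l1r_sim_config`.
#' @export
sim_config <- function(n_mice = c("TS-t" = 13, "WT-t" = 17, "TS-nt" = 9, "WT-nt" = 9),
                       pool_size = 3,
                       tissues = c("CX", "HC"),
                       n_genes = 2000,
                       n_l1 = 200,
                       frac_dosage_genes = 0.1,
                       dosage_fold = 1.5,
                       frac_rescued = 0.3,
                       rescue_scale = 1,
                       trans_effect_sd = 0.05,
                       frac_strong_trans = 0.02,
                       frac_dosage_l1 = 0.05,
                       frac_l1_intragenic = 0.4,
                       frac_l1_proximal = 0.3,
                       dispersion_range = c(0.05, 0.2),
                       mean_expression_log_range = log(c(50, 5000)),
                       size_factor_sd = 0.1,
                       behavior_coupling = -30,
                       behavior_intercept = 50,
                       di_noise_sd = 15,
                       di_baseline_sd = 10,
                       total_exploration = 40,
                       seed = 1L) {
  if (is.null(names(n_mice)) || !setequal(names(n_mice), GROUP_LEVELS)) {
    abort_validation("n_mice must be named with the four group labels")
  }
  n_mice <- n_mice[GROUP_LEVELS]
  fracs <- c(frac_dosage_genes, frac_rescued, frac_dosage_l1,
             frac_l1_intragenic, frac_l1_proximal, rescue_scale, frac_strong_trans)
  if (any(fracs < 0 | fracs > 1)) abort_validation("fractions must lie in [0, 1]")
  if (frac_l1_intragenic + frac_l1_proximal > 1) {
    abort_validation("frac_l1_intragenic + frac_l1_proximal must not exceed 1")
  }
  if (dosage_fold <= 0) abort_validation("dosage_fold must be positive")
  if (pool_size < 1) abort_validation("pool_size must be >= 1")
  if (!all(tissues %in% TISSUE_LEVELS)) abort_validation("tissues must be CX and/or HC")
  if (diff(range(dispersion_range)) < 0 || any(dispersion_range < 0)) {
    abort_validation("dispersion_range must be non-negative (lo, hi)")
  }
  structure(list(
    n_mice = n_mice, pool_size = pool_size, tissues = tissues,
    n_genes = n_genes, n_l1 = n_l1,
    frac_dosage_genes = frac_dosage_genes, dosage_fold = dosage_fold,
    frac_rescued = frac_rescued, rescue_scale = rescue_scale,
    trans_effect_sd = trans_effect_sd, frac_strong_trans = frac_strong_trans,
    frac_dosage_l1 = frac_dosage_l1,
    frac_l1_intragenic = frac_l1_intragenic, frac_l1_proximal = frac_l1_proximal,
    dispersion_range = dispersion_range,
    mean_expression_log_range = mean_expression_log_range,
    size_factor_sd = size_factor_sd,
    behavior_coupling = behavior_coupling, behavior_intercept = behavior_intercept,
    di_noise_sd = di_noise_sd, di_baseline_sd = di_baseline_sd,
    total_exploration = total_exploration,
    seed = as.integer(seed)
  ), class = "l1r_sim_config")
}

simulate_annotation <- function(config) {
  n_genes <- config$n_genes
  n_dosage <- round(config$frac_dosage_genes * n_genes)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  chroms <- paste0("MMU", 1:19)
  is_dosage <- seq_len(n_genes) <= n_dosage
  gene_chrom <- character(n_genes)
  gene_chrom[is_dosage] <- sample(c("MMU16", "MMU17"), n_dosage, replace = TRUE, prob = c(0.7, 0.3))
  gene_chrom[!is_dosage] <- sample(setdiff(chroms, c("MMU16", "MMU17")),
                                   n_genes - n_dosage, replace = TRUE)
  gene_start <- floor(stats::runif(n_genes, 0, 1e8))
  gene_len <- floor(stats::runif(n_genes, 1e4, 2e5))
  genes <- tibble::tibble(
    feature_id = gene_ids,
    feature_type = "gene",
    chrom = gene_chrom,
    start = gene_start,
    end = gene_start + gene_len,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    hsa21_ortholog = is_dosage,
    biotype = sample(c("protein_coding", "lncRNA", "pseudogene"), n_genes,
                     replace = TRUE, prob = c(0.7, 0.2, 0.1))
  )

  n_l1 <- config$n_l1
  l1_ids <- sprintf("L1_%04d", seq_len(n_l1))
  placement <- sample(c("intragenic", "proximal", "uniform"), n_l1, replace = TRUE,
                      prob = c(config$frac_l1_intragenic, config$frac_l1_proximal,
                               1 - config$frac_l1_intragenic - config$frac_l1_proximal))
  l1_len <- floor(stats::runif(n_l1, 500, 6000))
  host <- sample.int(n_genes, n_l1, replace = TRUE)
  l1_start <- numeric(n_l1)
  l1_chrom <- character(n_l1)
  for (i in seq_len(n_l1)) {
    h <- host[i]
    if (placement[i] == "intragenic") {
      l1_chrom[i] <- genes$chrom[h]
      lo <- genes$start[h]
      hi <- max(lo + 1, genes$end[h] - l1_len[i])
      l1_start[i] <- floor(stats::runif(1, lo, hi))
    } else if (placement[i] == "proximal") {
      l1_chrom[i] <- genes$chrom[h]
      gap <- floor(stats::runif(1, 1, 1e5 - l1_len[i]))
      l1_start[i] <- genes$end[h] + gap
    } else {
      l1_chrom[i] <- sample(chroms, 1)
      l1_start[i] <- floor(stats::runif(1, 0, 1e8))
    }
  }
  l1 <- tibble::tibble(
    feature_id = l1_ids,
    feature_type = "L1",
    chrom = l1_chrom,
    start = l1_start,
    end = l1_start + l1_len,
    strand = sample(c("+", "-"), n_l1, replace = TRUE),
    hsa21_ortholog = FALSE,
    biotype = "L1"
  )
  dplyr::bind_rows(genes, l1)
}

simulate_truth <- function(config, features) {
  n_feat <- nrow(features)
  is_gene <- features$feature_type == "gene"
  is_dosage <- is_gene & features$hsa21_ortholog

  n_dosage_l1 <- round(config$frac_dosage_l1 * sum(!is_gene))
  l1_idx <- which(!is_gene)
  dosage_l1 <- rep(FALSE, n_feat)
  if (n_dosage_l1 > 0) dosage_l1[l1_idx[seq_len(n_dosage_l1)]] <- TRUE

  beta_g <- numeric(n_feat)
  beta_g[is_dosage] <- log2(config$dosage_fold)
  # L1 genotype effects: dosage-magnitude, random sign (both directions seen
  # in trisomic brain)
  beta_g[dosage_l1] <- log2(config$dosage_fold) *
    sample(c(1, -1), sum(dosage_l1), replace = TRUE)
  # strong trans tier: non-dosage genes deregulated in either direction,
  # rescuable like dosage genes (supplies the down-rescued features)
  free <- which(is_gene & !is_dosage)
  n_strong <- round(config$frac_strong_trans * length(free))
  strong_trans <- rep(FALSE, n_feat)
  if (n_strong > 0) {
    strong_trans[sample(free, n_strong)] <- TRUE
    beta_g[strong_trans] <- log2(config$dosage_fold) *
      sample(c(1, -1), n_strong, replace = TRUE)
  }
  is_trans <- is_gene & !is_dosage & !strong_trans & config$trans_effect_sd > 0
  beta_g[is_trans] <- stats::rnorm(sum(is_trans), 0, config$trans_effect_sd)

  rescued <- rep(FALSE, n_feat)
  for (set in list(which(is_dosage), which(dosage_l1), which(strong_trans))) {
    n_res <- round(config$frac_rescued * length(set))
    if (n_res > 0) rescued[sample(set, n_res)] <- TRUE
  }
  beta_int <- numeric(n_feat)
  beta_int[rescued] <- -config$rescue_scale * beta_g[rescued]

  tibble::tibble(
    feature_id = features$feature_id,
    true_log2fc_genotype = beta_g,
    true_log2fc_treatment_interaction = beta_int,
    dispersion = stats::runif(n_feat, config$dispersion_range[1], config$dispersion_range[2]),
    mean_expression = exp(stats::runif(n_feat, config$mean_expression_log_range[1],
                                       config$mean_expression_log_range[2])),
    is_dosage = is_dosage | dosage_l1,
    is_strong_trans = strong_trans,
    is_rescued = rescued,
    is_trans = is_trans | strong_trans,
    seed = config$seed
  )
}

pool_assignment <- function(mice_in_group, pool_size) {
  split(mice_in_group, ceiling(seq_along(mice_in_group) / pool_size))
}

#' Simulate a pooled count study with ground truth
#'
#' Draws per-mouse NB counts `NB(mean = s_m * q_g * 2^(x_m . beta_g),
#' dispersion = alpha_g)` where `x_m` encodes genotype (TS) and the
#' genotype-by-treatment interaction (TS-t), then sums mice into pools of
#' `pool_size` within each (tissue, genotype, treatment) cell; a final smaller
#' pool keeps the remainder. Dosage genes carry `beta = log2(dosage_fold)`;
#' for rescued features the genotype effect is cancelled (scaled by
#' `rescue_scale`) in treated trisomic mice; non-dosage genes may carry
#' Normal(0, `trans_effect_sd`) trans effects.
#'
#' @param config A [sim_config()].
#' @param keep_mouse_counts Keep the per-mouse draws (debug; used to assert
#'   that pooled counts equal member sums).
#' @return A list of class `l1r_sim` with elements `counts`, `features`,
#'   `samples`, `truth`, `config`, and optionally `mouse_counts` (one matrix
#'   per tissue).
#' @export
simulate_counts <- function(config, keep_mouse_counts = FALSE) {
  stopifnot(inherits(config, "l1r_sim_config"))
  if (any(pmax(1L, config$n_mice %/% config$pool_size +
               as.integer(config$n_mice %% config$pool_size > 0)) < 2)) {
    abort_validation("every group needs at least 2 pools; contrasts are impossible otherwise")
  }
  set.seed(config$seed)
  features <- simulate_annotation(config)
  truth <- simulate_truth(config, features)

  groups <- rep(names(config$n_mice), config$n_mice)
  mouse_ids <- unlist(lapply(names(config$n_mice), function(g) {
    sprintf("%s_m%02d", g, seq_len(config$n_mice[[g]]))
  }))
  names(groups) <- mouse_ids
  is_ts <- grepl("^TS", groups)
  is_tst <- groups == "TS-t"

  n_feat <- nrow(features)
  log2_mu0 <- log2(truth$mean_expression)

  sample_rows <- list()
  count_cols <- list()
  mouse_counts <- list()

  for (tissue in config$tissues) {
    s_m <- exp(stats::rnorm(length(mouse_ids), 0, config$size_factor_sd))
    names(s_m) <- mouse_ids
    # feature x mouse means
    beta_part <- outer(truth$true_log2fc_genotype, as.numeric(is_ts)) +
      outer(truth$true_log2fc_treatment_interaction, as.numeric(is_tst))
    mu <- 2^(log2_mu0 + beta_part) * rep(s_m, each = n_feat)
    draws <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / pmax(truth$dispersion, 1e-12)),
      nrow = n_feat, dimnames = list(features$feature_id, mouse_ids)
    )
    if (keep_mouse_counts) mouse_counts[[tissue]] <- draws
    for (g in names(config$n_mice)) {
      pools <- pool_assignment(mouse_ids[groups == g], config$pool_size)
      for (k in seq_along(pools)) {
        sid <- sprintf("%s_%s_p%02d", tissue, g, k)
        count_cols[[sid]] <- unname(rowSums(draws[, pools[[k]], drop = FALSE]))
        sample_rows[[sid]] <- tibble::tibble(
          sample_id = sid, tissue = tissue,
          genotype = sub("-.*$", "", g), treatment = sub("^.*-", "", g),
          pooled_mouse_ids = paste(pools[[k]], collapse = ",")
        )
      }
    }
  }

  counts <- tibble::tibble(feature_id = features$feature_id, !!!count_cols)
  samples <- dplyr::bind_rows(sample_rows)
  samples$group <- group_label(samples$genotype, samples$treatment)

  out <- list(counts = counts, features = features, samples = samples,
              truth = truth, config = config)
  if (keep_mouse_counts) out$mouse_counts <- mouse_counts
  structure(out, class = "l1r_sim")
}

#' Simulate behaviour coupled to a per-pool expression index
#'
#' Each mouse's endpoint discrimination index is
#' `DI_4M = intercept + behavior_coupling * (ratio index of the mouse's pool)
#' + Normal(0, di_noise_sd)`, truncated to `[-100, 100]`; the baseline DI is
#' drawn independently near 0. Exploration times are back-solved so that the
#' DI formula reproduces each DI exactly at a fixed total exploration time.
#'
#' @param samples Sample sheet (with `pooled_mouse_ids`) of the simulated
#'   study.
#' @param ratio_index A tibble with columns `sample_id` and `ratio_index`
#'   (e.g. from [rescue_ratio_index()]), one row per pooled sample; a mouse
#'   appearing in several listed pools gets their mean index.
#' @param config The [sim_config()] used for the study.
#' @param seed Seed for the behavioural noise (default `config$seed + 1`).
#' @return A behaviour tibble with exploration times, `di_baseline`, `di_4m`
#'   and the latent `ratio_index` per mouse.
#' @export
simulate_behavior <- function(samples, ratio_index, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "l1r_sim_config"))
  if (!all(c("sample_id", "ratio_index") %in% names(ratio_index))) {
    abort_format("ratio_index must have columns sample_id and ratio_index")
  }
  use <- samples[samples$sample_id %in% ratio_index$sample_id, , drop = FALSE]
  if (nrow(use) == 0) abort_validation("no sample sheet rows match the ratio_index samples")
  idx <- stats::setNames(ratio_index$ratio_index, ratio_index$sample_id)

  members <- pooled_ids(use$pooled_mouse_ids)
  mouse_tbl <- tibble::tibble(
    mouse_id = unlist(members),
    group = rep(use$group, lengths(members)),
    ri = rep(idx[use$sample_id], lengths(members))
  )
  if (any(is.na(mouse_tbl$ri))) abort_validation("pool lookup failure: missing ratio index")
  mouse_tbl <- mouse_tbl |>
    dplyr::group_by(.data$mouse_id, .data$group) |>
    dplyr::summarise(ratio_index = mean(.data$ri), .groups = "drop") |>
    dplyr::arrange(.data$mouse_id)

  set.seed(seed)
  n <- nrow(mouse_tbl)
  di_4m <- config$behavior_intercept + config$behavior_coupling * mouse_tbl$ratio_index +
    stats::rnorm(n, 0, config$di_noise_sd)
  di_4m <- pmin(100, pmax(-100, di_4m))
  di_base <- pmin(100, pmax(-100, stats::rnorm(n, 0, config$di_baseline_sd)))

  tot <- config$total_exploration
  solve_times <- function(di) {
    t_novel <- tot * (1 + di / 100) / 2
    cbind(t_novel = t_novel, t_familiar = tot - t_novel)
  }
  t4 <- solve_times(di_4m)
  tb <- solve_times(di_base)
  tibble::tibble(
    mouse_id = mouse_tbl$mouse_id,
    group = mouse_tbl$group,
    t_novel_baseline = tb[, 1], t_familiar_baseline = tb[, 2],
    t_novel_4m = t4[, 1], t_familiar_4m = t4[, 2],
    di_baseline = di_base, di_4m = di_4m,
    ratio_index = mouse_tbl$ratio_index
  )
}

#' Write a simulated study to disk
#'
#' Writes `counts.tsv`, `samples.tsv`, `features.bedlike.tsv`, `truth.tsv`
#' and, when supplied, `behavior.tsv` into `out_dir` via the package readers'
#' counterpart writers.
#'
#' @param sim A result of [simulate_counts()].
#' @param out_dir Output directory (created if absent).
#' @param behavior Optional behaviour tibble from [simulate_behavior()].
#' @param force Overwrite an existing non-empty directory.
#' @return The output directory, invisibly.
#' @export
write_fixture <- function(sim, out_dir, behavior = NULL, force = FALSE) {
  stopifnot(inherits(sim, "l1r_sim"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort_validation(paste0("output directory '", out_dir, "' is non-empty; use force = TRUE"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
  write_sample_sheet(sim$samples, file.path(out_dir, "samples.tsv"))
  write_annotation(sim$features, file.path(out_dir, "features.bedlike.tsv"))
  readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"), quote = "none",
                   escape = "none", progress = FALSE)
  if (!is.null(behavior)) write_behavior(behavior, file.path(out_dir, "behavior.tsv"))
  invisible(out_dir)
}
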