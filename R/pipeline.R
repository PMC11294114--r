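# End-to-end orchestration: simulate (or load) -> differential expression ->
# rescue -> L1 summaries -> behaviour -> enrichment, with per-tissue TSV
# outputs and a machine-readable JSON summary. Re-running with the same
# configuration and seed is byte-identical.

DEFAULT_CONTRASTS <- list(
  c("TS-nt", "WT-nt"),  # genotype effect
  c("TS-t", "TS-nt"),   # treatment effect in TS
  c("WT-t", "WT-nt"),   # treatment effect in WT
  c("TS-t", "WT-nt")    # treated trisomic vs untreated wild type
)

#' Pipeline configuration
#'
#' Either simulate a study (`sim` = a [sim_config()]) or analyse files on
#' disk (`paths` = named list with `counts`, `samples`, `features`, and
#' optionally `behavior` and `gene_sets`).
#'
#' @param sim A [sim_config()]; its seed is overwritten by `seed`.
#' @param paths Named list of input file paths (alternative to `sim`).
#' @param contrasts List of `c(group_a, group_b)` pairs run in every tissue;
#'   defaults to the four study contrasts (genotype, treatment within each
#'   genotype, treated-trisomic vs untreated-wild-type).
#' @param rule,alpha,p_threshold,lfc_threshold DE call thresholds, see
#'   [call_de()].
#' @param min_total Low-count filter, see [wald_test()].
#' @param direction_check Stricter rescue mode, see [rescued_features()].
#' @param l1_window Nearest-gene window in bases.
#' @param seed Integer seed recorded in the summary and used for any
#'   simulation.
#' @return A list of class `l1r_run_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, contrasts = NULL,
                            rule = "padj_le", alpha = 0.1, p_threshold = 0.05,
                            lfc_threshold = 1.5, min_total = 10,
                            direction_check = FALSE, l1_window = 100000,
                            seed = 1L) {
  if (is.null(sim) == is.null(paths)) {
    abort_validation("supply exactly one of sim (a sim_config) or paths")
  }
  if (!is.null(paths)) {
    need <- c("counts", "samples", "features")
    miss <- setdiff(need, names(paths))
    if (length(miss) > 0) abort_validation(paste0("paths missing: ", paste(miss, collapse = ", ")))
  }
  contrasts <- contrasts %||% DEFAULT_CONTRASTS
  labels <- unlist(contrasts)
  if (!all(labels %in% GROUP_LEVELS)) abort_validation("contrast groups must be defined group labels")
  structure(list(
    sim = sim, paths = paths, contrasts = contrasts, rule = rule, alpha = alpha,
    p_threshold = p_threshold, lfc_threshold = lfc_threshold,
    min_total = min_total, direction_check = direction_check,
    l1_window = l1_window, seed = as.integer(seed)
  ), class = "l1r_run_config")
}

write_pipe_tsv <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name), quote = "none", escape = "none",
                   progress = FALSE)
}

#' Run the full analysis pipeline
#'
#' Per tissue: the configured contrasts (NB Wald DE), the rescue report with
#' HSA21-ortholog fraction, L1 transcript fractions with pairwise group
#' comparisons and nearest-gene assignments, learner classification, the
#' rescued-gene ratio index and its Spearman correlation with DI_4M, and
#' (when gene sets are available) over-representation of the rescued genes.
#' All tables are written as TSV under `out_dir` together with
#' `summary.json`.
#'
#' @param config An [pipeline_config()].
#' @param out_dir Output directory (created; must be empty unless `force`).
#' @param force Overwrite an existing non-empty directory.
#' @param gene_sets Optional gene-set tibble (see [read_gmt()]) used for
#'   enrichment, overriding `config$paths$gene_sets`.
#' @return The summary (a nested list), invisibly; written as
#'   `summary.json`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, gene_sets = NULL) {
  stopifnot(inherits(config, "l1r_run_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort_validation(paste0("output directory '", out_dir, "' is non-empty; use force = TRUE"))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  behavior <- NULL
  if (!is.null(config$sim)) {
    simcfg <- config$sim
    simcfg$seed <- config$seed
    sim <- simulate_counts(simcfg)
    counts <- sim$counts; samples <- sim$samples; features <- sim$features
    # behaviour generated from the true rescued sets' ratio index in the
    # first simulated tissue
    truth <- sim$truth
    up_true <- truth$feature_id[truth$is_rescued & truth$true_log2fc_genotype > 0]
    down_true <- truth$feature_id[truth$is_rescued & truth$true_log2fc_genotype < 0]
    t1 <- simcfg$tissues[1]
    s1 <- samples[samples$tissue == t1, , drop = FALSE]
    cnt1 <- counts[, c("feature_id", s1$sample_id)]
    norm1 <- normalized_counts(cnt1, estimate_size_factors(cnt1))
    if (length(up_true) > 0 && length(down_true) > 0) {
      ri <- rescue_ratio_index(norm1, up_true, down_true)
    } else {
      # degenerate truth (e.g. null model): flat index, no coupling signal
      ri <- tibble::tibble(sample_id = s1$sample_id,
                           ratio_index = rep(1, nrow(s1)))
    }
    behavior <- simulate_behavior(samples, ri, simcfg)
    write_pipe_tsv(truth, out_dir, "truth.tsv")
  } else {
    counts <- read_count_matrix(config$paths$counts)
    samples <- read_sample_sheet(config$paths$samples)
    features <- read_annotation(config$paths$features)
    if (!is.null(config$paths$behavior)) behavior <- read_behavior(config$paths$behavior)
    if (is.null(gene_sets) && !is.null(config$paths$gene_sets)) {
      gene_sets <- read_gmt(config$paths$gene_sets)
    }
  }
  if (!is.null(behavior)) write_pipe_tsv(behavior, out_dir, "behavior.tsv")

  genotype_pair <- c("TS-nt", "WT-nt")
  treated_pair <- c("TS-t", "WT-nt")

  call_from <- function(res) {
    call_de(res, rule = config$rule, alpha = config$alpha,
            p_threshold = config$p_threshold, lfc_threshold = config$lfc_threshold)
  }

  summary <- list(seed = config$seed, rule = config$rule,
                  thresholds = list(alpha = config$alpha,
                                    p_threshold = config$p_threshold,
                                    lfc_threshold = config$lfc_threshold),
                  tissues = list())

  for (tis in sort(unique(samples$tissue))) {
    tdir <- file.path(out_dir, tis)
    dir.create(tdir, showWarnings = FALSE)
    smp <- samples[samples$tissue == tis, , drop = FALSE]
    cnt <- counts[, c("feature_id", smp$sample_id)]
    tsum <- list()

    results <- list()
    for (pair in config$contrasts) {
      res <- de_contrast(cnt, smp, pair[1], pair[2], tissue = tis,
                         min_total = config$min_total)
      key <- paste0(pair[1], ":", pair[2])
      results[[key]] <- res
      fname <- paste0("de_", gsub(":", "_vs_", key), ".tsv")
      write_pipe_tsv(as.data.frame(res), tdir, fname)
      cl <- call_from(res)
      tsum$contrasts[[key]] <- list(
        n_tested = sum(!res$filtered),
        n_de = nrow(cl),
        n_up = sum(cl$direction == "up"),
        n_down = sum(cl$direction == "down")
      )
    }

    gkey <- paste0(genotype_pair[1], ":", genotype_pair[2])
    tkey <- paste0(treated_pair[1], ":", treated_pair[2])
    rescue_sum <- NULL
    ri <- NULL
    if (!is.null(results[[gkey]]) && !is.null(results[[tkey]])) {
      call_g <- call_from(results[[gkey]])
      call_t <- call_from(results[[tkey]])
      rescued <- rescued_features(call_g, call_t,
                                  direction_check = config$direction_check,
                                  result_treated = results[[tkey]])
      write_pipe_tsv(as.data.frame(rescued), tdir, "rescue.tsv")
      ofrac <- if (nrow(rescued) > 0) ortholog_fraction(rescued, features) else NA_real_
      rescue_sum <- list(
        n_rescued = nrow(rescued),
        n_up = sum(rescued$direction == "up"),
        n_down = sum(rescued$direction == "down"),
        ortholog_fraction = ofrac,
        empty = nrow(rescued) == 0
      )
      up <- rescued$feature_id[rescued$direction == "up"]
      down <- rescued$feature_id[rescued$direction == "down"]
      norm <- normalized_counts(cnt, estimate_size_factors(cnt))
      if (length(up) > 0 && length(down) > 0) {
        ri <- rescue_ratio_index(norm, up, down)
        write_pipe_tsv(ri, tdir, "ratio_index.tsv")
      }

      if (!is.null(gene_sets)) {
        gene_ids <- features$feature_id[features$feature_type == "gene"]
        universe <- intersect(attr(rescued, "universe"), gene_ids)
        query <- intersect(rescued$feature_id, gene_ids)
        if (length(query) > 0) {
          enr <- enrich_sets(query, gene_sets, universe)
          write_pipe_tsv(as.data.frame(enr), tdir, "enrich_rescued.tsv")
          tsum$enrichment <- list(n_sets_tested = nrow(enr),
                                  n_sets_padj_05 = sum(enr$padj <= 0.05))
        }
      }
    }
    tsum$rescue <- rescue_sum

    # L1 arm
    lf <- l1_fraction(cnt, features)
    write_pipe_tsv(lf, tdir, "l1_fraction.tsv")
    lcomp <- compare_l1_fraction(lf, smp)
    write_pipe_tsv(lcomp, tdir, "l1_fraction_tests.tsv")
    assign <- nearest_gene(features[features$feature_type == "L1", ],
                           features[features$feature_type == "gene", ],
                           window = config$l1_window)
    write_pipe_tsv(assign, tdir, "l1_nearest_gene.tsv")
    tsum$l1 <- list(
      mean_fraction = mean(lf$l1_fraction),
      min_comparison_p = if (nrow(lcomp) > 0) min(lcomp$p) else NA_real_,
      n_intragenic = sum(assign$relation == "intragenic"),
      n_proximal = sum(assign$relation == "proximal")
    )

    # behaviour arm
    if (!is.null(behavior)) {
      classified <- classify_learners(behavior)
      write_pipe_tsv(classified, tdir, "learners.tsv")
      tsum$behavior <- list(
        n_good = sum(classified$learner_class == "good"),
        n_poor = sum(classified$learner_class == "poor")
      )
      if (!is.null(ri)) {
        cor_tbl <- correlate_expression_with_di(ri, smp, behavior)
        write_pipe_tsv(cor_tbl, tdir, "ratio_index_di_correlation.tsv")
        tsum$behavior$ratio_index_rho <- cor_tbl$rho[1]
        tsum$behavior$ratio_index_p <- cor_tbl$p[1]
      }
    }

    summary$tissues[[tis]] <- tsum
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(summary)
}

#' Sample-level PCA overview
#'
#' Projects the per-feature-centred `log2(normalised + 1)` matrix onto its
#' first two principal axes; the scores are the standard QC view of sample
#' relatedness. Scores have zero mean on each axis; the rotation and centre
#' are attached as attributes.
#'
#' @param normalized A normalised count table with at least 3 samples.
#' @return A tibble with columns `sample_id`, `PC1`, `PC2` and attributes
#'   `rotation`, `center`, `var_explained`.
#' @export
qc_overview <- function(normalized) {
  m <- counts_to_matrix(normalized)
  if (ncol(m) < 3) abort_validation("PCA overview needs at least 3 samples")
  x <- t(log2(m + 1))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  out <- tibble::tibble(sample_id = rownames(x),
                        PC1 = pc$x[, 1], PC2 = pc$x[, 2])
  attr(out, "rotation") <- pc$rotation[, 1:2, drop = FALSE]
  attr(out, "center") <- pc$center
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[1:2]
  out
}
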