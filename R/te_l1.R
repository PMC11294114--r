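# LINE-1 locus summaries: transcript fraction, group comparison, and
# nearest-gene assignment. Differential expression and rescue of L1 loci use
# the same engine as genes (wald_test / rescued_features on the L1 rows).

#' Per-sample L1 transcript fraction
#'
#' The sum of counts on L1 features divided by the total counts of the
#' sample, i.e. the share of the transcriptome assigned to LINE-1 loci.
#'
#' @param counts A count table containing gene and L1 features.
#' @param features Annotation distinguishing `feature_type` gene vs L1.
#' @return A tibble with columns `sample_id` and `l1_fraction`.
#' @export
l1_fraction <- function(counts, features) {
  m <- counts_to_matrix(counts)
  types <- stats::setNames(features$feature_type, features$feature_id)[rownames(m)]
  if (any(is.na(types))) abort_validation("count features missing from the annotation")
  total <- colSums(m)
  if (any(total == 0)) {
    abort_validation(paste0("zero total counts for sample(s): ",
                            paste(colnames(m)[total == 0], collapse = ", ")))
  }
  l1_sum <- colSums(m[types == "L1", , drop = FALSE])
  tibble::tibble(sample_id = colnames(m), l1_fraction = unname(l1_sum / total))
}

#' Pairwise group comparison of L1 fractions
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of groups' fraction
#' vectors (the same engine as [rank_sum_test()]). Groups with fewer than 2
#' samples are skipped with a warning.
#'
#' @param fractions A tibble from [l1_fraction()].
#' @param samples A sample sheet with a `group` column.
#' @return A tibble with one row per group pair: `group_a`, `group_b`,
#'   `n_a`, `n_b`, `statistic`, `p`.
#' @export
compare_l1_fraction <- function(fractions, samples) {
  if (!"group" %in% names(samples)) {
    samples$group <- group_label(samples$genotype, samples$treatment)
  }
  grp <- stats::setNames(samples$group, samples$sample_id)[fractions$sample_id]
  if (any(is.na(grp))) abort_validation("fraction samples missing from the sample sheet")
  by_group <- split(fractions$l1_fraction, grp)
  sizes <- vapply(by_group, length, integer(1))
  small <- names(by_group)[sizes < 2]
  if (length(small) > 0) {
    rlang::warn(paste0("group(s) with <2 samples skipped: ", paste(small, collapse = ", ")))
    by_group <- by_group[sizes >= 2]
  }
  gs <- names(by_group)
  if (length(gs) < 2) abort_validation("need at least two groups with 2+ samples")
  pairs <- utils::combn(gs, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    res <- rank_sum_test(by_group[[a]], by_group[[b]])
    tibble::tibble(group_a = a, group_b = b,
                   n_a = length(by_group[[a]]), n_b = length(by_group[[b]]),
                   statistic = res$statistic, p = res$p)
  })
}

# Interval gap between [s1, e1) and [s2, e2): 0 if they overlap or touch.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Nearest-gene assignment for L1 loci
#'
#' Each L1 interval is classified `intragenic` when it overlaps a gene
#' interval by at least 1 bp (distance 0), otherwise `proximal` to the
#' nearest gene on the same chromosome within `window` bases (distance = the
#' interval gap; touching intervals under the half-open convention have gap
#' 0 but, having no shared base, count as proximal), otherwise
#' `distal_none`. Ties are broken by smaller gene start, then lexicographic
#' gene id. Strand is ignored.
#'
#' @param l1_features,gene_features Annotation tables (0-based half-open
#'   coordinates) for the L1 loci and genes.
#' @param window Maximum gap for a proximal assignment (default 100 kb).
#' @return A tibble with columns `l1_id`, `gene_id` (NA when none),
#'   `relation`, `distance`.
#' @export
nearest_gene <- function(l1_features, gene_features, window = 100000) {
  purrr::map_dfr(seq_len(nrow(l1_features)), function(i) {
    l1 <- l1_features[i, ]
    cand <- gene_features[gene_features$chrom == l1$chrom, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(tibble::tibble(l1_id = l1$feature_id, gene_id = NA_character_,
                            relation = "distal_none", distance = NA_real_))
    }
    overlap <- cand$start < l1$end & l1$start < cand$end
    if (any(overlap)) {
      hit <- cand[overlap, , drop = FALSE]
      hit <- hit[order(hit$start, hit$feature_id), , drop = FALSE]
      return(tibble::tibble(l1_id = l1$feature_id, gene_id = hit$feature_id[1],
                            relation = "intragenic", distance = 0))
    }
    gap <- interval_gap(l1$start, l1$end, cand$start, cand$end)
    near <- gap <= window
    if (!any(near)) {
      return(tibble::tibble(l1_id = l1$feature_id, gene_id = NA_character_,
                            relation = "distal_none", distance = NA_real_))
    }
    hit <- cand[near, , drop = FALSE]
    g <- gap[near]
    o <- order(g, hit$start, hit$feature_id)
    tibble::tibble(l1_id = l1$feature_id, gene_id = hit$feature_id[o[1]],
                   relation = "proximal", distance = g[o[1]])
  })
}
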