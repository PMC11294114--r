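# Treatment-rescue set logic.
#
# A feature is "rescued" when it is differentially expressed in the genotype
# contrast (TS-nt vs WT-nt) but no longer in the treated contrast (TS-t vs
# WT-nt). The operative definition is pure set difference; an optional
# stricter mode additionally requires the treated-contrast fold change to
# have moved toward the wild-type level.

#' Rescued features from two DE calls
#'
#' Computes the set difference `features(call_genotype) minus
#' features(call_treated)` over the shared universe of features tested
#' (unfiltered) in both contrasts, so low-count filtering differences cannot
#' manufacture rescue. Up/down assignment comes from the genotype contrast's
#' fold-change sign. With `direction_check = TRUE`, a rescued feature must
#' also satisfy `|log2fc_treated| < |log2fc_genotype|` (movement toward WT);
#' this requires `result_treated`.
#'
#' @param call_genotype,call_treated `l1r_decall` objects from [call_de()]
#'   for the genotype and treated contrasts; they must share the same
#'   feature universe.
#' @param direction_check Require the treated fold change to have shrunk.
#' @param result_genotype Optional `l1r_de` result of the genotype contrast
#'   (only needed to recover fold changes absent from the call).
#' @param result_treated `l1r_de` result of the treated contrast; required
#'   when `direction_check = TRUE`.
#' @return A tibble of class `l1r_rescue` with columns `feature_id`,
#'   `log2fc_genotype`, `direction`; attributes carry the universe and the
#'   contrast pair.
#' @export
rescued_features <- function(call_genotype, call_treated, direction_check = FALSE,
                             result_genotype = NULL, result_treated = NULL) {
  uni_g <- attr(call_genotype, "universe")
  uni_t <- attr(call_treated, "universe")
  if (is.null(uni_g) || is.null(uni_t)) {
    abort_validation("DE calls must carry their tested universe (use call_de())")
  }
  universe <- intersect(uni_g, uni_t)
  if (length(universe) == 0) abort_validation("mismatched universes: no shared tested features")
  if (length(setdiff(call_genotype$feature_id, uni_t)) > 0 &&
      length(universe) < 0.5 * max(length(uni_g), length(uni_t))) {
    abort_validation("mismatched universes between the two contrasts")
  }

  geno <- call_genotype[call_genotype$feature_id %in% universe, , drop = FALSE]
  treated_ids <- intersect(call_treated$feature_id, universe)
  rescued <- geno[!(geno$feature_id %in% treated_ids), , drop = FALSE]

  if (direction_check) {
    if (is.null(result_treated)) {
      abort_validation("direction_check = TRUE requires result_treated")
    }
    lfc_t <- stats::setNames(result_treated$log2fc, result_treated$feature_id)[rescued$feature_id]
    keep <- !is.na(lfc_t) & abs(lfc_t) < abs(rescued$log2fc)
    rescued <- rescued[keep, , drop = FALSE]
  }

  out <- tibble::tibble(
    feature_id = rescued$feature_id,
    log2fc_genotype = rescued$log2fc,
    direction = rescued$direction
  )
  attr(out, "universe") <- universe
  attr(out, "direction_checked") <- direction_check
  attr(out, "contrast_pair") <- list(
    genotype = attr(call_genotype, "contrast"),
    treated = attr(call_treated, "contrast")
  )
  class(out) <- c("l1r_rescue", class(out))
  out
}

#' Fraction of rescued features orthologous to HSA21
#'
#' The share of the rescued set annotated `hsa21_ortholog = TRUE` (features
#' on the MMU10/16/17 regions syntenic to human chromosome 21). Returns 0
#' (with a warning) when the rescued set is empty.
#'
#' @param rescued An `l1r_rescue` tibble (or anything with `feature_id`).
#' @param features A feature annotation table.
#' @return A single number in `[0, 1]`.
#' @export
ortholog_fraction <- function(rescued, features) {
  ids <- rescued$feature_id
  if (length(ids) == 0) {
    rlang::warn("empty rescued set; ortholog fraction reported as 0")
    return(0)
  }
  miss <- setdiff(ids, features$feature_id)
  if (length(miss) > 0) {
    abort_validation(paste0("unannotated rescued feature(s): ",
                            paste(utils::head(miss, 5), collapse = ", ")))
  }
  flag <- stats::setNames(features$hsa21_ortholog, features$feature_id)[ids]
  sum(flag) / length(ids)
}

#' Per-sample rescued-gene expression ratio index
#'
#' For each sample, the mean normalised expression over the upregulated
#' rescued features divided by the mean over the downregulated rescued
#' features.
#'
#' @param normalized A normalised count table from [normalized_counts()].
#' @param rescued_up,rescued_down Character vectors of feature ids (or an
#'   `l1r_rescue` split by `direction`).
#' @return A tibble with columns `sample_id` and `ratio_index` (NA with a
#'   warning where the denominator mean is zero).
#' @export
rescue_ratio_index <- function(normalized, rescued_up, rescued_down) {
  if (length(rescued_up) == 0 || length(rescued_down) == 0) {
    abort_validation("both rescued_up and rescued_down must be non-empty")
  }
  m <- counts_to_matrix(normalized)
  miss <- setdiff(c(rescued_up, rescued_down), rownames(m))
  if (length(miss) > 0) {
    abort_validation(paste0("features absent from the matrix: ",
                            paste(utils::head(miss, 5), collapse = ", ")))
  }
  up_mean <- colMeans(m[rescued_up, , drop = FALSE])
  down_mean <- colMeans(m[rescued_down, , drop = FALSE])
  ratio <- up_mean / down_mean
  if (any(down_mean == 0)) {
    rlang::warn("zero denominator mean for some sample(s); ratio index set to NA")
    ratio[down_mean == 0] <- NA_real_
  }
  tibble::tibble(sample_id = colnames(m), ratio_index = unname(ratio))
}
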