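# Tabular IO for the shared study formats.
#
# All genomic coordinates in this package are 0-based, half-open intervals
# (BED convention): a feature covering the first 100 bases of a chromosome has
# start = 0, end = 100. GTF-style 1-based inputs must be shifted before use.
# Files are TSV, UTF-8, unquoted; missing strand is ".".

GROUP_LEVELS <- c("TS-t", "TS-nt", "WT-t", "WT-nt")
TISSUE_LEVELS <- c("CX", "HC")
GENOTYPE_LEVELS <- c("TS", "WT")
TREATMENT_LEVELS <- c("t", "nt")
STRAND_LEVELS <- c("+", "-", ".")

abort_format <- function(msg) {
  rlang::abort(msg, class = "l1rescue_format_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "l1rescue_validation_error")
}

#' Group label from genotype and treatment
#'
#' Combines a genotype (`"TS"` or `"WT"`) and a treatment (`"t"` for treated,
#' `"nt"` for non-treated) into the group labels used throughout the package:
#' `"TS-t"`, `"TS-nt"`, `"WT-t"`, `"WT-nt"`.
#'
#' @param genotype Character vector of genotypes.
#' @param treatment Character vector of treatments.
#' @return Character vector of group labels.
#' @export
#' @examples
#' group_label("TS", "nt")
group_label <- function(genotype, treatment) {
  stopifnot(all(genotype %in% GENOTYPE_LEVELS), all(treatment %in% TREATMENT_LEVELS))
  paste(genotype, treatment, sep = "-")
}

sample_columns <- function(counts) {
  setdiff(names(counts), "feature_id")
}

counts_to_matrix <- function(counts) {
  m <- as.matrix(counts[, sample_columns(counts), drop = FALSE])
  rownames(m) <- counts$feature_id
  storage.mode(m) <- "double"
  m
}

matrix_to_counts <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

#' Validate a count table
#'
#' Checks that a count table is a data frame with a `feature_id` first column,
#' unique feature ids, and non-negative integer-valued counts in every cell.
#'
#' @param counts A data frame with column `feature_id` plus one numeric column
#'   per sample.
#' @return The validated table, invisibly.
#' @export
validate_counts <- function(counts) {
  if (!is.data.frame(counts) || names(counts)[1] != "feature_id") {
    abort_format("count table must be a data frame with first column 'feature_id'")
  }
  if (anyDuplicated(counts$feature_id)) {
    dup <- unique(counts$feature_id[duplicated(counts$feature_id)])
    abort_validation(paste0("duplicate feature_id(s): ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  smp <- sample_columns(counts)
  if (length(smp) == 0) abort_format("count table has no sample columns")
  for (s in smp) {
    v <- counts[[s]]
    if (!is.numeric(v)) abort_format(paste0("non-numeric counts in sample '", s, "'"))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      abort_format(paste0(
        "non-integer or negative count at feature '", counts$feature_id[bad[1]],
        "', sample '", s, "'"
      ))
    }
  }
  invisible(counts)
}

#' Read / write a feature-by-sample count matrix
#'
#' The file is TSV with a header row naming the samples, a first column
#' `feature_id`, and non-negative integer cells. Ordering is preserved.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `feature_id` plus one integer-valued double column per
#'   sample.
#' @export
read_count_matrix <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  if (names(counts)[1] != "feature_id") {
    abort_format("first column of a count matrix must be 'feature_id'")
  }
  validate_counts(counts)
  counts
}

#' @rdname read_count_matrix
#' @param counts A validated count table.
#' @export
write_count_matrix <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, quote = "none", escape = "none", progress = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' A sample sheet has columns `sample_id`, `tissue` (CX/HC), `genotype`
#' (TS/WT), `treatment` (t/nt) and `pooled_mouse_ids` (comma-separated mouse
#' ids, at least one per sample). Sample ids must be unique.
#'
#' @param samples A data frame.
#' @return The validated sheet, invisibly.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "tissue", "genotype", "treatment", "pooled_mouse_ids")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) abort_format(paste0("sample sheet missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(samples$sample_id)) abort_validation("duplicate sample_id in sample sheet")
  bad <- setdiff(unique(samples$tissue), TISSUE_LEVELS)
  if (length(bad) > 0) abort_validation(paste0("unknown tissue value(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(samples$genotype), GENOTYPE_LEVELS)
  if (length(bad) > 0) abort_validation(paste0("unknown genotype value(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(samples$treatment), TREATMENT_LEVELS)
  if (length(bad) > 0) abort_validation(paste0("unknown treatment value(s): ", paste(bad, collapse = ", ")))
  if (any(is.na(samples$pooled_mouse_ids) | samples$pooled_mouse_ids == "")) {
    abort_validation("pooled_mouse_ids must be non-empty for every sample")
  }
  invisible(samples)
}

#' Read / write a sample sheet
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per (pooled) sample and a derived `group`
#'   column (`genotype-treatment`).
#' @export
read_sample_sheet <- function(path) {
  samples <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  validate_samples(samples)
  samples$group <- group_label(samples$genotype, samples$treatment)
  samples
}

#' @rdname read_sample_sheet
#' @param samples A validated sample sheet.
#' @export
write_sample_sheet <- function(samples, path) {
  validate_samples(samples)
  out <- samples[, c("sample_id", "tissue", "genotype", "treatment", "pooled_mouse_ids")]
  readr::write_tsv(out, path, quote = "none", escape = "none", progress = FALSE)
  invisible(path)
}

#' Split pooled mouse ids
#'
#' @param pooled_mouse_ids Character vector of comma-separated mouse ids.
#' @return A list of character vectors, one per sample.
#' @export
pooled_ids <- function(pooled_mouse_ids) {
  strsplit(pooled_mouse_ids, ",", fixed = TRUE)
}

#' Validate a feature annotation table
#'
#' Columns: `feature_id`, `feature_type` (gene/L1), `chrom`, `start`, `end`
#' (0-based half-open, `end > start`), `strand` (+/-/.), `hsa21_ortholog`
#' (logical) and `biotype`. The HSA21-ortholog flag may be TRUE only for
#' features on the configured ortholog chromosomes (default MMU10, MMU16,
#' MMU17, the mouse regions syntenic to human chromosome 21).
#'
#' @param features A data frame.
#' @param ortholog_chroms Chromosomes on which `hsa21_ortholog` may be TRUE.
#' @return The validated table, invisibly.
#' @export
validate_features <- function(features, ortholog_chroms = c("MMU10", "MMU16", "MMU17")) {
  need <- c("feature_id", "feature_type", "chrom", "start", "end", "strand",
            "hsa21_ortholog", "biotype")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0) abort_format(paste0("annotation missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(features$feature_id)) abort_validation("duplicate feature_id in annotation")
  bad <- setdiff(unique(features$feature_type), c("gene", "L1"))
  if (length(bad) > 0) abort_validation(paste0("unknown feature_type value(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(features$strand), STRAND_LEVELS)
  if (length(bad) > 0) abort_validation(paste0("unknown strand value(s): ", paste(bad, collapse = ", ")))
  if (any(features$start < 0)) abort_validation("negative start coordinate")
  if (any(features$end <= features$start)) {
    bad_id <- features$feature_id[which(features$end <= features$start)[1]]
    abort_validation(paste0("end must exceed start (half-open intervals): feature '", bad_id, "'"))
  }
  if (!is.logical(features$hsa21_ortholog)) abort_format("hsa21_ortholog must be logical")
  off <- features$hsa21_ortholog & !(features$chrom %in% ortholog_chroms)
  if (any(off)) {
    abort_validation(paste0(
      "hsa21_ortholog = TRUE outside ortholog chromosomes for: ",
      paste(utils::head(features$feature_id[off], 5), collapse = ", ")
    ))
  }
  invisible(features)
}

#' Read / write a feature annotation table
#'
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param path Path to a TSV file.
#' @param ortholog_chroms Chromosomes on which `hsa21_ortholog` may be TRUE.
#' @return A validated tibble.
#' @export
read_annotation <- function(path, ortholog_chroms = c("MMU10", "MMU16", "MMU17")) {
  features <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(),
    feature_type = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    strand = readr::col_character(),
    hsa21_ortholog = readr::col_logical(),
    biotype = readr::col_character()
  ), progress = FALSE)
  validate_features(features, ortholog_chroms)
  features
}

#' @rdname read_annotation
#' @param features A validated annotation table.
#' @export
write_annotation <- function(features, path) {
  validate_features(features)
  out <- features[, c("feature_id", "feature_type", "chrom", "start", "end",
                      "strand", "hsa21_ortholog", "biotype")]
  readr::write_tsv(out, path, quote = "none", escape = "none", progress = FALSE)
  invisible(path)
}

#' Read / write a GMT gene-set collection
#'
#' Each GMT line is `set_id <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a set are removed on load (first occurrence kept).
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `description` and a list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short)) abort_format("GMT line with fewer than 3 fields (set_id, description, members)")
  sets <- tibble::tibble(
    set_id = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(sets$set_id)) abort_validation("duplicate set_id in GMT")
  if (any(vapply(sets$members, length, integer(1)) == 0)) {
    abort_validation("gene set with no members")
  }
  sets
}

#' @rdname read_gmt
#' @param sets A gene-set tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$description[i], sets$members[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read / write a behaviour table
#'
#' Exploration times (seconds) for the novel and familiar object at baseline
#' and after the 4-month treatment window. Discrimination indices may be
#' supplied directly instead via `di_baseline` / `di_4m` columns.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per mouse.
#' @export
read_behavior <- function(path) {
  behavior <- readr::read_tsv(path, col_types = readr::cols(
    mouse_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("mouse_id", "group")
  miss <- setdiff(need, names(behavior))
  if (length(miss) > 0) abort_format(paste0("behaviour table missing column(s): ", paste(miss, collapse = ", ")))
  has_times <- all(c("t_novel_baseline", "t_familiar_baseline", "t_novel_4m", "t_familiar_4m") %in% names(behavior))
  has_di <- all(c("di_baseline", "di_4m") %in% names(behavior))
  if (!has_times && !has_di) {
    abort_format("behaviour table needs exploration-time columns or di_baseline/di_4m")
  }
  bad <- setdiff(unique(behavior$group), GROUP_LEVELS)
  if (length(bad) > 0) abort_validation(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  if (anyDuplicated(behavior$mouse_id)) abort_validation("duplicate mouse_id in behaviour table")
  behavior
}

#' @rdname read_behavior
#' @param behavior A behaviour tibble.
#' @export
write_behavior <- function(behavior, path) {
  readr::write_tsv(behavior, path, quote = "none", escape = "none", progress = FALSE)
  invisible(path)
}
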