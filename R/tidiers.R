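# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x An `l1r_de` tibble.
#' @param ... Ignored.
#' @return A plain tibble of the per-feature statistics.
#' @exportS3Method generics::tidy
tidy.l1r_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "l1r_de")
  out
}

#' One-row summary of a differential-expression result
#'
#' @param x An `l1r_de` tibble.
#' @param alpha Adjusted p-value cutoff counted as significant.
#' @param ... Ignored.
#' @return A one-row tibble: contrast name, features, tested, filtered and
#'   significant counts.
#' @exportS3Method generics::glance
glance.l1r_de <- function(x, alpha = 0.1, ...) {
  ct <- attr(x, "contrast")
  tibble::tibble(
    contrast = if (!is.null(ct)) ct$name else NA_character_,
    n_features = nrow(x),
    n_tested = sum(!x$filtered),
    n_filtered = sum(x$filtered),
    n_significant = sum(!is.na(x$padj) & x$padj <= alpha)
  )
}

#' @rdname tidy.l1r_de
#' @exportS3Method generics::tidy
tidy.l1r_rescue <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "l1r_rescue")
  out
}

#' One-row summary of a rescue report
#'
#' @param x An `l1r_rescue` tibble.
#' @param ... Ignored.
#' @return A one-row tibble with rescued counts and whether the direction
#'   check was applied.
#' @exportS3Method generics::glance
glance.l1r_rescue <- function(x, ...) {
  tibble::tibble(
    n_rescued = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_universe = length(attr(x, "universe")),
    direction_checked = isTRUE(attr(x, "direction_checked"))
  )
}

#' @rdname tidy.l1r_de
#' @exportS3Method generics::tidy
tidy.l1r_enrich <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "l1r_enrich")
  out
}

#' One-row summary of an enrichment result
#'
#' @param x An `l1r_enrich` tibble.
#' @param alpha Adjusted p-value cutoff counted as significant.
#' @param ... Ignored.
#' @return A one-row tibble of tested and significant set counts.
#' @exportS3Method generics::glance
glance.l1r_enrich <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_sets_tested = nrow(x),
    n_sets_significant = sum(x$padj <= alpha)
  )
}
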