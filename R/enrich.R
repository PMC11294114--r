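# Over-representation analysis against user-supplied gene-set collections.
# The catalogue is never shipped: sets come from a GMT file (see read_gmt()).

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: draw `n` features from a
#' universe of `N` containing `K` set members, and count members drawn.
#' Computed by summing exponentials of log binomial coefficients for
#' numerical stability.
#'
#' @param k Observed overlap.
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The upper-tail probability.
#' @export
#' @examples
#' hypergeom_upper_tail(4, 5, 4, 10)
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    abort_validation("inconsistent hypergeometric parameters")
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  feasible <- (n - i) <= (N - K)
  i <- i[feasible]
  if (length(i) == 0) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

#' Over-representation of a query set in a gene-set collection
#'
#' Intersects each set with the universe, tests every set with at least one
#' member in the universe and an overlap of at least `min_overlap` against
#' the upper-tail hypergeometric null, and BH-adjusts across the tested
#' sets. `gene_ratio` is overlap / query size, the quantity plotted in
#' enrichment dot plots.
#'
#' @param query Character vector of feature ids (must lie in `universe`).
#' @param collection A gene-set tibble from [read_gmt()].
#' @param universe Character vector of background feature ids (e.g. all
#'   unfiltered features of the tested tissue).
#' @param min_overlap Minimum overlap for a set to be tested (default 2).
#' @return A tibble sorted by p with columns `set_id`, `description`, `k`,
#'   `K`, `n`, `N`, `gene_ratio`, `p`, `padj`.
#' @export
enrich_sets <- function(query, collection, universe, min_overlap = 2) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0 || length(query) == 0) {
    abort_validation("query and universe must be non-empty")
  }
  out_q <- setdiff(query, universe)
  if (length(out_q) > 0) {
    abort_validation(paste0("query features outside the universe: ",
                            paste(utils::head(out_q, 5), collapse = ", ")))
  }
  N <- length(universe)
  n <- length(query)
  res <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
    members <- intersect(collection$members[[i]], universe)
    K <- length(members)
    k <- length(intersect(members, query))
    if (K < 1 || k < min_overlap) return(NULL)
    tibble::tibble(
      set_id = collection$set_id[i], description = collection$description[i],
      k = k, K = K, n = n, N = N,
      gene_ratio = k / n,
      p = hypergeom_upper_tail(k, K, n, N)
    )
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(set_id = character(), description = character(),
                          k = integer(), K = integer(), n = integer(), N = integer(),
                          gene_ratio = numeric(), p = numeric())
  }
  res$padj <- adjust_bh(res$p)
  res <- res[order(res$p, res$set_id), , drop = FALSE]
  class(res) <- c("l1r_enrich", class(res))
  res
}
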