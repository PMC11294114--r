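# Novel-object-recognition behaviour analysis: discrimination index,
# learner classification by the group mean +/- 3 SEM rule, exact
# Mann-Whitney rank-sum comparison, Spearman correlation, and
# expression-behaviour correlation through the pool membership of each
# mouse.

#' Discrimination index
#'
#' `DI = (t_novel - t_familiar) / (t_novel + t_familiar) * 100`, ranging
#' from -100 (only the familiar object explored) to 100 (only the novel
#' object explored). Vectorised.
#'
#' @param t_novel,t_familiar Exploration times in seconds (both >= 0, total
#'   > 0).
#' @return DI values in `[-100, 100]`.
#' @export
#' @examples
#' discrimination_index(0, 12)   # -100
#' discrimination_index(30, 10)  # 50
discrimination_index <- function(t_novel, t_familiar) {
  if (any(t_novel < 0 | t_familiar < 0)) abort_validation("exploration times must be >= 0")
  total <- t_novel + t_familiar
  if (any(total == 0)) abort_validation("zero total exploration time: DI undefined")
  (t_novel - t_familiar) / total * 100
}

#' Add discrimination indices to a behaviour table
#'
#' Computes `di_baseline`, `di_4m` (from exploration times where DI columns
#' are absent) and `delta_di = di_4m - di_baseline`.
#'
#' @param behavior A behaviour tibble (see [read_behavior()]).
#' @return The tibble with `di_baseline`, `di_4m`, `delta_di` columns.
#' @export
add_di <- function(behavior) {
  out <- behavior
  if (!"di_baseline" %in% names(out)) {
    out$di_baseline <- discrimination_index(out$t_novel_baseline, out$t_familiar_baseline)
  }
  if (!"di_4m" %in% names(out)) {
    out$di_4m <- discrimination_index(out$t_novel_4m, out$t_familiar_4m)
  }
  out$delta_di <- out$di_4m - out$di_baseline
  out
}

classify_values <- function(values) {
  n <- length(values)
  if (n < 2) abort_validation("learner classification needs n >= 2 per group (SEM undefined)")
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(n)
  dplyr::case_when(
    sem > 0 & values >= m + 3 * sem ~ "good",
    sem > 0 & values <= m - 3 * sem ~ "poor",
    .default = "intermediate"
  )
}

#' Classify learners by the group mean +/- 3 SEM rule
#'
#' Within each group, a mouse is a `good` learner when its metric (delta DI
#' or DI_4M) is at or above the group mean plus 3 standard errors of the
#' mean, `poor` at or below the mean minus 3 SEM, and `intermediate`
#' otherwise. SEM uses the n-1 sample standard deviation. When all values in
#' a group are equal (SEM 0), everyone is intermediate.
#'
#' @param behavior A behaviour tibble with DI columns (see [add_di()]).
#' @param metric `"delta_di"` (default) or `"di_4m"`.
#' @return The tibble with `learner_class` and `learner_metric` columns.
#' @export
classify_learners <- function(behavior, metric = c("delta_di", "di_4m")) {
  metric <- match.arg(metric)
  if (!metric %in% names(behavior)) behavior <- add_di(behavior)
  behavior |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(learner_class = classify_values(.data[[metric]]),
                  learner_metric = metric) |>
    dplyr::ungroup()
}

u_distribution <- function(n, m) {
  # f[k, u+1] = number of ways to pick k of the first j values with U
  # contribution u; iterate j = 1..n+m adding each value to x or y.
  maxu <- n * m
  f <- matrix(0, nrow = n + 1, ncol = maxu + 1)
  f[1, 1] <- 1
  # After processing j values with k in x, adding value j+1 to x adds
  # (j - k) pairwise wins (it exceeds the j - k y-values seen so far).
  for (j in 0:(n + m - 1)) {
    g <- matrix(0, nrow = n + 1, ncol = maxu + 1)
    for (k in 0:min(j, n)) {
      row <- f[k + 1, ]
      if (all(row == 0)) next
      ny <- j - k
      if (ny < m) g[k + 1, ] <- g[k + 1, ] + row  # value j+1 goes to y
      if (k < n) {                                # value j+1 goes to x
        add <- ny
        if (add == 0) g[k + 2, ] <- g[k + 2, ] + row
        else g[k + 2, (add + 1):(maxu + 1)] <- g[k + 2, (add + 1):(maxu + 1)] +
            row[1:(maxu + 1 - add)]
      }
    }
    f <- g
  }
  f[n + 1, ]
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent samples. `exact` mode (default
#' whenever both samples are untied and `n_x + n_y <= 12`) computes the
#' exact null distribution of the U statistic by enumeration of rank
#' partitions; otherwise a normal approximation with tie and continuity
#' corrections is used. The statistic reported is U for the first sample.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return A list with `statistic`, `p` and the `mode` used.
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))
rank_sum_test <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort_validation("both samples must be non-empty")
  n <- length(x); m <- length(y)
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1) {
    rlang::warn("all values identical across both groups; p = 1")
    return(list(statistic = n * m / 2, p = 1, mode = "degenerate"))
  }
  r <- rank(all_v)
  has_ties <- anyDuplicated(all_v) > 0
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2

  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = !has_ties && (n + m) <= 12
  )
  if (use_exact && has_ties) {
    rlang::warn("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    dist <- u_distribution(n, m)
    total <- sum(dist)
    lower <- sum(dist[seq_len(u + 1)]) / total            # P(U <= u)
    upper <- sum(dist[(u + 1):length(dist)]) / total      # P(U >= u)
    p <- min(1, 2 * min(lower, upper))
    return(list(statistic = u, p = p, mode = "exact"))
  }
  mu <- n * m / 2
  ties <- table(all_v)
  nn <- n + m
  sigma2 <- n * m / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sigma2 <= 0) {
    rlang::warn("degenerate rank variance; p = 1")
    return(list(statistic = u, p = 1, mode = "degenerate"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = u, p = p, mode = "normal_approx")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). The p-value
#' uses the t approximation with n - 2 degrees of freedom, or a permutation
#' null when `permutation = TRUE` (recommended for very small n).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param permutation Use a permutation p-value instead of the t
#'   approximation.
#' @param n_perm Number of permutations.
#' @return A list with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y, permutation = FALSE, n_perm = 10000) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort_validation("Spearman correlation needs n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort_validation("values must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort_validation("zero variance in ranks; correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  if (permutation) {
    obs <- abs(rho)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(stats::cor(rx, sample(ry))) >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

sample_di <- function(samples, behavior, aggregation = mean) {
  behavior <- add_di(behavior)
  di <- stats::setNames(behavior$di_4m, behavior$mouse_id)
  members <- pooled_ids(samples$pooled_mouse_ids)
  miss <- setdiff(unlist(members), names(di))
  if (length(miss) > 0) {
    abort_validation(paste0("mice without behaviour records: ",
                            paste(utils::head(miss, 5), collapse = ", ")))
  }
  vapply(members, function(ids) aggregation(di[ids]), numeric(1))
}

#' Correlate expression with the discrimination index
#'
#' Maps each (pooled) sample to a DI_4M value by aggregating the member
#' mice's indices (default: mean), then computes the Spearman correlation of
#' each feature's normalised expression (or of a supplied per-sample ratio
#' index) with DI across samples, BH-adjusted across features.
#'
#' @param normalized A normalised count table, or a tibble with `sample_id`
#'   and a single value column (e.g. a ratio index).
#' @param samples Sample sheet with `pooled_mouse_ids` for the samples to
#'   use.
#' @param behavior Behaviour tibble with per-mouse DI (or exploration
#'   times).
#' @param features Optional character vector restricting the features
#'   correlated.
#' @param aggregation Function pooling member-mouse DIs (default `mean`).
#' @return A tibble with `feature_id`, `rho`, `p`, `padj`, `n`; constant
#'   features get NA with a warning.
#' @export
correlate_expression_with_di <- function(normalized, samples, behavior,
                                         features = NULL, aggregation = mean) {
  if ("sample_id" %in% names(normalized)) {
    # per-sample index table: one value column
    value_col <- setdiff(names(normalized), "sample_id")
    if (length(value_col) != 1) abort_format("index table must have exactly one value column")
    mat <- matrix(normalized[[value_col]], nrow = 1,
                  dimnames = list(value_col, normalized$sample_id))
  } else {
    mat <- counts_to_matrix(normalized)
  }
  samples <- samples[samples$sample_id %in% colnames(mat), , drop = FALSE]
  if (nrow(samples) < 3) abort_validation("need at least 3 mapped samples")
  di <- sample_di(samples, behavior, aggregation)
  mat <- mat[, samples$sample_id, drop = FALSE]
  if (!is.null(features)) mat <- mat[intersect(features, rownames(mat)), , drop = FALSE]

  res <- purrr::map_dfr(rownames(mat), function(f) {
    v <- mat[f, ]
    if (stats::sd(rank(v)) == 0 || stats::sd(di) == 0) {
      return(tibble::tibble(feature_id = f, rho = NA_real_, p = NA_real_, n = length(v)))
    }
    sc <- spearman_correlation(v, di)
    tibble::tibble(feature_id = f, rho = sc$rho, p = sc$p, n = length(v))
  })
  if (any(is.na(res$rho))) rlang::warn("constant feature(s) or DI: correlation undefined, NA returned")
  res$padj <- adjust_bh(res$p)
  res
}
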