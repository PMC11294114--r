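test_that("size factors match the hand-computed median-of-ratios example", {
  sf <- estimate_size_factors(tiny_counts())
  # all per-gene ratios to the geometric mean coincide within a sample, so
  # the median is that common ratio: sqrt(1/2) and sqrt(2)
  expect_equal(round(sf$size_factor, 4), c(0.7071, 1.4142))

  ident <- tibble::tibble(feature_id = c("a", "b"), s1 = c(3, 7), s2 = c(3, 7))
  expect_equal(estimate_size_factors(ident)$size_factor, c(1, 1))
})

test_that("scaling one sample rescales the factors as depth ratios demand", {
  # median-of-ratios factors are defined up to the geometric-mean scale:
  # multiplying one column by 4 multiplies its factor by 4 relative to every
  # other sample's, and leaves the other samples' relative factors unchanged
  study <- two_group_study(50, 3, mu = 100, alpha = 0.1, seed = 2)
  sf1 <- estimate_size_factors(study$counts)$size_factor
  scaled <- study$counts
  scaled$s1 <- scaled$s1 * 4
  sf2 <- estimate_size_factors(scaled)$size_factor
  expect_equal(sf2[1] / sf2[2], 4 * sf1[1] / sf1[2], tolerance = 1e-12)
  expect_equal(sf2[-1] / sf2[2], sf1[-1] / sf1[2], tolerance = 1e-12)
  # direct recomputation oracle on the scaled table (reference features:
  # positive in every sample)
  m <- as.matrix(scaled[, -1])
  m <- m[rowSums(m > 0) == ncol(m), ]
  geo <- exp(rowMeans(log(m)))
  expect_equal(sf2, unname(apply(m / geo, 2, stats::median)), tolerance = 1e-12)
})

test_that("size factors error without a reference feature unless the fallback is on", {
  counts <- tibble::tibble(feature_id = c("a", "b"), s1 = c(0, 5), s2 = c(5, 0))
  err <- expect_error(estimate_size_factors(counts), class = "l1rescue_validation_error")
  expect_match(conditionMessage(err), "pseudo_reference")
  expect_silent(estimate_size_factors(counts, pseudo_reference = TRUE))
})

test_that("normalized_counts and log_transform behave as documented", {
  counts <- tiny_counts()
  sf <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(1, 1))
  expect_equal(normalized_counts(counts, sf)[, -1], counts[, -1])
  sf2 <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(2, 4))
  norm <- normalized_counts(counts, sf2)
  expect_equal(norm$s2 * 4, counts$s2)
  expect_equal(log_transform(tibble::tibble(feature_id = "a", s1 = 0))$s1, 0)
  sf_bad <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(1, 0))
  expect_error(normalized_counts(counts, sf_bad), class = "l1rescue_validation_error")
})

test_that("dispersion estimator hits the floor in the Poisson limit and flags zeros", {
  # variance equal to the mean => moment estimate at the floor
  counts <- tibble::tibble(feature_id = "f", s1 = 9, s2 = 10, s3 = 11)
  sf <- tibble::tibble(sample_id = paste0("s", 1:3), size_factor = rep(1, 3))
  d <- estimate_dispersions(counts, sf, groups = rep("a", 3))
  expect_equal(d$dispersion, 1e-8)

  zero <- tibble::tibble(feature_id = "f", s1 = 0, s2 = 0, s3 = 0)
  dz <- estimate_dispersions(zero, sf, groups = rep("a", 3))
  expect_equal(dz$dispersion, 1e-8)
  expect_true(dz$filtered)
})

test_that("dispersion estimator recovers the simulation truth on average", {
  study <- two_group_study(2000, 6, mu = 500, alpha = 0.2, seed = 31)
  sf <- estimate_size_factors(study$counts)
  d <- estimate_dispersions(study$counts, sf,
                            groups = rep(c("a", "b"), each = 6))
  expect_gt(mean(d$dispersion), 0.15)
  expect_lt(mean(d$dispersion), 0.25)
})

test_that("a flat feature gives log2fc 0 and p 1", {
  counts <- tibble::tibble(feature_id = "f", s1 = 7, s2 = 7, s3 = 7, s4 = 7)
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:4), tissue = "CX",
    genotype = rep(c("TS", "WT"), each = 2), treatment = "nt",
    pooled_mouse_ids = paste0("m", 1:4)
  )
  sf <- tibble::tibble(sample_id = paste0("s", 1:4), size_factor = rep(1, 4))
  disp <- tibble::tibble(feature_id = "f", dispersion = 0.1, filtered = FALSE)
  res <- wald_test(counts, samples, contrast_spec("TS-nt", "WT-nt"),
                   size_factors = sf, dispersions = disp, min_total = 1)
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)
})

test_that("swapping contrast groups negates fold changes and keeps p-values", {
  study <- two_group_study(80, 5, mu = 300, alpha = 0.1, lfc = 0.3, seed = 17)
  r1 <- de_contrast(study$counts, study$samples, "TS-nt", "WT-nt")
  r2 <- de_contrast(study$counts, study$samples, "WT-nt", "TS-nt")
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("low-count features are filtered and excluded from the BH family", {
  study <- two_group_study(30, 3, mu = 100, alpha = 0.05, seed = 8)
  study$counts[1, -1] <- as.list(rep(0, 6))
  study$counts[2, -1] <- as.list(c(1, 0, 0, 0, 0, 1))
  res <- de_contrast(study$counts, study$samples, "TS-nt", "WT-nt", min_total = 10)
  expect_true(all(res$filtered[1:2]))
  expect_true(all(is.na(res$p[1:2])))
  tested <- !res$filtered
  expect_equal(res$padj[tested], adjust_bh(res$p[tested]))
})

test_that("BH adjustment matches hand-computed examples and handles NA", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(adjust_bh(c(0.005, NA, 0.1)), c(0.01, NA, 0.1))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "l1rescue_validation_error")
})

test_that("BH equals the brute-force step-up definition on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    p <- round(stats::runif(sample(3:40, 1)), 3)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # independent cross-check against the standard library implementation
  set.seed(100)
  p <- stats::runif(500)
  expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("DE calls honour both threshold regimes", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    base_mean = 10, log2fc = c(2, 1.2, -1.8, 0.1), se = 1,
    wald_z = 1, p = c(0.001, 0.04, 0.04, 0.9),
    padj = c(0.004, 0.1, 0.12, 0.9), filtered = FALSE
  )
  class(res) <- c("l1r_de", class(res))
  call1 <- call_de(res, rule = "padj_le", alpha = 0.1)
  # padj exactly at the cutoff is included (inclusive rule)
  expect_setequal(call1$feature_id, c("a", "b"))
  call2 <- call_de(res, rule = "rawp_and_lfc")
  # b fails the fold-change arm, d fails the p arm
  expect_setequal(call2$feature_id, c("a", "c"))
  expect_equal(call2$direction, c("up", "down"))
  res$p <- rep(1, 4); res$padj <- rep(1, 4)
  expect_equal(nrow(call_de(res)), 0)
})

test_that("the NB Wald test matches a Poisson GLM in the zero-dispersion limit", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    mu <- stats::runif(1, 10, 500)
    y <- stats::rpois(2 * n, lambda = mu)
    counts <- dplyr::bind_cols(tibble::tibble(feature_id = "f"),
                               tibble::as_tibble(as.data.frame(t(y))))
    names(counts)[-1] <- paste0("s", seq_len(2 * n))
    samples <- tibble::tibble(
      sample_id = names(counts)[-1], tissue = "CX",
      genotype = rep(c("TS", "WT"), each = n), treatment = "nt",
      pooled_mouse_ids = paste0("m", seq_len(2 * n))
    )
    sf_val <- stats::runif(2 * n, 0.5, 2)
    sf <- tibble::tibble(sample_id = samples$sample_id, size_factor = sf_val)
    disp <- tibble::tibble(feature_id = "f", dispersion = 0, filtered = FALSE)
    res <- wald_test(counts, samples, contrast_spec("TS-nt", "WT-nt"),
                     size_factors = sf, dispersions = disp, min_total = 1)
    orc <- poisson_wald_oracle(y[1:n], y[(n + 1):(2 * n)],
                               sf_val[1:n], sf_val[(n + 1):(2 * n)],
                               df = 2 * n - 2)
    expect_equal(res$p, orc$p, tolerance = 1e-9)
    expect_equal(res$log2fc, orc$log2fc, tolerance = 1e-9)
    # convention-free cross-check of the fit against stats::glm (tightened
    # convergence so glm reaches the MLE to comparable precision)
    g <- stats::glm(y ~ rep(c(1, 0), each = n) + offset(log(sf_val)),
                    family = stats::poisson(),
                    control = stats::glm.control(epsilon = 1e-14, maxit = 100))
    sm <- summary(g)$coefficients
    expect_equal(res$wald_z, sm[2, 3], tolerance = 1e-6)
  }
})
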