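test_that("discrimination index follows its defining formula and bounds", {
  expect_equal(discrimination_index(0, 12), -100)
  expect_equal(discrimination_index(12, 0), 100)
  expect_equal(discrimination_index(7.5, 7.5), 0)
  expect_equal(discrimination_index(30, 10), 50)
  expect_error(discrimination_index(0, 0), class = "l1rescue_validation_error")
  expect_error(discrimination_index(-1, 5), class = "l1rescue_validation_error")
})

test_that("discrimination index is antisymmetric and scale-invariant", {
  set.seed(14)
  a <- stats::runif(50, 0, 30)
  b <- stats::runif(50, 0.1, 30)
  expect_equal(discrimination_index(a, b), -discrimination_index(b, a))
  k <- stats::runif(50, 0.1, 10)
  expect_equal(discrimination_index(k * a, k * b), discrimination_index(a, b))
  expect_true(all(abs(discrimination_index(a, b)) <= 100))
})

test_that("learner classification reproduces the 3-SEM rule by hand", {
  beh <- tibble::tibble(
    mouse_id = paste0("m", 1:8),
    group = rep(c("TS-t", "WT-t"), each = 4),
    di_baseline = 0,
    di_4m = c(0, 0, 0, 30, -60, 0, 0, 0)
  )
  cl <- classify_learners(beh, metric = "delta_di")
  # group 1: sd = 15, SEM = 7.5, mean 7.5 -> threshold 30 (good, inclusive)
  expect_equal(cl$learner_class[1:4], c(rep("intermediate", 3), "good"))
  # mirrored group: mean -15, SEM 7.5, poor threshold -37.5
  expect_equal(cl$learner_class[5:8], c("poor", rep("intermediate", 3)))
  expect_true(all(cl$learner_metric == "delta_di"))
})

test_that("degenerate groups classify as intermediate and tiny groups error", {
  beh <- tibble::tibble(mouse_id = paste0("m", 1:3), group = "TS-nt",
                        di_baseline = 0, di_4m = c(5, 5, 5))
  cl <- classify_learners(beh)
  expect_true(all(cl$learner_class == "intermediate"))
  one <- tibble::tibble(mouse_id = "m1", group = "TS-nt",
                        di_baseline = 0, di_4m = 5)
  expect_error(classify_learners(one), class = "l1rescue_validation_error")
  # ordering of rows does not change the assignment
  beh2 <- tibble::tibble(mouse_id = paste0("m", 1:4), group = "TS-t",
                         di_baseline = 0, di_4m = c(0, 0, 0, 30))
  cl2 <- classify_learners(beh2)
  cl2r <- classify_learners(beh2[4:1, ])
  expect_equal(cl2$learner_class[cl2$mouse_id == "m4"],
               cl2r$learner_class[cl2r$mouse_id == "m4"])
})

test_that("exact rank-sum p matches full enumeration", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_equal(r$mode, "exact")

  set.seed(23)
  for (i in 1:200) {
    n <- sample(2:6, 1); m <- sample(2:(12 - n), 1)
    v <- sample(1000, n + m)  # untied
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(rank_sum_test(x, y, mode = "exact")$p, ranksum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum handles degenerate and tied inputs", {
  expect_warning(r <- rank_sum_test(5, 5))
  expect_equal(r$p, 1)
  expect_warning(rt <- rank_sum_test(c(1, 1, 2), c(1, 2, 2), mode = "exact"))
  expect_equal(rt$mode, "normal_approx")
  # cross-check the tie-corrected normal approximation against wilcox.test
  x <- c(1, 1, 2, 5, 7, 9); y <- c(2, 3, 3, 8, 10, 11)
  ours <- suppressWarnings(rank_sum_test(x, y, mode = "normal_approx"))
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(ours$statistic, unname(ref$statistic))
})

test_that("rank-sum p is invariant to group swap and monotone transforms", {
  set.seed(31)
  for (i in 1:20) {
    x <- stats::runif(4); y <- stats::runif(5)
    p1 <- rank_sum_test(x, y)$p
    expect_equal(rank_sum_test(y, x)$p, p1, tolerance = 1e-12)
    expect_equal(rank_sum_test(exp(3 * x), exp(3 * y))$p, p1, tolerance = 1e-12)
  }
})

test_that("Spearman correlation matches the rank formula and is monotone-invariant", {
  expect_equal(spearman_correlation(1:5, 1:5)$rho, 1)
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  # untied closed form: 1 - 6 * sum(d^2) / (n (n^2 - 1)), sum(d^2) = 2
  expect_equal(spearman_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  set.seed(41)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  s1 <- spearman_correlation(x, y)
  s2 <- spearman_correlation(exp(x), y^3 + 5 * y)
  expect_equal(s1$rho, s2$rho, tolerance = 1e-12)
  expect_equal(s1$p, s2$p, tolerance = 1e-12)
  # agreement with the Pearson-on-ranks definition and the stats reference
  expect_equal(s1$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(s1$rho, unname(stats::cor(x, y, method = "spearman")), tolerance = 1e-12)
  expect_error(spearman_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "l1rescue_validation_error")
  expect_error(spearman_correlation(1:2, 1:2), class = "l1rescue_validation_error")
})

test_that("expression-DI correlation recovers the simulated coupling sign", {
  cfg <- sim_config(n_mice = c("TS-t" = 9, "WT-t" = 9, "TS-nt" = 9, "WT-nt" = 9),
                    tissues = "CX", n_genes = 200, n_l1 = 20,
                    frac_strong_trans = 0.1, behavior_coupling = -40,
                    di_noise_sd = 2, seed = 19)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  up <- tr$feature_id[tr$is_rescued & tr$true_log2fc_genotype > 0]
  down <- tr$feature_id[tr$is_rescued & tr$true_log2fc_genotype < 0]
  skip_if(length(up) == 0 || length(down) == 0)
  norm <- normalized_counts(sim$counts, estimate_size_factors(sim$counts))
  ri <- rescue_ratio_index(norm, up, down)
  beh <- simulate_behavior(sim$samples, ri, cfg)
  res <- correlate_expression_with_di(ri, sim$samples, beh)
  expect_lt(res$rho[1], 0)
  expect_equal(res$n[1], nrow(sim$samples))
})

test_that("constant features give NA correlations with a warning", {
  samples <- tibble::tibble(
    sample_id = paste0("s", 1:4), tissue = "CX", genotype = "TS",
    treatment = "nt", pooled_mouse_ids = paste0("m", 1:4),
    group = "TS-nt"
  )
  norm <- tibble::tibble(feature_id = c("flat", "var"),
                         s1 = c(5, 1), s2 = c(5, 2), s3 = c(5, 3), s4 = c(5, 4))
  beh <- tibble::tibble(mouse_id = paste0("m", 1:4), group = "TS-nt",
                        di_baseline = 0, di_4m = c(10, 20, 30, 15))
  expect_warning(res <- correlate_expression_with_di(norm, samples, beh))
  expect_true(is.na(res$rho[res$feature_id == "flat"]))
  expect_false(is.na(res$rho[res$feature_id == "var"]))
  bad_beh <- beh[1:2, ]
  expect_error(correlate_expression_with_di(norm, samples, bad_beh),
               class = "l1rescue_validation_error")
})
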