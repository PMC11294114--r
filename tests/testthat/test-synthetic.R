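small_cfg <- function(...) {
  sim_config(n_mice = c("TS-t" = 6, "WT-t" = 6, "TS-nt" = 6, "WT-nt" = 6),
             tissues = "CX", n_genes = 120, n_l1 = 30, ...)
}

test_that("simulation is deterministic given the seed", {
  a <- simulate_counts(small_cfg(seed = 9))
  b <- simulate_counts(small_cfg(seed = 9))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_counts(small_cfg(seed = 10))
  expect_false(identical(a$counts, c2$counts))
})

test_that("null configuration has all true effects at zero", {
  cfg <- small_cfg(frac_dosage_genes = 0, trans_effect_sd = 0,
                   frac_strong_trans = 0, frac_dosage_l1 = 0, frac_rescued = 0)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$true_log2fc_genotype == 0))
  expect_true(all(sim$truth$true_log2fc_treatment_interaction == 0))
  expect_false(any(sim$truth$is_dosage))
})

test_that("rescued features are a subset of the affected tiers", {
  sim <- simulate_counts(small_cfg(seed = 3))
  tr <- sim$truth
  expect_true(all(tr$feature_id[tr$is_rescued] %in%
                    tr$feature_id[tr$is_dosage | tr$is_strong_trans]))
  expect_equal(anyDuplicated(tr$feature_id), 0)
})

test_that("dosage genes show the expected 1.5x group mean ratio", {
  # law-of-large-numbers check by direct averaging of simulated counts
  cfg <- sim_config(n_mice = c("TS-t" = 2, "WT-t" = 2, "TS-nt" = 30, "WT-nt" = 30),
                    pool_size = 1, tissues = "CX", n_genes = 2000, n_l1 = 0,
                    frac_dosage_genes = 1, frac_rescued = 0, trans_effect_sd = 0,
                    frac_strong_trans = 0, frac_dosage_l1 = 0,
                    size_factor_sd = 0, seed = 13)
  sim <- simulate_counts(cfg)
  smp <- sim$samples
  m <- as.matrix(sim$counts[, -1])
  ts <- rowMeans(m[, smp$sample_id[smp$group == "TS-nt"]])
  wt <- rowMeans(m[, smp$sample_id[smp$group == "WT-nt"]])
  expect_gt(mean(ts / wt), 1.45)
  expect_lt(mean(ts / wt), 1.55)
})

test_that("pooled counts equal the sum of member-mouse counts", {
  sim <- simulate_counts(small_cfg(seed = 4), keep_mouse_counts = TRUE)
  draws <- sim$mouse_counts[["CX"]]
  for (i in seq_len(nrow(sim$samples))) {
    mice <- pooled_ids(sim$samples$pooled_mouse_ids[i])[[1]]
    expect_equal(sim$counts[[sim$samples$sample_id[i]]],
                 unname(rowSums(draws[, mice, drop = FALSE])))
  }
})

test_that("simulated counts are overdispersed when dispersion > 0", {
  cfg <- sim_config(n_mice = c("TS-t" = 2, "WT-t" = 2, "TS-nt" = 50, "WT-nt" = 2),
                    pool_size = 1, tissues = "CX", n_genes = 400, n_l1 = 0,
                    frac_dosage_genes = 0, trans_effect_sd = 0, frac_strong_trans = 0,
                    frac_dosage_l1 = 0, dispersion_range = c(0.2, 0.2),
                    size_factor_sd = 0, seed = 6)
  sim <- simulate_counts(cfg)
  smp <- sim$samples$sample_id[sim$samples$group == "TS-nt"]
  m <- as.matrix(sim$counts[, smp])
  v <- apply(m, 1, stats::var)
  mu <- rowMeans(m)
  expect_gt(mean(v > mu), 0.95)
})

test_that("group too small for two pools is rejected", {
  expect_error(
    simulate_counts(sim_config(n_mice = c("TS-t" = 3, "WT-t" = 6,
                                          "TS-nt" = 6, "WT-nt" = 6),
                               pool_size = 3, tissues = "CX",
                               n_genes = 20, n_l1 = 0)),
    class = "l1rescue_validation_error"
  )
})

test_that("behaviour generator couples DI to the pool ratio index", {
  sim <- simulate_counts(small_cfg(seed = 8))
  ri <- tibble::tibble(sample_id = sim$samples$sample_id,
                       ratio_index = seq_len(nrow(sim$samples)))
  cfg0 <- small_cfg(behavior_coupling = 0, di_noise_sd = 0, seed = 8)
  beh0 <- simulate_behavior(sim$samples, ri, cfg0)
  expect_true(all(beh0$di_4m == cfg0$behavior_intercept))

  # negative coupling, low noise: Spearman rho of (index, DI) is negative
  cfg1 <- small_cfg(behavior_coupling = -0.5, di_noise_sd = 0.01,
                    behavior_intercept = 0, seed = 8)
  beh1 <- simulate_behavior(sim$samples, ri, cfg1)
  rho <- spearman_correlation(beh1$ratio_index, beh1$di_4m)$rho
  expect_lt(rho, 0)

  # back-solved exploration times reproduce the DI exactly
  expect_equal(discrimination_index(beh1$t_novel_4m, beh1$t_familiar_4m),
               beh1$di_4m, tolerance = 1e-12)
  # DI 50 at 40 s total -> 30 s novel, 10 s familiar
  i <- which.min(abs(beh0$di_4m - 50))
  cfg2 <- small_cfg(behavior_coupling = 0, di_noise_sd = 0,
                    behavior_intercept = 50, seed = 8)
  beh2 <- simulate_behavior(sim$samples, ri, cfg2)
  expect_equal(beh2$t_novel_4m[1], 30)
  expect_equal(beh2$t_familiar_4m[1], 10)
})

test_that("write_fixture refuses a non-empty directory without force", {
  sim <- simulate_counts(small_cfg(seed = 2))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  expect_true(file.exists(file.path(dir, "counts.tsv")))
  expect_error(write_fixture(sim, dir), class = "l1rescue_validation_error")
  expect_silent(write_fixture(sim, dir, force = TRUE))
  back <- read_count_matrix(file.path(dir, "counts.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(sim$counts))
})
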