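test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_dataset(sim_config(n_proteins = 200, n_phosphosites = 200, seed = 7))
  b <- simulate_dataset(sim_config(n_proteins = 200, n_phosphosites = 200, seed = 7))
  expect_identical(intensity_values(a$proteome), intensity_values(b$proteome))
  expect_identical(intensity_values(a$phospho), intensity_values(b$phospho))
  expect_identical(a$design, b$design)
  expect_identical(a$truth$differential, b$truth$differential)
  expect_identical(a$ksmap, b$ksmap)
})

test_that("a silent configuration yields exactly zero within-patient differences", {
  cfg <- sim_config(
    n_proteins = 100, n_phosphosites = 50, frac_differential = 0,
    sigma_noise = 0, missing_beta = 0, missing_alpha = -Inf,
    n_planted_sets = 0, n_active_kinases = 0, seed = 3
  )
  sim <- simulate_dataset(cfg)
  v <- log2(intensity_values(sim$proteome))
  pairs <- design_pairs(sim$design, "discovery")
  deltas <- v[, pairs$be_sample] - v[, pairs$adj_sample]
  expect_equal(max(abs(deltas)), 0)
})

test_that("estimated fold changes track compression x true effect", {
  cfg <- sim_config(
    n_patients_be_discovery = 10, n_patients_nonbe_discovery = 0,
    n_proteins = 500, frac_differential = 0.05, compression_factor = 0.5,
    sigma_noise = 0.1, missing_beta = 0, missing_alpha = -Inf,
    n_planted_sets = 0, n_active_kinases = 0, seed = 5
  )
  sim <- simulate_dataset(cfg)
  # measure the generator directly (log2 values, no normalization)
  v <- log2(intensity_values(sim$proteome))
  pairs <- design_pairs(sim$design, "discovery")
  est_all <- rowMeans(v[, pairs$be_sample] - v[, pairs$adj_sample])
  truth <- sim$truth$differential[sim$truth$differential$level == "protein", ]
  est <- est_all[match(truth$feature_id, sim$proteome$feature_id)]
  se <- sqrt(2) * cfg$sigma_noise / sqrt(10)
  expect_true(all(abs(est - truth$expected_delta) < 3.5 * se))
  expect_equal(mean(est / truth$true_effect), 0.5, tolerance = 0.05)
})

test_that("missingness decreases with intensity when missing_beta > 0", {
  cfg <- sim_config(
    n_proteins = 4000, n_phosphosites = 50, frac_differential = 0,
    missing_alpha = 9, missing_beta = 0.5,
    n_planted_sets = 0, n_active_kinases = 0, seed = 9
  )
  sim <- simulate_dataset(cfg)
  v <- intensity_values(sim$proteome)
  mean_log <- rowMeans(log2(v), na.rm = TRUE)
  rate <- rowMeans(is.na(v))
  bins <- cut(mean_log, breaks = stats::quantile(mean_log, seq(0, 1, 0.2), na.rm = TRUE),
    include.lowest = TRUE)
  by_bin <- tapply(rate, bins, mean)
  expect_true(all(diff(by_bin) <= 0.01))
  expect_gt(by_bin[1], by_bin[5])
})

test_that("simulated designs satisfy the cohort pairing structure", {
  sim <- simulate_dataset(sim_config(n_proteins = 500, n_phosphosites = 300, seed = 1))
  d <- sim$design
  expect_silent(validate_design(d))
  expect_equal(nrow(design_pairs(d, "discovery")), 3)
  expect_equal(nrow(design_pairs(d, "validation")), 2)
  expect_equal(sum(d$cohort == "discovery"), 10)
  expect_equal(sum(d$cohort == "validation"), 10)
  nonbe_patients <- unique(d$patient_id[d$tissue_class == "NONBE"])
  expect_false(any(nonbe_patients %in% d$patient_id[d$tissue_class == "BE"]))
})

test_that("phosphosite localization probabilities follow the stated mixture", {
  cfg <- sim_config(n_proteins = 100, n_phosphosites = 4000,
    loc_prob_true_mix = 0.8, seed = 2)
  sim <- simulate_dataset(cfg)
  p <- sim$phospho$localization_prob
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean(p >= 0.7), 0.8, tolerance = 0.03)
})

test_that("transcriptome effects obey the stated correlation model", {
  sim <- simulate_dataset(sim_config(n_proteins = 1000, n_phosphosites = 50,
    frac_differential = 0.05, n_planted_sets = 0, n_active_kinases = 0, seed = 4))

  tx1 <- simulate_transcriptome(sim$truth, correlation = 1, seed = 11)
  expect_equal(tx1$effects, sim$truth$transcript_effects$protein_effect)

  tx0 <- simulate_transcriptome(sim$truth, correlation = 0, seed = 12)
  r <- cor(tx0$effects, sim$truth$transcript_effects$protein_effect)
  expect_lt(abs(r), 3 / sqrt(1000))

  tx <- simulate_transcriptome(sim$truth, n_be = 7, n_normal = 7, seed = 13)
  expect_equal(sum(tx$labels$tissue_class == "BE"), 7)
  expect_equal(sum(tx$labels$tissue_class == "NORMAL"), 7)
  expect_equal(length(sample_ids(tx$expr)), 14)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(frac_differential = 0), "frac_differential")
  expect_error(
    sim_config(n_proteins = 10, frac_differential = 0.5, geneset_size_range = c(15, 20)),
    "universe"
  )
  expect_error(sim_config(n_planted_sets = 99), "n_planted_sets")
  expect_error(sim_config(compression_factor = 0), "compression_factor")
})
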