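test_that("paired differences are BE minus ADJ within patient", {
  v <- matrix(c(
    5, 3, 6, 6, # feature 1: BE1 ADJ1 BE2 ADJ2
    2, 2, 9, 4
  ), 2, 4, byrow = TRUE, dimnames = list(NULL, c("P01_BE", "P01_ADJ", "P02_BE", "P02_ADJ")))
  x <- make_intensity(v, scale = "log2")
  design <- make_paired_design(2)
  d <- pair_differences(x, design)
  expect_equal(unname(as.matrix(d[, c("P01", "P02")])),
    matrix(c(2, 0, 0, 5), 2, 2, byrow = TRUE))
  expect_equal(ncol(d) - 1, 2)

  # a pair member absent from the matrix is an error naming the patient
  x2 <- make_intensity(v[, 1:3, drop = FALSE], scale = "log2")
  colnames(v)
  expect_error(pair_differences(x2, design), "P02")
})

test_that("EB hyperparameter estimation recovers a hierarchical generative model", {
  withr::with_seed(42, {
    n <- 20000
    d0_true <- 8
    s0_true <- 1
    d <- 4
    sigma2 <- s0_true * d0_true / stats::rchisq(n, df = d0_true)
    s2 <- sigma2 * stats::rchisq(n, df = d) / d
  })
  h <- estimate_eb_hyperparams(s2, df = d)
  expect_equal(h$s0_sq, s0_true, tolerance = 0.05)
  expect_equal(h$d0, d0_true, tolerance = 0.25)
})

test_that("degenerate variance spreads drive d0 to its limits", {
  h <- estimate_eb_hyperparams(rep(0.25, 50), df = 4)
  expect_identical(h$d0, Inf)
  # total shrinkage: posterior variance is constant at s0_sq for any s2
  res <- moderated_t(make_pairdiff(matrix(rnorm(50 * 5), 50, 5)), hyper = h)
  expect_equal(length(unique(res$df_total)), 1)
  expect_true(is.infinite(res$df_total[1]))

  h2 <- estimate_eb_hyperparams(c(0.01, 100), df = 4)
  expect_true(is.finite(h2$d0) && h2$d0 > 0)

  expect_error(estimate_eb_hyperparams(c(1), df = 4), "2")
  expect_error(estimate_eb_hyperparams(c(1, 0), df = 4), "positive")
})

test_that("moderated t matches its closed form and degenerate cases", {
  h <- structure(list(d0 = Inf, s0_sq = 0.25, df = 2, n_features = 3), class = "eb_prior")
  res <- moderated_t(make_pairdiff(matrix(c(1, 1, 1), 1, 3)), hyper = h)
  expect_equal(res$t_mod, 1 / (0.5 / sqrt(3)), tolerance = 1e-12)

  res0 <- moderated_t(make_pairdiff(matrix(0, 1, 3)), hyper = h)
  expect_equal(res0$t_mod, 0)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$flag, "zero_variance")

  expect_error(moderated_t(make_pairdiff(matrix(1, 3, 1))), "2 pairs")
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  withr::with_seed(7, {
    deltas <- matrix(rnorm(2000 * 5, 0, sqrt(rep(exp(rnorm(2000, -2, 0.8)), 5))), 2000, 5)
  })
  mine <- moderated_t(make_pairdiff(deltas))
  fit <- limma::lmFit(deltas, design = matrix(1, 5, 1))
  fit <- limma::eBayes(fit)
  expect_equal(attr(mine, "eb_prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mine, "eb_prior")$s0_sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t_mod, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(mine$p_value, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("|t_mod| is strictly increasing in |mean delta| at fixed variance", {
  h <- structure(list(d0 = 4, s0_sq = 0.2, df = 3, n_features = 2), class = "eb_prior")
  base <- c(-1.5, 0.5, 1) # sample variance fixed by construction below
  shifts <- seq(0, 3, by = 0.5)
  t_abs <- vapply(shifts, function(s) {
    abs(moderated_t(make_pairdiff(matrix(base + s, 1, 3)), hyper = h)$t_mod)
  }, numeric(1))
  expect_true(all(diff(t_abs) > 0))
})

test_that("BH adjustment matches the hand example and trivial cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the two-group contrast is calibrated and handles degenerate groups", {
  # identical group means => t = 0 for a constructed feature
  withr::with_seed(11, {
    v <- matrix(rnorm(200 * 8, 20), 200, 8)
  })
  v[1, ] <- c(3, 4, 5, 6, 3, 4, 5, 6) # same patient-level means in both groups
  colnames(v) <- c(paste0("N", 1:4), paste0("A", 1:4))
  x <- make_intensity(v, scale = "log2")
  design <- tibble::tibble(
    sample_id = colnames(v),
    patient_id = colnames(v),
    tissue_class = rep(c("NONBE", "ADJ"), each = 4),
    cohort = "discovery",
    tmt_channel = sprintf("C%02d", 1:8)
  )
  res <- two_group_contrast(x, design, "ADJ", "NONBE")
  expect_equal(res$log2fc[res$feature_id == "F001"], 0)
  expect_equal(res$t_mod[res$feature_id == "F001"], 0)
  expect_equal(attr(res, "contrast"), "ADJ_vs_NONBE")

  expect_error(
    two_group_contrast(x, design[c(1, 2, 5), ], "ADJ", "NONBE"),
    "2 patients"
  )
})

test_that("replicate biopsies are collapsed to patients in the two-group contrast", {
  # two samples per control patient; the contrast must use patient means
  withr::with_seed(12, {
    v <- matrix(rnorm(50 * 8, 20, rep(exp(rnorm(50, -1, 0.8)), 8)), 50, 8)
  })
  colnames(v) <- c("p1_a", "p1_b", "p2_a", "p2_b", "a1", "a2", "a3", "a4")
  x <- make_intensity(v, scale = "log2")
  design <- tibble::tibble(
    sample_id = colnames(v),
    patient_id = c("p1", "p1", "p2", "p2", "a1", "a2", "a3", "a4"),
    tissue_class = rep(c("NONBE", "ADJ"), each = 4),
    cohort = "discovery",
    tmt_channel = sprintf("C%02d", 1:8)
  )
  res <- two_group_contrast(x, design, "ADJ", "NONBE")
  manual_lfc <- rowMeans(v[, 5:8]) - rowMeans(cbind(rowMeans(v[, 1:2]), rowMeans(v[, 3:4])))
  expect_equal(res$log2fc, unname(manual_lfc))
  # pooled df: 4 ADJ patients + 2 NONBE patients - 2
  expect_equal(unique(res$df_total - attr(res, "eb_prior")$d0), 4)
})
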