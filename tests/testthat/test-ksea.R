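make_ksmap <- function(kinase, site_id) {
  parts <- strsplit(site_id, "_", fixed = TRUE)
  make_kinase_substrate_tbl <- tibble::tibble(
    kinase = kinase,
    substrate_gene = vapply(parts, `[[`, "", 1),
    site = vapply(parts, `[[`, "", 2),
    site_id = site_id
  )
  make_kinase_substrate_tbl
}

test_that("the kinase z-score matches its closed form on a standardized background", {
  # background engineered so that, with four substrate sites at +2, the full
  # site-statistic vector has mean exactly 0 and sd exactly 1
  n_rest <- 4996
  withr::with_seed(1, w <- rnorm(n_rest))
  w <- (w - mean(w)) / sd(w)
  b <- -8 / n_rest
  a <- sqrt((4983 - n_rest * b^2) / (n_rest - 1))
  rest <- a * w + b
  stats <- tibble::tibble(
    site_id = c(sprintf("GS%d_S1", 1:4), sprintf("BG%04d_S9", seq_len(n_rest))),
    stat = c(rep(2, 4), rest)
  )
  expect_equal(mean(stats$stat), 0, tolerance = 1e-12)
  expect_equal(sd(stats$stat), 1, tolerance = 1e-12)

  ks <- make_ksmap(rep("KIN1", 4), sprintf("GS%d_S1", 1:4))
  z <- kinase_zscores(stats, ks, min_substrates = 3)
  expect_equal(z$z, 2 * sqrt(4), tolerance = 1e-10)
  expect_equal(z$m, 4)
  expect_equal(z$direction, "BE")

  # substrate mean equal to the global mean => z = 0, p = 1
  ks0 <- make_ksmap(rep("KIN0", 2), stats$site_id[5:6])
  stats0 <- stats
  s_rest <- sum(stats0$stat[-(5:6)])
  stats0$stat[5:6] <- s_rest / (nrow(stats0) - 2) # equals the resulting global mean
  z0 <- kinase_zscores(stats0, ks0, min_substrates = 2)
  expect_equal(z0$z, 0, tolerance = 1e-12)
  expect_equal(z0$p_value, 1)
})

test_that("kinase z-scores are invariant to affine transforms of the site stats", {
  withr::with_seed(2, {
    stats <- tibble::tibble(site_id = sprintf("G%04d_S1", 1:500), stat = rnorm(500))
    ks <- make_ksmap(rep(sprintf("K%02d", 1:10), each = 6),
      sample(stats$site_id, 60))
  })
  z1 <- kinase_zscores(stats, ks)
  shifted <- stats
  shifted$stat <- 3 * stats$stat + 10
  z2 <- kinase_zscores(shifted, ks)
  expect_equal(z1$z, z2$z, tolerance = 1e-10)
})

test_that("eligibility, matching and degenerate inputs are handled", {
  stats <- tibble::tibble(site_id = sprintf("G%d_S1", 1:20), stat = c(rnorm(19), 5))
  ks <- make_ksmap(c("KA", "KA", "KB", "KB", "KB", "KC"),
    c("G1_S1", "G2_S1", "G3_S1", "G4_S1", "G5_S1", "ZZ_S9"))
  z <- kinase_zscores(stats, ks, min_substrates = 3)
  expect_equal(z$kinase, "KB") # KA has 2 substrates, KC's site is unquantified
  expect_equal(attr(z, "n_unmatched_edges"), 1)

  expect_warning(empty <- kinase_zscores(stats, ks, min_substrates = 10), "enough")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(significant_kinases(empty)), 0)

  const <- tibble::tibble(site_id = stats$site_id, stat = 1)
  expect_error(kinase_zscores(const, ks), "SD")
})

test_that("permutation p-values verify the analytic normal approximation", {
  withr::with_seed(3, {
    stats <- tibble::tibble(site_id = sprintf("G%04d_S1", 1:2500), stat = rnorm(2500))
    cases <- lapply(1:10, function(i) {
      m <- sample(5:12, 1)
      shift <- runif(1, 0, 1.2)
      sites <- sample(stats$site_id, m)
      list(kinase = sprintf("K%02d", i), sites = sites, shift = shift)
    })
  })
  st <- stats
  ks <- dplyr::bind_rows(lapply(cases, function(cs) {
    st$stat[st$site_id %in% cs$sites] <<- st$stat[st$site_id %in% cs$sites] + cs$shift
    make_ksmap(rep(cs$kinase, length(cs$sites)), cs$sites)
  }))
  z <- kinase_zscores(st, ks, min_substrates = 3)
  for (i in seq_len(nrow(z))) {
    p_perm <- kinase_permutation_p(st, ks, z$kinase[i], n_perm = 4000, seed = 100 + i)
    expect_lt(abs(p_perm - z$p_value[i]), 0.02)
  }
  # determinism
  p1 <- kinase_permutation_p(st, ks, z$kinase[1], n_perm = 500, seed = 7)
  p2 <- kinase_permutation_p(st, ks, z$kinase[1], n_perm = 500, seed = 7)
  expect_identical(p1, p2)
})

test_that("significant kinases are filtered at alpha and sorted by |z|", {
  z <- tibble::tibble(
    kinase = c("A", "B", "C"), m = 5, mean_stat = 1,
    z = c(1.0, -4, 2.5),
    p_value = c(0.3, 1e-4, 0.01), bh_q = c(0.3, 3e-4, 0.015),
    direction = c("BE", "adjacent", "BE")
  )
  class(z) <- c("besig_ksea", class(tibble::tibble()))
  out <- significant_kinases(z, alpha = 0.05)
  expect_equal(out$kinase, c("B", "C"))
  expect_equal(nrow(significant_kinases(z, alpha = 1e-6)), 0)
})

test_that("edge export keeps the max-|log2FC| site per substrate gene", {
  res <- tibble::tibble(
    feature_id = c("GA_S1", "GA_S2", "GB_S3"),
    log2fc = c(0.5, -2, 1),
    t_mod = c(1, -3, 2), flag = "ok"
  )
  ks <- make_ksmap(c("K1", "K1", "K1"), c("GA_S1", "GA_S2", "GB_S3"))
  edges <- kinase_substrate_edges(ks, res)
  expect_equal(nrow(edges), 2)
  expect_equal(edges$site_log2fc[edges$substrate_gene == "GA"], -2)
})
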