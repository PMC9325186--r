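ranked_from <- function(stats, ids = NULL) {
  ids <- ids %||% sprintf("G%03d", seq_along(stats))
  out <- tibble::tibble(feature_id = toupper(ids), stat = stats)
  out <- dplyr::arrange(out, dplyr::desc(stat), feature_id)
  class(out) <- c("besig_ranked", class(tibble::tibble()))
  out
}

test_that("ranked lists collapse phosphosites to the site with max |t| per gene", {
  res <- tibble::tibble(
    feature_id = c("GA_S1", "GA_S2", "GB_S9", "GC_S3"),
    gene_symbol = c("GA", "GA", "GB", "GC"),
    level = "phosphosite",
    log2fc = c(1, -0.1, 0.2, 0.2),
    s2 = 0.1,
    t_mod = c(3.1, -0.2, 0.5, NA),
    df_total = 8,
    p_value = c(0.01, 0.9, 0.5, 1),
    q_value = c(0.04, 0.9, 0.6, 1),
    flag = c("ok", "ok", "ok", "zero_variance")
  )
  class(res) <- c("besig_diff", class(tibble::tibble()))
  rk <- make_ranked_list(res)
  expect_equal(rk$feature_id, c("GA", "GB")) # GC dropped (undefined t)
  expect_equal(rk$stat, c(3.1, 0.5))

  # equal stats: deterministic order by id
  rk2 <- ranked_from(c(1, 1, 1), c("C", "A", "B"))
  expect_equal(rk2$feature_id, c("A", "B", "C"))
})

test_that("the enrichment score reproduces hand-computed running sums", {
  rk <- ranked_from(c(4, 3, 2, 1), c("A", "B", "C", "D"))
  top <- enrichment_score(rk, "A")
  expect_equal(top$running_sum, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(top$es, 1)

  bottom <- enrichment_score(rk, "D")
  ref <- oracle_es(rk$stat, rk$feature_id %in% "D")
  expect_equal(bottom$es, ref$es)
  expect_lt(bottom$es, 0)
  expect_equal(bottom$running_sum, ref$running_sum)

  expect_error(enrichment_score(rk, "ZZ"), "overlap")
  expect_error(enrichment_score(rk, c("A", "B", "C", "D")), "overlap")
})

test_that("weight 0 reduces to the classic unweighted KS statistic", {
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(8:30, 1)
      rk <- ranked_from(sort(rnorm(n), decreasing = TRUE))
      members <- sample(rk$feature_id, sample(2:(n - 2), 1))
      es <- enrichment_score(rk, members, weight_exp = 0)$es
      ref <- oracle_es(rk$stat, rk$feature_id %in% members, weight_exp = 0)$es
      expect_equal(es, ref, tolerance = 1e-12)
    }
  })
})

test_that("reversing and negating the ranking negates the enrichment score", {
  withr::with_seed(6, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      stats <- sort(rnorm(n), decreasing = TRUE)
      ids <- sprintf("G%03d", 1:n)
      members <- sample(ids, 4)
      es_fwd <- enrichment_score(ranked_from(stats, ids), members)$es
      es_rev <- enrichment_score(ranked_from(rev(-stats), rev(ids)), members)$es
      expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
    }
  })
})

test_that("nested top-rank sets have non-increasing enrichment scores", {
  rk <- ranked_from(seq(5, 0.1, length.out = 30))
  es_small <- enrichment_score(rk, rk$feature_id[1:3])$es
  es_large <- enrichment_score(rk, rk$feature_id[1:10])$es
  expect_gte(es_small, es_large)
})

test_that("enrichment scores agree with the reference GSEA implementation", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(30:120, 1)
      stats <- sort(rnorm(n), decreasing = TRUE)
      ids <- sprintf("G%03d", 1:n)
      m <- sample(3:12, 1)
      members <- sample(ids, m)
      mine <- enrichment_score(ranked_from(stats, ids), members)$es
      ref <- fgsea::calcGseaStat(setNames(stats, ids),
        selectedStats = which(ids %in% members), gseaParam = 1
      )
      expect_equal(mine, ref, tolerance = 1e-10)
    }
  })
})

test_that("preranked GSEA is deterministic and respects p-value floors", {
  withr::with_seed(8, {
    rk <- ranked_from(sort(rnorm(300), decreasing = TRUE))
    sets <- tibble::tibble(
      set_name = sprintf("S%02d", 1:10), description = "x",
      members = lapply(1:10, function(i) sample(rk$feature_id, 12))
    )
  })
  a <- gsea_preranked(rk, sets, n_perm = 200, seed = 9)
  b <- gsea_preranked(rk, sets, n_perm = 200, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$p_value >= 1 / (200 + 1)))
  expect_true(all(sign(a$nes) == sign(a$es)))
  expect_true(all(a$size == 12))
  expect_warning(gsea_preranked(rk, sets, n_perm = 50, seed = 1), "100")
  tiny <- sets
  tiny$members <- lapply(tiny$members, head, 2)
  expect_error(gsea_preranked(rk, tiny, n_perm = 200, seed = 1), "size bounds")
})

test_that("a strongly planted set is recovered with positive NES and small FDR", {
  withr::with_seed(10, {
    stats <- sort(rnorm(400), decreasing = TRUE)
    ids <- sprintf("G%03d", 1:400)
    sets <- tibble::tibble(
      set_name = c("PLANTED", sprintf("R%02d", 1:19)), description = "x",
      members = c(
        list(ids[1:15]),
        lapply(1:19, function(i) sample(ids, 15))
      )
    )
  })
  g <- gsea_preranked(ranked_from(stats, ids), sets, n_perm = 500, seed = 2)
  planted <- g[g$set_name == "PLANTED", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$fdr, 0.05)
  expect_setequal(planted$leading_edge[[1]], ids[1:15])
})
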