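# Kinase-substrate enrichment: per-kinase z-score of substrate-site
# statistics against the background of all quantified sites, with an
# optional permutation verification.
#
#   z_k = (mean(stat of kinase k's quantified substrate sites) - mean(all))
#          * sqrt(m_k) / sd(all)
#
# Positive z = inferred kinase activity elevated in BE; negative = elevated
# in adjacent normal tissue.

site_stat_frame <- function(site_stats) {
  if (inherits(site_stats, "besig_diff")) {
    res <- site_stats[site_stats$flag == "ok" & !is.na(site_stats$t_mod), ]
    return(tibble(site_id = toupper(res$feature_id), stat = res$t_mod))
  }
  if (is.data.frame(site_stats)) {
    id_col <- intersect(c("site_id", "feature_id"), names(site_stats))[1]
    stat_col <- intersect(c("stat", "t_mod"), names(site_stats))[1]
    if (is.na(id_col) || is.na(stat_col)) {
      abort("`site_stats` needs a site/feature id column and a stat column.")
    }
    return(tibble(site_id = toupper(site_stats[[id_col]]), stat = site_stats[[stat_col]]))
  }
  if (!is.null(names(site_stats))) {
    return(tibble(site_id = toupper(names(site_stats)), stat = as.numeric(site_stats)))
  }
  abort("`site_stats` must be a besig_diff, a data frame, or a named vector.")
}

#' Kinase activity z-scores
#'
#' Scores each kinase with at least `min_substrates` quantified substrate
#' sites by the standardized deviation of its substrates' statistics from
#' the background of all quantified sites. Substrates are matched on the
#' canonical site id (`GENE_S123`); unmatched map edges are counted in the
#' `n_unmatched_edges` attribute.
#'
#' @param site_stats Site-level statistics: a phosphosite `besig_diff`
#'   (moderated t is used), a data frame with id + stat columns, or a named
#'   vector.
#' @param ksmap Kinase-substrate map from [read_kinase_substrate()].
#' @param min_substrates Minimum quantified substrates per kinase (default 3).
#' @return Tibble of class `besig_ksea`: `kinase`, `m`, `mean_stat`, `z`,
#'   `p_value` (two-sided normal), `bh_q`, `direction` (`BE` for z > 0,
#'   `adjacent` otherwise), ordered by |z| descending. Empty (with a
#'   warning) when no kinase is eligible.
#' @export
kinase_zscores <- function(site_stats, ksmap, min_substrates = 3) {
  stats_tbl <- site_stat_frame(site_stats)
  if (anyDuplicated(stats_tbl$site_id)) abort("Duplicate site ids in `site_stats`.")
  mu <- mean(stats_tbl$stat)
  sigma <- sd(stats_tbl$stat)
  if (!is.finite(sigma) || sigma == 0) abort("Background SD of site statistics is 0.")
  edges <- dplyr::distinct(ksmap[, c("kinase", "site_id")])
  edges$stat <- stats_tbl$stat[match(edges$site_id, stats_tbl$site_id)]
  n_unmatched <- sum(is.na(edges$stat))
  edges <- edges[!is.na(edges$stat), ]
  scored <- edges %>%
    dplyr::group_by(.data$kinase) %>%
    dplyr::summarise(m = dplyr::n(), mean_stat = mean(.data$stat), .groups = "drop") %>%
    dplyr::filter(.data$m >= min_substrates)
  if (!nrow(scored)) {
    warn("No kinase has enough quantified substrates.")
    out <- tibble(
      kinase = character(), m = integer(), mean_stat = numeric(),
      z = numeric(), p_value = numeric(), bh_q = numeric(), direction = character()
    )
  } else {
    scored$z <- (scored$mean_stat - mu) * sqrt(scored$m) / sigma
    scored$p_value <- pmin(pmax(2 * pnorm(-abs(scored$z)), .Machine$double.xmin), 1)
    scored$bh_q <- bh_adjust(scored$p_value)
    scored$direction <- ifelse(scored$z > 0, "BE", "adjacent")
    out <- scored[order(-abs(scored$z), scored$kinase), ]
  }
  attr(out, "background") <- list(mu = mu, sigma = sigma, n_sites = nrow(stats_tbl))
  attr(out, "n_unmatched_edges") <- n_unmatched
  class(out) <- c("besig_ksea", class(tibble()))
  out
}

#' Permutation p-value for one kinase
#'
#' Independent verification of the analytic z-based p-value: draws `n_perm`
#' random site sets of the kinase's substrate count from the background and
#' compares their mean deviation from the background mean with the observed
#' one; `p = (1 + #{|mean_null - mu| >= |mean_obs - mu|}) / (1 + n_perm)`.
#'
#' @param site_stats As in [kinase_zscores()].
#' @param ksmap Kinase-substrate map.
#' @param kinase Kinase symbol to test.
#' @param n_perm Number of permutations (default 10000; < 100 warns).
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
kinase_permutation_p <- function(site_stats, ksmap, kinase, n_perm = 10000,
                                 seed = 1L) {
  if (n_perm < 100) warn("Fewer than 100 permutations: p-values will be coarse.")
  stats_tbl <- site_stat_frame(site_stats)
  mu <- mean(stats_tbl$stat)
  sites <- unique(ksmap$site_id[toupper(ksmap$kinase) == toupper(kinase)])
  obs_stats <- stats_tbl$stat[stats_tbl$site_id %in% sites]
  m <- length(obs_stats)
  if (m == 0) abort(sprintf("Kinase %s has no quantified substrates.", kinase))
  obs_dev <- abs(mean(obs_stats) - mu)
  withr::with_seed(seed, {
    null_dev <- vapply(seq_len(n_perm), function(i) {
      abs(mean(stats_tbl$stat[sample.int(nrow(stats_tbl), m)]) - mu)
    }, numeric(1))
    (1 + sum(null_dev >= obs_dev)) / (1 + n_perm)
  })
}

#' Filter to significant kinases
#'
#' @param results A `besig_ksea` tibble.
#' @param alpha Significance level on the (uncorrected) p-value, matching
#'   the nominal p < 0.05 convention of substrate enrichment analyses; BH
#'   values remain available in `bh_q`.
#' @return The significant subset, sorted by |z| descending.
#' @export
significant_kinases <- function(results, alpha = 0.05) {
  if (!nrow(results)) return(results)
  out <- results[results$p_value < alpha, ]
  out[order(-abs(out$z), out$kinase), ]
}

#' Kinase-substrate edge table for plotting/export
#'
#' One row per (kinase, substrate gene): the substrate's site with the
#' largest |log2FC| is retained, for graphing substrate-level effects.
#'
#' @param ksmap Kinase-substrate map.
#' @param results Phosphosite `besig_diff` with `log2fc`.
#' @return Tibble `kinase`, `substrate_gene`, `site`, `site_log2fc`.
#' @export
kinase_substrate_edges <- function(ksmap, results) {
  edges <- ksmap
  idx <- match(edges$site_id, toupper(results$feature_id))
  edges$site_log2fc <- results$log2fc[idx]
  edges <- edges[!is.na(edges$site_log2fc), ]
  edges %>%
    dplyr::group_by(.data$kinase, .data$substrate_gene) %>%
    dplyr::slice(which.max(abs(.data$site_log2fc))) %>%
    dplyr::ungroup() %>%
    dplyr::select("kinase", "substrate_gene", "site", "site_log2fc") %>%
    dplyr::arrange(.data$kinase, .data$substrate_gene)
}

#' @export
#' @method glance besig_ksea
glance.besig_ksea <- function(x, ...) {
  bg <- attr(x, "background")
  tibble(
    n_kinases_scored = nrow(x),
    n_significant = sum(x$p_value < 0.05),
    n_sites_background = bg$n_sites,
    n_unmatched_edges = attr(x, "n_unmatched_edges")
  )
}
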