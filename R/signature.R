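# Disease-signature selection (top percentile by p-value intersected with a
# fold-change floor), sign-flip randomization empirical FDR, projection onto
# other cohorts/omics, and hierarchical-clustering classification.

#' Select the disease signature
#'
#' Ranks features by ascending p-value (ties broken by descending |t|, then
#' feature id), keeps the top `ceil(top_frac * m)` candidates, and intersects
#' with features whose |log2FC| is at least `min_abs_lfc`. Directions record
#' the sign of the fold change (`up_in_BE` / `down_in_BE`).
#'
#' @param results A `besig_diff` tibble (non-empty).
#' @param top_frac Top fraction of the p-value ranking (default 0.01).
#' @param min_abs_lfc Fold-change floor in log2 units (default 0.75).
#' @return Tibble of class `besig_signature` with `feature_id`,
#'   `gene_symbol` (if available), `direction`, `log2fc`, `t_mod`,
#'   `p_value`, `q_value`; selection parameters travel as attribute
#'   `selection_params`. An empty selection is returned with a warning.
#' @export
select_signature <- function(results, top_frac = 0.01, min_abs_lfc = 0.75) {
  if (!nrow(results)) abort("`results` is empty.")
  m <- nrow(results)
  ord <- order(results$p_value, -abs(ifelse(is.na(results$t_mod), 0, results$t_mod)),
    results$feature_id)
  n_top <- ceiling(top_frac * m)
  top <- results[ord[seq_len(min(n_top, m))], ]
  sel <- top[abs(top$log2fc) >= min_abs_lfc, ]
  if (!nrow(sel)) warn("Signature selection is empty under the given criteria.")
  keep <- intersect(
    c("feature_id", "gene_symbol", "level", "log2fc", "t_mod", "p_value", "q_value"),
    names(sel)
  )
  out <- sel[, keep]
  out$direction <- ifelse(out$log2fc > 0, "up_in_BE", "down_in_BE")
  attr(out, "selection_params") <- list(
    top_frac = top_frac, min_abs_lfc = min_abs_lfc, n_candidates = n_top, m = m
  )
  class(out) <- c("besig_signature", class(tibble()))
  out
}

#' @export
#' @method glance besig_signature
glance.besig_signature <- function(x, ...) {
  p <- attr(x, "selection_params")
  tibble(
    n_selected = nrow(x),
    n_up = sum(x$direction == "up_in_BE"),
    n_down = sum(x$direction == "down_in_BE"),
    top_frac = p$top_frac,
    min_abs_lfc = p$min_abs_lfc,
    n_candidates = p$n_candidates
  )
}

#' Randomization-based empirical FDR of the signature selection
#'
#' Reruns the entire selection procedure (hyperparameter estimation,
#' moderated t, [select_signature()]) on label-randomized data: for each of
#' `n_rand` randomizations the sign of each patient's difference column is
#' independently flipped with probability 1/2 (the exact null for a paired
#' design). The empirical FDR is the mean null selection count divided by
#' the observed selection count.
#'
#' @param x Normalized [intensity_tbl()] (complete features).
#' @param design Design table with >= 2 BE/ADJ pairs among the samples of `x`.
#' @param top_frac,min_abs_lfc Selection parameters, as in [select_signature()].
#' @param n_rand Number of randomizations (default 100).
#' @param seed Integer seed.
#' @return List of class `besig_efdr`: `estimate` (NA with a flag when the
#'   observed selection is empty), `n_observed`, `mean_null`, `null_counts`,
#'   `n_rand`, `seed`.
#' @export
empirical_fdr <- function(x, design, top_frac = 0.01, min_abs_lfc = 0.75,
                          n_rand = 100, seed = 1L) {
  diffs <- pair_differences(x, design)
  pat_cols <- setdiff(names(diffs), "feature_id")
  if (length(pat_cols) < 2) abort("Empirical FDR needs >= 2 pairs.")
  observed <- select_signature(
    suppressWarnings(moderated_t(diffs)),
    top_frac = top_frac, min_abs_lfc = min_abs_lfc
  )
  n_obs <- nrow(observed)
  v <- as.matrix(diffs[, pat_cols, drop = FALSE])
  null_counts <- withr::with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      flips <- sample(c(-1, 1), length(pat_cols), replace = TRUE)
      flipped <- sweep(v, 2, flips, `*`)
      d2 <- dplyr::bind_cols(
        tibble(feature_id = diffs$feature_id),
        as_tibble(flipped, .name_repair = "minimal")
      )
      class(d2) <- class(diffs)
      res <- suppressWarnings(moderated_t(d2))
      nrow(suppressWarnings(
        select_signature(res, top_frac = top_frac, min_abs_lfc = min_abs_lfc)
      ))
    }, integer(1))
  })
  estimate <- if (n_obs == 0) NA_real_ else mean(null_counts) / n_obs
  structure(
    list(
      estimate = estimate,
      flag = if (n_obs == 0) "undefined_empty_selection" else "ok",
      n_observed = n_obs,
      mean_null = mean(null_counts),
      null_counts = null_counts,
      n_rand = n_rand,
      seed = seed,
      params = list(top_frac = top_frac, min_abs_lfc = min_abs_lfc)
    ),
    class = "besig_efdr"
  )
}

#' @export
print.besig_efdr <- function(x, ...) {
  cat(sprintf(
    "Empirical FDR: %s (observed selection %d, mean null %.2f over %d randomizations)\n",
    ifelse(is.na(x$estimate), "undefined (empty selection)", sprintf("%.4f", x$estimate)),
    x$n_observed, x$mean_null, x$n_rand
  ))
  invisible(x)
}

#' @export
#' @method glance besig_efdr
glance.besig_efdr <- function(x, ...) {
  tibble(
    empirical_fdr = x$estimate, n_observed = x$n_observed,
    mean_null = x$mean_null, n_rand = x$n_rand, flag = x$flag
  )
}

#' Project a signature onto another matrix
#'
#' Row-subsets `x` to the signature features, matching first on feature id
#' and then on upper-cased gene symbol (for cross-omics projection onto
#' transcript profiles). Rows are standardized (centered/scaled across
#' samples); constant rows are dropped with a warning. Unmatched signature
#' members are reported via the `n_unmatched` attribute, not silently
#' dropped.
#'
#' @param x An [intensity_tbl()] (any scale).
#' @param signature A `besig_signature`.
#' @return Standardized `intensity_tbl` of the overlapping features.
#' @export
project_signature <- function(x, signature) {
  by_id <- x$feature_id %in% signature$feature_id
  sig_genes <- toupper(stats::na.omit(signature$gene_symbol %||% character(0)))
  by_gene <- !is.na(x$gene_symbol) & toupper(x$gene_symbol) %in% sig_genes
  keep <- by_id | by_gene
  if (!any(keep)) abort("Signature/matrix overlap is 0 features.")
  sig_gene <- toupper(signature$gene_symbol %||% rep(NA_character_, nrow(signature)))
  matched <- signature$feature_id %in% x$feature_id |
    (!is.na(sig_gene) & sig_gene %in% toupper(x$gene_symbol[keep]))
  n_unmatched <- sum(!matched)
  v <- intensity_values(x)[keep, , drop = FALSE]
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, sd, na.rm = TRUE)
  constant <- is.na(sdv) | sdv == 0
  if (any(constant)) {
    warn(sprintf("Dropping %d constant (zero-variance) row(s).", sum(constant)))
  }
  z <- (v - mu) / sdv
  z <- z[!constant, , drop = FALSE]
  out <- rebuild_intensity(x, z, scale = "standardized", keep = which(keep)[!constant])
  attr(out, "n_unmatched") <- n_unmatched
  out
}

cluster_purity <- function(cluster, label) {
  tab <- table(cluster, label)
  sum(apply(tab, 1, max)) / length(cluster)
}

#' Hierarchical clustering classification
#'
#' Agglomerative clustering of samples with distance 1 - Pearson correlation
#' (computed over the supplied, typically signature-projected, features) and
#' average linkage; the tree is cut into exactly `k` clusters. Samples are
#' ordered lexicographically before clustering so ties resolve
#' deterministically. When labels are supplied, cluster purity and the
#' adjusted Rand index are computed against them.
#'
#' @param x An [intensity_tbl()] (usually from [project_signature()]).
#' @param k Number of clusters (`2 <= k <= n_samples`).
#' @param labels Optional: a design table (labels = `tissue_class`) or a
#'   vector named by sample id.
#' @return List of class `besig_clust`: `tree` (hclust), `assignments`
#'   (tibble `sample_id`, `cluster`, `label`), `k`, `purity`,
#'   `adjusted_rand`.
#' @export
hierarchical_cluster <- function(x, k, labels = NULL) {
  v <- intensity_values(x)
  if (ncol(v) < k) abort(sprintf("k = %d exceeds the %d samples.", k, ncol(v)))
  if (nrow(v) < 1) abort("Need at least one feature to cluster on.")
  v <- v[, order(colnames(v)), drop = FALSE]
  d <- as.dist(1 - cor(v, use = "pairwise.complete.obs"))
  tree <- hclust(d, method = "average")
  cl <- cutree(tree, k = k)
  lab <- NULL
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      lab <- setNames(labels$tissue_class, labels$sample_id)[colnames(v)]
    } else {
      lab <- labels[colnames(v)]
    }
  }
  assignments <- tibble(
    sample_id = colnames(v),
    cluster = unname(cl),
    label = if (is.null(lab)) NA_character_ else unname(lab)
  )
  purity <- if (is.null(lab)) NA_real_ else cluster_purity(cl, lab)
  ari <- if (is.null(lab)) NA_real_ else mclust::adjustedRandIndex(cl, lab)
  if (k == ncol(v)) {
    inform("k equals the number of samples: every sample is its own cluster (degenerate).")
  }
  structure(
    list(tree = tree, assignments = assignments, k = k,
      purity = purity, adjusted_rand = ari),
    class = "besig_clust"
  )
}

#' @export
print.besig_clust <- function(x, ...) {
  cat(sprintf(
    "Hierarchical clustering (1 - Pearson, average linkage): %d samples, k = %d\n",
    nrow(x$assignments), x$k
  ))
  if (!is.na(x$purity)) {
    cat(sprintf("  purity = %.3f, adjusted Rand = %.3f\n", x$purity, x$adjusted_rand))
  }
  invisible(x)
}

#' @export
#' @method tidy besig_clust
tidy.besig_clust <- function(x, ...) x$assignments

#' @export
#' @method glance besig_clust
glance.besig_clust <- function(x, ...) {
  tibble(
    n_samples = nrow(x$assignments), k = x$k,
    purity = x$purity, adjusted_rand = x$adjusted_rand
  )
}
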