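# Preprocessing: localization filtering, per-cohort complete-case filtering,
# log2 transformation and quantile normalization (in that canonical order).

#' Filter phosphosites by localization probability
#'
#' Retains phosphosite features whose localization probability is at least
#' `min_prob` (inclusive threshold: "minimum of 0.7" is read as the lowest
#' allowed value). Protein-level tables pass through unchanged. Idempotent.
#'
#' @param x An [intensity_tbl()].
#' @param min_prob Minimum localization probability (default 0.7).
#' @return Filtered `intensity_tbl`.
#' @export
filter_localization <- function(x, min_prob = 0.7) {
  is_site <- !is.na(x$level) & x$level == "phosphosite"
  if (!any(is_site)) {
    return(x)
  }
  if (anyNA(x$localization_prob[is_site])) {
    abort("Phosphosite feature(s) lack a localization probability.")
  }
  keep <- !is_site | x$localization_prob >= min_prob
  if (!any(keep)) {
    warn("No features pass the localization filter; returning an empty table.")
  }
  rebuild_intensity(x, intensity_values(x)[keep, , drop = FALSE], keep = keep)
}

#' Log2-transform raw intensities
#'
#' @param x A raw-scale [intensity_tbl()] with strictly positive present
#'   values. Missing cells stay missing.
#' @return `intensity_tbl` on the log2 scale.
#' @export
log2_transform <- function(x) {
  if (intensity_scale(x) != "raw") {
    abort(sprintf("Expected a raw-scale table, got scale '%s'.", intensity_scale(x)))
  }
  v <- intensity_values(x)
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Non-positive intensity for feature %s, sample %s.",
      rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]
    ))
  }
  rebuild_intensity(x, log2(v), scale = "log2")
}

#' Quantile-normalize a log2 intensity matrix
#'
#' Forces every sample (column) to share the same distribution: the sorted
#' values of each column become the vector of row-wise means of the
#' column-sorted matrix; ties receive the mean of the reference values across
#' their tied span. Idempotent and rank-preserving within columns. Apply per
#' cohort (plex), after completeness filtering.
#'
#' @param x An [intensity_tbl()] on the log2 scale with at least 2 samples.
#' @return `intensity_tbl` with scale `log2_quantile_normalized`.
#' @export
quantile_normalize <- function(x) {
  if (!intensity_scale(x) %in% c("log2", "log2_quantile_normalized")) {
    abort("Quantile normalization expects a log2-scale table.")
  }
  v <- intensity_values(x)
  if (ncol(v) < 2) abort("Quantile normalization needs at least 2 samples.")
  qn <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(qn) <- dimnames(v)
  rebuild_intensity(x, qn, scale = "log2_quantile_normalized")
}

#' Complete-case filter within cohorts
#'
#' Retains features observed in every sample of each cohort present in
#' `design` (restricted to samples that are columns of `x`). With
#' `design = NULL`, completeness is required across all columns.
#'
#' @param x An [intensity_tbl()].
#' @param design Optional design table defining cohort membership.
#' @return Filtered `intensity_tbl`.
#' @export
filter_complete <- function(x, design = NULL) {
  v <- intensity_values(x)
  if (nrow(v) == 0) {
    return(x)
  }
  if (is.null(design)) {
    keep <- rowSums(is.na(v)) == 0
  } else {
    design <- design[design$sample_id %in% colnames(v), ]
    keep <- rep(TRUE, nrow(v))
    for (co in unique(design$cohort)) {
      ids <- design$sample_id[design$cohort == co]
      keep <- keep & rowSums(is.na(v[, ids, drop = FALSE])) == 0
    }
  }
  rebuild_intensity(x, v[keep, , drop = FALSE], keep = keep)
}

#' Run the canonical preprocessing chain for one cohort
#'
#' Localization filter, then complete-case filter over the cohort's samples,
#' then log2 transform and quantile normalization. Returns the normalized
#' matrix together with a provenance report of feature counts and per-sample
#' medians before/after normalization.
#'
#' @param x Raw-scale [intensity_tbl()] (proteome or phosphoproteome).
#' @param design Design table; only samples of `cohort` are used.
#' @param cohort Cohort to preprocess (`"discovery"` or `"validation"`).
#' @param min_loc_prob Localization threshold for phosphosite tables.
#' @return List with `data` (normalized `intensity_tbl`) and `report`
#'   (one-row tibble: `n_input_features`, `n_after_localization`,
#'   `n_after_completeness`, plus median summaries).
#' @export
preprocess <- function(x, design, cohort = "discovery", min_loc_prob = 0.7) {
  design <- validate_design(design)
  d <- design[design$cohort == cohort, ]
  if (!nrow(d)) abort(sprintf("No samples for cohort '%s'.", cohort))
  x <- subset_samples(x, d)
  n_input <- nrow(x)
  x <- filter_localization(x, min_prob = min_loc_prob)
  n_loc <- nrow(x)
  x <- filter_complete(x, design = d)
  n_complete <- nrow(x)
  x <- log2_transform(x)
  med_before <- median(apply(intensity_values(x), 2, median, na.rm = TRUE))
  x <- quantile_normalize(x)
  med_after <- median(apply(intensity_values(x), 2, median, na.rm = TRUE))
  report <- tibble(
    cohort = cohort,
    n_input_features = n_input,
    n_after_localization = n_loc,
    n_after_completeness = n_complete,
    median_log2_before = med_before,
    median_log2_after = med_after
  )
  list(data = x, report = report)
}
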