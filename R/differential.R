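# Paired and two-group moderated-t differential analysis.
#
# The paired contrast is a one-sample moderated t on within-patient
# log2(BE) - log2(ADJ) differences; per-feature variances are shrunk toward
# a prior (s0^2, d0) estimated by moment-matching log sample variances to a
# scaled F distribution (trigamma inversion), and the statistic
#   t_mod = mean(delta) / sqrt(s2_post / n),  s2_post = (d0 s0^2 + d s^2) / (d0 + d)
# is referred to a t distribution on d0 + d degrees of freedom.

#' Within-patient paired differences
#'
#' For every BE/ADJ pair of the design, computes the per-feature difference
#' log2(BE sample) - log2(ADJ sample). Every feature must be complete over
#' the paired samples (run [filter_complete()] first).
#'
#' @param x Normalized [intensity_tbl()].
#' @param design Validated design table; pairs are taken from the cohorts
#'   whose samples appear in `x`.
#' @return Tibble of class `besig_pairdiff`: `feature_id` plus one numeric
#'   column per patient; feature annotations travel in the `feature_meta`
#'   attribute.
#' @export
pair_differences <- function(x, design) {
  design <- validate_design(design)
  pairs <- design_pairs(design)
  pairs <- pairs[pairs$be_sample %in% sample_ids(x) | pairs$adj_sample %in% sample_ids(x), ]
  missing_members <- pairs$patient_id[!(pairs$be_sample %in% sample_ids(x) &
    pairs$adj_sample %in% sample_ids(x))]
  if (length(missing_members)) {
    abort(sprintf(
      "Patient(s) missing one pair member in the matrix: %s",
      paste(missing_members, collapse = ", ")
    ))
  }
  if (!nrow(pairs)) abort("No BE/ADJ pairs found among the matrix samples.")
  v <- intensity_values(x)
  deltas <- v[, pairs$be_sample, drop = FALSE] - v[, pairs$adj_sample, drop = FALSE]
  if (anyNA(deltas)) {
    abort("Paired samples contain missing values; apply filter_complete() first.")
  }
  colnames(deltas) <- pairs$patient_id
  out <- dplyr::bind_cols(
    tibble(feature_id = x$feature_id),
    as_tibble(deltas, .name_repair = "minimal")
  )
  attr(out, "feature_meta") <- feature_meta(x)
  class(out) <- c("besig_pairdiff", class(tibble()))
  out
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(y) {
  if (y > 1e7) {
    return(1 / sqrt(y))
  }
  if (y < 1e-6) {
    return(1 / y)
  }
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Moment-matches the log sample variances to a scaled F distribution:
#' the excess spread of `log(s2)` beyond `trigamma(d/2)` determines the
#' prior degrees of freedom `d0` (by trigamma inversion); the prior variance
#' `s0_sq` follows from the mean of `log(s2)` with the digamma bias
#' correction. When the observed spread does not exceed the sampling
#' expectation, `d0` is infinite and `s0_sq` is the bias-corrected mean
#' `exp(mean(log(s2)) - digamma(d/2) + log(d/2))`, which keeps null t
#' statistics calibrated under total shrinkage.
#'
#' @param s2 Vector of positive per-feature sample variances (exclude
#'   zero-variance features beforehand).
#' @param df Residual degrees of freedom per feature (scalar; `n_pairs - 1`
#'   for the paired design).
#' @return List of class `eb_prior` with `d0`, `s0_sq`, `df`, `n_features`.
#' @export
estimate_eb_hyperparams <- function(s2, df) {
  s2 <- as.numeric(s2)
  if (length(s2) < 2) abort("Need at least 2 positive-variance features.")
  if (any(s2 <= 0)) abort("All `s2` must be positive.")
  if (length(df) != 1 || df < 1) abort("`df` must be a scalar >= 1.")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e)
  excess <- evar - trigamma(df / 2)
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  structure(
    list(d0 = d0, s0_sq = s0_sq, df = df, n_features = length(s2)),
    class = "eb_prior"
  )
}

#' @export
print.eb_prior <- function(x, ...) {
  cat(sprintf(
    "Empirical-Bayes variance prior: d0 = %s, s0^2 = %.4g (from %d features, d = %g)\n",
    format(x$d0), x$s0_sq, x$n_features, x$df
  ))
  invisible(x)
}

#' @export
#' @method tidy eb_prior
tidy.eb_prior <- function(x, ...) {
  tibble(
    term = c("d0", "s0_sq"),
    estimate = c(x$d0, x$s0_sq)
  )
}

finish_diff <- function(feature_id, log2fc, s2, n_eff, d, hyper, meta = NULL,
                        n_pairs = NULL, contrast = "BE_vs_ADJ") {
  feature_id <- unname(feature_id)
  log2fc <- unname(log2fc)
  s2 <- unname(s2)
  positive <- s2 > 0
  estimated <- is.null(hyper)
  if (estimated) {
    if (sum(positive) < 2) abort("Fewer than 2 features with positive variance.")
    hyper <- estimate_eb_hyperparams(s2[positive], df = d)
  }
  d0 <- hyper$d0
  s0 <- hyper$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else (d0 * s0 + d * s2) / (d0 + d)
  df_total <- d0 + d
  t_mod <- log2fc / sqrt(s2_post * n_eff)
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  flag <- ifelse(positive, "ok", "zero_variance")
  if (estimated) {
    # zero sample variance with a data-estimated prior: the statistic is not
    # trusted; t is undefined unless the mean is also 0 (then t = 0), p = 1
    t_mod[!positive] <- ifelse(log2fc[!positive] == 0, 0, NA_real_)
    p[!positive] <- 1
  }
  out <- tibble(
    feature_id = feature_id,
    log2fc = log2fc,
    s2 = s2,
    t_mod = t_mod,
    df_total = df_total,
    p_value = p,
    q_value = bh_adjust(p),
    flag = flag
  )
  if (!is.null(meta)) {
    out <- dplyr::left_join(
      out, meta[, c("feature_id", "gene_symbol", "level")],
      by = "feature_id"
    )
  }
  attr(out, "eb_prior") <- hyper
  attr(out, "n_pairs") <- n_pairs
  attr(out, "contrast") <- contrast
  class(out) <- c("besig_diff", class(tibble()))
  out
}

#' Moderated t-test on paired differences
#'
#' One-sample empirical-Bayes moderated t on within-patient differences.
#' Features with zero sample variance are excluded from hyperparameter
#' estimation and reported with `t_mod = NA`, `p_value = 1` and flag
#' `"zero_variance"` (their t is undefined; conservative). With `d0 = Inf`
#' the posterior variance is `s0_sq` and p-values are normal-limit.
#'
#' @param diffs A `besig_pairdiff` from [pair_differences()] (>= 2 pairs).
#' @param hyper Optional [estimate_eb_hyperparams()] result; estimated from
#'   the data when `NULL`.
#' @return Tibble of class `besig_diff` with `feature_id`, `log2fc`, `s2`,
#'   `t_mod`, `df_total`, `p_value`, `q_value` (BH), `flag`, and feature
#'   annotations when available. The prior travels as attribute `eb_prior`.
#' @export
moderated_t <- function(diffs, hyper = NULL) {
  v <- as.matrix(diffs[, setdiff(names(diffs), "feature_id"), drop = FALSE])
  storage.mode(v) <- "double"
  n <- ncol(v)
  if (n < 2) abort("Moderated t needs at least 2 pairs.")
  log2fc <- rowMeans(v)
  s2 <- apply(v, 1, var)
  finish_diff(
    feature_id = diffs$feature_id, log2fc = log2fc, s2 = s2,
    n_eff = 1 / n, d = n - 1, hyper = hyper,
    meta = attr(diffs, "feature_meta"), n_pairs = n
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment mapped back to input order (delegates to
#' [stats::p.adjust()] after domain validation).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) {
    return(numeric(0))
  }
  if (anyNA(p) || any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1].")
  p.adjust(p, method = "BH")
}

#' Unpaired two-group moderated t contrast
#'
#' For contrasts without within-patient pairing (e.g. adjacent-normal versus
#' non-BE tissue): `log2fc = mean(a) - mean(b)`, pooled two-sample variance
#' with `d = n_a + n_b - 2`, and the same variance-shrinkage machinery as
#' [moderated_t()]. Replicate biopsies of the same patient are averaged
#' first, so the experimental unit is the patient (pooling replicates as
#' independent samples would understate the variance). Features with a
#' missing value in either group are dropped (complete-case).
#'
#' @param x Normalized [intensity_tbl()].
#' @param design Design table; classes are matched on `tissue_class`.
#' @param class_a,class_b Tissue classes to contrast (>= 2 patients each).
#' @return A `besig_diff` tibble (see [moderated_t()]).
#' @export
two_group_contrast <- function(x, design, class_a = "ADJ", class_b = "NONBE") {
  design <- validate_design(design)
  patient_means <- function(class) {
    d <- design[design$tissue_class == class & design$sample_id %in% sample_ids(x), ]
    cols <- lapply(split(d$sample_id, d$patient_id), function(ids) {
      rowMeans(intensity_values(x)[, ids, drop = FALSE])
    })
    if (!length(cols)) {
      return(matrix(numeric(0), nrow(x), 0))
    }
    do.call(cbind, cols)
  }
  va <- patient_means(class_a)
  vb <- patient_means(class_b)
  if (ncol(va) < 2 || ncol(vb) < 2) {
    abort(sprintf(
      "Both classes need >= 2 patients (found %d %s, %d %s).",
      ncol(va), class_a, ncol(vb), class_b
    ))
  }
  complete <- rowSums(is.na(va)) == 0 & rowSums(is.na(vb)) == 0
  if (!all(complete)) {
    inform(sprintf("Dropping %d incomplete feature(s) for the contrast.", sum(!complete)))
    va <- va[complete, , drop = FALSE]
    vb <- vb[complete, , drop = FALSE]
  }
  na <- ncol(va)
  nb <- ncol(vb)
  d <- na + nb - 2
  log2fc <- rowMeans(va) - rowMeans(vb)
  s2 <- ((na - 1) * apply(va, 1, var) + (nb - 1) * apply(vb, 1, var)) / d
  finish_diff(
    feature_id = x$feature_id[complete], log2fc = log2fc, s2 = s2,
    n_eff = 1 / na + 1 / nb, d = d, hyper = NULL,
    meta = feature_meta(x),
    contrast = sprintf("%s_vs_%s", class_a, class_b)
  )
}

#' Paired differential analysis in one call
#'
#' Convenience wrapper: [pair_differences()] then [moderated_t()].
#'
#' @param x Normalized [intensity_tbl()].
#' @param design Design table.
#' @return A `besig_diff` tibble.
#' @export
differential_paired <- function(x, design) {
  moderated_t(pair_differences(x, design))
}

#' @export
#' @method tidy besig_diff
tidy.besig_diff <- function(x, ...) as_tibble(x)

#' @export
#' @method glance besig_diff
glance.besig_diff <- function(x, ...) {
  prior <- attr(x, "eb_prior")
  tibble(
    n_features = nrow(x),
    n_pairs = attr(x, "n_pairs") %||% NA_integer_,
    contrast = attr(x, "contrast") %||% NA_character_,
    d0 = prior$d0,
    s0_sq = prior$s0_sq,
    n_zero_variance = sum(x$flag == "zero_variance"),
    n_sig_q05 = sum(x$q_value < 0.05, na.rm = TRUE)
  )
}
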