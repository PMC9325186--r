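# Core tabular containers shared by all stages.
#
# An intensity table is a tibble with six feature-annotation columns followed
# by one numeric column per sample; NA marks a missing (undetected) cell.
# The measurement scale travels as an attribute so stages can enforce their
# preconditions (raw -> log2 -> log2_quantile_normalized -> standardized).

.meta_cols <- c(
  "feature_id", "gene_symbol", "level",
  "site_residue", "site_position", "localization_prob"
)

.scales <- c("raw", "log2", "log2_quantile_normalized", "standardized")

#' Construct an intensity table
#'
#' Builds the package's standard feature-by-sample container: a tibble with
#' feature annotation columns (`feature_id`, `gene_symbol`, `level`,
#' `site_residue`, `site_position`, `localization_prob`) followed by one
#' numeric column per sample. `NA` encodes a missing measurement.
#'
#' @param features Data frame of feature annotations. Must contain
#'   `feature_id`; missing annotation columns are filled with `NA`.
#' @param values Numeric matrix, features in rows (same order as `features`),
#'   samples in columns; column names become sample ids.
#' @param scale One of `"raw"`, `"log2"`, `"log2_quantile_normalized"`,
#'   `"standardized"`.
#' @return A tibble of class `intensity_tbl` with a `scale` attribute.
#' @export
intensity_tbl <- function(features, values, scale = "raw") {
  scale <- match.arg(scale, .scales)
  features <- as_tibble(features)
  if (!"feature_id" %in% names(features)) {
    abort("`features` must contain a `feature_id` column.")
  }
  for (col in setdiff(.meta_cols, names(features))) {
    features[[col]] <- if (col == "site_position") NA_integer_ else NA_character_
  }
  features$site_position <- as.integer(features$site_position)
  features$localization_prob <- as.numeric(features$localization_prob)
  values <- as.matrix(values)
  if (nrow(values) != nrow(features)) {
    abort("`values` must have one row per feature.")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    abort("`values` must have unique column (sample) names.")
  }
  out <- dplyr::bind_cols(
    features[, .meta_cols],
    as_tibble(values, .name_repair = "minimal")
  )
  out <- validate_intensity(new_intensity(out, scale))
  out
}

new_intensity <- function(x, scale) {
  x <- as_tibble(x)
  attr(x, "scale") <- scale
  class(x) <- c("intensity_tbl", class(tibble()))
  x
}

#' @export
print.intensity_tbl <- function(x, ...) {
  cat(sprintf(
    "# Intensity table: %d features x %d samples (scale: %s)\n",
    nrow(x), length(sample_ids(x)), intensity_scale(x)
  ))
  NextMethod()
}

#' Sample ids of an intensity table
#' @param x An `intensity_tbl`.
#' @return Character vector of sample ids (column order).
#' @export
sample_ids <- function(x) setdiff(names(x), .meta_cols)

#' Measurement scale of an intensity table
#' @param x An `intensity_tbl`.
#' @return The scale string.
#' @export
intensity_scale <- function(x) attr(x, "scale") %||% "raw"

#' Extract the numeric value matrix
#' @param x An `intensity_tbl`.
#' @return Numeric matrix, feature ids as rownames, sample ids as colnames;
#'   `NA` where the measurement is missing.
#' @export
intensity_values <- function(x) {
  m <- as.matrix(x[, sample_ids(x), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$feature_id
  m
}

#' Feature annotations of an intensity table
#' @param x An `intensity_tbl`.
#' @return Tibble of the six annotation columns.
#' @export
feature_meta <- function(x) as_tibble(x[, .meta_cols])

# Rebuild an intensity table from (possibly filtered) annotations + values.
rebuild_intensity <- function(x, values, scale = intensity_scale(x),
                              keep = NULL) {
  meta <- feature_meta(x)
  if (!is.null(keep)) meta <- meta[keep, , drop = FALSE]
  stopifnot(nrow(meta) == nrow(values))
  out <- dplyr::bind_cols(meta, as_tibble(values, .name_repair = "minimal"))
  new_intensity(out, scale)
}

#' Validate intensity-table invariants
#'
#' Checks feature-id uniqueness, that phosphosite features carry residue,
#' position and localization probability (and protein features do not), and
#' that present raw-scale values are strictly positive.
#'
#' @param x An `intensity_tbl`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_intensity <- function(x) {
  if (anyDuplicated(x$feature_id)) {
    dup <- unique(x$feature_id[duplicated(x$feature_id)])
    abort(sprintf(
      "Duplicate feature_id(s): %s",
      paste(head(dup, 5), collapse = ", ")
    ))
  }
  bad_level <- setdiff(unique(x$level), c("protein", "phosphosite", NA))
  if (length(bad_level)) {
    abort(sprintf("Unknown feature level(s): %s", paste(bad_level, collapse = ", ")))
  }
  is_site <- !is.na(x$level) & x$level == "phosphosite"
  if (any(is_site)) {
    miss <- is_site & (is.na(x$site_residue) | is.na(x$site_position) |
      is.na(x$localization_prob))
    if (any(miss)) {
      abort(sprintf(
        "Phosphosite feature(s) missing residue/position/localization: %s",
        paste(head(x$feature_id[miss], 5), collapse = ", ")
      ))
    }
    bad_res <- is_site & !x$site_residue %in% c("S", "T", "Y")
    if (any(bad_res)) {
      abort(sprintf(
        "Phosphosite residue must be S, T or Y: %s",
        paste(head(x$feature_id[bad_res], 5), collapse = ", ")
      ))
    }
    bad_p <- is_site & (x$localization_prob < 0 | x$localization_prob > 1)
    if (any(bad_p)) abort("localization_prob must lie in [0, 1].")
  }
  if (any(!is_site & !is.na(x$level) & x$level == "protein" &
    (!is.na(x$site_residue) | !is.na(x$site_position) |
      !is.na(x$localization_prob)))) {
    abort("Protein-level features must not carry phosphosite annotations.")
  }
  if (intensity_scale(x) == "raw") {
    v <- intensity_values(x)
    if (any(v <= 0, na.rm = TRUE)) {
      abort("Raw-scale intensities must be positive; encode non-detection as NA.")
    }
  }
  invisible(x)
}

#' Validate a sample design table
#'
#' A design table has columns `sample_id`, `patient_id`, `tissue_class`
#' (`BE`, `ADJ` or `NONBE`), `cohort` (`discovery` or `validation`) and
#' `tmt_channel`. Enforced invariants: unique sample ids; unique
#' (cohort, channel) assignments; every BE sample paired with exactly one
#' ADJ sample of the same patient and cohort; no patient contributing both
#' BE and NONBE tissue.
#'
#' @param design Data frame with the five design columns.
#' @return The design as a tibble (invisibly validated).
#' @export
validate_design <- function(design) {
  design <- as_tibble(design)
  need <- c("sample_id", "patient_id", "tissue_class", "cohort", "tmt_channel")
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols)) {
    abort(sprintf("Design is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(design$sample_id)) abort("Duplicate sample_id in design.")
  bad <- setdiff(unique(design$tissue_class), c("BE", "ADJ", "NONBE"))
  if (length(bad)) abort(sprintf("Unknown tissue_class: %s", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(design$cohort), c("discovery", "validation"))
  if (length(bad)) abort(sprintf("Unknown cohort: %s", paste(bad, collapse = ", ")))
  key <- paste(design$cohort, design$tmt_channel)
  if (anyDuplicated(key)) {
    abort(sprintf(
      "Duplicate (cohort, tmt_channel): %s",
      paste(unique(key[duplicated(key)]), collapse = ", ")
    ))
  }
  for (co in unique(design$cohort)) {
    d <- design[design$cohort == co, ]
    be <- d[d$tissue_class == "BE", ]
    adj <- d[d$tissue_class == "ADJ", ]
    for (p in be$patient_id) {
      n_adj <- sum(adj$patient_id == p)
      if (n_adj != 1L) {
        abort(sprintf(
          "Patient %s (%s cohort) has %d ADJ samples for a BE sample; exactly 1 required.",
          p, co, n_adj
        ))
      }
    }
  }
  nonbe_pat <- unique(design$patient_id[design$tissue_class == "NONBE"])
  be_pat <- unique(design$patient_id[design$tissue_class == "BE"])
  both <- intersect(nonbe_pat, be_pat)
  if (length(both)) {
    abort(sprintf(
      "Patient(s) with both BE and NONBE tissue: %s",
      paste(both, collapse = ", ")
    ))
  }
  invisible(design)
}

#' BE/ADJ pairs of a cohort
#'
#' @param design Validated design table.
#' @param cohort Cohort to extract pairs from (default all cohorts).
#' @return Tibble with `patient_id`, `cohort`, `be_sample`, `adj_sample`,
#'   ordered by patient id.
#' @export
design_pairs <- function(design, cohort = NULL) {
  design <- validate_design(design)
  if (!is.null(cohort)) design <- design[design$cohort %in% cohort, ]
  be <- design[design$tissue_class == "BE", c("patient_id", "cohort", "sample_id")]
  adj <- design[design$tissue_class == "ADJ", c("patient_id", "cohort", "sample_id")]
  out <- dplyr::inner_join(
    dplyr::rename(be, be_sample = "sample_id"),
    dplyr::rename(adj, adj_sample = "sample_id"),
    by = c("patient_id", "cohort")
  )
  dplyr::arrange(out, .data$cohort, .data$patient_id)
}

#' Subset an intensity table to the samples of a design
#'
#' @param x An `intensity_tbl`.
#' @param design Design table (already filtered to the samples wanted).
#' @return `intensity_tbl` with only those sample columns, in design order.
#' @export
subset_samples <- function(x, design) {
  ids <- design$sample_id
  missing_s <- setdiff(ids, sample_ids(x))
  if (length(missing_s)) {
    abort(sprintf(
      "Sample(s) absent from intensity table: %s",
      paste(missing_s, collapse = ", ")
    ))
  }
  rebuild_intensity(x, intensity_values(x)[, ids, drop = FALSE])
}
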