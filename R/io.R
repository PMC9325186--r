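# Readers/writers for the external dialects: MaxQuant-style intensity TSVs,
# the sample design TSV, GMT gene sets, and the kinase-substrate TSV.
# All readers validate eagerly and return the typed containers in types.R;
# all writers emit deterministic column and row order.

.site_pattern <- "^[STY][0-9]+$"

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
}

#' Read a MaxQuant-style intensity table
#'
#' Parses a tab-separated quantification table with a `feature_id` column,
#' optional annotation columns (`gene_symbol`, and for phosphosite tables
#' `site_residue`, `site_position`, `localization_prob`) and one numeric
#' intensity column per TMT channel/sample. Zero and empty intensity cells
#' are recorded as missing (the MaxQuant convention: zero is non-detection,
#' not a measurement).
#'
#' @param path Path to the TSV file.
#' @param level `"protein"` or `"phosphosite"`; phosphosite tables must carry
#'   the three site annotation columns.
#' @return An [intensity_tbl()] on the raw scale; file order is preserved for
#'   both features and samples.
#' @export
read_intensity_table <- function(path, level = c("protein", "phosphosite")) {
  level <- match.arg(level)
  raw <- read_tsv_strict(path)
  required <- "feature_id"
  if (level == "phosphosite") {
    required <- c(required, "site_residue", "site_position", "localization_prob")
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf(
      "Intensity table %s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  meta_present <- intersect(.meta_cols, names(raw))
  sample_cols <- setdiff(names(raw), meta_present)
  if (!length(sample_cols)) abort("Intensity table has no intensity columns.")
  if (anyDuplicated(raw$feature_id)) {
    dup <- unique(raw$feature_id[duplicated(raw$feature_id)])
    abort(sprintf(
      "Duplicate feature_id(s) in %s: %s", path,
      paste(head(dup, 5), collapse = ", ")
    ))
  }

  values <- matrix(NA_real_, nrow(raw), length(sample_cols),
    dimnames = list(NULL, sample_cols)
  )
  for (col in sample_cols) {
    txt <- trimws(raw[[col]])
    blank <- txt == "" | toupper(txt) %in% c("NA", "NAN")
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(!blank & is.na(num))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric intensity '%s' in column %s, row %d of %s",
        txt[bad[1]], col, bad[1], path
      ))
    }
    num[blank | (!is.na(num) & num == 0)] <- NA_real_
    values[, col] <- num
  }

  features <- tibble(
    feature_id = raw$feature_id,
    gene_symbol = if ("gene_symbol" %in% names(raw)) {
      toupper(trimws(raw$gene_symbol))
    } else {
      NA_character_
    },
    level = level,
    site_residue = NA_character_,
    site_position = NA_integer_,
    localization_prob = NA_real_
  )
  if (level == "phosphosite") {
    pos <- suppressWarnings(as.integer(raw$site_position))
    prob <- suppressWarnings(as.numeric(raw$localization_prob))
    if (anyNA(pos) || any(pos < 1)) {
      abort(sprintf("Invalid site_position in %s (1-based positive integer required).", path))
    }
    if (anyNA(prob)) abort(sprintf("Invalid localization_prob in %s.", path))
    features$site_residue <- toupper(trimws(raw$site_residue))
    features$site_position <- pos
    features$localization_prob <- prob
  }
  intensity_tbl(features, values, scale = "raw")
}

#' Write an intensity table to TSV
#'
#' Inverse of [read_intensity_table()] for present cells: values are printed
#' with 17 significant digits so a read/write round trip is bit-identical;
#' missing cells are written as empty fields.
#'
#' @param x An `intensity_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_table <- function(x, path) {
  level <- x$level[1] %||% "protein"
  meta_out <- if (identical(level, "phosphosite")) .meta_cols else c("feature_id", "gene_symbol")
  v <- intensity_values(x)
  chr <- apply(v, 2, function(col) {
    out <- sprintf("%.17g", col)
    out[is.na(col)] <- ""
    out
  })
  chr <- matrix(chr, nrow = nrow(v), dimnames = dimnames(v))
  meta <- feature_meta(x)[, meta_out]
  meta$gene_symbol[is.na(meta$gene_symbol)] <- ""
  out <- dplyr::bind_cols(meta, as_tibble(chr, .name_repair = "minimal"))
  readr::write_tsv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `patient_id`, `tissue_class`, `cohort`,
#' `tmt_channel`; validated with [validate_design()] (BE/ADJ pairing within
#' patient and cohort, unique channel assignment).
#'
#' @param path Path to the design TSV.
#' @return A validated design tibble in file order.
#' @export
read_design <- function(path) {
  raw <- read_tsv_strict(path)
  need <- c("sample_id", "patient_id", "tissue_class", "cohort", "tmt_channel")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Design %s is missing column(s): %s", path, paste(missing_cols, collapse = ", ")))
  }
  design <- as_tibble(raw[, need])
  validate_design(design)
  design
}

#' Write a design table
#' @param design Design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(validate_design(design), path, progress = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Members are trimmed, upper-cased and de-duplicated.
#'
#' @param path Path to the GMT file.
#' @return Tibble with columns `set_name`, `description` and a list-column
#'   `members` (character vectors). An empty file yields an empty collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble(set_name = character(), description = character(), members = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", short[1]))
  }
  out <- tibble(
    set_name = vapply(parts, `[[`, "", 1L),
    description = vapply(parts, `[[`, "", 2L),
    members = lapply(parts, function(p) unique(toupper(trimws(p[-(1:2)]))))
  )
  out$members <- lapply(out$members, function(m) m[nzchar(m)])
  if (anyDuplicated(out$set_name)) abort("Duplicate set names in GMT.")
  if (any(!lengths(out$members))) abort("Empty gene set in GMT.")
  out
}

#' Write gene sets to GMT
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_name[i], sets$description[i], sort(sets$members[[i]])),
      collapse = "\t"
    )
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a kinase-substrate map
#'
#' TSV with columns `kinase`, `substrate_gene`, `site` (residue letter +
#' 1-based position, e.g. `S213`). Rows are de-duplicated; a canonical
#' `site_id` (`GENE_S213`) is added to join against phosphosite feature ids.
#'
#' @param path Path to the TSV.
#' @return Tibble with `kinase`, `substrate_gene`, `site`, `site_id`.
#' @export
read_kinase_substrate <- function(path) {
  raw <- read_tsv_strict(path)
  need <- c("kinase", "substrate_gene", "site")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf(
      "Kinase-substrate map %s is missing column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  make_kinase_substrate(raw$kinase, raw$substrate_gene, raw$site)
}

make_kinase_substrate <- function(kinase, substrate_gene, site) {
  site <- toupper(trimws(site))
  bad <- which(!grepl(.site_pattern, site))
  if (length(bad)) {
    abort(sprintf(
      "Malformed site string '%s' (row %d): expected S/T/Y + position.",
      site[bad[1]], bad[1]
    ))
  }
  out <- tibble(
    kinase = toupper(trimws(kinase)),
    substrate_gene = toupper(trimws(substrate_gene)),
    site = site
  )
  out <- dplyr::distinct(out)
  out$site_id <- paste0(out$substrate_gene, "_", out$site)
  out
}

#' Write a kinase-substrate map
#' @param ksmap Tibble as from [read_kinase_substrate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinase_substrate <- function(ksmap, path) {
  out <- dplyr::arrange(
    ksmap[, c("kinase", "substrate_gene", "site")],
    .data$kinase, .data$substrate_gene, .data$site
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
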