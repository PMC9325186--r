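# Seeded synthetic two-cohort TMT dataset generator with known ground truth.
#
# Generative model per feature f and sample s (log2 scale):
#   value(f, s) = baseline_f + patient_effect(f, patient(s)) + class_effect(f, s)
#                 + technical_noise
#   baseline_f        ~ Normal(24, 2)
#   patient_effect    ~ Normal(0, sigma_feature), shared by both biopsies of a
#                       patient (cancels in the paired BE - ADJ contrast)
#   class_effect      = compression_factor * effect_f + field_f  (BE sample)
#                     = field_f                                  (ADJ sample)
#                     = 0                                        (NONBE sample)
#   technical_noise   ~ Normal(0, sigma_noise)
# Raw intensity is 2^value; each cell is independently censored (missing) with
# probability plogis(missing_alpha - missing_beta * value), so low-abundance
# features go missing more often. Planted effects effect_f exist for a
# frac_differential subset, with balanced random signs and magnitudes
# Uniform(effect_size_range); the multiplicative compression_factor emulates
# TMT ratio compression. field_f is a patient-level "field effect": tissue
# from BE patients (both the lesion and the adjacent biopsy) carries an
# independent planted offset on the differential features, which cancels in
# the paired contrast but separates ADJ from NONBE tissue.

#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_dataset()].
#' Defaults mirror the study design: a discovery cohort of 3 BE patients
#' (paired BE + adjacent biopsies) and 2 non-BE control patients (two
#' biopsies each, 10 TMT channels per cohort) and a validation cohort with
#' 2 BE and 3 control patients.
#'
#' @param n_patients_be_discovery,n_patients_be_validation Number of BE
#'   patients (each contributes one BE and one ADJ sample).
#' @param n_patients_nonbe_discovery,n_patients_nonbe_validation Number of
#'   control patients (each contributes two NONBE samples).
#' @param n_proteins,n_phosphosites Number of features per data level.
#' @param frac_differential Fraction of features with a planted BE effect.
#' @param effect_size_range Magnitude range (log2) of planted effects, drawn
#'   uniformly with balanced random signs, before ratio compression.
#' @param compression_factor Multiplicative TMT ratio compression applied to
#'   planted effects (1 = none).
#' @param sigma_feature Patient-level biological SD (log2).
#' @param sigma_noise Technical SD per measurement (log2).
#' @param missing_alpha,missing_beta Intercept and slope of the logistic
#'   intensity-dependent missingness model (probability
#'   `plogis(missing_alpha - missing_beta * log2_value)`).
#' @param loc_prob_true_mix Probability that a phosphosite's localization
#'   probability is drawn from the confident component Uniform(0.7, 1].
#' @param field_effect_range Magnitude range (log2) of the patient-level
#'   field effect carried by BE-patient tissue on differential features.
#' @param n_genesets,geneset_size_range,n_planted_sets Gene-set collection
#'   size, per-set size range, and number of sets planted to be enriched
#'   (alternating up/down direction).
#' @param n_kinases,substrates_per_kinase,n_active_kinases Kinase-substrate
#'   map size and number of kinases planted as differentially active.
#' @param transcript_effect_correlation Correlation between planted protein
#'   effects and the emulated transcriptome effects.
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients_be_discovery = 3,
                       n_patients_be_validation = 2,
                       n_patients_nonbe_discovery = 2,
                       n_patients_nonbe_validation = 3,
                       n_proteins = 2000,
                       n_phosphosites = 3000,
                       frac_differential = 0.01,
                       effect_size_range = c(1.8, 3.0),
                       compression_factor = 0.7,
                       sigma_feature = 0.5,
                       sigma_noise = 0.25,
                       missing_alpha = 7.8,
                       missing_beta = 0.5,
                       loc_prob_true_mix = 0.9,
                       field_effect_range = c(0.5, 1.0),
                       n_genesets = 50,
                       geneset_size_range = c(10, 25),
                       n_planted_sets = 4,
                       n_kinases = 40,
                       substrates_per_kinase = 12,
                       n_active_kinases = 5,
                       transcript_effect_correlation = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  pos_int <- c(
    "n_patients_be_discovery", "n_patients_be_validation",
    "n_proteins", "n_phosphosites", "n_genesets", "n_kinases",
    "substrates_per_kinase"
  )
  for (f in pos_int) {
    if (cfg[[f]] < 1) abort(sprintf("`%s` must be a positive integer.", f))
  }
  for (f in c(
    "n_patients_nonbe_discovery", "n_patients_nonbe_validation",
    "n_planted_sets", "n_active_kinases"
  )) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be non-negative.", f))
  }
  if (cfg$frac_differential < 0 || cfg$frac_differential > 1) {
    abort("`frac_differential` must lie in [0, 1].")
  }
  if (cfg$compression_factor <= 0 || cfg$compression_factor > 1) {
    abort("`compression_factor` must lie in (0, 1].")
  }
  for (f in c("sigma_feature", "sigma_noise")) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be non-negative.", f))
  }
  if (cfg$loc_prob_true_mix < 0 || cfg$loc_prob_true_mix > 1) {
    abort("`loc_prob_true_mix` must lie in [0, 1].")
  }
  if (abs(cfg$transcript_effect_correlation) > 1) {
    abort("`transcript_effect_correlation` must lie in [-1, 1].")
  }
  for (f in c("effect_size_range", "geneset_size_range", "field_effect_range")) {
    r <- cfg[[f]]
    if (length(r) != 2 || any(r < 0) || r[2] < r[1]) {
      abort(sprintf("`%s` must be an increasing non-negative pair.", f))
    }
  }
  planted_requested <- cfg$n_planted_sets > 0 || cfg$n_active_kinases > 0
  if (planted_requested && cfg$frac_differential * cfg$n_proteins < 1) {
    abort("Planted signal requested but frac_differential * n_proteins < 1.")
  }
  if (cfg$geneset_size_range[2] > cfg$n_proteins) {
    abort("Planted/random gene sets larger than the gene universe.")
  }
  if (cfg$n_planted_sets > cfg$n_genesets) {
    abort("`n_planted_sets` cannot exceed `n_genesets`.")
  }
  if (cfg$n_active_kinases > cfg$n_kinases) {
    abort("`n_active_kinases` cannot exceed `n_kinases`.")
  }
  invisible(cfg)
}

balanced_signs <- function(n) {
  if (n == 0) return(numeric(0))
  sample(rep(c(1, -1), length.out = n))
}

planted_effects <- function(n_features, frac, range, field_range) {
  n_diff <- round(frac * n_features)
  effect <- numeric(n_features)
  field <- numeric(n_features)
  idx <- integer(0)
  if (n_diff > 0) {
    idx <- sort(sample.int(n_features, n_diff))
    effect[idx] <- balanced_signs(n_diff) * runif(n_diff, range[1], range[2])
    field[idx] <- balanced_signs(n_diff) * runif(n_diff, field_range[1], field_range[2])
  }
  list(idx = idx, effect = effect, field = field)
}

sim_design <- function(cfg) {
  one_cohort <- function(cohort, tag, n_be, n_nonbe) {
    rows <- list()
    for (i in seq_len(n_be)) {
      pat <- sprintf("P%s_BE%02d", tag, i)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = paste0(pat, c("_BE", "_ADJ")),
        patient_id = pat,
        tissue_class = c("BE", "ADJ"),
        cohort = cohort
      )
    }
    for (i in seq_len(n_nonbe)) {
      pat <- sprintf("P%s_NB%02d", tag, i)
      rows[[length(rows) + 1]] <- tibble(
        sample_id = paste0(pat, c("_N1", "_N2")),
        patient_id = pat,
        tissue_class = "NONBE",
        cohort = cohort
      )
    }
    d <- dplyr::bind_rows(rows)
    d$tmt_channel <- sprintf("C%02d", seq_len(nrow(d)))
    d
  }
  design <- dplyr::bind_rows(
    one_cohort("discovery", "D", cfg$n_patients_be_discovery, cfg$n_patients_nonbe_discovery),
    one_cohort("validation", "V", cfg$n_patients_be_validation, cfg$n_patients_nonbe_validation)
  )
  validate_design(design)
  design
}

sim_matrix <- function(features, effect, field, design, cfg) {
  n <- nrow(features)
  s <- nrow(design)
  baseline <- rnorm(n, 24, 2)
  patients <- unique(design$patient_id)
  pat_eff <- matrix(rnorm(n * length(patients), 0, cfg$sigma_feature),
    n, length(patients),
    dimnames = list(NULL, patients)
  )
  values <- matrix(0, n, s, dimnames = list(NULL, design$sample_id))
  for (j in seq_len(s)) {
    cls <- design$tissue_class[j]
    class_eff <- switch(cls,
      BE = cfg$compression_factor * effect + field,
      ADJ = field,
      NONBE = 0
    )
    values[, j] <- baseline + pat_eff[, design$patient_id[j]] + class_eff +
      rnorm(n, 0, cfg$sigma_noise)
  }
  p_miss <- plogis(cfg$missing_alpha - cfg$missing_beta * values)
  mask <- matrix(runif(n * s) < p_miss, n, s)
  raw <- 2^values
  raw[mask] <- NA_real_
  intensity_tbl(features, raw, scale = "raw")
}

sim_phospho_features <- function(cfg, genes) {
  n <- cfg$n_phosphosites
  gene <- sample(genes, n, replace = TRUE)
  residue <- sample(c("S", "T", "Y"), n, replace = TRUE, prob = c(0.55, 0.35, 0.10))
  position <- sample.int(999, n, replace = TRUE)
  id <- paste0(gene, "_", residue, position)
  while (anyDuplicated(id)) {
    dup <- which(duplicated(id))
    position[dup] <- sample.int(999, length(dup), replace = TRUE)
    id <- paste0(gene, "_", residue, position)
  }
  loc_true <- runif(n) < cfg$loc_prob_true_mix
  loc_prob <- ifelse(loc_true, runif(n, 0.7, 1.0), runif(n, 0, 0.7))
  tibble(
    feature_id = id, gene_symbol = gene, level = "phosphosite",
    site_residue = residue, site_position = as.integer(position),
    localization_prob = loc_prob
  )
}

sim_genesets <- function(cfg, genes, diff_idx, effect) {
  sizes <- sample(seq(cfg$geneset_size_range[1], cfg$geneset_size_range[2]),
    cfg$n_genesets,
    replace = TRUE
  )
  planted_dir <- rep(c(1, -1), length.out = cfg$n_planted_sets)
  members <- vector("list", cfg$n_genesets)
  nondiff <- setdiff(genes, genes[diff_idx])
  for (i in seq_len(cfg$n_genesets)) {
    if (i <= cfg$n_planted_sets) {
      same_sign <- genes[diff_idx][sign(effect[diff_idx]) == planted_dir[i]]
      n_core <- min(floor(0.6 * sizes[i]), length(same_sign))
      core <- sample(same_sign, n_core)
      filler <- sample(nondiff, sizes[i] - n_core)
      members[[i]] <- sample(c(core, filler))
    } else {
      members[[i]] <- sample(genes, sizes[i])
    }
  }
  sets <- tibble(
    set_name = sprintf("SET%03d", seq_len(cfg$n_genesets)),
    description = "synthetic gene set",
    members = members
  )
  planted <- tibble(
    set_name = sets$set_name[seq_len(cfg$n_planted_sets)],
    direction = ifelse(planted_dir > 0, "up_in_BE", "down_in_BE")
  )
  list(sets = sets, planted = planted)
}

sim_ksmap <- function(cfg, phospho, diff_idx, effect) {
  kinases <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
  active_dir <- rep(c(1, -1), length.out = cfg$n_active_kinases)
  all_sites <- phospho$feature_id
  edges <- vector("list", cfg$n_kinases)
  for (i in seq_len(cfg$n_kinases)) {
    if (i <= cfg$n_active_kinases) {
      same_sign <- diff_idx[sign(effect[diff_idx]) == active_dir[i]]
      n_core <- min(cfg$substrates_per_kinase - 2, length(same_sign))
      core <- phospho$feature_id[sample_vec(same_sign, n_core)]
      filler <- sample(setdiff(all_sites, core), cfg$substrates_per_kinase - n_core)
      subs <- c(core, filler)
    } else {
      subs <- sample(all_sites, min(cfg$substrates_per_kinase, length(all_sites)))
    }
    j <- match(subs, phospho$feature_id)
    edges[[i]] <- tibble(
      kinase = kinases[i],
      substrate_gene = phospho$gene_symbol[j],
      site = paste0(phospho$site_residue[j], phospho$site_position[j])
    )
  }
  ks <- dplyr::bind_rows(edges)
  active <- tibble(
    kinase = kinases[seq_len(cfg$n_active_kinases)],
    direction = ifelse(active_dir > 0, "up_in_BE", "down_in_BE")
  )
  list(
    ksmap = make_kinase_substrate(ks$kinase, ks$substrate_gene, ks$site),
    active = active
  )
}

# sample() without the length-1 surprise
sample_vec <- function(x, n) x[sample.int(length(x), n)]

#' Simulate a complete two-cohort (phospho)proteomic dataset
#'
#' Generates paired-cohort proteome and phosphoproteome intensity tables, a
#' sample design, a gene-set collection with planted enriched sets, a
#' kinase-substrate map with planted active kinases, and the ground truth
#' needed to score every downstream stage. Discovery and validation cohorts
#' share the planted effects (same biology) but have independent patients
#' and noise. The same seed reproduces the dataset bit-identically.
#'
#' @param config A [sim_config()].
#' @return A list of class `besig_sim` with elements `proteome`, `phospho`
#'   (raw-scale [intensity_tbl()]s), `design`, `genesets`, `ksmap`, `truth`
#'   and the `config` used. `truth` contains tibbles `differential`
#'   (feature, level, signed true log2 effect and its compressed expectation),
#'   `field_effects`, `planted_sets`, `active_kinases`, `transcript_effects`
#'   and the protein `gene_universe`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    design <- sim_design(config)
    genes <- sprintf("G%04d", seq_len(config$n_proteins))
    prot_features <- tibble(
      feature_id = genes, gene_symbol = genes, level = "protein",
      site_residue = NA_character_, site_position = NA_integer_,
      localization_prob = NA_real_
    )
    prot_fx <- planted_effects(
      config$n_proteins, config$frac_differential,
      config$effect_size_range, config$field_effect_range
    )
    phospho_features <- sim_phospho_features(config, genes)
    phos_fx <- planted_effects(
      config$n_phosphosites, config$frac_differential,
      config$effect_size_range, config$field_effect_range
    )

    proteome <- sim_matrix(prot_features, prot_fx$effect, prot_fx$field, design, config)
    phospho <- sim_matrix(phospho_features, phos_fx$effect, phos_fx$field, design, config)

    gs <- sim_genesets(config, genes, prot_fx$idx, prot_fx$effect)
    ks <- sim_ksmap(config, phospho_features, phos_fx$idx, phos_fx$effect)

    rho <- config$transcript_effect_correlation
    e <- prot_fx$effect
    eta <- rnorm(config$n_proteins, 0, sd(e))
    transcript_effect <- rho * e + sqrt(1 - rho^2) * eta

    truth <- list(
      differential = dplyr::bind_rows(
        tibble(
          feature_id = prot_features$feature_id[prot_fx$idx],
          level = "protein",
          true_effect = prot_fx$effect[prot_fx$idx],
          expected_delta = config$compression_factor * prot_fx$effect[prot_fx$idx]
        ),
        tibble(
          feature_id = phospho_features$feature_id[phos_fx$idx],
          level = "phosphosite",
          true_effect = phos_fx$effect[phos_fx$idx],
          expected_delta = config$compression_factor * phos_fx$effect[phos_fx$idx]
        )
      ),
      field_effects = dplyr::bind_rows(
        tibble(
          feature_id = prot_features$feature_id[prot_fx$idx],
          level = "protein", field_effect = prot_fx$field[prot_fx$idx]
        ),
        tibble(
          feature_id = phospho_features$feature_id[phos_fx$idx],
          level = "phosphosite", field_effect = phos_fx$field[phos_fx$idx]
        )
      ),
      planted_sets = gs$planted,
      active_kinases = ks$active,
      transcript_effects = tibble(
        gene_symbol = genes,
        protein_effect = e,
        effect = transcript_effect
      ),
      gene_universe = genes
    )
    structure(
      list(
        proteome = proteome, phospho = phospho, design = design,
        genesets = gs$sets, ksmap = ks$ksmap, truth = truth, config = config
      ),
      class = "besig_sim"
    )
  })
}

#' Simulate a correlated transcriptome cohort
#'
#' Emulates an independent BE-vs-normal gene-expression study for signature
#' projection: per-gene transcript effect = `correlation` x protein effect +
#' `sqrt(1 - correlation^2)` x an independent draw scaled to equal variance.
#' Default sizes (7 BE vs 7 normal) mirror the smallest of the public
#' transcriptome cohorts used for cross-omics validation.
#'
#' @param truth Ground truth from [simulate_dataset()].
#' @param n_be,n_normal Samples per class.
#' @param correlation Transcript-protein effect correlation; `NULL` reuses
#'   the transcript effects already recorded in `truth`.
#' @param seed Integer seed.
#' @param sigma_sample Per-sample expression SD (log2).
#' @return List with `expr` (log2-scale [intensity_tbl()], gene symbols as
#'   feature ids) and `labels` (tibble `sample_id`, `tissue_class` in
#'   `BE`/`NORMAL`).
#' @export
simulate_transcriptome <- function(truth, n_be = 7, n_normal = 7,
                                   correlation = NULL, seed = 1L,
                                   sigma_sample = 0.5) {
  if (!is.null(correlation) && abs(correlation) > 1) {
    abort("`correlation` must lie in [-1, 1].")
  }
  genes <- truth$gene_universe
  e <- truth$transcript_effects$protein_effect
  withr::with_seed(seed, {
    t_eff <- if (is.null(correlation)) {
      truth$transcript_effects$effect
    } else {
      eta <- rnorm(length(e), 0, sd(e))
      correlation * e + sqrt(1 - correlation^2) * eta
    }
    labels <- tibble(
      sample_id = c(sprintf("T_BE%02d", seq_len(n_be)), sprintf("T_N%02d", seq_len(n_normal))),
      tissue_class = rep(c("BE", "NORMAL"), c(n_be, n_normal))
    )
    baseline <- rnorm(length(genes), 8, 2)
    values <- vapply(seq_len(nrow(labels)), function(j) {
      eff <- if (labels$tissue_class[j] == "BE") t_eff else 0
      baseline + eff + rnorm(length(genes), 0, sigma_sample)
    }, numeric(length(genes)))
    colnames(values) <- labels$sample_id
    expr <- intensity_tbl(
      tibble(feature_id = genes, gene_symbol = genes, level = "protein"),
      values,
      scale = "log2"
    )
    list(expr = expr, labels = labels, effects = t_eff)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits every input file the pipeline reads (proteome/phospho intensity
#' TSVs, design TSV, GMT, kinase-substrate TSV) plus `truth.tsv` (feature,
#' true_effect, is_differential) and `truth_sets.tsv` (planted gene sets and
#' kinases) for scoring.
#'
#' @param sim A `besig_sim` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_intensity_table(sim$proteome, file.path(outdir, "proteome.tsv"))
  write_intensity_table(sim$phospho, file.path(outdir, "phospho.tsv"))
  write_design(sim$design, file.path(outdir, "design.tsv"))
  write_gmt(sim$genesets, file.path(outdir, "genesets.gmt"))
  write_kinase_substrate(sim$ksmap, file.path(outdir, "kinase_substrate.tsv"))
  all_features <- dplyr::bind_rows(
    tibble(feature = sim$proteome$feature_id, level = "protein"),
    tibble(feature = sim$phospho$feature_id, level = "phosphosite")
  )
  tr <- dplyr::left_join(
    all_features,
    dplyr::select(sim$truth$differential,
      feature = "feature_id", "level", "true_effect"
    ),
    by = c("feature", "level")
  )
  tr$is_differential <- !is.na(tr$true_effect)
  tr$true_effect[is.na(tr$true_effect)] <- 0
  readr::write_tsv(tr, file.path(outdir, "truth.tsv"), progress = FALSE)
  sets <- dplyr::bind_rows(
    dplyr::mutate(sim$truth$planted_sets, kind = "gene_set", name = .data$set_name) |>
      dplyr::select("kind", "name", "direction"),
    dplyr::mutate(sim$truth$active_kinases, kind = "kinase", name = .data$kinase) |>
      dplyr::select("kind", "name", "direction")
  )
  readr::write_tsv(sets, file.path(outdir, "truth_sets.tsv"), progress = FALSE)
  invisible(outdir)
}
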