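# End-to-end orchestration: simulate (or read) -> preprocess -> paired
# differential analysis -> signature + empirical FDR -> clustering
# classification (validation cohort and transcriptome projection) -> GSEA
# (proteome + phosphoproteome) -> kinase enrichment -> ADJ-vs-NONBE
# contrast. One master seed deterministically derives per-stage seeds, and
# reruns with the same seed are byte-identical.

#' Pipeline configuration
#'
#' All stage parameters with their study defaults: localization probability
#' floor 0.7; signature = top 1% by p-value with |log2FC| >= 0.75; 100
#' sign-flip randomizations for the empirical FDR; 10,000 permutations for
#' GSEA; kinase significance at p < 0.05; pathway significance at
#' FDR < 0.05.
#'
#' @param input_dir Directory with user-supplied inputs (`proteome.tsv`,
#'   `phospho.tsv`, `design.tsv`, `genesets.gmt`, `kinase_substrate.tsv`);
#'   `NULL` simulates inputs with `sim`.
#' @param sim A [sim_config()] used when simulating (its seed is overridden
#'   by a stage seed derived from `seed`).
#' @param min_loc_prob,top_frac,min_abs_lfc,n_rand,n_perm,alpha,fdr_pathway
#'   Stage parameters (see module functions).
#' @param min_substrates Minimum quantified substrates per scored kinase.
#' @param k_validation Clusters for the validation-cohort classification
#'   (BE/ADJ/NONBE = 3).
#' @param gsea_min_size,gsea_max_size Eligible gene-set sizes.
#' @param transcriptome_n_be,transcriptome_n_normal Simulated transcriptome
#'   cohort sizes (7/7 mirrors the smallest public cohort).
#' @param seed Master seed.
#' @return List of class `besig_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            sim = sim_config(),
                            min_loc_prob = 0.7,
                            top_frac = 0.01,
                            min_abs_lfc = 0.75,
                            n_rand = 100,
                            n_perm = 10000,
                            alpha = 0.05,
                            fdr_pathway = 0.05,
                            min_substrates = 3,
                            k_validation = 3,
                            gsea_min_size = 5,
                            gsea_max_size = 500,
                            transcriptome_n_be = 7,
                            transcriptome_n_normal = 7,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    min_loc_prob >= 0, min_loc_prob <= 1,
    top_frac > 0, top_frac <= 1,
    min_abs_lfc >= 0, n_rand >= 1, n_perm >= 1,
    alpha > 0, alpha < 1, fdr_pathway > 0, fdr_pathway < 1,
    min_substrates >= 1, k_validation >= 2
  )
  class(cfg) <- "besig_config"
  cfg
}

#' Write / read a pipeline configuration (YAML)
#'
#' The configuration round-trips unchanged (`sim = NULL` inside the file
#' means "use input_dir").
#'
#' @param config A `besig_config`.
#' @param path YAML path.
#' @return `path` / the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$sim <- if (is.null(out$sim)) NULL else unclass(out$sim)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (is.null(raw$sim)) sim_config() else do.call(sim_config, raw$sim)
  raw$sim <- NULL
  do.call(pipeline_config, c(raw, list(sim = sim)))
}

# Deterministic per-stage seed derived from the master seed and stage name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 97) %% (.Machine$integer.max - 1)) + 1L
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

read_inputs <- function(input_dir) {
  need <- c(
    proteome = "proteome.tsv", phospho = "phospho.tsv", design = "design.tsv",
    genesets = "genesets.gmt", ksmap = "kinase_substrate.tsv"
  )
  paths <- file.path(input_dir, need)
  missing_f <- paths[!file.exists(paths)]
  if (length(missing_f)) {
    abort(sprintf("Missing input file(s): %s", paste(missing_f, collapse = ", ")))
  }
  list(
    proteome = read_intensity_table(paths[1], level = "protein"),
    phospho = read_intensity_table(paths[2], level = "phosphosite"),
    design = read_design(paths[3]),
    genesets = read_gmt(paths[4]),
    ksmap = read_kinase_substrate(paths[5]),
    truth = NULL
  )
}

combine_cohort_matrices <- function(mats) {
  mats <- mats[!vapply(mats, is.null, TRUE)]
  common <- Reduce(intersect, lapply(mats, function(m) m$feature_id))
  if (!length(common)) abort("No features shared across cohorts.")
  pieces <- lapply(mats, function(m) {
    intensity_values(m)[match(common, m$feature_id), , drop = FALSE]
  })
  values <- do.call(cbind, pieces)
  meta <- feature_meta(mats[[1]])[match(common, mats[[1]]$feature_id), ]
  out <- dplyr::bind_cols(meta, as_tibble(values, .name_repair = "minimal"))
  new_intensity(out, intensity_scale(mats[[1]]))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated or user-supplied inputs, writing each
#' intermediate as a TSV under `outdir` plus a `manifest.yaml` recording
#' package version, parameters, per-stage seeds and input digests. Rerunning
#' with the same configuration reproduces every output byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  # -- inputs -------------------------------------------------------------
  inputs <- run_stage("simulate", {
    if (is.null(config$input_dir)) {
      sim_cfg <- config$sim
      sim_cfg$seed <- stage_seed(config$seed, "simulate")
      sim <- simulate_dataset(sim_cfg)
      write_simulated_dataset(sim, file.path(outdir, "input"))
      sim
    } else {
      read_inputs(config$input_dir)
    }
  })
  note("simulate")
  has_validation <- "validation" %in% inputs$design$cohort

  # -- preprocess ---------------------------------------------------------
  pp <- run_stage("preprocess", {
    out <- list(
      prot_disc = preprocess(inputs$proteome, inputs$design, "discovery", config$min_loc_prob),
      phos_disc = preprocess(inputs$phospho, inputs$design, "discovery", config$min_loc_prob)
    )
    if (has_validation) {
      out$prot_val <- preprocess(inputs$proteome, inputs$design, "validation", config$min_loc_prob)
      out$phos_val <- preprocess(inputs$phospho, inputs$design, "validation", config$min_loc_prob)
    }
    out
  })
  report <- dplyr::bind_rows(lapply(names(pp), function(nm) {
    dplyr::mutate(pp[[nm]]$report, table = nm, .before = 1)
  }))
  readr::write_tsv(report, file.path(outdir, "preprocess_report.tsv"), progress = FALSE)
  for (nm in names(pp)) {
    write_intensity_table(pp[[nm]]$data, file.path(outdir, paste0("normalized_", nm, ".tsv")))
  }
  note("preprocess")

  # -- paired differential (discovery, BE vs ADJ) -------------------------
  diff_prot <- run_stage("diff", differential_paired(pp$prot_disc$data, inputs$design))
  diff_phos <- run_stage("diff", differential_paired(pp$phos_disc$data, inputs$design))
  readr::write_tsv(tidy(diff_prot), file.path(outdir, "diff_proteome_discovery.tsv"), progress = FALSE)
  readr::write_tsv(tidy(diff_phos), file.path(outdir, "diff_phospho_discovery.tsv"), progress = FALSE)
  note("diff")

  # -- signature + empirical FDR ------------------------------------------
  sig <- run_stage("signature", {
    sig_prot <- select_signature(diff_prot, config$top_frac, config$min_abs_lfc)
    sig_phos <- select_signature(diff_phos, config$top_frac, config$min_abs_lfc)
    efdr <- empirical_fdr(
      pp$prot_disc$data, inputs$design,
      top_frac = config$top_frac, min_abs_lfc = config$min_abs_lfc,
      n_rand = config$n_rand, seed = stage_seed(config$seed, "signature")
    )
    list(prot = sig_prot, phos = sig_phos, efdr = efdr)
  })
  readr::write_tsv(as_tibble(sig$prot), file.path(outdir, "signature_proteome.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(sig$phos), file.path(outdir, "signature_phospho.tsv"), progress = FALSE)
  readr::write_tsv(glance(sig$efdr), file.path(outdir, "empirical_fdr.tsv"), progress = FALSE)
  note("signature")

  # -- classification -----------------------------------------------------
  clust_rows <- list()
  if (has_validation && nrow(sig$prot)) {
    cl_val <- run_stage("classify", {
      proj <- project_signature(pp$prot_val$data, sig$prot)
      hierarchical_cluster(proj, k = config$k_validation, labels = inputs$design)
    })
    readr::write_tsv(tidy(cl_val), file.path(outdir, "clusters_validation.tsv"), progress = FALSE)
    clust_rows$validation <- dplyr::mutate(glance(cl_val), cohort = "validation", .before = 1)
  }
  if (!is.null(inputs$truth) && nrow(sig$prot)) {
    cl_tx <- run_stage("classify", {
      tx <- simulate_transcriptome(
        inputs$truth,
        n_be = config$transcriptome_n_be, n_normal = config$transcriptome_n_normal,
        seed = stage_seed(config$seed, "transcriptome")
      )
      proj <- project_signature(tx$expr, sig$prot)
      hierarchical_cluster(proj, k = 2, labels = setNames(tx$labels$tissue_class, tx$labels$sample_id))
    })
    readr::write_tsv(tidy(cl_tx), file.path(outdir, "clusters_transcriptome.tsv"), progress = FALSE)
    clust_rows$transcriptome <- dplyr::mutate(glance(cl_tx), cohort = "transcriptome", .before = 1)
  }
  if (length(clust_rows)) {
    readr::write_tsv(dplyr::bind_rows(clust_rows), file.path(outdir, "clustering_summary.tsv"),
      progress = FALSE)
    note("classify")
  }

  # -- GSEA ---------------------------------------------------------------
  gsea <- run_stage("gsea", {
    list(
      prot = gsea_preranked(make_ranked_list(diff_prot), inputs$genesets,
        n_perm = config$n_perm, min_size = config$gsea_min_size,
        max_size = config$gsea_max_size, seed = stage_seed(config$seed, "gsea_prot")
      ),
      phos = gsea_preranked(make_ranked_list(diff_phos), inputs$genesets,
        n_perm = config$n_perm, min_size = config$gsea_min_size,
        max_size = config$gsea_max_size, seed = stage_seed(config$seed, "gsea_phos")
      )
    )
  })
  write_gsea(gsea$prot, file.path(outdir, "gsea_proteome.tsv"))
  write_gsea(gsea$phos, file.path(outdir, "gsea_phospho.tsv"))
  note("gsea")

  # -- kinase enrichment --------------------------------------------------
  ksea <- run_stage("ksea", kinase_zscores(diff_phos, inputs$ksmap, config$min_substrates))
  readr::write_tsv(as_tibble(ksea), file.path(outdir, "kinases.tsv"), progress = FALSE)
  readr::write_tsv(kinase_substrate_edges(inputs$ksmap, diff_phos),
    file.path(outdir, "kinase_edges.tsv"), progress = FALSE)
  note("ksea")

  # -- ADJ vs NONBE contrast ---------------------------------------------
  if (sum(inputs$design$tissue_class == "NONBE") >= 2) {
    contrast <- run_stage("contrast_adj_nonbe", {
      mats <- list(pp$prot_disc$data, if (has_validation) pp$prot_val$data)
      combined <- combine_cohort_matrices(mats)
      suppressMessages(two_group_contrast(combined, inputs$design, "ADJ", "NONBE"))
    })
    readr::write_tsv(tidy(contrast), file.path(outdir, "diff_adj_vs_nonbe.tsv"), progress = FALSE)
    note("contrast_adj_nonbe")
  }

  # -- manifest -----------------------------------------------------------
  input_files <- list.files(file.path(outdir, "input"), full.names = TRUE)
  manifest <- list(
    package = "besig",
    version = as.character(utils::packageVersion("besig")),
    seed = config$seed,
    stage_seeds = lapply(
      setNames(nm = c("simulate", "signature", "gsea_prot", "gsea_phos", "transcriptome")),
      function(s) stage_seed(config$seed, s)
    ),
    parameters = unclass(config[setdiff(names(config), "sim")]),
    sim = if (is.null(config$input_dir)) unclass(config$sim) else NULL,
    stages = unique(stages),
    input_digests = if (length(input_files)) {
      as.list(setNames(unname(tools::md5sum(input_files)), basename(input_files)))
    } else {
      NULL
    }
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

report_quantity <- function(quantity, value) tibble(quantity = quantity, value = value)

#' Summarize a completed pipeline run
#'
#' Builds a deterministic one-row-per-quantity report (feature counts,
#' signature size and direction split, empirical FDR, clustering agreement,
#' enriched pathway and significant kinase counts) and exports volcano-plot
#' data (log2FC vs -log10 p) for the paired contrasts.
#'
#' @param outdir Directory written by [run_pipeline()].
#' @param fdr_pathway Pathway significance threshold used in the counts.
#' @param alpha Kinase significance threshold.
#' @return The report tibble (also written to `report.tsv`).
#' @export
pipeline_report <- function(outdir, fdr_pathway = 0.05, alpha = 0.05) {
  need <- c(
    "preprocess_report.tsv", "diff_proteome_discovery.tsv",
    "diff_phospho_discovery.tsv", "signature_proteome.tsv",
    "empirical_fdr.tsv", "gsea_proteome.tsv", "gsea_phospho.tsv", "kinases.tsv"
  )
  missing_f <- need[!file.exists(file.path(outdir, need))]
  if (length(missing_f)) {
    abort(sprintf("Incomplete run; missing: %s", paste(missing_f, collapse = ", ")))
  }
  rd <- function(f) readr::read_tsv(file.path(outdir, f), show_col_types = FALSE, progress = FALSE)
  pp <- rd("preprocess_report.tsv")
  dp <- rd("diff_proteome_discovery.tsv")
  dph <- rd("diff_phospho_discovery.tsv")
  sig <- rd("signature_proteome.tsv")
  sigph <- rd("signature_phospho.tsv")
  efdr <- rd("empirical_fdr.tsv")
  gsp <- rd("gsea_proteome.tsv")
  gsph <- rd("gsea_phospho.tsv")
  kin <- rd("kinases.tsv")

  for (f in c("diff_proteome_discovery.tsv", "diff_phospho_discovery.tsv")) {
    d <- rd(f)
    volcano <- tibble(
      feature_id = d$feature_id, log2fc = d$log2fc,
      neg_log10_p = -log10(d$p_value)
    )
    readr::write_tsv(volcano,
      file.path(outdir, sub("^diff_", "volcano_", f)),
      progress = FALSE
    )
  }

  rows <- dplyr::bind_rows(
    report_quantity(
      "n_proteins_quantified_discovery",
      pp$n_after_completeness[pp$table == "prot_disc"]
    ),
    report_quantity(
      "n_phosphosites_quantified_discovery",
      pp$n_after_completeness[pp$table == "phos_disc"]
    ),
    report_quantity("n_proteins_p05", sum(dp$p_value < 0.05)),
    report_quantity("n_phosphosites_p05", sum(dph$p_value < 0.05)),
    report_quantity("signature_size_proteome", nrow(sig)),
    report_quantity("signature_up_in_be", sum(sig$direction == "up_in_BE")),
    report_quantity("signature_down_in_be", sum(sig$direction == "down_in_BE")),
    report_quantity("signature_size_phospho", nrow(sigph)),
    report_quantity("empirical_fdr", efdr$empirical_fdr[1]),
    report_quantity("n_pathways_fdr05_proteome", sum(gsp$fdr < fdr_pathway)),
    report_quantity("n_pathways_fdr05_phospho", sum(gsph$fdr < fdr_pathway)),
    report_quantity("n_kinases_significant", sum(kin$p_value < alpha))
  )
  cs_path <- file.path(outdir, "clustering_summary.tsv")
  if (file.exists(cs_path)) {
    cs <- rd("clustering_summary.tsv")
    for (i in seq_len(nrow(cs))) {
      rows <- dplyr::bind_rows(
        rows,
        report_quantity(paste0("clustering_purity_", cs$cohort[i]), cs$purity[i]),
        report_quantity(paste0("clustering_ari_", cs$cohort[i]), cs$adjusted_rand[i])
      )
    }
  }
  readr::write_tsv(rows, file.path(outdir, "report.tsv"), progress = FALSE)
  rows
}
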