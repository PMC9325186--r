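# Shared fixture builders and independent oracles (kept as separate, naive
# code paths so they can cross-check the package implementations).

make_intensity <- function(values, ids = NULL, genes = NULL, scale = "raw") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  ids <- ids %||% sprintf("F%03d", seq_len(nrow(values)))
  intensity_tbl(
    tibble::tibble(
      feature_id = ids, gene_symbol = genes %||% ids, level = "protein"
    ),
    values,
    scale = scale
  )
}

make_phospho_intensity <- function(values, ids, genes, residues, positions, probs,
                                   scale = "raw") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  intensity_tbl(
    tibble::tibble(
      feature_id = ids, gene_symbol = genes, level = "phosphosite",
      site_residue = residues, site_position = as.integer(positions),
      localization_prob = probs
    ),
    values,
    scale = scale
  )
}

make_paired_design <- function(n_pairs, cohort = "discovery", n_nonbe_patients = 0) {
  rows <- list()
  for (i in seq_len(n_pairs)) {
    pat <- sprintf("P%02d", i)
    rows[[i]] <- tibble::tibble(
      sample_id = paste0(pat, c("_BE", "_ADJ")), patient_id = pat,
      tissue_class = c("BE", "ADJ"), cohort = cohort
    )
  }
  for (i in seq_len(n_nonbe_patients)) {
    pat <- sprintf("N%02d", i)
    rows[[n_pairs + i]] <- tibble::tibble(
      sample_id = paste0(pat, c("_N1", "_N2")), patient_id = pat,
      tissue_class = "NONBE", cohort = cohort
    )
  }
  d <- dplyr::bind_rows(rows)
  d$tmt_channel <- sprintf("C%02d", seq_len(nrow(d)))
  d
}

make_pairdiff <- function(deltas, ids = NULL) {
  deltas <- as.matrix(deltas)
  colnames(deltas) <- sprintf("P%02d", seq_len(ncol(deltas)))
  ids <- ids %||% sprintf("F%03d", seq_len(nrow(deltas)))
  out <- dplyr::bind_cols(
    tibble::tibble(feature_id = ids),
    tibble::as_tibble(deltas, .name_repair = "minimal")
  )
  attr(out, "feature_meta") <- tibble::tibble(
    feature_id = ids, gene_symbol = ids, level = "protein",
    site_residue = NA_character_, site_position = NA_integer_,
    localization_prob = NA_real_
  )
  class(out) <- c("besig_pairdiff", class(tibble::tibble()))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles ---------------------------------------------------

# Benjamini-Hochberg by explicit step-up over all thresholds.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(seq_len(m), function(j) {
      if (p[ord[j]] >= p[ord[i]]) m * p[ord[j]] / j else Inf
    }, numeric(1))
    q[ord[i]] <- min(1, min(candidates))
  }
  q
}

# Naive O(N * |S|) running-sum enrichment score: recompute hit/miss sums from
# scratch at every rank position.
oracle_es <- function(stats, hit, weight_exp = 1) {
  n <- length(stats)
  m <- sum(hit)
  w <- abs(stats)^weight_exp
  w[w == 0] <- .Machine$double.xmin
  denom <- sum(w[hit])
  running <- numeric(n)
  for (i in seq_len(n)) {
    hits_sum <- 0
    miss_count <- 0
    for (j in seq_len(i)) {
      if (hit[j]) hits_sum <- hits_sum + w[j] else miss_count <- miss_count + 1
    }
    running[i] <- hits_sum / denom - miss_count / (n - m)
  }
  pos <- max(running)
  neg <- min(running)
  list(es = if (pos >= -neg) pos else neg, running_sum = running)
}

classical_paired_t <- function(deltas) {
  n <- length(deltas)
  mean(deltas) / (sd(deltas) / sqrt(n))
}

run_default_sim <- function(seed) {
  sim <- simulate_dataset(sim_config(seed = seed))
  pp <- preprocess(sim$proteome, sim$design, "discovery")
  d <- differential_paired(pp$data, sim$design)
  list(sim = sim, pp = pp, diff = d)
}
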