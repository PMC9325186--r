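# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score with a gene-permutation (random same-size set) null.
#
# For a ranked list of N statistics and a set S of m members, walking down
# the ranking increments the running sum by |stat|^w / sum_hits |stat|^w at
# members and decrements by 1/(N - m) at non-members; the enrichment score
# is the signed maximum deviation from zero.

#' Build a ranked gene list from differential results
#'
#' Ranks by the moderated t statistic (descending). Phosphosite results are
#' collapsed to gene level by keeping, per gene, the site with the largest
#' |t|. Features flagged `zero_variance` (undefined t) are dropped. Ties are
#' broken by feature id so the order is deterministic.
#'
#' @param results A `besig_diff` tibble with `gene_symbol` (phosphosite
#'   collapse requires it; protein results fall back to `feature_id` when
#'   the symbol is missing).
#' @return Tibble of class `besig_ranked` with `feature_id` (upper-cased
#'   gene symbol) and `stat`, strictly ordered.
#' @export
make_ranked_list <- function(results) {
  if (!nrow(results)) abort("`results` is empty.")
  res <- results[results$flag == "ok" & !is.na(results$t_mod), ]
  gene <- if ("gene_symbol" %in% names(res)) {
    ifelse(is.na(res$gene_symbol), res$feature_id, res$gene_symbol)
  } else {
    res$feature_id
  }
  out <- tibble(feature_id = toupper(gene), stat = res$t_mod)
  out <- out %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::slice(which.max(abs(.data$stat))) %>%
    dplyr::ungroup()
  out <- dplyr::arrange(out, dplyr::desc(.data$stat), .data$feature_id)
  class(out) <- c("besig_ranked", class(tibble()))
  out
}

rank_weights <- function(stat, weight_exp) {
  w <- abs(stat)^weight_exp
  # degenerate guard: a hit with |stat| = 0 carries the smallest usable weight
  w[w == 0] <- .Machine$double.xmin
  w
}

#' Running-sum enrichment score
#'
#' @param ranked A `besig_ranked` list (or tibble with `feature_id`, `stat`
#'   in descending-stat order).
#' @param members Character vector of set members (matched case-insensitively
#'   against `feature_id`); the overlap must be non-empty and proper.
#' @param weight_exp Weighting exponent on |stat| (1 = weighted KS; 0 =
#'   classic unweighted KS).
#' @return List with `es` (in [-1, 1]) and `running_sum` (length N).
#' @export
enrichment_score <- function(ranked, members, weight_exp = 1) {
  hit <- ranked$feature_id %in% toupper(members)
  n <- length(hit)
  m <- sum(hit)
  if (m == 0 || m == n) {
    abort("Set must overlap the ranked list in at least 1 and fewer than N features.")
  }
  w <- rank_weights(ranked$stat, weight_exp)
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - m)
  running <- cumsum(inc)
  pos <- max(running)
  neg <- min(running)
  es <- if (pos >= -neg) pos else neg
  list(es = es, running_sum = running)
}

# Null enrichment scores for random same-size member sets, vectorized over
# permutations. Only hit positions matter: with sorted positions p_1<...<p_m,
# the running sum just after hit i is cum_i/S - (p_i - i)/(N - m) and just
# before it is the same minus w_i/S; the extremes over i give the ES.
null_enrichment_scores <- function(w, m, n_perm) {
  n <- length(w)
  pos_mat <- vapply(seq_len(n_perm), function(i) sort.int(sample.int(n, m)),
    integer(m))
  pos_mat <- matrix(pos_mat, nrow = m)
  wm <- matrix(w[pos_mat], nrow = m)
  s <- .colSums(wm, m, n_perm)
  cum <- apply(wm, 2, cumsum)
  cum <- matrix(cum, nrow = m)
  miss <- (pos_mat - seq_len(m)) / (n - m)
  after <- sweep(cum, 2, s, "/") - miss
  before <- after - sweep(wm, 2, s, "/")
  pos_ext <- Reduce(pmax, asplit(after, 1))
  neg_ext <- Reduce(pmin, asplit(before, 1))
  ifelse(pos_ext >= -neg_ext, pos_ext, neg_ext)
}

#' Preranked GSEA with permutation p-values
#'
#' For each eligible gene set, computes the observed enrichment score and a
#' null distribution of scores from `n_perm` random same-size member sets
#' (gene-permutation null). The p-value compares |ES| with same-sign null
#' scores, `p = (1 + #{same sign, |ES_null| >= |ES|}) / (1 + #same-sign)`;
#' NES divides ES by the mean |ES_null| of the same sign; FDR is
#' Benjamini-Hochberg across sets.
#'
#' @param ranked A `besig_ranked` list.
#' @param sets Gene-set tibble as from [read_gmt()] (`set_name`,
#'   `description`, `members` list-column).
#' @param n_perm Permutations per set (default 10000; < 100 warns).
#' @param min_size,max_size Eligible set-size bounds after intersection with
#'   the ranked universe.
#' @param weight_exp Weighting exponent (see [enrichment_score()]).
#' @param seed Integer seed.
#' @return Tibble of class `besig_gsea`: `set_name`, `size`, `es`, `nes`,
#'   `p_value`, `fdr`, `leading_edge` (list-column of feature ids), ordered
#'   by p-value.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 10000, min_size = 5,
                           max_size = 500, weight_exp = 1, seed = 1L) {
  if (n_perm < 100) warn("Fewer than 100 permutations: p-values will be coarse.")
  universe <- ranked$feature_id
  n <- length(universe)
  overlap <- lapply(sets$members, function(m) intersect(toupper(m), universe))
  size <- lengths(overlap)
  eligible <- which(size >= min_size & size <= max_size & size < n)
  if (!length(eligible)) abort("No gene set within the size bounds overlaps the ranking.")
  w <- rank_weights(ranked$stat, weight_exp)

  rows <- withr::with_seed(seed, {
    lapply(eligible, function(i) {
      memb <- overlap[[i]]
      obs <- enrichment_score(ranked, memb, weight_exp)
      es <- obs$es
      null_es <- null_enrichment_scores(w, length(memb), n_perm)
      same <- if (es >= 0) null_es > 0 else null_es < 0
      n_same <- sum(same)
      p <- (1 + sum(same & abs(null_es) >= abs(es))) / (1 + n_same)
      nes <- if (n_same > 0) es / mean(abs(null_es[same])) else NA_real_
      run <- obs$running_sum
      hit <- ranked$feature_id %in% memb
      le <- if (es >= 0) {
        ranked$feature_id[hit & seq_len(n) <= which.max(run)]
      } else {
        ranked$feature_id[hit & seq_len(n) >= which.min(run)]
      }
      tibble(
        set_name = sets$set_name[i], size = length(memb), es = es,
        nes = nes, p_value = p, leading_edge = list(le)
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name),
    c("set_name", "size", "es", "nes", "p_value", "fdr", "leading_edge")]
  class(out) <- c("besig_gsea", class(tibble()))
  out
}

#' @export
#' @method glance besig_gsea
glance.besig_gsea <- function(x, ...) {
  tibble(
    n_sets = nrow(x),
    n_fdr05 = sum(x$fdr < 0.05),
    n_up = sum(x$nes > 0, na.rm = TRUE),
    n_down = sum(x$nes < 0, na.rm = TRUE)
  )
}

#' Write GSEA results to TSV (leading edge comma-joined)
#' @param x A `besig_gsea` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gsea <- function(x, path) {
  out <- x
  out$leading_edge <- vapply(x$leading_edge, paste, "", collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
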