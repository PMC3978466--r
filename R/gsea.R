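#' Running enrichment score of a gene set on a ranked list
#'
#' Weighted Kolmogorov-Smirnov-like statistic: walking down the ranked list,
#' the running sum increases by `|score|^weight_p / N_R` at each member gene
#' ("hit", `N_R` the sum of those weights) and decreases by `1 / (N - N_H)`
#' at each non-member. The enrichment score (ES) is the running sum's value
#' at its maximum absolute deviation from zero; the first index attaining
#' the extremum is the peak. Positive ES means the set is concentrated at
#' the top (upregulated end) of the list. With `weight_p = 0` the statistic
#' reduces to the classical equal-increment Kolmogorov-Smirnov form.
#'
#' @param ranked A `ranked_list` (tibble with `gene`, `d_score`, sorted by
#'   descending score).
#' @param members Character vector of gene-set member symbols.
#' @param weight_p Hit-weight exponent (default 1).
#' @return A list with `es`, `peak_index` (1-based rank of the extremum),
#'   `hit_index` (ranks of the detected members) and `running` (numeric
#'   vector of the running sum at every rank).
#' @export
enrichment_score <- function(ranked, members, weight_p = 1) {
  n <- nrow(ranked)
  hit_index <- which(ranked$gene %in% members)
  nh <- length(hit_index)
  if (nh == 0L) abort("Gene set has no members in the ranked list")
  if (nh == n) abort("Gene set covers the entire ranked list")
  w <- abs(ranked$d_score[hit_index])^weight_p
  nr <- sum(w)
  if (nr == 0) abort("All member scores are zero; enrichment score undefined")
  incr <- rep.int(-1 / (n - nh), n)
  incr[hit_index] <- w / nr
  running <- cumsum(incr)
  # first index attaining the extremum; exact ties between the positive and
  # negative deviation (rational in exact arithmetic) are recognized at
  # floating-point resolution
  m <- max(abs(running))
  peak <- which(abs(running) >= m - 1e-12)[1L]
  list(es = running[peak], peak_index = peak,
       hit_index = hit_index, running = running)
}

# Fast ES for permutation nulls: the running sum is piecewise linear between
# hits, so its extrema lie at hit positions (maxima) or just before hits
# (minima); only those candidates are evaluated.
es_fast <- function(hit_index, weights, n) {
  nh <- length(hit_index)
  nr <- sum(weights)
  cumw <- cumsum(weights) / nr
  missed <- (hit_index - seq_len(nh)) / (n - nh)
  v_at <- cumw - missed                  # value at each hit position
  v_before <- c(0, cumw[-nh]) - missed   # value at hit position - 1
  idx <- c(hit_index, hit_index - 1L)
  val <- c(v_at, v_before)
  keep <- idx >= 1L
  idx <- idx[keep]; val <- val[keep]
  m <- max(abs(val))
  at <- which(abs(val) >= m - 1e-12)   # same tie rule as enrichment_score
  pick <- at[which.min(idx[at])]
  list(es = val[pick], peak_index = idx[pick])
}

#' Leading-edge genes of an enrichment result
#'
#' For positive ES the leading edge is the set members at ranks at or before
#' the peak; for negative ES, the members at ranks at or after the peak.
#'
#' @param ranked A `ranked_list`.
#' @param members Gene-set member symbols.
#' @param es_result Result of [enrichment_score()].
#' @return Character vector of leading-edge gene symbols.
#' @export
leading_edge <- function(ranked, members, es_result) {
  if (es_result$es == 0) abort("Leading edge undefined for ES = 0")
  hit <- es_result$hit_index
  le_idx <- if (es_result$es > 0) {
    hit[hit <= es_result$peak_index]
  } else {
    hit[hit >= es_result$peak_index]
  }
  ranked$gene[le_idx]
}

#' TAGS, LIST and SIGNAL descriptors
#'
#' TAGS is the percentage of detected set members in the leading edge; LIST
#' is the percentage of the ranked list at or before the peak (positive ES)
#' or at or after it (negative ES); SIGNAL combines the two as
#' `TAGS * (1 - LIST/100) * N / (N - N_H)`, capped at 100.
#'
#' @param ranked A `ranked_list`.
#' @param es_result Result of [enrichment_score()].
#' @param n_le Number of leading-edge genes.
#' @return Named list with `tags_pct`, `list_pct`, `signal_pct` in \[0, 100\].
#' @export
gsea_descriptors <- function(ranked, es_result, n_le) {
  n <- nrow(ranked)
  nh <- length(es_result$hit_index)
  peak <- es_result$peak_index
  tags <- 100 * n_le / nh
  list_pct <- if (es_result$es > 0) 100 * peak / n else 100 * (n - peak + 1) / n
  signal <- min(100, tags * (1 - list_pct / 100) * n / (n - nh))
  list(tags_pct = tags, list_pct = list_pct, signal_pct = signal)
}

#' Preranked gene set enrichment analysis
#'
#' Scores every gene set of a (size-filtered) collection on a ranked list:
#' observed ES and leading edge, a permutation null from random gene sets of
#' the same detected size, a two-sided nominal p-value
#' `(b + 1) / (n_perm + 1)` with `b` the number of permuted `|ES*| >= |ES|`,
#' the normalized enrichment score `NES = ES / mean(|ES*|)` over
#' same-signed permutations, and an FDR q-value from the tail-ratio of the
#' pooled permutation NES distribution to the observed NES distribution
#' (computed separately for positive and negative scores, clamped to
#' \[0, 1\]). Permutation draws are shared across sets of equal detected
#' size and are deterministic for a fixed `seed`.
#'
#' @param ranked A `ranked_list`.
#' @param sets Gene-set collection tibble, already filtered with
#'   [filter_gene_sets()] against the ranked universe.
#' @param weight_p Hit-weight exponent (default 1).
#' @param n_perm Number of gene-set permutations (default 1000).
#' @param seed Integer seed for the permutation RNG.
#' @return A `gsea_result` tibble with one row per set: `set_id`, `name`,
#'   `source`, `detected_size`, `direction`, `es`, `nes`, `p_nominal`,
#'   `fdr_q`, `tags_pct`, `list_pct`, `signal_pct`, `peak_index` and the
#'   list-column `le_genes`.
#' @export
run_gsea <- function(ranked, sets, weight_p = 1, n_perm = 1000L, seed = 1L) {
  if (n_perm < 1L) abort("n_perm must be >= 1")
  n <- nrow(ranked)
  absw <- abs(ranked$d_score)^weight_p

  obs <- map(sets$genes, function(g) {
    esr <- enrichment_score(ranked, g, weight_p)
    le <- leading_edge(ranked, g, esr)
    desc <- gsea_descriptors(ranked, esr, length(le))
    c(list(le = le, nh = length(esr$hit_index),
           es = esr$es, peak = esr$peak_index), desc)
  })
  nh_all <- map_int(obs, "nh")

  # one permutation null per distinct detected size
  sizes <- sort(unique(nh_all))
  perm_es <- withr::with_seed(seed, {
    setNames(lapply(sizes, function(nh) {
      vapply(seq_len(n_perm), function(j) {
        idx <- sort(sample.int(n, nh))
        es_fast(idx, absw[idx], n)$es
      }, numeric(1))
    }), as.character(sizes))
  })

  norm_one <- function(es_star, pos_mean, neg_mean) {
    out <- rep(NA_real_, length(es_star))
    if (!is.na(pos_mean)) out[es_star > 0] <- es_star[es_star > 0] / pos_mean
    if (!is.na(neg_mean)) out[es_star < 0] <- es_star[es_star < 0] / neg_mean
    out[!is.na(out)]
  }

  es_obs <- map_dbl(obs, "es")
  nes <- rep(NA_real_, length(es_obs))
  p_nom <- numeric(length(es_obs))
  perm_nes_pool <- vector("list", length(es_obs))
  for (i in seq_along(es_obs)) {
    es_star <- perm_es[[as.character(nh_all[i])]]
    p_nom[i] <- (sum(abs(es_star) >= abs(es_obs[i])) + 1) / (n_perm + 1)
    pos_mean <- if (any(es_star > 0)) mean(es_star[es_star > 0]) else NA_real_
    neg_mean <- if (any(es_star < 0)) mean(abs(es_star[es_star < 0])) else NA_real_
    nes[i] <- if (es_obs[i] > 0) es_obs[i] / pos_mean else es_obs[i] / neg_mean
    perm_nes_pool[[i]] <- norm_one(es_star, pos_mean, neg_mean)
  }
  pool <- unlist(perm_nes_pool, use.names = FALSE)
  fdr <- fdr_tail_ratio(nes, pool)

  out <- tibble(
    set_id = sets$set_id,
    name = if ("name" %in% names(sets)) sets$name else sets$set_id,
    source = if ("source" %in% names(sets)) sets$source else gs_source(sets$set_id),
    detected_size = nh_all,
    direction = ifelse(es_obs >= 0, "enriched", "depleted"),
    es = es_obs,
    nes = nes,
    p_nominal = p_nom,
    fdr_q = fdr,
    tags_pct = map_dbl(obs, "tags_pct"),
    list_pct = map_dbl(obs, "list_pct"),
    signal_pct = map_dbl(obs, "signal_pct"),
    peak_index = map_int(obs, "peak"),
    le_genes = map(obs, "le")
  )
  structure(out,
            class = c("gsea_result", class(tibble())),
            params = list(weight_p = weight_p, n_perm = n_perm, seed = seed),
            strain = attr(ranked, "strain"),
            transition = attr(ranked, "transition"),
            universe_size = n)
}

# Reference-style FDR: for a positive NES, the fraction of pooled permutation
# NES at least as extreme divided by the fraction of observed NES at least as
# extreme; mirrored for negative NES; clamped to [0, 1].
fdr_tail_ratio <- function(nes_obs, nes_perm) {
  ok <- !is.na(nes_obs)
  q <- rep(NA_real_, length(nes_obs))
  perm_pos <- nes_perm[nes_perm > 0]
  perm_neg <- nes_perm[nes_perm < 0]
  obs_pos <- nes_obs[ok & nes_obs > 0]
  obs_neg <- nes_obs[ok & nes_obs < 0]
  for (i in which(ok)) {
    v <- nes_obs[i]
    if (v > 0) {
      num <- if (length(perm_pos)) mean(perm_pos >= v) else 0
      den <- mean(obs_pos >= v)
    } else {
      num <- if (length(perm_neg)) mean(perm_neg <= v) else 0
      den <- mean(obs_neg <= v)
    }
    q[i] <- max(0, min(1, num / den))
  }
  q
}

#' Write a GSEA report as TSV
#'
#' One row per gene set with ES, NES, p, FDR q, TAGS/LIST/SIGNAL, peak index
#' and the leading-edge genes semicolon-joined.
#'
#' @param res A `gsea_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gsea_report <- function(res, path) {
  flat <- as_tibble(res)
  flat$le_genes <- map_chr(flat$le_genes, paste, collapse = ";")
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
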