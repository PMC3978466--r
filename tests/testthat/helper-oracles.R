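# Independent oracles, deliberately coded along different paths than the
# package implementation.

# Brute-force running enrichment score: evaluates the running sum at every
# index by explicit summation (O(N * N_H)), no cumulative shortcuts.
oracle_es <- function(scores, is_hit, weight_p = 1) {
  n <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^weight_p
  nr <- sum(w[is_hit])
  run <- sapply(seq_len(n), function(i) {
    upto <- seq_len(i)
    hit_part <- sum(w[upto][is_hit[upto]]) / nr
    miss_part <- sum(!is_hit[upto]) / (n - nh)
    hit_part - miss_part
  })
  # first index attaining the extremum, ties at floating-point resolution
  peak <- which(abs(run) >= max(abs(run)) - 1e-12)[1]
  list(es = run[peak], peak_index = peak, running = run)
}

# Classical (unweighted) Kolmogorov-Smirnov running statistic: equal hit
# increments 1/N_H.
oracle_ks <- function(is_hit) {
  n <- length(is_hit)
  nh <- sum(is_hit)
  run <- cumsum(ifelse(is_hit, 1 / nh, -1 / (n - nh)))
  peak <- which(abs(run) >= max(abs(run)) - 1e-12)[1]
  list(es = run[peak], peak_index = peak)
}

# Reference Markov clustering, independently written: same mathematical
# definition (self-loops = max incident weight, column-stochastic expansion /
# inflation), but attractor-based cluster extraction (each attractor row's
# support is a cluster; overlapping clusters are merged).
oracle_mcl <- function(adj, inflation = 2.5, max_iter = 200, tol = 1e-8) {
  k <- nrow(adj)
  ids <- rownames(adj)
  if (is.null(ids)) ids <- as.character(seq_len(k))
  if (k == 1L) return(stats::setNames(1L, ids))
  a <- adj
  diag(a) <- 0
  for (j in seq_len(k)) a[j, j] <- if (max(a[, j]) > 0) max(a[, j]) else 1
  m <- apply(a, 2L, function(col) col / sum(col))
  repeat {
    nxt <- m %*% m
    nxt <- apply(nxt^inflation, 2L, function(col) col / sum(col))
    nxt[nxt < 1e-14] <- 0
    delta <- max(abs(nxt - m))
    m <- nxt
    max_iter <- max_iter - 1L
    if (delta < tol || max_iter == 0L) break
  }
  attractors <- which(apply(m, 1L, max) > tol)
  clusters <- lapply(attractors, function(r) which(m[r, ] > tol))
  # merge overlapping attractor supports
  merged <- list()
  for (cl in clusters) {
    hit <- which(vapply(merged, function(m0) length(intersect(m0, cl)) > 0,
                        logical(1)))
    if (length(hit) == 0L) {
      merged[[length(merged) + 1L]] <- cl
    } else {
      merged[[hit[1L]]] <- Reduce(union, c(merged[hit], list(cl)))
      if (length(hit) > 1L) merged <- merged[-hit[-1L]]
    }
  }
  membership <- integer(k)
  for (i in seq_along(merged)) membership[merged[[i]]] <- i
  # any node outside all attractor supports becomes its own cluster
  loose <- which(membership == 0L)
  for (i in seq_along(loose)) membership[loose[i]] <- length(merged) + i
  stats::setNames(membership, ids)
}

# Canonical form of a partition: labels renumbered by first appearance, so
# two labelings of the same partition compare equal.
canonical_partition <- function(membership) {
  membership <- membership[order(names(membership))]
  as.integer(factor(membership, levels = unique(membership)))
}

# Closed-form one-way ANOVA + Tukey HSD from first principles.
oracle_anova_tukey <- function(values, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  k <- length(lev)
  n_tot <- length(values)
  means <- tapply(values, groups, mean)[lev]
  ns <- tapply(values, groups, length)[lev]
  gm <- mean(values)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L
  df2 <- n_tot - k
  msw <- ssw / df2
  f <- (ssb / df1) / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(lev, 2L)
  tukey <- data.frame(
    contrast = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
    diff = means[pairs[2L, ]] - means[pairs[1L, ]],
    p_adj = apply(pairs, 2L, function(pr) {
      se <- sqrt(msw / 2 * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
      q <- abs(means[pr[2L]] - means[pr[1L]]) / se
      stats::ptukey(q, k, df2, lower.tail = FALSE)
    }),
    row.names = NULL
  )
  list(f = f, p = p, df1 = df1, df2 = df2, tukey = tukey)
}

# Small ranked list for GSEA unit tests.
make_ranked <- function(scores, genes = sprintf("g%02d", seq_along(scores)),
                        strain = "dis", transition = c(4, 8)) {
  ord <- order(-scores, genes)
  emlandscape:::new_ranked_list(
    tibble::tibble(gene = genes[ord], d_score = scores[ord]),
    strain = strain, transition = transition)
}

# Hand-built gsea_result-like tibble for contrast/network tests.
make_result <- function(set_id, es, fdr_q, p_nominal, tags_pct, le_genes,
                        detected_size = lengths(le_genes),
                        source = emlandscape:::gs_source(set_id),
                        strain = "dis", transition = c(4, 8)) {
  structure(
    tibble::tibble(
      set_id = set_id, name = set_id, source = source,
      detected_size = as.integer(detected_size),
      direction = ifelse(es >= 0, "enriched", "depleted"),
      es = es, nes = es * 1.5, p_nominal = p_nominal, fdr_q = fdr_q,
      tags_pct = tags_pct, list_pct = 10, signal_pct = tags_pct,
      peak_index = 5L, le_genes = le_genes),
    class = c("gsea_result", class(tibble::tibble())),
    strain = strain, transition = transition, universe_size = 1000L)
}
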