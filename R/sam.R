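#' SAM relative-difference statistic for one gene
#'
#' The moderated mean-difference statistic
#' `d = (mean(x2) - mean(x1)) / (s + s0)` with pooled gene-specific scatter
#' `s = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))`. The fudge factor
#' `s0` stabilizes genes with near-zero scatter so that ranking by `d`
#' behaves like a non-arbitrary fold-change criterion. Positive `d` means
#' higher expression in `x2` (the later time point).
#'
#' @param x1,x2 Numeric replicate vectors (earlier / later condition), each
#'   of length >= 2.
#' @param s0 Non-negative fudge factor; must be positive if the pooled
#'   scatter is zero.
#' @return The signed statistic (finite scalar).
#' @export
#' @examples
#' sam_statistic(c(1, 1, 1), c(2, 2, 2), s0 = 0.5)  # 2
sam_statistic <- function(x1, x2, s0) {
  if (length(x1) < 2L || length(x2) < 2L) {
    abort("sam_statistic needs >= 2 replicates in each group")
  }
  s <- sam_scatter(x1, x2)
  if (s + s0 == 0) {
    abort("Pooled scatter plus s0 is zero; use a positive s0")
  }
  (mean(x2) - mean(x1)) / (s + s0)
}

sam_scatter <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
  sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
}

#' Estimate the SAM fudge factor s0
#'
#' With `method = "percentile_cv_min"` (the default) the candidate values
#' are the percentiles 0, 5, ..., 100 of the per-gene scatter distribution;
#' the one minimizing the coefficient of variation of the `d` statistic's
#' spread across scatter-quantile windows is chosen (ties go to the smallest
#' percentile). `method = "median"` returns the median scatter and
#' `method = "fixed"` returns `s0` unchanged.
#'
#' @param numerators Per-gene mean differences (the `d` numerators).
#' @param scatters Per-gene pooled scatters `s` (same length).
#' @param method One of `"percentile_cv_min"`, `"median"`, `"fixed"`.
#' @param s0 The value returned by `method = "fixed"`.
#' @return A non-negative scalar.
#' @export
estimate_s0 <- function(numerators, scatters,
                        method = c("percentile_cv_min", "median", "fixed"),
                        s0 = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(s0) || s0 < 0) abort("`fixed` method needs a non-negative s0")
    return(s0)
  }
  if (length(scatters) != length(numerators)) {
    abort("`numerators` and `scatters` must have equal length")
  }
  if (all(scatters == 0)) {
    warn("All scatters are zero; falling back to s0 = 1")
    return(1.0)
  }
  if (method == "median") return(stats::median(scatters))
  n <- length(scatters)
  if (n < 100L) warn("Fewer than 100 genes; s0 estimate may be unstable")
  cand <- quantile(scatters, probs = seq(0, 1, by = 0.05), names = FALSE)
  n_win <- max(2L, min(100L, n %/% 25L))
  win <- cut(rank(scatters, ties.method = "first"),
             breaks = n_win, labels = FALSE)
  cv <- vapply(cand, function(a) {
    d <- numerators / (scatters + a)
    v <- vapply(split(d, win), mad, numeric(1))
    m <- mean(v)
    if (m == 0) Inf else sd(v) / m
  }, numeric(1))
  cand[which.min(cv)]  # which.min takes the first minimum: smallest percentile
}

#' Rank genes between two timepoints of one strain
#'
#' Computes the SAM relative-difference statistic for every gene between the
#' replicates at `t1` and `t2` within `strain` and returns the genes sorted
#' by descending statistic (ties broken by gene id). Positive scores mean
#' upregulation at the later timepoint.
#'
#' @param expr Expression tibble, first column `id` (gene symbols), one
#'   column per sample.
#' @param samples Sample-annotation tibble (`sample`, `strain`,
#'   `timepoint_weeks`, `replicate`).
#' @param strain Strain label to rank within.
#' @param t1,t2 The two timepoints in weeks (`t1` earlier).
#' @param s0 Optional fixed fudge factor; when `NULL` it is estimated with
#'   `s0_method`.
#' @param s0_method Passed to [estimate_s0()].
#' @return A `ranked_list`: tibble with columns `gene`, `d_score` sorted by
#'   descending score, carrying attributes `strain`, `transition` and
#'   `universe_size`.
#' @export
rank_transition <- function(expr, samples, strain, t1, t2,
                            s0 = NULL, s0_method = "percentile_cv_min") {
  names(expr)[1] <- "id"
  sel <- function(tp) {
    s <- samples$sample[samples$strain == strain &
                          samples$timepoint_weeks == tp]
    intersect(s, names(expr))
  }
  cols1 <- sel(t1); cols2 <- sel(t2)
  if (length(cols1) < 2L || length(cols2) < 2L) {
    avail <- unique(paste0(samples$strain, " @ ", samples$timepoint_weeks, "wk"))
    abort(paste0("Need >= 2 replicates for strain '", strain, "' at ", t1,
                 " and ", t2, " weeks. Available: ",
                 paste(sort(avail), collapse = "; ")))
  }
  x1 <- as.matrix(expr[, cols1]); x2 <- as.matrix(expr[, cols2])
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  num <- m2 - m1
  if (is.null(s0)) s0 <- estimate_s0(num, s, method = s0_method)
  if (any(s + s0 == 0)) {
    abort("Zero scatter plus s0 for some gene; use a positive s0")
  }
  d <- num / (s + s0)
  ord <- order(-d, expr$id)
  out <- tibble(gene = expr$id[ord], d_score = d[ord])
  new_ranked_list(out, strain = strain, transition = c(t1, t2))
}

new_ranked_list <- function(df, strain, transition) {
  structure(df,
            class = c("ranked_list", class(tibble())),
            strain = strain,
            transition = transition,
            universe_size = nrow(df))
}

#' Write a ranked list as a two-column .rnk file
#'
#' @param ranked A `ranked_list` (or any tibble with `gene`, `d_score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  readr::write_tsv(tibble(gene = ranked$gene, score = ranked$d_score),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
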