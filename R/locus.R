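#' Susceptibility locus definitions
#'
#' Convenience constructor for locus interval tables; the default returns
#' the Aec1 (chromosome 3, 0-46 cM) and Aec2 (chromosome 1, 29.7-106.1 cM)
#' congenic intervals. Intervals are closed in cM.
#'
#' @param name,chromosome,start_cM,end_cM Equal-length vectors.
#' @return A tibble with those four columns.
#' @export
locus_table <- function(name = c("Aec1", "Aec2"),
                        chromosome = c("3", "1"),
                        start_cM = c(0, 29.7),
                        end_cM = c(46, 106.1)) {
  stopifnot(all(start_cM <= end_cM))
  tibble(name = name, chromosome = as.character(chromosome),
         start_cM = start_cM, end_cM = end_cM)
}

#' Fraction of leading-edge genes inside susceptibility loci
#'
#' Percent of `le_genes` located within any of the locus intervals (closed
#' in cM). Genes without a map position count as outside.
#'
#' @param le_genes Character vector of leading-edge genes (non-empty).
#' @param positions Tibble with columns `gene`, `chromosome`, `cM`.
#' @param loci Locus tibble (see [locus_table()]).
#' @return Percent in \[0, 100\].
#' @export
locus_fraction <- function(le_genes, positions, loci = locus_table()) {
  le_genes <- unique(le_genes)
  if (length(le_genes) == 0L) abort("Empty leading-edge set")
  pos <- positions[match(le_genes, positions$gene), ]
  unmapped <- sum(is.na(pos$gene))
  if (unmapped > 0L) {
    message(unmapped, " leading-edge gene(s) without map position ",
            "counted as outside the loci")
  }
  inside <- map_lgl(seq_len(nrow(pos)), function(i) {
    if (is.na(pos$gene[i])) return(FALSE)
    any(loci$chromosome == as.character(pos$chromosome[i]) &
          loci$start_cM <= pos$cM[i] & pos$cM[i] <= loci$end_cM)
  })
  100 * sum(inside) / length(le_genes)
}

#' Per-set locus fractions and theme assignment
#'
#' Computes [locus_fraction()] for every retained gene set of a contrast and
#' joins the gene-set-to-theme mapping.
#'
#' @param contrast A `contrast_result`.
#' @param positions Gene-position tibble (`gene`, `chromosome`, `cM`).
#' @param themes Tibble mapping `set_id` to `theme`.
#' @param loci Locus tibble (see [locus_table()]).
#' @return Tibble with `set_id`, `theme`, `direction`, `locus_pct`.
#' @export
locus_fractions <- function(contrast, positions, themes,
                            loci = locus_table()) {
  df <- as_tibble(contrast)
  df <- df[df$retained, , drop = FALSE]
  out <- tibble(
    set_id = df$set_id,
    direction = df$direction,
    locus_pct = map_dbl(df$le_genes, locus_fraction,
                        positions = positions, loci = loci)
  )
  left_join(out, themes, by = "set_id") |>
    select("set_id", "theme", "direction", "locus_pct")
}

#' Compare locus dependence across biological themes
#'
#' One-way ANOVA of per-set locus fractions across themes followed by
#' Tukey's honest-significant-difference post hoc test. Themes with fewer
#' than two observations are excluded with a warning. Significance stars:
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.0001.
#'
#' @param fractions Tibble with columns `theme` and `locus_pct` (e.g. from
#'   [locus_fractions()]).
#' @return A `theme_anova` object with `summary` (per-theme mean/SEM/n),
#'   `anova` (F statistic, df, p), `tukey` (pairwise table with stars) and
#'   the underlying `aov` fit. Has [tidy()] and [glance()] methods.
#' @export
compare_themes <- function(fractions) {
  stopifnot(all(c("theme", "locus_pct") %in% names(fractions)))
  df <- fractions[!is.na(fractions$theme), c("theme", "locus_pct")]
  counts <- table(df$theme)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warn(paste0("Theme(s) with < 2 gene sets excluded: ",
                paste(small, collapse = ", ")))
    df <- df[!df$theme %in% small, ]
  }
  if (length(unique(df$theme)) < 2L) {
    abort("compare_themes needs >= 2 themes with >= 2 gene sets each")
  }
  df$theme <- factor(df$theme)
  if (sd(df$locus_pct) == 0) {
    # no variation anywhere: F is defined as 0, nothing can be significant
    k <- nlevels(df$theme)
    pairs <- utils::combn(levels(df$theme), 2L)
    smry <- df |>
      group_by(.data$theme) |>
      summarise(mean_pct = mean(.data$locus_pct), sem = 0, n = n(),
                .groups = "drop")
    return(structure(list(
      summary = smry,
      anova = list(f = 0, df1 = k - 1L, df2 = nrow(df) - k, p = 1),
      tukey = tibble(contrast = paste(pairs[2L, ], pairs[1L, ], sep = "-"),
                     diff = 0, lwr = 0, upr = 0, p_adj = 1, stars = ""),
      fit = NULL), class = "theme_anova"))
  }
  fit <- aov(locus_pct ~ theme, data = df)
  av <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$theme
  pair <- tibble(
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    stars = signif_stars(unname(tk[, "p adj"]))
  )
  smry <- df |>
    group_by(.data$theme) |>
    summarise(mean_pct = mean(.data$locus_pct),
              sem = sd(.data$locus_pct) / sqrt(n()),
              n = n(), .groups = "drop")
  structure(list(
    summary = smry,
    anova = list(f = av["theme", "F value"],
                 df1 = av["theme", "Df"],
                 df2 = av["Residuals", "Df"],
                 p = av["theme", "Pr(>F)"]),
    tukey = pair,
    fit = fit
  ), class = "theme_anova")
}

signif_stars <- function(p) {
  dplyr::case_when(p < 1e-4 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "")
}

#' @export
print.theme_anova <- function(x, ...) {
  cat("One-way ANOVA of locus fractions across themes\n")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  print(x$summary)
  invisible(x)
}

#' Cumulative leading-edge gene counts per theme
#'
#' Size of the union of leading-edge genes per theme and direction, plus the
#' count of those genes located inside the loci.
#'
#' @param contrast A `contrast_result`.
#' @param themes Tibble mapping `set_id` to `theme`.
#' @param positions Gene-position tibble.
#' @param loci Locus tibble.
#' @return Tibble `theme`, `direction`, `n_le_genes`, `n_in_loci`.
#' @export
theme_le_counts <- function(contrast, themes, positions,
                            loci = locus_table()) {
  df <- as_tibble(contrast)
  df <- df[df$retained, , drop = FALSE]
  df <- left_join(df, themes, by = "set_id")
  df <- df[!is.na(df$theme), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(tibble(theme = character(), direction = character(),
                  n_le_genes = integer(), n_in_loci = integer()))
  }
  df |>
    group_by(.data$theme, .data$direction) |>
    summarise(n_le = list(unique(unlist(.data$le_genes))), .groups = "drop") |>
    mutate(
      n_le_genes = lengths(.data$n_le),
      n_in_loci = map_int(.data$n_le, function(g) {
        as.integer(round(locus_fraction(g, positions, loci) * length(g) / 100))
      })
    ) |>
    select("theme", "direction", "n_le_genes", "n_in_loci")
}
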