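#' @describeIn compare_themes Tidy the Tukey pairwise table.
#' @param x A `theme_anova`.
#' @exportS3Method generics::tidy
tidy.theme_anova <- function(x, ...) {
  x$tukey
}

#' @describeIn compare_themes One-row model summary (F, dfs, p, theme count).
#' @exportS3Method generics::glance
glance.theme_anova <- function(x, ...) {
  tibble(statistic = x$anova$f, df = x$anova$df1, df_residual = x$anova$df2,
         p_value = x$anova$p, n_themes = nrow(x$summary))
}

#' @describeIn build_em_network Tidy node table of an EM network.
#' @param x An `em_network`.
#' @exportS3Method generics::tidy
tidy.em_network <- function(x, ...) {
  out <- as_tibble(x$nodes)
  out$n_le <- lengths(out$le_genes)
  out$le_genes <- NULL
  out
}

#' @describeIn build_em_network One-row network summary.
#' @exportS3Method generics::glance
glance.em_network <- function(x, ...) {
  tibble(direction = x$direction,
         n_nodes = nrow(x$nodes),
         n_em_related = sum(x$nodes$em_class == "EM_related"),
         n_edges = nrow(x$edges),
         n_clusters = if (all(is.na(x$nodes$cluster))) NA_integer_
                      else length(unique(x$nodes$cluster)),
         threshold_pct = x$threshold_pct)
}

#' @describeIn run_gsea One-row run summary of a `gsea_result`.
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.gsea_result <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_sets = nrow(x), universe_size = attr(x, "universe_size"),
         n_perm = p$n_perm, weight_p = p$weight_p, seed = p$seed)
}
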