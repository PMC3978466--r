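#' Plot the running enrichment score of one gene set
#'
#' Line plot of the running sum over the ranked list with the peak marked
#' and a rug of member-gene positions.
#'
#' @param ranked A `ranked_list`.
#' @param members Gene-set member symbols.
#' @param weight_p Hit-weight exponent.
#' @return A ggplot object.
#' @export
plot_running_score <- function(ranked, members, weight_p = 1) {
  esr <- enrichment_score(ranked, members, weight_p)
  df <- tibble(rank = seq_len(nrow(ranked)), running = esr$running)
  hits <- tibble(rank = esr$hit_index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = esr$peak_index, linetype = 3) +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = .data$rank),
                      inherit.aes = FALSE, sides = "b", alpha = 0.5) +
    ggplot2::labs(x = "Rank in list", y = "Running enrichment score",
                  subtitle = sprintf("ES = %.3f at rank %d",
                                     esr$es, esr$peak_index)) +
    ggplot2::theme_minimal()
}

#' @describeIn build_em_network Plot an EM network: triangles for EM-related
#'   and circles for EM-associated nodes, sized by detected-set size, colored
#'   by MCL cluster, on a seeded force-directed layout.
#' @param object An `em_network`.
#' @param layout_seed Seed for the force-directed layout.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.em_network <- function(object, layout_seed = 1L, ...) {
  if (nrow(object$nodes) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "Empty network"))
  }
  g <- as_igraph(object)
  xy <- withr::with_seed(layout_seed, igraph::layout_with_fr(
    g, weights = if (nrow(object$edges)) object$edges$connectivity else NULL))
  nodes <- as_tibble(object$nodes)
  nodes$x <- xy[, 1L]; nodes$y <- xy[, 2L]
  seg <- NULL
  if (nrow(object$edges) > 0L) {
    seg <- object$edges
    seg$x <- nodes$x[match(seg$from, nodes$set_id)]
    seg$y <- nodes$y[match(seg$from, nodes$set_id)]
    seg$xend <- nodes$x[match(seg$to, nodes$set_id)]
    seg$yend <- nodes$y[match(seg$to, nodes$set_id)]
  }
  p <- ggplot2::ggplot()
  if (!is.null(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, alpha = .data$connectivity),
      colour = "grey50")
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   shape = .data$em_class,
                   size = .data$size_scale,
                   colour = factor(.data$cluster),
                   stroke = ifelse(.data$border == "present", 2, 0.5))) +
    ggplot2::scale_shape_manual(values = c(EM_related = 17, EM_associated = 16)) +
    ggplot2::labs(colour = "MCL cluster", shape = NULL, size = "Set size / 50",
                  alpha = "Connectivity (%)",
                  title = paste0("EM network (", object$direction, ")")) +
    ggplot2::theme_void()
}

#' @describeIn compare_themes Bar plot of per-theme mean locus fractions with
#'   SEM error bars.
#' @param object A `theme_anova`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.theme_anova <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$theme, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "#7fcdbb", colour = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$sem,
                   ymax = .data$mean_pct + .data$sem), width = 0.25) +
    ggplot2::labs(x = NULL, y = "LE genes in loci (%)",
                  subtitle = sprintf("ANOVA F(%d, %d) = %.2f, p = %.2g",
                                     object$anova$df1, object$anova$df2,
                                     object$anova$f, object$anova$p)) +
    ggplot2::theme_minimal()
}

#' Plot a metanode gene cloud
#'
#' Deterministic spiral word layout: font size proportional to the gene's
#' leading-edge frequency, colour by intra-metanode sub-cluster.
#'
#' @param clouds Cloud tibble from [gene_clouds()].
#' @param cluster Which metanode to draw (default: the first).
#' @return A ggplot object.
#' @export
plot_gene_cloud <- function(clouds, cluster = NULL) {
  cluster <- cluster %||% min(clouds$cluster)
  df <- clouds[clouds$cluster == cluster, ]
  if (nrow(df) == 0L) abort("No genes in that metanode")
  k <- seq_len(nrow(df))
  theta <- 2.4 * k          # golden-angle spiral
  r <- sqrt(k)
  df$x <- r * cos(theta); df$y <- r * sin(theta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   label = .data$gene,
                                   size = .data$frequency,
                                   colour = factor(.data$color_group))) +
    ggplot2::geom_text(fontface = "italic") +
    ggplot2::scale_size_continuous(range = c(2.5, 7)) +
    ggplot2::labs(title = paste0("Metanode ", cluster, " LE gene cloud"),
                  size = "LE frequency", colour = "Sub-cluster") +
    ggplot2::theme_void()
}
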