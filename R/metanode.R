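#' Collapse MCL clusters into metanodes
#'
#' Each cluster of a clustered EM network becomes one metanode whose size is
#' scaled against a 15-set reference node. Member lists are disjoint and
#' jointly cover the network's nodes.
#'
#' @param net A clustered `em_network` (see [mcl_cluster()]).
#' @param reference_n Gene sets per reference metanode (default 15).
#' @return A tibble with one row per metanode: `cluster`, `n_sets`,
#'   `size_scale` and the list-column `member_gs`.
#' @export
collapse_metanodes <- function(net, reference_n = 15) {
  stopifnot(inherits(net, "em_network"))
  if (nrow(net$nodes) == 0L) {
    return(tibble(cluster = integer(), n_sets = integer(),
                  size_scale = numeric(), member_gs = list()))
  }
  if (anyNA(net$nodes$cluster)) {
    abort("Network has no cluster labels; run mcl_cluster() first")
  }
  net$nodes |>
    as_tibble() |>
    group_by(cluster = .data$cluster) |>
    summarise(n_sets = n(),
              member_gs = list(sort(.data$set_id)),
              .groups = "drop") |>
    mutate(size_scale = .data$n_sets / reference_n) |>
    select("cluster", "n_sets", "size_scale", "member_gs") |>
    arrange(.data$cluster)
}

#' Weighted leading-edge gene cloud of each metanode
#'
#' For every metanode, each gene appearing in the leading edge of at least
#' one member set is listed with its frequency (the number of member sets
#' whose leading edge contains it; the display font size is proportional to
#' this). Genes are colored by sub-clustering the metanode's internal
#' set-overlap subgraph with MCL and assigning each gene to the sub-cluster
#' in whose sets it appears most often (ties to the smaller label).
#'
#' @param net A clustered `em_network`.
#' @param inflation MCL inflation for the internal sub-clustering.
#' @return A tibble with columns `cluster`, `gene`, `frequency`,
#'   `color_group`, sorted by cluster, then frequency descending, then gene.
#' @export
gene_clouds <- function(net, inflation = 2.5) {
  meta <- collapse_metanodes(net)
  if (nrow(meta) == 0L) {
    return(tibble(cluster = integer(), gene = character(),
                  frequency = integer(), color_group = integer()))
  }
  le_map <- setNames(net$nodes$le_genes, net$nodes$set_id)
  adj_full <- network_adjacency(net)
  clouds <- map(seq_len(nrow(meta)), function(i) {
    members <- meta$member_gs[[i]]
    sub <- mcl_partition(adj_full[members, members, drop = FALSE],
                         inflation = inflation)
    gene_counts <- table(unlist(le_map[members], use.names = FALSE))
    genes <- names(gene_counts)
    # per gene, occurrences within each sub-cluster's sets
    color <- map_int(genes, function(g) {
      hits <- map_int(split(members, sub[members]), function(ms) {
        sum(map_lgl(le_map[ms], function(le) g %in% le))
      })
      as.integer(names(hits)[which.max(hits)])  # first max = smaller label
    })
    tibble(cluster = meta$cluster[i], gene = genes,
           frequency = as.integer(gene_counts), color_group = color)
  })
  bind_rows(clouds) |>
    arrange(.data$cluster, dplyr::desc(.data$frequency), .data$gene)
}

#' Write metanodes and gene clouds as TSV
#'
#' @param net A clustered `em_network`.
#' @param stem Output path stem (`_metanodes.tsv`, `_clouds.tsv`).
#' @return The written paths, invisibly.
#' @export
write_clouds <- function(net, stem) {
  paths <- paste0(stem, c("_metanodes.tsv", "_clouds.tsv"))
  meta <- collapse_metanodes(net)
  meta$member_gs <- map_chr(meta$member_gs, paste, collapse = ";")
  readr::write_tsv(meta, paths[1L], progress = FALSE)
  readr::write_tsv(gene_clouds(net), paths[2L], progress = FALSE)
  invisible(paths)
}
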