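#' Qualify EM-related gene sets through GO ancestry
#'
#' A gene set is related to the extracellular milieu (EM) when it is a GO
#' set with FDR below `fdr_max` whose term is, or descends from, one of the
#' cell periphery (GO_0071944), extracellular matrix (GO_0031012) or
#' cell-cell junction (GO_0005911) roots. A root term itself qualifies. GO
#' sets whose term is absent from the ontology are excluded with a warning.
#'
#' @param res A `gsea_result` or `contrast_result` tibble (needs `set_id`,
#'   `source`, `fdr_q`).
#' @param ontology Ontology edge tibble (see [read_ontology()]).
#' @param roots Character vector of qualifying ancestor term ids.
#' @param fdr_max FDR threshold (default 0.05, strict).
#' @return Character vector of qualifying `set_id`s.
#' @export
qualify_em_related <- function(res, ontology,
                               roots = c("GO_0071944", "GO_0031012", "GO_0005911"),
                               fdr_max = 0.05) {
  go <- res[res$source == "GO" & !is.na(res$fdr_q) & res$fdr_q < fdr_max, ]
  if (nrow(go) == 0L) return(character())
  terms <- ontology_terms(ontology)
  unresolved <- setdiff(go$set_id, terms)
  if (length(unresolved) > 0L) {
    warn(paste0(length(unresolved), " GO set(s) not resolvable in the ",
                "ontology, excluded: ",
                paste(head(unresolved, 5L), collapse = ", ")))
  }
  ids <- intersect(go$set_id, terms)
  keep <- map_lgl(ids, function(id) {
    any(c(id, term_ancestors(ontology, id)) %in% roots)
  })
  ids[keep]
}

#' Leading-edge connectivity between two gene sets
#'
#' Percent overlap between two leading-edge gene sets; `"jaccard"` (the
#' default) uses the union as denominator, `"overlap"` the smaller set.
#'
#' @param le_a,le_b Character vectors of leading-edge genes (non-empty).
#' @param method `"jaccard"` or `"overlap"`.
#' @return Percent in \[0, 100\]; symmetric.
#' @export
le_connectivity <- function(le_a, le_b, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  if (length(le_a) == 0L || length(le_b) == 0L) {
    abort("Leading-edge sets must be non-empty")
  }
  shared <- length(intersect(le_a, le_b))
  denom <- switch(method,
                  jaccard = length(union(le_a, le_b)),
                  overlap = min(length(unique(le_a)), length(unique(le_b))))
  100 * shared / denom
}

#' Build the EM leading-edge-overlap network for one direction
#'
#' Nodes are the EM-related gene sets plus every retained set that passes
#' the full significance criteria and shares at least `threshold_pct` of
#' leading-edge members (see [le_connectivity()]) with at least one
#' EM-related set (these become EM-associated). Edges connect every node
#' pair at or above the threshold; EM-related sets without a qualifying edge
#' remain as isolated nodes. Node attributes follow the display conventions:
#' triangles for EM-related and circles for EM-associated sets, node size
#' relative to a 50-gene reference, label size relative to a TAGS of 75%,
#' and a border for reciprocal alterations.
#'
#' @param contrast A `contrast_result` (see [classify_contrast()]).
#' @param ontology Ontology edge tibble for EM qualification.
#' @param direction `"enriched"` or `"depleted"`; the network is built from
#'   retained sets of that direction only.
#' @param criteria Full significance criteria for EM-associated candidates.
#' @param threshold_pct Minimum connectivity for an edge (default 8,
#'   inclusive).
#' @param roots,em_fdr_max Passed to [qualify_em_related()].
#' @param method Overlap metric, passed to [le_connectivity()].
#' @param reference_size,reference_tags Attribute scaling references.
#' @return An `em_network`: list with `nodes` and `edges` tibbles plus the
#'   build parameters. `nodes$cluster` is `NA` until [mcl_cluster()] is run.
#' @export
build_em_network <- function(contrast, ontology, direction,
                             criteria = significance_criteria(),
                             threshold_pct = 8,
                             roots = c("GO_0071944", "GO_0031012", "GO_0005911"),
                             em_fdr_max = 0.05,
                             method = "jaccard",
                             reference_size = 50, reference_tags = 75) {
  df <- as_tibble(contrast)
  df <- df[df$retained & df$direction == direction, , drop = FALSE]
  em_ids <- qualify_em_related(df, ontology, roots = roots, fdr_max = em_fdr_max)
  empty <- function() {
    structure(list(
      nodes = tibble(set_id = character(), em_class = character(),
                     klass = character(), detected_size = integer(),
                     tags_pct = numeric(), shape = character(),
                     border = character(), size_scale = numeric(),
                     label_scale = numeric(), cluster = integer(),
                     le_genes = list()),
      edges = tibble(from = character(), to = character(),
                     connectivity = numeric()),
      direction = direction, threshold_pct = threshold_pct,
      method = method, transition = attr(contrast, "transition")),
      class = "em_network")
  }
  if (length(em_ids) == 0L) {
    warn(paste0("No EM-related seed sets for direction '", direction,
                "'; empty network"))
    return(empty())
  }
  cand <- df[passes_criteria(df, criteria), , drop = FALSE]
  all_ids <- union(em_ids, cand$set_id)
  sub <- df[match(all_ids, df$set_id), , drop = FALSE]
  conn <- connectivity_matrix(sub$le_genes, sub$set_id, method)

  is_em <- sub$set_id %in% em_ids
  assoc <- !is_em & sub$set_id %in% cand$set_id &
    apply(conn[, is_em, drop = FALSE] >= threshold_pct, 1L, any)
  keep <- is_em | assoc
  sub <- sub[keep, , drop = FALSE]
  conn <- conn[keep, keep, drop = FALSE]
  is_em <- is_em[keep]

  pairs <- which(upper.tri(conn) & conn >= threshold_pct, arr.ind = TRUE)
  edges <- tibble(from = sub$set_id[pairs[, 1L]],
                  to = sub$set_id[pairs[, 2L]],
                  connectivity = conn[pairs])
  nodes <- tibble(
    set_id = sub$set_id,
    em_class = ifelse(is_em, "EM_related", "EM_associated"),
    klass = sub$klass,
    detected_size = sub$detected_size,
    tags_pct = sub$tags_pct,
    shape = ifelse(is_em, "triangle", "circle"),
    border = ifelse(sub$klass == "reciprocal", "present", "none"),
    size_scale = sub$detected_size / reference_size,
    label_scale = sub$tags_pct / reference_tags,
    cluster = NA_integer_,
    le_genes = sub$le_genes
  )
  structure(list(nodes = nodes, edges = edges, direction = direction,
                 threshold_pct = threshold_pct, method = method,
                 transition = attr(contrast, "transition")),
            class = "em_network")
}

connectivity_matrix <- function(le_list, ids, method = "jaccard") {
  k <- length(le_list)
  m <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        m[i, j] <- m[j, i] <- le_connectivity(le_list[[i]], le_list[[j]], method)
      }
    }
  }
  m
}

#' @export
print.em_network <- function(x, ...) {
  cat("EM leading-edge-overlap network (", x$direction, ")\n", sep = "")
  if (!is.null(x$transition)) {
    cat("  transition: ", paste(x$transition, collapse = " -> "), " weeks\n",
        sep = "")
  }
  cat("  ", nrow(x$nodes), " nodes (",
      sum(x$nodes$em_class == "EM_related"), " EM-related), ",
      nrow(x$edges), " edges at connectivity >= ", x$threshold_pct, "%\n",
      sep = "")
  if (!all(is.na(x$nodes$cluster))) {
    cat("  ", length(unique(x$nodes$cluster)), " MCL clusters\n", sep = "")
  }
  invisible(x)
}

#' Markov cluster algorithm on a weighted adjacency matrix
#'
#' Column-stochastic flow simulation: self-loops are set to the maximum
#' incident edge weight (1 for isolated nodes), columns are normalized, and
#' expansion (matrix squaring) alternates with inflation (entrywise power
#' `inflation` followed by column renormalization) until the matrix changes
#' by less than `tol`. Clusters are the connected components of the non-zero
#' structure of the limit matrix. Labels are integers ordered by descending
#' cluster size, ties by the lexicographically smallest member.
#'
#' @param adjacency Symmetric non-negative weight matrix with dimnames.
#' @param inflation Inflation exponent (default 2.5).
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence tolerance on the max entry change (default 1e-8).
#' @return Named integer vector of cluster labels.
#' @export
mcl_partition <- function(adjacency, inflation = 2.5, max_iter = 100L,
                          tol = 1e-8) {
  k <- nrow(adjacency)
  if (k == 0L) return(setNames(integer(), character()))
  ids <- rownames(adjacency) %||% as.character(seq_len(k))
  if (k == 1L) return(setNames(1L, ids))
  a <- adjacency
  diag(a) <- 0
  loops <- apply(a, 2L, max)
  loops[loops == 0] <- 1
  diag(a) <- loops
  m <- sweep(a, 2L, colSums(a), "/")
  converged <- FALSE
  resid <- NA_real_
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m
    m2 <- m2^inflation
    m2[m2 < 1e-14] <- 0
    m2 <- sweep(m2, 2L, colSums(m2), "/")
    resid <- max(abs(m2 - m))
    m <- m2
    if (resid < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(paste0("MCL did not converge in ", max_iter,
                 " iterations (residual ", format(resid), ")"))
  }
  keep <- (m > tol) | (t(m) > tol)
  g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  order_cluster_labels(setNames(comp, ids))
}

# renumber labels: descending cluster size, ties by smallest member id
order_cluster_labels <- function(membership) {
  ids <- names(membership)
  grp <- split(ids, membership)
  sizes <- lengths(grp)
  firsts <- map_chr(grp, function(g) min(g))
  ord <- order(-sizes, firsts)
  relabel <- setNames(seq_along(ord), names(grp)[ord])
  setNames(as.integer(relabel[as.character(membership)]), ids)
}

#' Cluster an EM network with the Markov cluster algorithm
#'
#' Runs [mcl_partition()] on the network's connectivity-weighted adjacency
#' and fills `nodes$cluster`.
#'
#' @param net An `em_network`.
#' @param inflation,max_iter,tol Passed to [mcl_partition()].
#' @return The network with cluster labels assigned.
#' @export
mcl_cluster <- function(net, inflation = 2.5, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(net, "em_network"))
  if (nrow(net$nodes) == 0L) return(net)
  adj <- network_adjacency(net)
  labels <- mcl_partition(adj, inflation = inflation, max_iter = max_iter,
                          tol = tol)
  net$nodes$cluster <- as.integer(labels[net$nodes$set_id])
  net$inflation <- inflation
  net
}

network_adjacency <- function(net) {
  ids <- net$nodes$set_id
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges) > 0L) {
    a[cbind(net$edges$from, net$edges$to)] <- net$edges$connectivity
    a[cbind(net$edges$to, net$edges$from)] <- net$edges$connectivity
  }
  a
}

as_igraph <- function(net) {
  nodes <- as_tibble(net$nodes)
  nodes$le_genes <- map_chr(nodes$le_genes, paste, collapse = ";")
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = nodes)
}

#' Export an EM network for Cytoscape
#'
#' Writes GraphML with all node and edge attributes, a SIF file, and
#' node-attribute / edge-attribute / cluster-membership TSVs next to it.
#'
#' @param net An `em_network`.
#' @param stem Output path stem (files get `.graphml`, `.sif`,
#'   `_nodes.tsv`, `_edges.tsv`, `_clusters.tsv` suffixes).
#' @return Character vector of the written paths, invisibly.
#' @export
write_network <- function(net, stem) {
  paths <- paste0(stem, c(".graphml", ".sif", "_nodes.tsv", "_edges.tsv",
                          "_clusters.tsv"))
  igraph::write_graph(as_igraph(net), paths[1L], format = "graphml")
  sif <- if (nrow(net$edges) > 0L) {
    paste(net$edges$from, "le_overlap", net$edges$to)
  } else character()
  isolated <- setdiff(net$nodes$set_id, c(net$edges$from, net$edges$to))
  writeLines(c(sif, isolated), paths[2L])
  nodes <- as_tibble(net$nodes)
  nodes$le_genes <- map_chr(nodes$le_genes, paste, collapse = ";")
  readr::write_tsv(nodes, paths[3L], progress = FALSE)
  readr::write_tsv(net$edges, paths[4L], progress = FALSE)
  readr::write_tsv(nodes[, c("set_id", "cluster")], paths[5L], progress = FALSE)
  invisible(paths)
}
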