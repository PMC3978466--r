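#' Read an ontology parent-child edge table
#'
#' The table is tab-separated with columns `child`, `parent` and optionally
#' `relation` (`is_a` / `part_of`; both are traversed when computing
#' ancestors). The edge set must be acyclic.
#'
#' @param path Path to a TSV file with a header line.
#' @return A tibble with columns `child`, `parent`, `relation`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) abort(paste0("Ontology file not found: ", path))
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("child", "parent") %in% names(edges))) {
    abort("Ontology table needs columns `child` and `parent`")
  }
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  edges <- as_tibble(edges[, c("child", "parent", "relation")])
  validate_ontology(edges)
  edges
}

validate_ontology <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) abort("Ontology edge table contains a cycle")
  invisible(edges)
}

#' All terms mentioned in an ontology edge table
#' @param edges Ontology tibble (see [read_ontology()]).
#' @return Character vector of term ids.
#' @export
ontology_terms <- function(edges) {
  unique(c(edges$child, edges$parent))
}

#' Transitive ancestors of an ontology term
#'
#' Walks child-to-parent edges (both `is_a` and `part_of`) to their
#' transitive closure. The term itself is excluded; a root term therefore
#' has no ancestors.
#'
#' @param edges Ontology tibble (see [read_ontology()]).
#' @param term A single term id present in the ontology.
#' @return Character vector of ancestor term ids (possibly empty).
#' @export
term_ancestors <- function(edges, term) {
  terms <- ontology_terms(edges)
  if (!term %in% terms) {
    abort(paste0("Unknown ontology term: ", term))
  }
  parents <- split(edges$parent, edges$child)
  seen <- character()
  frontier <- term
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}
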