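#' Read an expression matrix and its sample annotations
#'
#' The expression table is tab-separated with the row identifier (probe or
#' gene) in the first column and one column per sample of normalized log2
#' intensities. The annotation table maps every sample to its strain,
#' timepoint (weeks) and replicate.
#'
#' @param expr_path Path to the expression TSV.
#' @param annot_path Path to the sample-annotation TSV with columns
#'   `sample`, `strain`, `timepoint_weeks`, `replicate`.
#' @return A list with `expression` (tibble, first column `id`) and
#'   `samples` (annotation tibble).
#' @export
read_expression <- function(expr_path, annot_path) {
  for (p in c(expr_path, annot_path)) {
    if (!file.exists(p)) abort(paste0("File not found: ", p))
  }
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "id"
  samples <- readr::read_tsv(annot_path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "strain", "timepoint_weeks", "replicate")
  if (!all(need %in% names(samples))) {
    abort(paste0("Annotation table needs columns: ", paste(need, collapse = ", ")))
  }
  validate_expression(expr, samples)
  list(expression = expr, samples = as_tibble(samples))
}

validate_expression <- function(expr, samples) {
  sample_cols <- setdiff(names(expr), "id")
  if (anyDuplicated(expr$id)) abort("Duplicate row ids in expression matrix")
  if (anyNA(expr[sample_cols])) abort("Expression matrix contains missing values")
  missing_annot <- setdiff(sample_cols, samples$sample)
  if (length(missing_annot) > 0L) {
    abort(paste0("Samples without annotation: ",
                 paste(head(missing_annot, 5L), collapse = ", ")))
  }
  invisible(expr)
}

#' Collapse probe rows to one row per gene
#'
#' Where several probes measure the same gene, the entire row of the probe
#' with the highest mean intensity across all samples is retained; ties are
#' broken by the lexicographically smallest probe id. Probes absent from the
#' mapping are dropped (with a message); probes mapping to several genes are
#' candidates for each of them.
#'
#' @param expr Expression tibble, first column `id` holding probe ids.
#' @param probe2gene Tibble with columns `probe` and `gene`.
#' @return Expression tibble with first column `id` holding gene symbols.
#' @export
collapse_probes <- function(expr, probe2gene) {
  if (nrow(probe2gene) == 0L) abort("Empty probe-to-gene mapping")
  stopifnot(all(c("probe", "gene") %in% names(probe2gene)))
  names(expr)[1] <- "id"
  sample_cols <- setdiff(names(expr), "id")

  unmapped <- setdiff(expr$id, probe2gene$probe)
  if (length(unmapped) > 0L) {
    message(length(unmapped), " probe(s) without gene mapping dropped")
  }
  multi <- sum(duplicated(probe2gene$probe))
  if (multi > 0L) {
    message(multi, " probe-to-gene assignment(s) beyond one gene per probe")
  }

  means <- rowMeans(as.matrix(expr[, sample_cols]))
  cand <- inner_join(probe2gene,
                     tibble(probe = expr$id, .mean = means, .row = seq_len(nrow(expr))),
                     by = "probe")
  keep <- cand |>
    arrange(.data$gene, dplyr::desc(.data$.mean), .data$probe) |>
    distinct(.data$gene, .keep_all = TRUE)
  out <- expr[keep$.row, , drop = FALSE]
  out$id <- keep$gene
  out <- out[order(out$id), , drop = FALSE]
  as_tibble(out)
}
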