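#' Significance criteria for a single enrichment result
#'
#' A gene set passes when `fdr_q < fdr_max` (strict), `p_nominal <
#' p_nominal_max` (strict) and `tags_pct >= tags_min_pct` (non-strict).
#' Defaults are FDR < 0.05, nominal p < 0.005 and TAGS >= 50%.
#'
#' @param fdr_max,p_nominal_max,tags_min_pct Threshold values.
#' @return A named list usable as the `criteria` argument downstream.
#' @export
significance_criteria <- function(fdr_max = 0.05, p_nominal_max = 0.005,
                                  tags_min_pct = 50) {
  stopifnot(fdr_max > 0, fdr_max <= 1,
            p_nominal_max > 0, p_nominal_max <= 1,
            tags_min_pct > 0, tags_min_pct <= 100)
  list(fdr_max = fdr_max, p_nominal_max = p_nominal_max,
       tags_min_pct = tags_min_pct)
}

#' Does an enrichment result pass the significance criteria?
#'
#' @param res A `gsea_result` tibble (or any data frame with `fdr_q`,
#'   `p_nominal`, `tags_pct`).
#' @param criteria See [significance_criteria()].
#' @return Logical vector, one element per row.
#' @export
passes_criteria <- function(res, criteria = significance_criteria()) {
  !is.na(res$fdr_q) &
    res$fdr_q < criteria$fdr_max &
    res$p_nominal < criteria$p_nominal_max &
    res$tags_pct >= criteria$tags_min_pct
}

#' Classify gene-set behavior across the diseased and control strains
#'
#' For each gene set scored in both strains over the same transition, the
#' alteration is `parallel` when both strains pass the criteria with the
#' same direction (normal development; discarded), `reciprocal` when both
#' pass with opposite directions (retained), `exclusive` when only the
#' diseased strain passes (retained), `control_only` when only the control
#' passes (logged, dropped) and `not_significant` otherwise.
#'
#' @param diseased,control `gsea_result` tibbles for the two strains over
#'   the same transition.
#' @param criteria See [significance_criteria()].
#' @return A `contrast_result` tibble: the diseased results joined with the
#'   control's (suffix `_ctrl`), plus `klass` and `retained`.
#' @export
classify_contrast <- function(diseased, control,
                              criteria = significance_criteria()) {
  tr_d <- attr(diseased, "transition"); tr_c <- attr(control, "transition")
  if (!is.null(tr_d) && !is.null(tr_c) && !identical(tr_d, tr_c)) {
    abort("Diseased and control results cover different transitions")
  }
  if (!setequal(diseased$set_id, control$set_id)) {
    abort("Diseased and control results cover different gene sets")
  }
  ctrl <- as_tibble(control)[, c("set_id", "direction", "es", "nes",
                                 "p_nominal", "fdr_q", "tags_pct", "le_genes")]
  names(ctrl)[-1] <- paste0(names(ctrl)[-1], "_ctrl")
  out <- left_join(as_tibble(diseased), ctrl, by = "set_id")
  pass_d <- passes_criteria(out, criteria)
  pass_c <- !is.na(out$fdr_q_ctrl) &
    out$fdr_q_ctrl < criteria$fdr_max &
    out$p_nominal_ctrl < criteria$p_nominal_max &
    out$tags_pct_ctrl >= criteria$tags_min_pct
  same_dir <- out$direction == out$direction_ctrl
  out$klass <- dplyr::case_when(
    pass_d & pass_c & same_dir ~ "parallel",
    pass_d & pass_c & !same_dir ~ "reciprocal",
    pass_d & !pass_c ~ "exclusive",
    !pass_d & pass_c ~ "control_only",
    .default = "not_significant"
  )
  out$retained <- out$klass %in% c("exclusive", "reciprocal")
  n_ctrl_only <- sum(out$klass == "control_only")
  if (n_ctrl_only > 0L) {
    message(n_ctrl_only,
            " gene set(s) significant in the control strain only (dropped)")
  }
  structure(out,
            class = c("contrast_result", class(tibble())),
            transition = tr_d,
            strain_diseased = attr(diseased, "strain"),
            strain_control = attr(control, "strain"),
            criteria = criteria)
}

#' Summarize a contrast classification
#'
#' Counts exclusive / reciprocal / parallel gene sets per direction and the
#' size of the union of leading-edge genes over retained sets per direction.
#'
#' @param contrast A `contrast_result`.
#' @return A tibble with one row per direction: `direction`, `n_exclusive`,
#'   `n_reciprocal`, `n_parallel`, `n_le_genes`.
#' @export
summarize_contrast <- function(contrast) {
  df <- as_tibble(contrast)
  if (nrow(df) == 0L) {
    return(tibble(direction = character(), n_exclusive = integer(),
                  n_reciprocal = integer(), n_parallel = integer(),
                  n_le_genes = integer()))
  }
  df |>
    group_by(.data$direction) |>
    summarise(
      n_exclusive = sum(.data$klass == "exclusive"),
      n_reciprocal = sum(.data$klass == "reciprocal"),
      n_parallel = sum(.data$klass == "parallel"),
      n_le_genes = length(unique(unlist(.data$le_genes[.data$retained]))),
      .groups = "drop"
    )
}
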