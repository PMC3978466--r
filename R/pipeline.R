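#' Run the full EM-landscape pipeline
#'
#' For every pair of chronologically consecutive timepoints and each strain,
#' genes are ranked with the SAM relative-difference statistic and scored by
#' preranked GSEA against the size-filtered collection; gene sets are then
#' classified as exclusive / reciprocal / parallel across strains (parallel
#' alterations are discarded), EM networks are built and MCL-clustered per
#' direction, metanode gene clouds are extracted, and per-set locus
#' fractions are compared across themes. When `outdir` is given, every
#' stage's tables are written along with a JSON manifest of parameters and
#' output checksums; the manifest is a pure function of inputs and seed.
#'
#' @param data A list with `expression`, `samples`, `gene_sets`, `ontology`,
#'   `positions`, `themes` (as produced by [simulate_study()] or assembled
#'   from [read_expression()], [read_gmt()], [read_ontology()]).
#' @param diseased,control Strain labels; default the first/second strain in
#'   the annotations.
#' @param criteria See [significance_criteria()].
#' @param weight_p,n_perm GSEA parameters.
#' @param threshold_pct Network edge threshold (percent connectivity).
#' @param inflation MCL inflation.
#' @param min_size,max_size Exclusive gene-set size bounds.
#' @param s0_method SAM fudge-factor policy (see [estimate_s0()]).
#' @param loci Locus tibble (see [locus_table()]).
#' @param seed Integer seed controlling all randomness.
#' @param outdir Optional output directory.
#' @return An `em_pipeline` list: `ranked`, `gsea`, `contrasts`,
#'   `summaries`, `networks`, `metanodes`, `clouds`, `locus`, `theme_anova`,
#'   `params` and (when written) `manifest`.
#' @export
run_pipeline <- function(data,
                         diseased = NULL, control = NULL,
                         criteria = significance_criteria(),
                         weight_p = 1, n_perm = 1000L,
                         threshold_pct = 8, inflation = 2.5,
                         min_size = 10L, max_size = 1000L,
                         s0_method = "percentile_cv_min",
                         loci = locus_table(),
                         seed = 1L, outdir = NULL) {
  need <- c("expression", "samples", "gene_sets", "ontology", "positions")
  missing_in <- setdiff(need, names(data))
  if (length(missing_in) > 0L) {
    abort(paste0("Pipeline input missing: ", paste(missing_in, collapse = ", ")))
  }
  strains <- unique(data$samples$strain)
  diseased <- diseased %||% strains[1L]
  control <- control %||% setdiff(strains, diseased)[1L]

  universe <- data$expression$id %||% data$expression[[1L]]
  sets <- filter_gene_sets(data$gene_sets, universe, min_size, max_size)

  tps <- sort(unique(data$samples$timepoint_weeks))
  transitions <- map(seq_len(length(tps) - 1L), function(i) tps[c(i, i + 1L)])
  tr_name <- map_chr(transitions, function(tr) paste0(tr[1L], "to", tr[2L], "wk"))

  ranked <- list(); gsea <- list(); contrasts <- list()
  networks <- list(); metanodes <- list(); clouds <- list()
  run_id <- 0L
  for (i in seq_along(transitions)) {
    tr <- transitions[[i]]
    for (st in c(diseased, control)) {
      run_id <- run_id + 1L
      key <- paste0(tr_name[i], "_", if (st == diseased) "diseased" else "control")
      ranked[[key]] <- rank_transition(data$expression, data$samples, st,
                                       tr[1L], tr[2L], s0_method = s0_method)
      gsea[[key]] <- run_gsea(ranked[[key]], sets, weight_p = weight_p,
                              n_perm = n_perm, seed = seed + run_id)
    }
    ctr <- classify_contrast(gsea[[paste0(tr_name[i], "_diseased")]],
                             gsea[[paste0(tr_name[i], "_control")]],
                             criteria)
    contrasts[[tr_name[i]]] <- ctr
    for (dir in c("enriched", "depleted")) {
      net <- withCallingHandlers(
        build_em_network(ctr, data$ontology, dir, criteria = criteria,
                         threshold_pct = threshold_pct),
        warning = function(w) invokeRestart("muffleWarning"))
      net <- mcl_cluster(net, inflation = inflation)
      nkey <- paste0(tr_name[i], "_", dir)
      networks[[nkey]] <- net
      metanodes[[nkey]] <- collapse_metanodes(net)
      clouds[[nkey]] <- gene_clouds(net, inflation = inflation)
    }
  }

  summaries <- imap(contrasts, function(ctr, nm) {
    mutate(summarize_contrast(ctr), transition = nm, .before = 1L)
  }) |> bind_rows()

  locus <- NULL; theme_anova <- NULL
  if (!is.null(data$themes)) {
    locus <- imap(contrasts, function(ctr, nm) {
      lf <- locus_fractions(ctr, data$positions, data$themes, loci)
      mutate(lf, transition = nm, .before = 1L)
    }) |> bind_rows()
    usable <- locus[!is.na(locus$theme), ]
    enough <- table(usable$theme)
    if (sum(enough >= 2L) >= 2L) {
      theme_anova <- compare_themes(usable)
    }
  }

  out <- list(ranked = ranked, gsea = gsea, contrasts = contrasts,
              summaries = summaries, networks = networks,
              metanodes = metanodes, clouds = clouds,
              locus = locus, theme_anova = theme_anova,
              params = list(diseased = diseased, control = control,
                            criteria = criteria, weight_p = weight_p,
                            n_perm = n_perm, threshold_pct = threshold_pct,
                            inflation = inflation, min_size = min_size,
                            max_size = max_size, s0_method = s0_method,
                            seed = seed))
  class(out) <- "em_pipeline"
  if (!is.null(outdir)) out$manifest <- write_pipeline(out, outdir)
  out
}

#' @export
print.em_pipeline <- function(x, ...) {
  cat("EM-landscape pipeline run (seed ", x$params$seed, ")\n", sep = "")
  cat("  ", length(x$ranked), " ranked lists, ",
      length(x$contrasts), " transitions\n", sep = "")
  print(x$summaries)
  invisible(x)
}

# Write every stage's outputs plus a deterministic JSON manifest
# (parameters, seed, md5 checksum per file; relative paths, no timestamps).
write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(res$ranked)) {
    write_rnk(res$ranked[[key]], file.path(outdir, paste0("ranked_", key, ".rnk")))
    write_gsea_report(res$gsea[[key]],
                      file.path(outdir, paste0("gsea_", key, ".tsv")))
  }
  for (key in names(res$contrasts)) {
    flat <- as_tibble(res$contrasts[[key]])
    flat$le_genes <- map_chr(flat$le_genes, paste, collapse = ";")
    flat$le_genes_ctrl <- map_chr(flat$le_genes_ctrl, paste, collapse = ";")
    readr::write_tsv(flat, file.path(outdir, paste0("contrast_", key, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(res$summaries, file.path(outdir, "summary.tsv"),
                   progress = FALSE)
  for (key in names(res$networks)) {
    net <- res$networks[[key]]
    if (nrow(net$nodes) == 0L) next
    write_network(net, file.path(outdir, paste0("network_", key)))
    write_clouds(net, file.path(outdir, paste0("cloud_", key)))
  }
  if (!is.null(res$locus)) {
    readr::write_tsv(res$locus, file.path(outdir, "locus_fractions.tsv"),
                     progress = FALSE)
  }
  if (!is.null(res$theme_anova)) {
    readr::write_tsv(mutate(res$theme_anova$tukey,
                            f = res$theme_anova$anova$f,
                            anova_p = res$theme_anova$anova$p),
                     file.path(outdir, "theme_anova.tsv"), progress = FALSE)
  }
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = "emlandscape",
    version = as.character(utils::packageVersion("emlandscape")),
    seed = res$params$seed,
    params = res$params[setdiff(names(res$params), "seed")],
    files = lapply(files, function(f) {
      list(path = f,
           md5 = unname(tools::md5sum(file.path(outdir, f))))
    })
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}
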