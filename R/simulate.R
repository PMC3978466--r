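#' Default planted gene-set perturbations
#'
#' A small mix of exclusive, reciprocal and parallel perturbations on the
#' 4 -> 8 week transition, in overlap blocks so that the resulting networks
#' have edges and clusters. `effect_log2 > 0` plants enrichment at the later
#' timepoint in the diseased strain; `source` decides whether the set gets a
#' synthetic GO term under an EM root (`"GO"`) or qualifies only through
#' leading-edge overlap (`"NC"`). Sets sharing a `block` share a fraction of
#' their member genes.
#'
#' @return A tibble understood by [simulate_study()]'s `plants` argument.
#' @export
default_plants <- function() {
  tibble(
    size = 40L,
    effect_log2 = c(1.5, 1.5, 1.5, 1.5, 1.5,
                    1.5, 1.5, 1.5,
                    1.5, 1.5,
                    -1.5, -1.5, -1.5),
    t1 = 4, t2 = 8,
    klass = c(rep("exclusive", 5L),
              rep("reciprocal", 3L),
              rep("parallel", 2L),
              rep("exclusive", 3L)),
    source = c("GO", "GO", "GO", "NC", "NC",
               "GO", "GO", "NC",
               "GO", "GO",
               "GO", "GO", "NC"),
    block = c("b1", "b1", "b1", "b1", "b1",
              "b2", "b2", "b2",
              "b3", "b3",
              "b4", "b4", "b4"),
    locus_frac = c(rep(0.02, 5L), rep(0.2, 3L), rep(0.1, 2L), rep(0.1, 3L))
  )
}

#' Planted perturbations for the recovery benchmark
#'
#' A larger planted design used to measure end-to-end recovery: by default 20
#' exclusive, 4 reciprocal and 4 parallel sets of 40 genes with a 1.5 log2
#' shift on the 4 -> 8 week transition, in blocks of up to five sets so the
#' resulting networks are non-trivial.
#'
#' @param n_exclusive,n_reciprocal,n_parallel Number of sets per class.
#' @param size Genes per set.
#' @param effect_log2 Planted shift.
#' @return A plants tibble for [simulate_study()].
#' @export
benchmark_plants <- function(n_exclusive = 20L, n_reciprocal = 4L,
                             n_parallel = 4L, size = 40L,
                             effect_log2 = 1.5) {
  klass <- c(rep("exclusive", n_exclusive),
             rep("reciprocal", n_reciprocal),
             rep("parallel", n_parallel))
  n <- length(klass)
  # blocks of <= 5 within one class so plants stay compatible; alternating
  # block signs give both enriched and depleted networks
  block_no <- (stats::ave(seq_len(n), klass, FUN = seq_along) - 1L) %/% 5L + 1L
  block <- paste0(klass, "_", block_no)
  tibble(
    size = as.integer(size),
    effect_log2 = effect_log2 * ifelse(klass == "exclusive" &
                                         block_no %% 2L == 0L, -1, 1),
    t1 = 4, t2 = 8,
    klass = klass,
    source = rep_len(c("GO", "GO", "NC"), n),
    block = block,
    locus_frac = 0.05
  )
}

#' Simulate a two-strain, multi-timepoint expression study
#'
#' Generates the full input bundle the pipeline consumes, with ground truth
#' for every stage: a log2 expression matrix (baseline `N(8, 1)` per gene,
#' replicate noise `N(0, noise_sd)`), sample annotations for two strains at
#' the given timepoints with `replicates` mice per cell, a gene-set
#' collection (planted sets plus random background sets), a small synthetic
#' GO-like DAG whose EM roots the planted GO sets descend from, gene map
#' positions, and a theme mapping (one theme per overlap block).
#'
#' Planted sets receive an additive log2 shift from `t2` onward: in the
#' diseased strain only (`exclusive`), in both strains with the same sign
#' (`parallel`) or with opposite signs (`reciprocal`). Sets sharing a
#' `block` share `overlap_frac` of their members (and must plant compatible
#' shifts there, otherwise an error is raised). Each planted gene lands
#' inside a susceptibility locus with its set's `locus_frac` probability.
#'
#' @param n_genes Number of genes (default 2000).
#' @param strains Named character vector `c(diseased = ..., control = ...)`.
#' @param timepoints Timepoints in weeks (default 4, 8, 12, 16).
#' @param replicates Replicates per strain x timepoint cell (default 5).
#' @param plants Planted-perturbation tibble (see [default_plants()]).
#' @param n_background_sets Number of unperturbed random sets (default 70).
#' @param background_size_range Size range of background sets.
#' @param noise_sd Replicate noise standard deviation (default 0.25).
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param overlap_frac Shared-gene fraction within a block (default 0.3).
#' @param ontology_depth Terms between a planted GO term and its root.
#' @param loci Locus tibble (see [locus_table()]).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `expression`, `samples`, `gene_sets`, `ontology`,
#'   `positions`, `themes`, `truth` (plants plus per-gene shifts and locus
#'   membership) and `config`.
#' @export
simulate_study <- function(n_genes = 2000L,
                           strains = c(diseased = "B6.NOD-Aec1Aec2",
                                       control = "B6"),
                           timepoints = c(4, 8, 12, 16),
                           replicates = 5L,
                           plants = default_plants(),
                           n_background_sets = 70L,
                           background_size_range = c(15L, 80L),
                           noise_sd = 0.25,
                           baseline_mean = 8, baseline_sd = 1,
                           overlap_frac = 0.3,
                           ontology_depth = 2L,
                           loci = locus_table(),
                           seed = 1L) {
  stopifnot(replicates >= 2L, length(strains) == 2L,
            all(c("diseased", "control") %in% names(strains)))
  if (!is.null(plants) && nrow(plants) > 0L) {
    stopifnot(all(is.finite(plants$effect_log2)),
              all(plants$klass %in% c("exclusive", "reciprocal", "parallel")))
    if (!"block" %in% names(plants)) plants$block <- NA_character_
    if (!"locus_frac" %in% names(plants)) plants$locus_frac <- 0.05
    if (!"source" %in% names(plants)) plants$source <- "GO"
  } else {
    plants <- default_plants()[0, ]
  }
  check_plant_compatibility(plants)

  withr::with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))

    # --- gene-set membership -------------------------------------------------
    plants$set_id <- plant_ids(plants)
    pool <- genes
    take <- function(k) {
      if (k > length(pool)) {
        abort("Planted sets need more genes than n_genes provides")
      }
      picked <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      picked
    }
    members <- vector("list", nrow(plants))
    blocks <- split(seq_len(nrow(plants)), plants$block)
    for (b in names(blocks)) {
      idx <- blocks[[b]]
      n_shared <- if (length(idx) > 1L)
        round(overlap_frac * min(plants$size[idx])) else 0L
      shared <- take(n_shared)
      for (i in idx) {
        members[[i]] <- c(shared, take(plants$size[i] - n_shared))
      }
    }
    for (i in setdiff(seq_len(nrow(plants)), unlist(blocks))) {
      members[[i]] <- take(plants$size[i])
    }
    plants$genes <- members

    bg_sizes <- sample(seq(background_size_range[1L],
                           background_size_range[2L]),
                       n_background_sets, replace = TRUE)
    bg <- tibble(
      set_id = sprintf("GO_BG%04d", seq_len(n_background_sets)),
      size = bg_sizes,
      genes = map(bg_sizes, function(k) sample(genes, k))
    )
    # half the background stays GO (under a neutral root), half is user-tier
    non_go <- seq_len(n_background_sets) %% 2L == 0L
    bg$set_id[non_go] <- sprintf("NC_BG%04d", which(non_go))

    gene_sets <- bind_rows(
      tibble(set_id = plants$set_id, name = plants$set_id,
             source = gs_source(plants$set_id), genes = plants$genes),
      tibble(set_id = bg$set_id, name = bg$set_id,
             source = gs_source(bg$set_id), genes = bg$genes)
    )

    # --- ontology: planted GO terms descend from EM roots --------------------
    ontology <- synth_ontology(plants, bg, ontology_depth)

    # --- expression ----------------------------------------------------------
    samples <- tidyr::expand_grid(
      strain = unname(strains),
      timepoint_weeks = timepoints,
      replicate = seq_len(replicates)
    )
    samples$sample <- sprintf("%s_%gwk_r%d", samples$strain,
                              samples$timepoint_weeks, samples$replicate)
    samples <- samples[, c("sample", "strain", "timepoint_weeks", "replicate")]

    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    mat <- matrix(rnorm(n_genes * nrow(samples), 0, noise_sd),
                  n_genes, nrow(samples)) + baseline
    rownames(mat) <- genes
    colnames(mat) <- samples$sample

    # apply each block's (compatible) shift once, so block-shared genes are
    # not shifted repeatedly
    shift_rows <- list()
    group_key <- ifelse(is.na(plants$block),
                        paste0(".row", seq_len(nrow(plants))), plants$block)
    for (grp in split(seq_len(nrow(plants)), group_key)) {
      i <- grp[1L]
      e <- plants$effect_log2[i]
      gs <- unique(unlist(plants$genes[grp]))
      strain_eff <- switch(plants$klass[i],
        exclusive = c(e, 0),
        parallel = c(e, e),
        reciprocal = c(e, -e))
      names(strain_eff) <- strains[c("diseased", "control")]
      for (st in names(strain_eff)) {
        if (strain_eff[[st]] == 0) next
        cols <- samples$sample[samples$strain == st &
                                 samples$timepoint_weeks >= plants$t2[i]]
        mat[gs, cols] <- mat[gs, cols] + strain_eff[[st]]
      }
    }
    for (i in seq_len(nrow(plants))) {
      shift_rows[[i]] <- tibble(gene = plants$genes[[i]],
                                set_id = plants$set_id[i],
                                effect_log2 = plants$effect_log2[i])
    }
    expression <- as_tibble(cbind(tibble(id = genes), as_tibble(mat)))

    # --- map positions -------------------------------------------------------
    positions <- tibble(
      gene = genes,
      chromosome = as.character(sample(1:19, n_genes, replace = TRUE)),
      cM = runif(n_genes, 0, 100)
    )
    for (i in seq_len(nrow(plants))) {
      gs <- plants$genes[[i]]
      inside <- gs[runif(length(gs)) < plants$locus_frac[i]]
      if (length(inside) > 0L) {
        pick <- sample.int(nrow(loci), length(inside), replace = TRUE)
        rows <- match(inside, positions$gene)
        positions$chromosome[rows] <- loci$chromosome[pick]
        positions$cM[rows] <- loci$start_cM[pick] +
          runif(length(inside)) * (loci$end_cM[pick] - loci$start_cM[pick])
      }
    }
    positions$in_locus <- map_lgl(seq_len(n_genes), function(i) {
      any(loci$chromosome == positions$chromosome[i] &
            loci$start_cM <= positions$cM[i] &
            positions$cM[i] <= loci$end_cM)
    })

    themes <- tibble(set_id = plants$set_id,
                     theme = ifelse(is.na(plants$block), "unthemed",
                                    paste0("theme_", plants$block)))

    truth <- list(
      plants = plants[, c("set_id", "size", "effect_log2", "t1", "t2",
                          "klass", "source", "block", "locus_frac")],
      gene_shifts = bind_rows(shift_rows),
      direction = ifelse(plants$effect_log2 >= 0, "enriched", "depleted")
    )
    truth$plants$direction <- truth$direction
    truth$direction <- NULL

    list(expression = expression, samples = samples, gene_sets = gene_sets,
         ontology = ontology, positions = positions, themes = themes,
         truth = truth,
         config = list(n_genes = n_genes, strains = strains,
                       timepoints = timepoints, replicates = replicates,
                       noise_sd = noise_sd, overlap_frac = overlap_frac,
                       seed = seed))
  })
}

plant_ids <- function(plants) {
  if (nrow(plants) == 0L) return(character())
  sprintf("%s_SYN%04d", plants$source, seq_len(nrow(plants)))
}

check_plant_compatibility <- function(plants) {
  if (nrow(plants) == 0L) return(invisible(plants))
  by_block <- split(seq_len(nrow(plants)), plants$block)
  for (idx in by_block) {
    if (length(idx) < 2L) next
    same <- length(unique(plants$klass[idx])) == 1L &&
      length(unique(plants$effect_log2[idx])) == 1L &&
      length(unique(paste(plants$t1[idx], plants$t2[idx]))) == 1L
    if (!same) {
      abort(paste0("Incompatible plants share block '",
                   plants$block[idx[1L]],
                   "': same block requires same klass, effect and transition"))
    }
  }
  invisible(plants)
}

# Small DAG: each planted GO set's term sits `depth` edges below one of the
# three EM roots (round-robin); background GO sets descend from a neutral
# biological-process root so they never qualify as EM-related.
synth_ontology <- function(plants, bg, depth = 2L) {
  em_roots <- c("GO_0071944", "GO_0031012", "GO_0005911")
  neutral_root <- "GO_0008150"
  edges <- list(tibble(child = em_roots, parent = "GO_0005575",
                       relation = "is_a"))
  chain <- function(term, root, tag) {
    nodes <- c(term, if (depth > 1L)
      sprintf("GO_MID_%s_%d", tag, seq_len(depth - 1L)), root)
    tibble(child = nodes[-length(nodes)], parent = nodes[-1L],
           relation = "is_a")
  }
  go_plants <- which(plants$source == "GO")
  for (k in seq_along(go_plants)) {
    i <- go_plants[k]
    root <- em_roots[(k - 1L) %% 3L + 1L]
    edges[[length(edges) + 1L]] <- chain(plants$set_id[i], root,
                                         plants$set_id[i])
  }
  go_bg <- grep("^GO_", bg$set_id, value = TRUE)
  for (id in go_bg) {
    edges[[length(edges) + 1L]] <- chain(id, neutral_root, id)
  }
  out <- distinct(bind_rows(edges))
  validate_ontology(out)
  out
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits `expression.tsv`, `samples.tsv`, `gene_sets.gmt`, `ontology.tsv`,
#' `positions.tsv`, `themes.tsv` and `truth.json` under `dir`.
#'
#' @param sim Result of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(sim$expression, p("expression.tsv"), progress = FALSE)
  readr::write_tsv(sim$samples, p("samples.tsv"), progress = FALSE)
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  readr::write_tsv(sim$ontology, p("ontology.tsv"), progress = FALSE)
  readr::write_tsv(sim$positions[, c("gene", "chromosome", "cM")],
                   p("positions.tsv"), progress = FALSE)
  readr::write_tsv(sim$themes, p("themes.tsv"), progress = FALSE)
  truth <- sim$truth
  truth$plants$genes <- NULL
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
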