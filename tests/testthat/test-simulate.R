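test_that("simulation is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(simulate_study(n_genes = 300, n_background_sets = 10,
                             plants = default_plants()[1:5, ], seed = 5), d1)
  write_study(simulate_study(n_genes = 300, n_background_sets = 10,
                             plants = default_plants()[1:5, ], seed = 5), d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  write_study(simulate_study(n_genes = 300, n_background_sets = 10,
                             plants = default_plants()[1:5, ], seed = 6), d2)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "expression.tsv"))),
    unname(tools::md5sum(file.path(d2, "expression.tsv")))))
})

test_that("truth and generated data are mutually consistent", {
  sim <- simulate_study(seed = 11)
  truth <- sim$truth
  # every planted set exists in the collection with its stated size
  idx <- match(truth$plants$set_id, sim$gene_sets$set_id)
  expect_false(anyNA(idx))
  expect_equal(lengths(sim$gene_sets$genes[idx]), truth$plants$size)
  # gene shifts cover exactly the planted memberships
  for (i in seq_len(nrow(truth$plants))) {
    planted <- truth$gene_shifts$gene[
      truth$gene_shifts$set_id == truth$plants$set_id[i]]
    expect_setequal(planted, sim$gene_sets$genes[[idx[i]]])
  }
  # reciprocal plants are recorded as reciprocal, never parallel
  expect_false(any(truth$plants$klass == "reciprocal" &
                     truth$plants$klass == "parallel"))
  # planted mean shifts are visible in the expression matrix
  p1 <- truth$plants[truth$plants$klass == "exclusive" &
                       truth$plants$direction == "enriched", ][1, ]
  genes <- sim$gene_sets$genes[[match(p1$set_id, sim$gene_sets$set_id)]]
  m <- as.matrix(sim$expression[match(genes, sim$expression$id), -1])
  colnames(m) <- names(sim$expression)[-1]
  dis <- sim$samples$strain == "B6.NOD-Aec1Aec2"
  pre <- sim$samples$sample[dis & sim$samples$timepoint_weeks < p1$t2]
  post <- sim$samples$sample[dis & sim$samples$timepoint_weeks >= p1$t2]
  expect_equal(mean(m[, post]) - mean(m[, pre]), p1$effect_log2,
               tolerance = 0.15)
  pre_ctl <- sim$samples$sample[!dis & sim$samples$timepoint_weeks < p1$t2]
  post_ctl <- sim$samples$sample[!dis & sim$samples$timepoint_weeks >= p1$t2]
  expect_lt(abs(mean(m[, post_ctl]) - mean(m[, pre_ctl])), 0.3)
})

test_that("planted GO terms descend from EM roots; background does not", {
  sim <- simulate_study(seed = 2)
  em_roots <- c("GO_0071944", "GO_0031012", "GO_0005911")
  go_plants <- sim$truth$plants$set_id[sim$truth$plants$source == "GO"]
  for (id in go_plants) {
    expect_gt(length(intersect(term_ancestors(sim$ontology, id), em_roots)), 0)
  }
  bg_go <- grep("^GO_BG", sim$gene_sets$set_id, value = TRUE)
  for (id in bg_go[1:5]) {
    expect_length(intersect(term_ancestors(sim$ontology, id), em_roots), 0)
  }
})

test_that("incompatible plants sharing a block are rejected", {
  bad <- default_plants()
  bad$block <- "same"
  expect_error(simulate_study(plants = bad, seed = 1), "Incompatible")
})

test_that("written study round-trips through the readers", {
  sim <- simulate_study(n_genes = 200, n_background_sets = 8,
                        plants = default_plants()[1:3, ], seed = 4)
  d <- withr::local_tempdir()
  write_study(sim, d)
  got <- read_expression(file.path(d, "expression.tsv"),
                         file.path(d, "samples.tsv"))
  expect_equal(got$expression$id, sim$expression$id)
  expect_equal(as.matrix(got$expression[, -1]),
               as.matrix(sim$expression[, -1]), tolerance = 1e-9)
  expect_equal(got$samples, sim$samples)
  sets <- read_gmt(file.path(d, "gene_sets.gmt"))
  expect_equal(sets$set_id, sim$gene_sets$set_id)
  expect_equal(sets$genes, sim$gene_sets$genes)
  onto <- read_ontology(file.path(d, "ontology.tsv"))
  expect_equal(onto, sim$ontology)
})

test_that("a null simulation yields almost no retained sets", {
  sim <- simulate_study(n_genes = 800, plants = NULL,
                        n_background_sets = 40, seed = 17)
  res <- suppressMessages(run_pipeline(sim, n_perm = 200, seed = 17))
  ctr <- dplyr::bind_rows(lapply(res$contrasts, tibble::as_tibble))
  # type-I tolerance: the triple gate (FDR, p, TAGS) makes retention rare
  expect_lte(sum(ctr$retained), ceiling(0.01 * nrow(ctr)))
})
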