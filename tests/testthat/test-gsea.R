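test_that("single-member sets give extreme enrichment scores", {
  r <- make_ranked(c(2, 1, -1), genes = c("g1", "g2", "g3"))
  top <- enrichment_score(r, "g1")
  expect_equal(top$es, 1.0)
  expect_equal(top$peak_index, 1L)
  bottom <- enrichment_score(r, "g3")
  expect_equal(bottom$es, -1.0)
  expect_equal(bottom$peak_index, 2L)  # deepest deficit just before the hit
  expect_error(enrichment_score(r, "absent"), "no members")
  expect_error(enrichment_score(r, c("g1", "g2", "g3")), "entire")
})

test_that("enrichment score matches the brute-force oracle on random cases", {
  set.seed(101)
  for (case in 1:300) {
    n <- sample(5:20, 1)
    scores <- sort(round(rnorm(n, 0, 2), 3), decreasing = TRUE)
    scores[scores == 0] <- 0.001
    r <- make_ranked(scores)
    nh <- sample(1:min(5, n - 1), 1)
    members <- sample(r$gene, nh)
    got <- enrichment_score(r, members)
    want <- oracle_es(r$d_score, r$gene %in% members)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_identical(got$peak_index, want$peak_index)
  }
})

test_that("the fast permutation scorer agrees with the full profile", {
  set.seed(77)
  for (case in 1:200) {
    n <- sample(20:200, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    r <- make_ranked(scores, genes = sprintf("g%03d", 1:n))
    nh <- sample(2:15, 1)
    members <- sample(r$gene, nh)
    full <- enrichment_score(r, members)
    idx <- which(r$gene %in% members)
    fast <- emlandscape:::es_fast(idx, abs(r$d_score[idx]), n)
    expect_equal(fast$es, full$es, tolerance = 1e-12)
    expect_identical(as.integer(fast$peak_index), full$peak_index)
  }
})

test_that("with weight 0 the score reduces to the classical KS form", {
  set.seed(55)
  for (case in 1:50) {
    n <- sample(8:25, 1)
    r <- make_ranked(sort(rnorm(n), decreasing = TRUE))
    members <- sample(r$gene, sample(2:5, 1))
    got <- enrichment_score(r, members, weight_p = 0)
    want <- oracle_ks(r$gene %in% members)
    expect_equal(got$es, want$es, tolerance = 1e-12)
  }
})

test_that("ES is invariant to positive rescaling of the scores", {
  set.seed(8)
  scores <- sort(rnorm(50), decreasing = TRUE)
  r1 <- make_ranked(scores, genes = sprintf("g%03d", 1:50))
  r2 <- make_ranked(scores * 7.3, genes = sprintf("g%03d", 1:50))
  members <- sample(r1$gene, 6)
  expect_equal(enrichment_score(r1, members)$es,
               enrichment_score(r2, members)$es, tolerance = 1e-12)
})

test_that("leading edge is the members at or before / after the peak", {
  r <- make_ranked(10:1, genes = sprintf("g%02d", 1:10))
  members <- c("g01", "g02", "g10")
  esr <- enrichment_score(r, members)
  want <- oracle_es(r$d_score, r$gene %in% members)
  expect_equal(esr$es, want$es, tolerance = 1e-12)
  expect_equal(esr$peak_index, 2L)
  expect_equal(sort(leading_edge(r, members, esr)), c("g01", "g02"))

  # single member at top
  esr1 <- enrichment_score(r, "g01")
  expect_equal(leading_edge(r, "g01", esr1), "g01")

  # negative ES with the peak at the last rank
  esr2 <- enrichment_score(r, "g10")
  expect_lt(esr2$es, 0)
  expect_equal(leading_edge(r, "g10", esr2), "g10")
})

test_that("descriptors follow their definitions", {
  r <- make_ranked(10:1, genes = sprintf("g%02d", 1:10))
  members <- c("g01", "g02")
  esr <- enrichment_score(r, members)
  d <- gsea_descriptors(r, esr, n_le = 2)
  expect_equal(d$tags_pct, 100)      # all members before the positive peak
  expect_equal(d$list_pct, 20)       # peak at rank 2 of 10

  # SIGNAL formula on stated values: TAGS 60, LIST 20, N 1000, N_H 50
  sig <- 60 * (1 - 20 / 100) * 1000 / (1000 - 50)
  fake <- list(es = 1, peak_index = 200L, hit_index = seq_len(50))
  fake_r <- make_ranked(sort(rnorm(1000), decreasing = TRUE),
                        genes = sprintf("g%04d", 1:1000))
  got <- gsea_descriptors(fake_r, fake, n_le = 30)
  expect_equal(got$tags_pct, 60)
  expect_equal(got$list_pct, 20)
  expect_equal(got$signal_pct, sig, tolerance = 1e-12)
  expect_equal(round(sig, 1), 50.5)
})

test_that("a planted top set attains the minimal nominal p", {
  set.seed(19)
  n <- 400
  r <- make_ranked(sort(rnorm(n, 0, 1), decreasing = TRUE),
                   genes = sprintf("g%04d", 1:n))
  sets <- tibble::tibble(set_id = "TOP", name = "TOP", source = "user",
                         genes = list(r$gene[1:20]))
  res <- run_gsea(r, sets, n_perm = 200, seed = 4)
  expect_equal(res$p_nominal, 1 / 201)
  expect_equal(res$fdr_q, 0)
  expect_equal(res$tags_pct, 100)
  expect_setequal(res$le_genes[[1]], r$gene[1:20])
})

test_that("nominal p is stable in n_perm and deterministic in the seed", {
  set.seed(23)
  n <- 300
  r <- make_ranked(sort(rnorm(n), decreasing = TRUE),
                   genes = sprintf("g%04d", 1:n))
  genes <- sample(r$gene, 25)
  sets <- tibble::tibble(set_id = "S", name = "S", source = "user",
                         genes = list(genes))
  a <- run_gsea(r, sets, n_perm = 500, seed = 11)
  a2 <- run_gsea(r, sets, n_perm = 500, seed = 11)
  expect_identical(a$p_nominal, a2$p_nominal)
  b <- run_gsea(r, sets, n_perm = 1000, seed = 11)
  # doubling the permutations moves p by no more than Monte-Carlo noise
  pbar <- (a$p_nominal + b$p_nominal) / 2
  expect_lt(abs(a$p_nominal - b$p_nominal),
            3 * sqrt(pbar * (1 - pbar) / 500) + 2 / 501)
  expect_error(run_gsea(r, sets, n_perm = 0), "n_perm")
})

test_that("TAGS equals 100 * |LE| / detected size on every emitted row", {
  sim <- simulate_study(n_genes = 600, n_background_sets = 15, seed = 31)
  sets <- filter_gene_sets(sim$gene_sets, sim$expression$id)
  r <- rank_transition(sim$expression, sim$samples, "B6.NOD-Aec1Aec2", 4, 8)
  res <- run_gsea(r, sets, n_perm = 100, seed = 3)
  expect_equal(res$tags_pct,
               100 * lengths(res$le_genes) / res$detected_size)
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$p_nominal >= 0 & res$p_nominal <= 1))
  expect_true(all(res$fdr_q >= 0))
})

test_that("the enrichment score agrees with fgsea on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(61)
  n <- 500
  scores <- sort(rnorm(n), decreasing = TRUE)
  r <- make_ranked(scores, genes = sprintf("g%04d", 1:n))
  stats_vec <- stats::setNames(r$d_score, r$gene)
  for (case in 1:20) {
    members <- sample(r$gene, sample(10:40, 1))
    mine <- enrichment_score(r, members)$es
    ref <- suppressWarnings(
      fgsea::calcGseaStat(stats_vec, selectedStats = which(r$gene %in% members),
                          gseaParam = 1))
    expect_equal(mine, ref, tolerance = 1e-6)
  }
})
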