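# tiny ontology: T1 -> GO_0031012; T2 -> GO_0008150 (neutral)
onto <- tibble::tibble(
  child = c("GO_T1", "GO_T2", "GO_0031012", "GO_0008150"),
  parent = c("GO_0031012", "GO_0008150", "GO_0005575", "GO_0005575"),
  relation = "is_a")

test_that("EM qualification needs GO ancestry below an EM root and FDR", {
  res <- make_result(c("GO_T1", "GO_T2", "GO_0031012", "NC_X"),
                     es = 0.6, fdr_q = c(0.01, 0.01, 0.01, 0.01),
                     p_nominal = 0.001, tags_pct = 80,
                     le_genes = list("a", "b", "c", "d"))
  expect_setequal(qualify_em_related(res, onto), c("GO_T1", "GO_0031012"))

  # FDR at/above 0.05 disqualifies
  res$fdr_q <- c(0.06, 0.01, 0.05, 0.01)
  expect_length(qualify_em_related(res, onto), 0L)

  # unresolvable GO id excluded with a warning
  res2 <- make_result(c("GO_T1", "GO_NOWHERE"), es = 0.6, fdr_q = 0.01,
                      p_nominal = 0.001, tags_pct = 80,
                      le_genes = list("a", "b"))
  expect_warning(ids <- qualify_em_related(res2, onto), "not resolvable")
  expect_equal(ids, "GO_T1")
})

test_that("connectivity is the Jaccard overlap in percent", {
  expect_equal(le_connectivity(c("a", "b"), c("a", "b")), 100)
  expect_equal(le_connectivity(c("a", "b"), c("c", "d")), 0)
  a <- sprintf("a%d", 1:8); sh <- c("s1", "s2")
  b <- sprintf("b%d", 1:8)
  expect_equal(le_connectivity(c(a, sh), c(b, sh)), 100 * 2 / 18)
  expect_equal(le_connectivity(c(a, sh), c(b, sh), method = "overlap"),
               100 * 2 / 10)
  # symmetry; 100 iff identical
  expect_equal(le_connectivity(c(a, sh), c(b, sh)),
               le_connectivity(c(b, sh), c(a, sh)))
  expect_lt(le_connectivity(a, c(a, "extra")), 100)
  expect_error(le_connectivity(character(), "a"), "non-empty")
})

# A contrast fixture with hand-computable LE overlaps. LE sets of size 25
# sharing k genes have Jaccard 100*k/(50-k): k=2 -> 4.17 (below the 8%
# threshold), k=4 -> 8.70 (above), and a pair sized 20/30 sharing 2 -> 4.35.
network_fixture <- function() {
  le <- list(
    EM1 = sprintf("m%02d", 1:25),                      # EM-related seed
    A   = c(sprintf("m%02d", 1:4), sprintf("a%02d", 1:21)),  # 4 shared -> in
    B   = c(sprintf("m%02d", 1:2), sprintf("b%02d", 1:23)),  # 2 shared -> out
    C   = c(sprintf("a%02d", 1:4), sprintf("c%02d", 1:21)),  # linked to A only
    FAILTAGS = c(sprintf("m%02d", 1:10), sprintf("f%02d", 1:15))
  )
  ids <- c("GO_T1", "NC_A", "NC_B", "NC_C", "NC_FAILTAGS")
  d <- make_result(ids, es = 0.6, fdr_q = 0.01, p_nominal = 0.001,
                   tags_pct = c(80, 80, 80, 80, 40),
                   le_genes = unname(le))
  ctl <- make_result(ids, es = 0.6, fdr_q = 0.5, p_nominal = 0.5,
                     tags_pct = 10, le_genes = unname(le), strain = "ctl")
  suppressMessages(classify_contrast(d, ctl))
}

test_that("network nodes and edges match hand-enumerated adjacency", {
  ctr <- network_fixture()
  # klass of FAILTAGS is not retained (TAGS 40 < 50) -> absent before building
  net <- build_em_network(ctr, onto, "enriched")
  expect_setequal(net$nodes$set_id, c("GO_T1", "NC_A"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$connectivity, 100 * 4 / 46, tolerance = 1e-12)
  expect_equal(
    net$nodes$em_class[match(c("GO_T1", "NC_A"), net$nodes$set_id)],
    c("EM_related", "EM_associated"))

  # inclusive threshold: exactly 8% qualifies, 7.9% does not
  d2 <- make_result(c("GO_T1", "NC_Y"), es = 0.6, fdr_q = 0.01,
                    p_nominal = 0.001, tags_pct = 80,
                    le_genes = list(c(sprintf("s%02d", 1:2), sprintf("x%02d", 1:11)),
                                    c(sprintf("s%02d", 1:2), sprintf("y%02d", 1:10))))
  c2 <- make_result(c("GO_T1", "NC_Y"), es = 0.6, fdr_q = 0.5, p_nominal = 0.5,
                    tags_pct = 10, le_genes = list("q", "r"), strain = "ctl")
  ctr2 <- suppressMessages(classify_contrast(d2, c2))
  # shared 2 of union 23 -> 8.70% >= 8
  net2 <- build_em_network(ctr2, onto, "enriched")
  expect_equal(nrow(net2$edges), 1L)
  net3 <- build_em_network(ctr2, onto, "enriched", threshold_pct = 8.7)
  expect_equal(nrow(net3$edges), 0L)   # EM seed stays as isolated node
  expect_equal(net3$nodes$set_id, "GO_T1")
})

test_that("every EM-associated node connects to an EM-related node", {
  sim <- simulate_study(seed = 3)
  res <- suppressMessages(run_pipeline(sim, n_perm = 200, seed = 3))
  for (net in res$networks) {
    if (nrow(net$nodes) == 0L) next
    em <- net$nodes$set_id[net$nodes$em_class == "EM_related"]
    for (assoc in net$nodes$set_id[net$nodes$em_class == "EM_associated"]) {
      touching <- c(net$edges$to[net$edges$from == assoc],
                    net$edges$from[net$edges$to == assoc])
      expect_gt(length(intersect(touching, em)), 0L)
    }
  }
})

test_that("an empty seed list yields an empty network with a warning", {
  ctr <- network_fixture()
  no_em_onto <- tibble::tibble(child = "GO_T1", parent = "GO_0008150",
                               relation = "is_a")
  expect_warning(net <- build_em_network(ctr, no_em_onto, "enriched"),
                 "No EM-related")
  expect_equal(nrow(net$nodes), 0L)
})

test_that("node attributes scale against the stated reference nodes", {
  ctr <- network_fixture()
  net <- build_em_network(ctr, onto, "enriched")
  n <- net$nodes
  expect_equal(n$size_scale, n$detected_size / 50)
  expect_equal(n$label_scale, n$tags_pct / 75)
  expect_true(all(n$shape[n$em_class == "EM_related"] == "triangle"))
  expect_true(all(n$shape[n$em_class == "EM_associated"] == "circle"))
  expect_true(all(n$border == "none"))  # all exclusive in this fixture
})

test_that("reciprocal alterations get a node border", {
  d <- make_result(c("GO_T1", "GO_0031012"), es = 0.6, fdr_q = 0.01,
                   p_nominal = 0.001, tags_pct = 75,
                   le_genes = list(c("a", "b", "c"), c("a", "b", "d")))
  ctl <- make_result(c("GO_T1", "GO_0031012"), es = c(-0.6, 0.2),
                     fdr_q = c(0.01, 0.9), p_nominal = c(0.001, 0.9),
                     tags_pct = c(75, 10),
                     le_genes = list(c("a", "x"), "y"), strain = "ctl")
  ctr <- suppressMessages(classify_contrast(d, ctl))
  net <- build_em_network(ctr, onto, "enriched")
  expect_equal(net$nodes$border[net$nodes$set_id == "GO_T1"], "present")
  expect_equal(net$nodes$border[net$nodes$set_id == "GO_0031012"], "none")
  expect_equal(net$nodes$label_scale[1], 1.0)   # TAGS 75 reference
})
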