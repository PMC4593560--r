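# Term selection, pair filtering and the multifunctionality caller.

# helper: ontology root R with leaves under it, annotated per `counts`
# (named leaf -> gene count); genes are disjoint across leaves.
leaf_fixture <- function(counts) {
  obo <- c("[Term]", "id: T:R", "namespace: bp", "")
  for (l in names(counts))
    obo <- c(obo, "[Term]", paste0("id: ", l), "namespace: bp",
             "is_a: T:R", "")
  g <- load_obo(obo)
  gene <- character(0); term <- character(0)
  i <- 0L
  for (l in names(counts)) {
    gene <- c(gene, sprintf("g%04d", i + seq_len(counts[[l]])))
    term <- c(term, rep(l, counts[[l]]))
    i <- i + counts[[l]]
  }
  rec <- data.frame(gene = gene, term = term, evidence = "EXP",
                    qualifiers = "", aspect = NA, stringsAsFactors = FALSE)
  list(graph = g, index = build_index(rec, g), records = rec)
}

test_that("level selection takes terms in [N, 2N) whose descendants stay below N", {
  # term A annotates 100 genes, its only descendant 82: selected at N = 90
  obo <- c("[Term]", "id: T:R", "namespace: bp", "",
           "[Term]", "id: T:A", "namespace: bp", "is_a: T:R", "",
           "[Term]", "id: T:D", "namespace: bp", "is_a: T:A", "",
           "[Term]", "id: T:O", "namespace: bp", "is_a: T:R", "")
  g <- load_obo(obo)
  rec <- data.frame(
    gene = sprintf("g%03d", 1:150),
    term = c(rep("T:D", 82), rep("T:A", 18), rep("T:O", 50)),
    evidence = "EXP", qualifiers = "", aspect = NA,
    stringsAsFactors = FALSE)
  idx <- build_index(rec, g)
  expect_equal(unname(term_count(idx, c("T:A", "T:D"))), c(100L, 82L))
  expect_true("T:A" %in% select_terms(idx, g, 90))
  expect_false("T:D" %in% select_terms(idx, g, 90))   # 82 < 90
  # root annotates 150 but a descendant annotates >= 90: excluded
  expect_false("T:R" %in% select_terms(idx, g, 90))
})

test_that("a broad term with only specific descendants is still bounded by 2N", {
  # count 508 with max descendant count 82: never selected on the grid
  obo <- c("[Term]", "id: T:R", "namespace: bp", "",
           "[Term]", "id: T:WING", "namespace: bp", "is_a: T:R", "",
           "[Term]", "id: T:SUB", "namespace: bp", "is_a: T:WING", "")
  g <- load_obo(obo)
  rec <- data.frame(
    gene = sprintf("g%03d", 1:508),
    term = c(rep("T:SUB", 82), rep("T:WING", 426)),
    evidence = "EXP", qualifiers = "", aspect = NA,
    stringsAsFactors = FALSE)
  idx <- build_index(rec, g)
  expect_equal(unname(term_count(idx, "T:WING")), 508L)
  for (N in seq(10, 120, by = 10))
    expect_false("T:WING" %in% select_terms(idx, g, N))
})

test_that("boundary: a leaf annotating exactly N genes is selected", {
  fx <- leaf_fixture(c("T:L1" = 15, "T:L2" = 40))
  expect_true("T:L1" %in% select_terms(fx$index, fx$graph, 15))
  expect_false("T:L1" %in% select_terms(fx$index, fx$graph, 16))
  expect_false("T:L2" %in% select_terms(fx$index, fx$graph, 15))  # 40 >= 2*15
})

test_that("co-annotation p-value matches enumeration and closed-form oracles", {
  expect_equal(coannotation_pvalue(0, 5, 7, 20), 1)
  expect_equal(coannotation_pvalue(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_equal(coannotation_pvalue(2, 2, 2, 4),
               oracle_hyper_enumerate(2, 2, 2, 4), tolerance = 1e-12)
  expect_lt(coannotation_pvalue(5, 10, 10, 100), 0.1)
  expect_equal(coannotation_pvalue(5, 10, 10, 100),
               oracle_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)
  # symmetry in the two set sizes
  expect_equal(coannotation_pvalue(3, 8, 12, 50),
               coannotation_pvalue(3, 12, 8, 50), tolerance = 1e-12)
  expect_error(coannotation_pvalue(5, 3, 10, 100), "inconsistent")
  expect_error(coannotation_pvalue(1, 10, 10, 5), "inconsistent")
})

test_that("pair filter applies structural disjointness then the overlap test", {
  obo <- c("[Term]", "id: T:R", "namespace: bp", "",
           "[Term]", "id: T:A", "namespace: bp", "is_a: T:R", "",
           "[Term]", "id: T:B", "namespace: bp", "is_a: T:R", "",
           "[Term]", "id: T:C", "namespace: bp", "is_a: T:R", "",
           "[Term]", "id: T:AB", "namespace: bp", "is_a: T:A",
           "is_a: T:B", "")
  g <- load_obo(obo)
  # A and B share descendant AB; A and C are disjoint with overlap 5 of
  # 10/10 in universe 100; B and C are disjoint with overlap 0
  rec <- data.frame(
    gene = c(sprintf("s%02d", 1:5), sprintf("s%02d", 1:5),   # shared A&C
             sprintf("a%02d", 1:5), sprintf("c%02d", 1:5),
             sprintf("b%02d", 1:10), sprintf("x%02d", 1:75)),
    term = c(rep("T:A", 5), rep("T:C", 5), rep("T:A", 5), rep("T:C", 5),
             rep("T:B", 10), rep("T:R", 75)),
    evidence = "EXP", qualifiers = "", aspect = NA,
    stringsAsFactors = FALSE)
  idx <- build_index(rec, g)
  expect_equal(length(idx$universe), 100L)
  pairs <- filter_pairs(c("T:A", "T:B", "T:C"), g, idx, "T:R", alpha = 0.1)
  key <- paste(pairs$term1, pairs$term2)
  expect_false("T:A T:B" %in% key)   # common descendant
  expect_false("T:A T:C" %in% key)   # co-annotation enriched (p < 0.1)
  expect_true("T:B T:C" %in% key)    # disjoint, overlap 0, p = 1
  expect_equal(pairs$p[key == "T:B T:C"], 1)
})

test_that("caller assembles calls, background and evidence correctly", {
  fx <- leaf_fixture(c("T:L1" = 12, "T:L2" = 12, "T:L3" = 12))
  # add one gene annotated to both L1 and L2
  rec <- rbind(fx$records,
               data.frame(gene = "mf1", term = c("T:L1", "T:L2"),
                          evidence = "EXP", qualifiers = "", aspect = NA))
  g <- fx$graph
  idx <- build_index(rec, g)
  fit <- detect_multifunctional(idx, g, M = 10)
  expect_equal(fit$multifunctional, "mf1")
  expect_true(all(c("g0001", "mf1") %in% fit$background))
  expect_false("g0001" %in% fit$multifunctional)  # single selected term
  expect_equal(fit$other, setdiff(fit$background, "mf1"))
  expect_equal(nrow(fit$evidence), 1L)
  expect_equal(fit$evidence$overlap, 1L)
})

test_that("caller errors informatively when no level selects a term", {
  fx <- leaf_fixture(c("T:L1" = 3, "T:L2" = 4))
  expect_error(detect_multifunctional(fx$index, fx$graph, M = 120),
               "no specificity level")
})

test_that("every evidence pair re-passes all three filters independently", {
  fx <- rand_fixture(101)
  idx <- build_index(fx$records, fx$graph)
  fit <- detect_multifunctional(idx, fx$graph, M = 60)
  R <- oracle_reachability(fx$graph$ids, fx$graph$parents)
  G <- length(idx$universe)
  for (r in seq_len(nrow(fit$evidence))) {
    t1 <- fit$evidence$term1[r]; t2 <- fit$evidence$term2[r]
    expect_false(R[t1, t2] || R[t2, t1])
    expect_length(setdiff(intersect(fx$graph$ids[R[t1, ]],
                                    fx$graph$ids[R[t2, ]]), fx$root), 0L)
    expect_length(intersect(fx$graph$ids[R[, t1]],
                            fx$graph$ids[R[, t2]]), 0L)
    g1 <- term_genes(idx, t1); g2 <- term_genes(idx, t2)
    expect_gte(oracle_hyper_tail(length(intersect(g1, g2)),
                                 length(g1), length(g2), G), 0.1)
    expect_true(fit$evidence$gene[r] %in% intersect(g1, g2))
  }
})

test_that("calls grow with M and shrink with alpha; background ignores alpha", {
  fx <- rand_fixture(77)
  idx <- build_index(fx$records, fx$graph)
  f30 <- detect_multifunctional(idx, fx$graph, M = 30)
  f60 <- detect_multifunctional(idx, fx$graph, M = 60)
  expect_true(all(f30$multifunctional %in% f60$multifunctional))
  expect_true(all(f30$background %in% f60$background))
  f_lo <- detect_multifunctional(idx, fx$graph, M = 60, alpha = 0.02)
  f_hi <- detect_multifunctional(idx, fx$graph, M = 60, alpha = 0.3)
  expect_true(all(f_hi$multifunctional %in% f_lo$multifunctional))
  expect_identical(f_lo$background, f_hi$background)
})

test_that("detection output files are written and byte-stable across reruns", {
  g <- gen_ontology(n_branches = 6, depth = 1, fanout = 1, seed = 3)
  sim <- gen_annotations(g, n_genes = 90, planted_mf = 5,
                         coannotation_enrichment = 0, seed = 3)
  idx <- build_index(sim$records, g)
  fit <- detect_multifunctional(idx, g, M = 20)
  d <- withr::local_tempdir()
  f1 <- write_detection(fit, file.path(d, "run1"), idx)
  f2 <- write_detection(fit, file.path(d, "run2"), idx)
  expect_true(all(file.exists(f1)))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  genes <- read.delim(f1[1L])
  expect_setequal(genes$gene[genes$is_multifunctional == 1],
                  fit$multifunctional)
})
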