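test_that("annotation propagation follows the true-path rule", {
  dag <- readObo(writeToyObo())
  tab <- geneAnnotationTable(list(G1 = "T:C", G2 = "T:D", G3 = "T:A"))
  prop <- propagateAnnotations(dag, tab)
  expect_setequal(annotations(prop)$G1, c("T:C", "T:A", "T:0"))
  expect_setequal(annotations(prop)$G2, c("T:D", "T:B", "T:0"))   # part_of
  ## the root collects every annotated gene
  byTerm <- split(rep(names(annotations(prop)), lengths(annotations(prop))),
    unlist(annotations(prop)))
  expect_true(all(vapply(byTerm, function(g) all(g %in% byTerm[["T:0"]]),
    logical(1))))
  ## idempotent
  expect_equal(annotations(propagateAnnotations(dag, prop)),
    annotations(prop))
})

test_that("the hypergeometric upper tail matches exact combinatorics", {
  expect_equal(hypergeomUpperTail(10, 4, 5, 3), 66 / 252, tolerance = 1e-14)
  expect_equal(hypergeomUpperTail(5, 5, 2, 2), 1)
  expect_equal(hypergeomUpperTail(20, 7, 6, 0), 1)
  expect_error(hypergeomUpperTail(10, 4, 5, 5), "min")
  expect_error(hypergeomUpperTail(10, 12, 5, 3), "exceed")
  CD <- chooseTableExact(25)
  set.seed(9)
  for (i in 1:50) {
    N <- sample(2:25, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- 0:min(K, n)
    expect_equal(hypergeomUpperTail(N, K, n, ks),
      oracleHyperTails(N, K, n, CD), tolerance = 1e-13)
  }
})

test_that("enrichment recovers a strongly planted term as the top hit", {
  ## 40 of 60 study genes annotated to T; background terms at ~10%
  set.seed(2024)
  study <- sprintf("S%03d", 1:60)
  filler <- sprintf("F%03d", 1:540)
  genes <- c(study, filler)
  annot <- list()
  annot[["T:planted"]] <- c(study[1:40], filler[1:54])
  for (t in sprintf("T:bg%02d", 1:15))
    annot[[t]] <- sample(genes, 60)
  tab <- termAnnotationTable(annot, reference = genes)
  res <- enrichGO(study, tab, mode = "top10")
  expect_equal(res$termId[1], "T:planted")
  expect_equal(res$studyCount[1], 40L)
  expect_equal(res$refCount[1], 94L)
  ## oracle comparison: its raw p must be the smallest of all tested terms
  pOracle <- vapply(names(annot), function(t) {
    k <- length(intersect(annot[[t]], study))
    hypergeomUpperTail(length(genes), length(annot[[t]]), length(study), k)
  }, numeric(1))
  expect_equal(res$pRaw[1], unname(min(pOracle)))
  ## contracts
  expect_true(all(res$pAdj >= res$pRaw - 1e-15))
  expect_true(all(res$pAdj <= 1))
  expect_equal(res$studyCount, lengths(res$contributors))
  expect_true(all(res$studyCount <= res$refCount))
})

test_that("degenerate enrichment cases behave as contracted", {
  genes <- sprintf("G%02d", 1:30)
  annot <- list(T1 = genes[1:12], T2 = genes[5:30])
  tab <- termAnnotationTable(annot, reference = genes)
  ## study == reference: sampling everything gives p_raw 1 for every term
  all30 <- enrichGO(genes, tab, mode = "top10")
  expect_true(all(all30$pRaw == 1))
  ## one tested term: Bonferroni family of 1 so p_adj == p_raw
  one <- enrichGO(genes[1:8], termAnnotationTable(list(T1 = genes[1:12]),
    reference = genes), mode = "top10")
  expect_equal(attr(one, "nTested"), 1L)
  expect_equal(one$pAdj, one$pRaw)
  ## study genes outside the universe are dropped with a warning
  expect_warning(dropped <- enrichGO(c(genes[1:8], "NOT_A_GENE"), tab,
    mode = "top10"), "dropped")
  expect_equal(attr(dropped, "nDropped"), 1L)
  expect_error(enrichGO(character(0), tab), "empty")
})

test_that("top-10 selection is deterministic under input permutation", {
  set.seed(31)
  genes <- sprintf("G%03d", 1:200)
  study <- genes[1:30]
  annot <- lapply(stats::setNames(1:25, sprintf("T:%02d", 1:25)),
    function(i) sample(genes, 40))
  tab <- termAnnotationTable(annot, reference = genes)
  r1 <- enrichGO(study, tab, mode = "top10")
  r2 <- enrichGO(rev(study), tab, mode = "top10")
  tab3 <- termAnnotationTable(annot[sample(names(annot))], reference = genes)
  r3 <- enrichGO(study, tab3, mode = "top10")
  expect_equal(r1$termId, r2$termId)
  expect_equal(r1$termId, r3$termId)
  expect_equal(r1$pAdj, r3$pAdj)
})

test_that("contributor sets union the genes behind each group", {
  res <- data.frame(termId = c("T1", "T2", "T3"), termName = "-",
    refCount = 3L, studyCount = 2L, pRaw = 0.01, pAdj = 0.03)
  res$contributors <- list(c("a", "b"), c("b", "c"), c("d"))
  grouping <- c(T1 = "grp1", T2 = "grp1", T3 = "grp2")
  P <- contributorSets(res, grouping)
  expect_equal(P$grp1, c("a", "b", "c"))
  expect_equal(P$grp2, "d")
  expect_error(contributorSets(res, grouping[-3]), "missing")
})

test_that("the intersection matrix reports row-normalized overlap percentages", {
  P <- list(A = c("p1", "p2"), B = "p2")
  M <- intersectionMatrix(P, studySize = 62)
  expect_equal(M["A", "B"], 50)
  expect_equal(M["B", "A"], 100)
  expect_equal(diag(M[names(P), names(P)]), c(A = 100, B = 100))
  expect_true(all(M >= 0 & M <= 100, na.rm = TRUE))
  ## last row: contributor share of the whole study set
  M2 <- intersectionMatrix(list(G = sprintf("p%d", 1:31)), studySize = 62)
  expect_equal(unname(M2["all_interactors", "G"]), 50)
  ## empty groups give undefined (NA) rows, not zeros
  M3 <- intersectionMatrix(list(A = c("p1"), B = character(0)), 10)
  expect_true(all(is.na(M3["B", ])))
  expect_error(intersectionMatrix(list(A = character(0)), 10), "non-empty")
})

test_that("significance-level composition applies the percentage formula per level", {
  res <- data.frame(
    termId = sprintf("T%d", 1:6), termName = "-", refCount = 5L,
    studyCount = 2L, pRaw = 1e-12,
    pAdj = c(1e-10, 2e-10, 5e-10, 9.5e-10, 1e-12, 1e-8))
  res$contributors <- list("a", "a", "a", "a", "a", "a")
  grouping <- c(T1 = "G1", T2 = "G2", T3 = "G2", T4 = "G2", T5 = "G3",
    T6 = "general terms")
  comp <- significanceComposition(res, grouping)
  lv10 <- comp[comp$level == 10, ]
  expect_equal(lv10$percentage[lv10$group == "G1"], 25)
  expect_equal(lv10$percentage[lv10$group == "G2"], 75)
  expect_equal(comp$percentage[comp$level == 12], 100)
  expect_false("general terms" %in% comp$group)
  ## per-level percentages always total 100
  for (lv in unique(comp$level))
    expect_equal(sum(comp$percentage[comp$level == lv]), 100)
})

test_that("composition levels clamp into the configured range and handle p = 0", {
  res <- data.frame(termId = c("T1", "T2", "T3"), termName = "-",
    refCount = 5L, studyCount = 2L, pRaw = 1e-30,
    pAdj = c(1e-30, 0, 1e-8))
  res$contributors <- list("a", "a", "a")
  grouping <- c(T1 = "G1", T2 = "G1", T3 = "G2")
  expect_message(comp <- significanceComposition(res, grouping), "zero")
  ## both G1 terms (1e-30 clamped, and exact zero) land on the top level
  expect_equal(comp$level[comp$group == "G1"], 16L)
  expect_equal(comp$nTerms[comp$group == "G1"], 2L)
  expect_equal(comp$level[comp$group == "G2"], 8L)
})

test_that("per-level percentages sum to 100 on random compositions", {
  set.seed(404)
  for (i in 1:20) {
    nTerms <- sample(5:40, 1)
    res <- data.frame(termId = sprintf("T%03d", seq_len(nTerms)),
      termName = "-", refCount = 5L, studyCount = 2L,
      pRaw = 10^-stats::runif(nTerms, 7.5, 18))
    res$pAdj <- pmin(1, nTerms * res$pRaw)
    res <- res[res$pAdj < 1e-7, , drop = FALSE]
    if (!nrow(res)) next
    res$contributors <- rep(list("x"), nrow(res))
    grouping <- stats::setNames(
      sample(c("G1", "G2", "G3"), nrow(res), replace = TRUE), res$termId)
    comp <- significanceComposition(res, grouping)
    ## direct re-count per level
    for (lv in unique(comp$level)) {
      at <- comp[comp$level == lv, ]
      expect_equal(sum(at$percentage), 100)
      expect_equal(sum(at$nTerms), at$levelTotal[1])
    }
  }
})

test_that("propagation keeps parent study counts at or above their children", {
  dag <- readObo(writeToyObo())
  set.seed(13)
  genes <- sprintf("G%02d", 1:40)
  annot <- lapply(stats::setNames(seq_along(ontologyTerms(dag)$id),
    ontologyTerms(dag)$id), function(i) sample(genes, 10))
  tab <- propagateAnnotations(dag, termAnnotationTable(annot, reference = genes))
  res <- enrichGO(genes[1:15], tab, mode = "top10", minGenes = 1L)
  counts <- stats::setNames(res$studyCount, res$termId)
  for (e in seq_len(nrow(ontologyEdges(dag)))) {
    child <- ontologyEdges(dag)$child[e]
    parent <- ontologyEdges(dag)$parent[e]
    if (child %in% names(counts) && parent %in% names(counts))
      expect_gte(counts[[parent]], counts[[child]])
  }
})
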