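test_that("interactor summaries count annotations, publications and methods", {
  rec <- harmonizeMethods(interactionRecords(
    rawIdA = "Q00001",
    rawIdB = c("P1", "P1", "P2", "P2", "P2", "P2", "P2", "P2"),
    detectionMethod = c("pull down", "two hybrid",
      rep(c("pull down", "protein kinase assay"), 3)),
    publicationId = c("1", "1", "1", "1", "2", "2", "3", "3"),
    throughput = c("high", rep("unknown", 7))))
  s <- summarizeInteractors(rec, "Q00001")
  p1 <- s[s$protein == "P1", ]
  expect_equal(p1$nAnnotations, 2L)
  expect_equal(p1$nPublications, 1L)
  expect_equal(p1$nMethods, 2L)
  expect_true(p1$htp)
  ## SNCA-like partner: 6 annotations over 2 methods and 3 publications
  p2 <- s[s$protein == "P2", ]
  expect_equal(c(p2$nAnnotations, p2$nPublications, p2$nMethods), c(6L, 3L, 2L))
  expect_false(p2$htp)
  ## conservation: summaries partition the annotations
  expect_equal(sum(s$nAnnotations), nrow(rec))
})

test_that("occurrence tiers follow the four ranking definitions", {
  expect_equal(classifyOccurrence(1, 1, 1), "low")
  expect_equal(classifyOccurrence(2, 1, 2), "medium_low")
  expect_equal(classifyOccurrence(3, 3, 1), "medium_high")
  expect_equal(classifyOccurrence(2, 2, 2), "high")
  expect_error(classifyOccurrence(0, 1, 1), "positive")
  expect_error(classifyOccurrence(1, 2, 1), "bound")
})

test_that("tier classification matches a hand-enumerated truth table and is total", {
  ## independently transcribed ranking rules over the full small grid
  oracleTier <- function(a, p, m) {
    if (a == 1) return("low")                      # reported just once
    if (p >= 2 && m >= 2) return("high")           # >1 pub, >1 method
    if (p >= 2 && m == 1) return("medium_high")    # >1 pub, 1 method
    "medium_low"                                   # 1 pub, replicated
  }
  grid <- expand.grid(a = 1:5, p = 1:5, m = 1:5)
  grid <- grid[grid$p <= grid$a & grid$m <= grid$a, ]
  got <- classifyOccurrence(grid$a, grid$p, grid$m)
  expect_equal(got, mapply(oracleTier, grid$a, grid$p, grid$m))
  expect_true(all(got %in% c("low", "medium_low", "medium_high", "high")))
})

test_that("new independent evidence never demotes a tier", {
  rank <- c(low = 1, medium_low = 2, medium_high = 2, high = 3)
  set.seed(77)
  for (i in 1:200) {
    a <- sample(1:6, 1)
    p <- sample(seq_len(a), 1)
    m <- sample(seq_len(a), 1)
    before <- classifyOccurrence(a, p, m)
    after <- classifyOccurrence(a + 1L, p + 1L, m + 1L)  # new pub, new method
    expect_gte(rank[[after]], rank[[before]])
    expect_false(after == "low")
  }
})

test_that("the filtered interactome is the complement of the low tier", {
  s <- data.frame(protein = sprintf("P%d", 1:5),
    nAnnotations = c(1L, 1L, 1L, 3L, 2L),
    nPublications = c(1L, 1L, 1L, 2L, 2L),
    nMethods = c(1L, 1L, 1L, 2L, 1L))
  s$tier <- classifyOccurrence(s$nAnnotations, s$nPublications, s$nMethods)
  f <- filteredInteractome(s)
  expect_equal(f, c("P4", "P5"))
  expect_equal(length(f) + sum(s$tier == "low"), nrow(s))
  expect_equal(filteredInteractome(s[s$tier == "low", ]), character(0))
})

test_that("family independence reflects the research groups behind the publications", {
  rec <- harmonizeMethods(interactionRecords(
    rawIdA = "Q00001",
    rawIdB = c("P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4"),
    detectionMethod = c("pull down", "two hybrid"),
    publicationId = c("1", "1", "2", "2", "3", "3", "4", "4")))
  s <- summarizeInteractors(rec, "Q00001")
  familyMap <- c(P1 = "famA", P2 = "famA", P3 = "famB", P4 = "famB")
  groups <- c("1" = "G1", "2" = "G2", "3" = "G3", "4" = "G3")
  fam <- groupFamilies(s, rec, "Q00001", familyMap, groups)
  expect_true(fam$independent[fam$family == "famA"])    # groups G1, G2
  expect_false(fam$independent[fam$family == "famB"])   # same group G3
  expect_error(groupFamilies(s, rec, "Q00001", familyMap, groups[-2]),
    "missing")
  ## empty family map: no groups, everything reported unassigned
  expect_message(empty <- groupFamilies(s, rec, "Q00001",
    character(0), groups), "no family")
  expect_equal(nrow(empty), 0L)
  expect_setequal(attr(empty, "unassigned"), s$protein)
})

test_that("the undefined one-publication one-method corner case is flagged medium_low", {
  rec <- harmonizeMethods(interactionRecords(
    rawIdA = "Q00001", rawIdB = "P1",
    detectionMethod = "pull down",
    hostOrganism = c("9606", "10090"),
    publicationId = "1"))
  s <- summarizeInteractors(rec, "Q00001")
  expect_equal(s$tier, "medium_low")
  expect_true(s$flagged)
})
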