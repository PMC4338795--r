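test_that("spoke-expansion removal keeps exactly the non-expanded records", {
  rec <- randomRecordSet(10)
  rec$expansion[c(2, 5, 9)] <- "spoke expansion"
  out <- removeSpokeExpanded(rec)
  expect_equal(nrow(out), 7L)
  expect_true(all(out$expansion == ""))
  expect_identical(removeSpokeExpanded(out), out)       # idempotent
  allExp <- rec
  allExp$expansion <- "spoke expansion"
  expect_equal(nrow(removeSpokeExpanded(allExp)), 0L)
})

test_that("the taxon filter keeps human-human pairs only", {
  rec <- interactionRecords(rawIdA = "Q00001",
    rawIdB = c("P1", "P2", "CHEBI:1"),
    taxidA = "9606", taxidB = c("9606", "10090", "chemical"),
    publicationId = "1")
  out <- filterTaxid(rec)
  expect_equal(out$rawIdB, "P1")
  expect_identical(filterTaxid(out), out)
})

test_that("within-publication dedup collapses bait/prey swaps but not host differences", {
  swap <- interactionRecords(
    rawIdA = c("Q00001", "P00001"), rawIdB = c("P00001", "Q00001"),
    detectionMethod = "pull down", hostOrganism = "9606",
    publicationId = "24000001")
  expect_equal(nrow(dedupWithinPublication(swap)), 1L)
  expect_equal(dedupWithinPublication(swap)$rawIdA, "Q00001")  # first kept

  hosts <- interactionRecords(
    rawIdA = "Q00001", rawIdB = "P00001",
    detectionMethod = "pull down",
    hostOrganism = c("9606", "10090"),
    publicationId = "24000001")
  expect_equal(nrow(dedupWithinPublication(hosts)), 2L)
})

test_that("a fixture with two planted duplicate pairs drops to five records", {
  rec <- interactionRecords(
    rawIdA = "Q00001",
    rawIdB = c("P1", "P2", "P3", "P1", "P4", "P2", "P5"),
    detectionMethod = c("m1", "m1", "m2", "m1", "m1", "m1", "m2"),
    hostOrganism = "9606",
    publicationId = c("1", "1", "1", "1", "2", "1", "2"))
  ## duplicates: rows 1/4 and rows 2/6
  expect_equal(oracleDedupClasses(rec), 5L)
  expect_equal(nrow(dedupWithinPublication(rec)), 5L)
})

test_that("dedup size equals the pairwise-oracle class count on random fixtures", {
  set.seed(101)
  for (i in 1:40) {
    rec <- randomRecordSet(sample(5:60, 1))
    out <- dedupWithinPublication(rec)
    expect_equal(nrow(out), oracleDedupClasses(rec))
    expect_identical(dedupWithinPublication(out), out)
  }
})

test_that("filter order spoke/taxon is immaterial to the surviving set", {
  set.seed(55)
  for (i in 1:10) {
    rec <- randomRecordSet(30)
    rec$expansion[sample(30, 6)] <- "spoke expansion"
    rec$taxidB[sample(30, 8)] <- "10090"
    a <- filterTaxid(removeSpokeExpanded(rec))
    b <- removeSpokeExpanded(filterTaxid(rec))
    expect_equal(a, b)
  }
})

test_that("homo/hetero split partitions the dataset and enforces the query", {
  rec <- interactionRecords(rawIdA = "Q5S007",
    rawIdB = c("Q5S007", "P46821", "Q5S007-2"),
    publicationId = "1")
  parts <- splitHomoHetero(rec, "Q5S007")
  expect_equal(nrow(parts$homo), 2L)   # isoform of the query collapses
  expect_equal(nrow(parts$hetero), 1L)
  expect_equal(nrow(parts$homo) + nrow(parts$hetero), nrow(rec))
  stray <- interactionRecords(rawIdA = "P1", rawIdB = "P2", publicationId = "1")
  expect_error(splitHomoHetero(stray, "Q5S007"), "query")
})

test_that("curation provenance counts are non-increasing and stage-correct", {
  rec <- interactionRecords(
    rawIdA = "Q00001",
    rawIdB = c("P1", "P2", "P3", "P1", "P4", "P5"),
    taxidB = c("9606", "9606", "10090", "9606", "9606", "9606"),
    detectionMethod = "m1", hostOrganism = "9606",
    publicationId = c("1", "1", "1", "1", "2", "2"),
    expansion = c("", "", "", "", "spoke expansion", ""))
  ds <- curateDataset(rec, "Q00001")
  expect_equal(provenance(ds)$count, c(6L, 5L, 4L, 3L))
  expect_s4_class(ds, "CuratedDataset")
})

test_that("merge keeps single-source publications verbatim and picks the larger shared record", {
  mk <- function(partners, pubs, methods, source, host) {
    interactionRecords(rawIdA = "Q00001", rawIdB = partners,
      detectionMethod = methods, publicationId = pubs,
      hostOrganism = host, sourceDb = source)
  }
  dsA <- curateDataset(mk(c("P1", "P2", "P3", "P4", "P1", "P2", "P3", "P4", "P5"),
    c("10", "10", "10", "10", "20", "20", "20", "20", "20"),
    "pull down", "intact", "9606"), "Q00001")
  dsB <- curateDataset(mk(c("P1", "P2", "P3"),
    c("20", "20", "20"),
    "Affinity Capture-Western", "biogrid", "unspecified"), "Q00001")
  merged <- mergeDatasets(dsA, dsB)
  rec <- records(merged)
  ## pub 10 only in A: verbatim; pub 20: 5 vs 3, A wholesale
  expect_equal(sum(rec$publicationId == "10"), 4L)
  expect_equal(sum(rec$publicationId == "20"), 5L)
  expect_true(all(rec$sourceDb == "intact"))
  choices <- merged@log$mergeChoices
  expect_equal(choices$source[choices$publication == "20"], "A")
  ## publication set is the union of the inputs
  expect_setequal(unique(rec$publicationId),
    union(records(dsA)$publicationId, records(dsB)$publicationId))
})

test_that("equal-count shared publications merge through harmonized dedup", {
  dsA <- curateDataset(interactionRecords(rawIdA = "Q00001", rawIdB = "P1",
    detectionMethod = "protein kinase assay", publicationId = "30",
    hostOrganism = "9606", sourceDb = "intact"), "Q00001")
  dsB <- curateDataset(interactionRecords(rawIdA = "Q00001", rawIdB = "P1",
    detectionMethod = "Biochemical Activity", publicationId = "30",
    hostOrganism = "unspecified", sourceDb = "biogrid"), "Q00001")
  merged <- mergeDatasets(dsA, dsB)
  expect_equal(nrow(records(merged)), 1L)
  expect_equal(records(merged)$detectionMethod, "protein kinase assay")
  expect_equal(merged@log$mergeChoices$source, "union")
  ## symmetric up to provenance when counts differ
  expect_error(mergeDatasets(dsA,
    curateDataset(interactionRecords(rawIdA = "Q9Y2K2", rawIdB = "Q9Y2K2",
      publicationId = "1"), "Q9Y2K2")), "different query")
})

test_that("merge is symmetric up to provenance labels when counts differ", {
  mk <- function(n, pub, source, host) {
    interactionRecords(rawIdA = "Q00001", rawIdB = sprintf("P%d", seq_len(n)),
      detectionMethod = "pull down", publicationId = pub,
      hostOrganism = host, sourceDb = source)
  }
  dsA <- curateDataset(mk(4, "40", "intact", "9606"), "Q00001")
  dsB <- curateDataset(mk(2, "40", "biogrid", "unspecified"), "Q00001")
  ab <- records(mergeDatasets(dsA, dsB))
  ba <- records(mergeDatasets(dsB, dsA))
  expect_equal(ab[order(ab$rawIdB), ], ba[order(ba$rawIdB), ],
    ignore_attr = TRUE)
})
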