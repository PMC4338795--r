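## Small in-code file fixtures for the format readers.

writeMitabFixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

mitabLine <- function(idA = "uniprotkb:Q00001", idB = "uniprotkb:P00001",
    method = 'psi-mi:"MI:0006"(anti bait coimmunoprecipitation)',
    author = "smith et al. (2014)", pub = "24000001",
    taxA = "taxid:9606(human)", taxB = "taxid:9606(human)",
    expansion = "-", host = "taxid:9606(homo sapiens)", features = "-") {
  f <- rep("-", 36)
  f[1] <- idA; f[2] <- idB; f[7] <- method; f[8] <- author
  f[9] <- paste0("pubmed:", pub); f[10] <- taxA; f[11] <- taxB
  f[13] <- 'psi-mi:"MI:0469"(IntAct)'; f[16] <- expansion
  f[29] <- host; f[33] <- features
  paste(f, collapse = "\t")
}

biogridLine <- function(rowid = 1, idA = "Q00001", idB = "P00001",
    method = "Affinity Capture-Western", author = "smith (2014)",
    pub = "24000001", taxA = "9606", taxB = "9606",
    throughput = "Low Throughput") {
  f <- rep("-", 24)
  f[1] <- as.character(rowid); f[8] <- idA; f[9] <- idB; f[12] <- method
  f[14] <- author; f[15] <- pub; f[16] <- taxA; f[17] <- taxB
  f[18] <- throughput; f[24] <- "BIOGRID"
  paste(f, collapse = "\t")
}

## five-term toy ontology: root with children A, B; C below A; D part_of B
writeToyObo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:0", "name: root", "namespace: biological_process", "",
    "[Term]", "id: T:A", "name: branch a", "namespace: biological_process",
    "is_a: T:0 ! root", "",
    "[Term]", "id: T:B", "name: branch b", "namespace: biological_process",
    "is_a: T:0 ! root", "",
    "[Term]", "id: T:C", "name: leaf c", "namespace: biological_process",
    "is_a: T:A ! branch a", "",
    "[Term]", "id: T:D", "name: leaf d", "namespace: biological_process",
    "relationship: part_of T:B"
  ), path)
  path
}

gafLine <- function(gene, term) {
  paste("SYNDB", gene, gene, "", term, "REF:1", "IEA", "", "P", gene, "",
    "protein", "taxon:9606", "20140801", "SYNDB", "", "", sep = "\t")
}

## annotation tables built directly (already propagated unless stated):
## geneAnnotationTable takes gene -> terms, termAnnotationTable takes the
## inverse orientation term -> genes
geneAnnotationTable <- function(geneTerms, reference = NULL) {
  new("AnnotationTable", annotations = geneTerms,
    referenceGenes = sort(unique(c(names(geneTerms), reference))))
}

termAnnotationTable <- function(termGenes, reference = NULL) {
  gene <- unlist(termGenes, use.names = FALSE)
  term <- rep(names(termGenes), lengths(termGenes))
  ann <- lapply(split(term, gene), function(x) sort(unique(x)))
  new("AnnotationTable", annotations = ann,
    referenceGenes = sort(unique(c(names(ann), reference))))
}

smallBatterySpec <- function(seed, ...) {
  fixtureSpec(seed = seed,
    tierComposition = c(low = 18L, medium_low = 4L, medium_high = 3L,
      high = 5L),
    nPubsIntactOnly = 5L, nPubsShared = 6L, nPubsBiogridOnly = 5L,
    nConflictPubs = 2L,
    extraHighAnnotationsMax = 2L,
    junkIntact = c(spoke = 6L, nonhuman = 4L, chemical = 2L, duplicate = 5L),
    junkBiogrid = c(spoke = 0L, nonhuman = 3L, chemical = 0L, duplicate = 3L),
    nIsoformIds = 2L,
    selfPubsIntactOnly = 3L, selfPubsShared = 2L, selfPubsBiogridOnly = 3L,
    proteinLength = 500L, coreRegion = c(150L, 420L), nPointResidues = 2L,
    nReferenceGenes = 300L, nBackgroundTerms = 20L, nPlantedTerms = 2L,
    plantedStudyRate = 1.0, plantedBackgroundRate = 0.02,
    nSnps = c(PD = 6L, IBD = 9L),
    pdHitDistancesKbp = c(20, 0), ibdHitDistancesKbp = c(0, 9.7, 120),
    nDecoyGenes = 12L, nFamilies = 3L,
    ...)
}

## compare a pipeline run against the generator's planted truth; returns a
## character vector of mismatches (empty when everything is reproduced)
truthMismatches <- function(result, truth) {
  bad <- character(0)
  chk <- function(cond, what) if (!isTRUE(cond)) bad <<- c(bad, what)
  for (s in c("intact", "biogrid"))
    chk(identical(unlist(result$counts[[s]]), unlist(truth$perSource[[s]])),
      paste(s, "stage counts"))
  m <- result$counts$merged
  tm <- truth$merged
  chk(m$heteroAnnotations == tm$heteroAnnotations, "merged hetero count")
  chk(m$homoAnnotations == tm$homoAnnotations, "merged homo count")
  chk(m$interactomeSize == tm$interactomeSize, "interactome size")
  chk(m$filteredSize == tm$filteredSize, "filtered size")
  chk(identical(unlist(m$tierHistogram), unlist(tm$tierHistogram)),
    "tier histogram")
  chk(identical(m$tiers[order(names(m$tiers))],
    tm$tiers[order(names(tm$tiers))]), "tier map")
  chk(identical(m$filteredInteractome, tm$filteredInteractome),
    "filtered membership")
  chk(identical(sort(result$enrichment$termId), truth$enrichedTerms),
    "enriched terms")
  pr <- truth$profileProbes
  chk(identical(coverage(result$profile)[pr$residue], pr$coverage),
    "profile probe coverage")
  g <- result$gwasHits
  tg <- truth$gwasHits
  chk(identical(g$protein, tg$protein) && identical(g$rsid, tg$rsid) &&
    identical(g$trait, tg$trait) &&
    isTRUE(all.equal(g$distanceKbp, tg$distanceKbp)) &&
    identical(g$candidate, tg$candidate), "gwas hits")
  bad
}
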