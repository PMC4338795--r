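## Harmonized method categories and the per-source vocabularies the
## generator draws from (each maps back to the category under the default
## harmonization map).
.methodCategories <- c("Affinity Capture", "Biochemical Activity",
  "Co-localization", "Two-hybrid", "Protein Array")

.intactVocab <- list(
  "Affinity Capture" = c("anti bait coimmunoprecipitation",
    "anti tag coimmunoprecipitation", "pull down",
    "affinity chromatography technology"),
  "Biochemical Activity" = "protein kinase assay",
  "Co-localization" = c("confocal microscopy", "fluorescence microscopy"),
  "Two-hybrid" = "two hybrid",
  "Protein Array" = "protein array"
)

.biogridVocab <- list(
  "Affinity Capture" = c("Affinity Capture-Western", "Affinity Capture-MS"),
  "Biochemical Activity" = "Biochemical Activity",
  "Co-localization" = "Co-localization",
  "Two-hybrid" = "Two-hybrid",
  "Protein Array" = "Protein Array"
)

#' Specify a synthetic input bundle
#'
#' Collects the generator parameters: the query accession, the occurrence
#' tier composition to plant, the publication structure shared between the
#' two database exports, per-source counts of junk rows removed by each
#' filter, the self-interaction publication structure and region model, the
#' ontology/annotation model with its planted enriched terms, and the GWAS
#' layout with planted overlap distances. The defaults emulate a
#' LRRK2-scale curation snapshot: 269 partners in tiers 207/24/13/25, 63
#' heterologous publications of which 22 are shared (6 of those with
#' equal-count vocabulary conflicts that force a harmonized merge), 31
#' self-interaction publications (7 shared), a 1000-gene reference universe
#' with 3 strongly planted terms, and 21 planted GWAS hits at Table-1-like
#' distances among 187 risk SNPs.
#'
#' @param seed integer seed; the same seed yields a byte-identical bundle.
#' @param ... overrides for any default listed above (see the source for
#'   the full field list).
#' @return object of class `FixtureSpec` (a named list).
#' @export
fixtureSpec <- function(seed = 1L, ...) {
  spec <- list(
    seed = as.integer(seed),
    query = "Q00001",
    tierComposition = c(low = 207L, medium_low = 24L, medium_high = 13L,
      high = 25L),
    nPubsIntactOnly = 21L, nPubsShared = 22L, nPubsBiogridOnly = 20L,
    nConflictPubs = 6L,
    extraHighAnnotationsMax = 4L,
    junkIntact = c(spoke = 150L, nonhuman = 40L, chemical = 10L,
      duplicate = 35L),
    junkBiogrid = c(spoke = 0L, nonhuman = 20L, chemical = 0L,
      duplicate = 10L),
    nIsoformIds = 3L,
    selfPubsIntactOnly = 10L, selfPubsShared = 7L, selfPubsBiogridOnly = 14L,
    proteinLength = 2527L,
    coreRegion = c(1300L, 2100L),
    nPointResidues = 5L,
    nReferenceGenes = 1000L,
    nBackgroundTerms = 40L,
    backgroundRate = 0.10,
    nPlantedTerms = 3L,
    plantedStudyRate = 0.95,
    plantedBackgroundRate = 0.02,
    minGenes = 2L,
    pThreshold = 1e-7,
    nSnps = c(PD = 24L, IBD = 163L),
    pdHitDistancesKbp = c(20, 14, 25, 0),
    ibdHitDistancesKbp = c(0, 23, 0, 9.7, 13, 18, 32, 73, 82, 89, 108,
      116, 163, 169, 178, 179, 189),
    nCandidatesPD = 4L, nCandidatesIBD = 4L,
    windowBp = 200000L,
    nDecoyGenes = 200L,
    nFamilies = 10L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown))
    stop("unknown fixture parameters: ", paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  structure(spec, class = "FixtureSpec")
}

.checkSpec <- function(spec, nPartners) {
  if (any(unlist(spec$tierComposition) < 0L) ||
      any(spec$junkIntact < 0L) || any(spec$junkBiogrid < 0L))
    stop("unachievable fixture: counts must be non-negative")
  if (spec$junkBiogrid[["spoke"]] > 0L)
    stop("unachievable fixture: the TAB 2.0 layout has no expansion column, ",
      "spoke rows can only be planted in the PSI-MI TAB file")
  if (spec$nReferenceGenes < nPartners)
    stop("unachievable fixture: reference universe smaller than the interactome")
  nHits <- length(spec$pdHitDistancesKbp) + length(spec$ibdHitDistancesKbp)
  if (nHits > nPartners)
    stop("unachievable fixture: more planted GWAS hits than interactors")
  if (length(spec$pdHitDistancesKbp) > spec$nSnps[["PD"]] ||
      length(spec$ibdHitDistancesKbp) > spec$nSnps[["IBD"]])
    stop("unachievable fixture: more planted hits than SNPs for a trait")
  if (any(c(spec$pdHitDistancesKbp, spec$ibdHitDistancesKbp) * 1000 >
      spec$windowBp))
    stop("unachievable fixture: a planted hit distance exceeds the window")
  if (spec$nPubsIntactOnly + spec$nPubsShared + spec$nPubsBiogridOnly < 2L &&
      nPartners > 0L)
    stop("unachievable fixture: at least two publications are required")
  invisible(TRUE)
}

## ---- delimited-line builders --------------------------------------------

.mitabRow <- function(idA, idB, method, author, pub, taxA, taxB,
    expansion = "-", host = "taxid:9606(homo sapiens)", features = "-") {
  f <- rep("-", 36L)
  f[1L] <- idA; f[2L] <- idB
  f[7L] <- sprintf('psi-mi:"MI:0000"(%s)', method)
  f[8L] <- author
  f[9L] <- paste0("pubmed:", pub)
  f[10L] <- taxA; f[11L] <- taxB
  f[13L] <- 'psi-mi:"MI:0469"(IntAct)'
  f[16L] <- expansion
  f[29L] <- host
  f[33L] <- features
  paste(f, collapse = "\t")
}

.biogridRow <- function(rowid, idA, idB, method, author, pub, taxA, taxB,
    throughput) {
  f <- rep("-", 24L)
  f[1L] <- as.character(rowid)
  f[8L] <- idA; f[9L] <- idB
  f[12L] <- method
  f[14L] <- author
  f[15L] <- pub
  f[16L] <- taxA; f[17L] <- taxB
  f[18L] <- throughput
  f[24L] <- "BIOGRID"
  paste(f, collapse = "\t")
}

.up <- function(acc) paste0("uniprotkb:", acc)
.tax <- function(id) sprintf("taxid:%s(organism)", id)
.author <- function(pub) sprintf("author_%s et al. (2014)", pub)
.regionStr <- function(m) {
  if (is.null(m) || !nrow(m)) return("-")
  paste(sprintf("binding-associated region:%d-%d", m[, 1L], m[, 2L]),
    collapse = "|")
}

## ---- the generator ------------------------------------------------------

#' Generate a synthetic input bundle with planted ground truth
#'
#' Writes a PSI-MI TAB 2.7 file, a BioGRID TAB 2.0 file, an OBO ontology, a
#' GAF annotation table, a BED gene table, a SNP table, the user-supplied
#' lookup maps, a pipeline configuration in YAML and a machine-readable
#' `truth.json` sidecar into `dir`. Identical seeds yield byte-identical
#' bundles. The returned truth records the expected value of every pipeline
#' stage: per-source filter-stage counts, the hetero/homo split, the merged
#' annotation counts, the tier of every partner, the filtered interactome,
#' the planted enriched terms, the self-interaction coverage at probe
#' residues and the planted GWAS hits.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, `list(files = <named paths>, truth = <list>)`.
#' @export
generateFixture <- function(spec = fixtureSpec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "FixtureSpec"))
  tiers <- spec$tierComposition
  nPartners <- sum(tiers)
  .checkSpec(spec, nPartners)
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  query <- spec$query
  partners <- sprintf("P%05d", seq_len(nPartners))
  tierOf <- if (nPartners) sample(rep(names(tiers), times = tiers)) else character(0)
  names(tierOf) <- partners

  ## hetero publication pool
  pubClass <- rep(c("I", "S", "B"), times = c(spec$nPubsIntactOnly,
    spec$nPubsShared, spec$nPubsBiogridOnly))
  hetPubs <- sprintf("2%06d", seq_along(pubClass))
  names(pubClass) <- hetPubs

  ## plant annotations per partner according to its tier
  annRows <- list()
  for (p in partners) {
    tier <- tierOf[[p]]
    used <- character(0)   # "pub\rcategory" combos taken for this partner
    add <- function(pub, cat) {
      annRows[[length(annRows) + 1L]] <<- data.frame(partner = p, pub = pub,
        category = cat, stringsAsFactors = FALSE)
      used <<- c(used, paste(pub, cat, sep = "\r"))
    }
    if (tier == "low") {
      add(sample(hetPubs, 1L), sample(.methodCategories, 1L))
    } else if (tier == "medium_low") {
      pub <- sample(hetPubs, 1L)
      cats <- sample(.methodCategories, 2L)
      add(pub, cats[1L]); add(pub, cats[2L])
    } else if (tier == "medium_high") {
      pubs <- sample(hetPubs, 2L)
      cat <- sample(.methodCategories, 1L)
      add(pubs[1L], cat); add(pubs[2L], cat)
    } else {
      pubs <- sample(hetPubs, 2L)
      cats <- sample(.methodCategories, 2L)
      add(pubs[1L], cats[1L]); add(pubs[2L], cats[2L])
      nExtra <- sample(0:spec$extraHighAnnotationsMax, 1L)
      tries <- 0L
      while (nExtra > 0L && tries < 50L) {
        tries <- tries + 1L
        pub <- sample(c(pubs, sample(hetPubs, 1L)), 1L)
        cat <- sample(.methodCategories, 1L)
        if (!(paste(pub, cat, sep = "\r") %in% used)) {
          add(pub, cat)
          nExtra <- nExtra - 1L
        }
      }
    }
  }
  het <- if (length(annRows)) do.call(rbind, annRows) else
    data.frame(partner = character(0), pub = character(0),
      category = character(0), stringsAsFactors = FALSE)

  ## distribute hetero annotations to the two sources
  sharedWithAnns <- hetPubs[pubClass == "S" & hetPubs %in% het$pub]
  conflictPubs <- utils::head(sharedWithAnns, spec$nConflictPubs)
  unequalPubs <- setdiff(sharedWithAnns, conflictPubs)
  dropSide <- stats::setNames(rep_len(c("B", "A"), length(unequalPubs)),
    unequalPubs)
  inIntact <- pubClass[het$pub] %in% c("I", "S")
  inBiogrid <- pubClass[het$pub] %in% c("B", "S")
  ## drop the last annotation of each unequal shared publication from one side
  for (pub in unequalPubs) {
    i <- utils::tail(which(het$pub == pub), 1L)
    if (dropSide[[pub]] == "B") inBiogrid[i] <- FALSE else inIntact[i] <- FALSE
  }
  hetIntact <- het[inIntact, , drop = FALSE]
  hetBiogrid <- het[inBiogrid, , drop = FALSE]

  ## self-interaction publications
  selfClass <- rep(c("I", "S", "B"), times = c(spec$selfPubsIntactOnly,
    spec$selfPubsShared, spec$selfPubsBiogridOnly))
  selfPubs <- sprintf("3%06d", seq_along(selfClass))
  names(selfClass) <- selfPubs
  core <- spec$coreRegion
  selfRows <- list()
  for (pub in selfPubs) {
    k <- sample(1:3, 1L)
    cats <- sample(.methodCategories, k)
    hasRegions <- selfClass[[pub]] %in% c("I", "S")
    for (j in seq_len(k)) {
      region <- NULL
      if (hasRegions && stats::runif(1) < 0.8) {
        s <- sample(core[1L]:(core[2L] - 50L), 1L)
        e <- min(s + sample(50:400, 1L), core[2L])
        region <- cbind(start = s, end = e)
      }
      selfRows[[length(selfRows) + 1L]] <- list(pub = pub,
        category = cats[j], region = region)
    }
  }
  ## point residues: extra single-residue intervals appended to the first
  ## region-bearing annotation of the first few IntAct-visible publications
  intactSelfIdx <- which(vapply(selfRows, function(r)
    selfClass[[r$pub]] %in% c("I", "S") && !is.null(r$region), logical(1L)))
  pointResidues <- if (spec$nPointResidues > 0L && length(intactSelfIdx))
    sample(core[1L]:core[2L], min(spec$nPointResidues, length(intactSelfIdx)))
  else integer(0)
  for (j in seq_along(pointResidues)) {
    i <- intactSelfIdx[j]
    selfRows[[i]]$region <- rbind(selfRows[[i]]$region,
      cbind(start = pointResidues[j], end = pointResidues[j]))
  }
  selfPubOf <- vapply(selfRows, `[[`, character(1L), "pub")
  selfIntact <- selfRows[selfClass[selfPubOf] %in% c("I", "S")]
  selfBiogrid <- selfRows[selfClass[selfPubOf] %in% c("B", "S")]

  ## probe coverage truth from the IntAct-visible planted regions
  probes <- sort(unique(c(1L, core[1L], (core[1L] + core[2L]) %/% 2L,
    core[2L], spec$proteinLength, pointResidues)))
  probeCoverage <- vapply(probes, function(r) {
    hit <- vapply(selfIntact, function(a)
      !is.null(a$region) && any(a$region[, 1L] <= r & r <= a$region[, 2L]),
      logical(1L))
    length(unique(vapply(selfIntact[hit], `[[`, character(1L), "pub")))
  }, integer(1L))

  ## ---- write the PSI-MI TAB file ----------------------------------------
  vocabFor <- function(vocab, cat) {
    v <- vocab[[cat]]
    v[sample.int(length(v), 1L)]
  }
  intactLines <- character(0)
  isoLeft <- spec$nIsoformIds
  for (i in seq_len(nrow(hetIntact))) {
    rawB <- hetIntact$partner[i]
    if (isoLeft > 0L) { rawB <- paste0(rawB, "-2"); isoLeft <- isoLeft - 1L }
    intactLines <- c(intactLines, .mitabRow(.up(query), .up(rawB),
      vocabFor(.intactVocab, hetIntact$category[i]),
      .author(hetIntact$pub[i]), hetIntact$pub[i],
      .tax("9606"), .tax("9606")))
  }
  for (a in selfIntact) {
    intactLines <- c(intactLines, .mitabRow(.up(query), .up(query),
      vocabFor(.intactVocab, a$category), .author(a$pub), a$pub,
      .tax("9606"), .tax("9606"), features = .regionStr(a$region)))
  }
  nCleanIntact <- length(intactLines)
  jI <- spec$junkIntact
  for (i in seq_len(jI[["spoke"]])) {
    intactLines <- c(intactLines, .mitabRow(.up(query),
      .up(sprintf("X%04d", i)), vocabFor(.intactVocab, sample(.methodCategories, 1L)),
      .author(sample(hetPubs, 1L)), sample(hetPubs, 1L),
      .tax("9606"), .tax("9606"),
      expansion = 'psi-mi:"MI:1060"(spoke expansion)'))
  }
  for (i in seq_len(jI[["nonhuman"]])) {
    intactLines <- c(intactLines, .mitabRow(.up(query),
      .up(sprintf("Y%04d", i)), vocabFor(.intactVocab, sample(.methodCategories, 1L)),
      .author(sample(hetPubs, 1L)), sample(hetPubs, 1L),
      .tax("9606"), .tax("10090")))
  }
  for (i in seq_len(jI[["chemical"]])) {
    intactLines <- c(intactLines, .mitabRow(.up(query),
      sprintf("chebi:CHEBI:%05d", i), vocabFor(.intactVocab, sample(.methodCategories, 1L)),
      .author(sample(hetPubs, 1L)), sample(hetPubs, 1L),
      .tax("9606"), "-"))
  }
  if (jI[["duplicate"]] > 0L) {
    if (!nCleanIntact) stop("unachievable fixture: duplicates need clean rows")
    originals <- sample(seq_len(nCleanIntact), jI[["duplicate"]], replace = TRUE)
    for (i in originals) {
      f <- strsplit(intactLines[i], "\t", fixed = TRUE)[[1L]]
      tmp <- f[1L]; f[1L] <- f[2L]; f[2L] <- tmp   # bait/prey swap
      tmp <- f[10L]; f[10L] <- f[11L]; f[11L] <- tmp
      intactLines <- c(intactLines, paste(f, collapse = "\t"))
    }
  }

  ## ---- write the BioGRID TAB file ---------------------------------------
  biogridLines <- character(0)
  rowid <- 0L
  bgRow <- function(idA, idB, cat, pub, taxA = "9606", taxB = "9606") {
    rowid <<- rowid + 1L
    .biogridRow(rowid, idA, idB, vocabFor(.biogridVocab, cat),
      .author(pub), pub, taxA, taxB,
      if (stats::runif(1) < 0.3) "High Throughput" else "Low Throughput")
  }
  for (i in seq_len(nrow(hetBiogrid)))
    biogridLines <- c(biogridLines, bgRow(query, hetBiogrid$partner[i],
      hetBiogrid$category[i], hetBiogrid$pub[i]))
  for (a in selfBiogrid)
    biogridLines <- c(biogridLines, bgRow(query, query, a$category, a$pub))
  nCleanBiogrid <- length(biogridLines)
  jB <- spec$junkBiogrid
  for (i in seq_len(jB[["nonhuman"]]))
    biogridLines <- c(biogridLines, bgRow(query, sprintf("Y%04d", i),
      sample(.methodCategories, 1L), sample(hetPubs, 1L), taxB = "10090"))
  for (i in seq_len(jB[["chemical"]])) {
    rowid <- rowid + 1L
    biogridLines <- c(biogridLines, .biogridRow(rowid, query,
      sprintf("chebi:CHEBI:%05d", i), "Biochemical Activity",
      .author(hetPubs[1L]), hetPubs[1L], "9606", "-", "Low Throughput"))
  }
  if (jB[["duplicate"]] > 0L) {
    if (!nCleanBiogrid) stop("unachievable fixture: duplicates need clean rows")
    originals <- sample(seq_len(nCleanBiogrid), jB[["duplicate"]], replace = TRUE)
    for (i in originals) {
      f <- strsplit(biogridLines[i], "\t", fixed = TRUE)[[1L]]
      tmp <- f[8L]; f[8L] <- f[9L]; f[9L] <- tmp
      tmp <- f[16L]; f[16L] <- f[17L]; f[17L] <- tmp
      rowid <- rowid + 1L
      f[1L] <- as.character(rowid)
      biogridLines <- c(biogridLines, paste(f, collapse = "\t"))
    }
  }

  ## ---- ontology, annotations, grouping ----------------------------------
  filteredAccs <- sort(partners[tierOf != "low"])
  study <- filteredAccs
  fillers <- sprintf("F%05d", seq_len(spec$nReferenceGenes - nPartners))
  genes <- c(partners, fillers)
  root <- "SYN:0000000"
  bgTerms <- sprintf("SYN:1%06d", seq_len(spec$nBackgroundTerms))
  plTerms <- sprintf("SYN:2%06d", seq_len(spec$nPlantedTerms))
  annot <- list()
  annot[[root]] <- genes
  for (t in bgTerms)
    annot[[t]] <- genes[stats::runif(length(genes)) < spec$backgroundRate]
  nonStudy <- setdiff(genes, study)
  for (t in plTerms) {
    inStudy <- sample(study, ceiling(spec$plantedStudyRate * length(study)))
    bgPart <- nonStudy[stats::runif(length(nonStudy)) < spec$plantedBackgroundRate]
    annot[[t]] <- c(inStudy, bgPart)
  }
  if (length(study) && spec$nPlantedTerms > 0L) {
    ## achievability: planted terms must clear the threshold after
    ## Bonferroni, background terms must stay clearly above it
    N <- length(genes); n <- length(study)
    kOf <- vapply(annot, function(g) length(intersect(g, study)), integer(1L))
    KOf <- lengths(annot)
    tested <- kOf >= spec$minGenes
    m <- sum(tested)
    pAdj <- stats::setNames(
      pmin(1, m * stats::phyper(kOf - 1L, KOf, N - KOf, n,
        lower.tail = FALSE)), names(kOf))
    if (any(pAdj[plTerms] >= spec$pThreshold / 10))
      stop("unachievable fixture: a planted term does not clear the ",
        "enrichment threshold at the generated sizes")
    others <- setdiff(names(annot), plTerms)
    if (any(pAdj[others] < spec$pThreshold * 10))
      stop("unachievable fixture: a background term falls below the ",
        "enrichment threshold")
  }
  oboLines <- c("format-version: 1.2", "",
    "[Term]", paste0("id: ", root), "name: biological process root",
    "namespace: biological_process")
  for (t in c(bgTerms, plTerms)) {
    rel <- if (match(t, c(bgTerms, plTerms)) %% 5L == 0L)
      paste0("relationship: part_of ", root) else
      paste0("is_a: ", root, " ! root")
    oboLines <- c(oboLines, "", "[Term]", paste0("id: ", t),
      paste0("name: synthetic term ", t),
      "namespace: biological_process", rel)
  }
  gafGene <- unlist(annot, use.names = FALSE)
  gafTerm <- rep(names(annot), lengths(annot))
  gafLines <- c("!gaf-version: 2.1",
    paste("SYNDB", gafGene, gafGene, "", gafTerm, "SYN_REF:0000001",
      "IEA", "", "P", gafGene, "", "protein", "taxon:9606", "20140801",
      "SYNDB", "", "", sep = "\t"))
  plantedGroups <- c("transport/localization", "cell organization",
    "signalling")
  grouping <- data.frame(
    term = c(root, bgTerms, plTerms),
    group = c("general terms", rep("general terms", length(bgTerms)),
      rep_len(plantedGroups, length(plTerms))),
    stringsAsFactors = FALSE)

  ## ---- GWAS layout -------------------------------------------------------
  symbols <- stats::setNames(sprintf("GENE%04d", seq_len(nPartners)), partners)
  nPD <- length(spec$pdHitDistancesKbp)
  nIBD <- length(spec$ibdHitDistancesKbp)
  lowAccs <- sort(partners[tierOf == "low"])
  pdHitAccs <- utils::head(c(filteredAccs, lowAccs), nPD)
  remaining <- setdiff(c(utils::head(setdiff(filteredAccs, pdHitAccs), 1L),
    setdiff(c(lowAccs, filteredAccs), pdHitAccs)), pdHitAccs)
  ibdHitAccs <- utils::head(remaining, nIBD)
  hits <- data.frame(
    protein = c(pdHitAccs, ibdHitAccs),
    trait = c(rep("PD", nPD), rep("IBD", nIBD)),
    distanceKbp = c(spec$pdHitDistancesKbp, spec$ibdHitDistancesKbp),
    stringsAsFactors = FALSE)
  geneWidth <- 50000L
  bedRows <- character(0)
  snpRows <- character(0)
  hitRows <- list()
  for (i in seq_len(nrow(hits))) {
    chrom <- paste0("chr", i)
    s <- 1000000L; e <- s + geneWidth - 1L
    d <- hits$distanceKbp[i]
    pos <- if (d == 0) s + geneWidth %/% 2L else e + as.integer(round(d * 1000))
    rsid <- sprintf("rs%06d", i)
    sym <- symbols[[hits$protein[i]]]
    bedRows <- c(bedRows, paste(chrom, s - 1L, e, sym, 0L, "+", sep = "\t"))
    snpRows <- c(snpRows, paste(rsid, chrom, pos, hits$trait[i], sep = "\t"))
    hitRows[[i]] <- data.frame(protein = hits$protein[i], geneSymbol = sym,
      trait = hits$trait[i], rsid = rsid, distanceKbp = d,
      stringsAsFactors = FALSE)
  }
  ## remaining interactome genes, far from every SNP
  otherAccs <- setdiff(partners, hits$protein)
  for (j in seq_along(otherAccs)) {
    chrom <- paste0("chrZ", (j - 1L) %/% 10L + 1L)
    s <- 1000000L + ((j - 1L) %% 10L) * 2000000L
    bedRows <- c(bedRows, paste(chrom, s - 1L, s + geneWidth - 1L,
      symbols[[otherAccs[j]]], 0L, "+", sep = "\t"))
  }
  ## SNPs without interactome genes nearby, with decoy genes around some
  extraPD <- spec$nSnps[["PD"]] - nPD
  extraIBD <- spec$nSnps[["IBD"]] - nIBD
  extraTraits <- c(rep("PD", extraPD), rep("IBD", extraIBD))
  for (j in seq_along(extraTraits)) {
    chrom <- paste0("chrE", j)
    pos <- 1000000L
    snpRows <- c(snpRows, paste(sprintf("rs9%05d", j), chrom, pos,
      extraTraits[j], sep = "\t"))
    if (j <= spec$nDecoyGenes)
      bedRows <- c(bedRows, paste(chrom, pos + 49999L, pos + 49999L + geneWidth,
        sprintf("DEC%04d", j), 0L, "+", sep = "\t"))
  }
  for (j in seq_len(max(0L, spec$nDecoyGenes - length(extraTraits)))) {
    chrom <- paste0("chrD", (j - 1L) %/% 10L + 1L)
    s <- 1000000L + ((j - 1L) %% 10L) * 2000000L
    bedRows <- c(bedRows, paste(chrom, s - 1L, s + geneWidth - 1L,
      sprintf("DED%04d", j), 0L, "+", sep = "\t"))
  }
  gwasTruth <- if (length(hitRows)) do.call(rbind, hitRows) else
    data.frame(protein = character(0), geneSymbol = character(0),
      trait = character(0), rsid = character(0), distanceKbp = numeric(0),
      stringsAsFactors = FALSE)
  gwasTruth$candidate <- logical(nrow(gwasTruth))
  gwasTruth$candidate[gwasTruth$trait == "PD"][
    seq_len(min(spec$nCandidatesPD, nPD))] <- TRUE
  gwasTruth$candidate[gwasTruth$trait == "IBD"][
    seq_len(min(spec$nCandidatesIBD, nIBD))] <- TRUE
  candidates <- sort(gwasTruth$geneSymbol[gwasTruth$candidate])
  gwasTruth <- gwasTruth[order(gwasTruth$trait, gwasTruth$distanceKbp,
    gwasTruth$geneSymbol, gwasTruth$rsid), , drop = FALSE]
  rownames(gwasTruth) <- NULL

  ## ---- family and research-group maps -----------------------------------
  famCandidates <- filteredAccs
  nFam <- min(spec$nFamilies, length(famCandidates) %/% 2L)
  famMap <- data.frame(protein = character(0), family = character(0),
    stringsAsFactors = FALSE)
  if (nFam > 0L) {
    members <- famCandidates[seq_len(2L * nFam)]
    famMap <- data.frame(protein = members,
      family = rep(sprintf("FAM%02d", seq_len(nFam)), each = 2L),
      stringsAsFactors = FALSE)
  }
  allPubs <- c(hetPubs, selfPubs)
  pubGroups <- data.frame(publication = allPubs,
    group = sprintf("RG%03d", (seq_along(allPubs) - 1L) %/% 3L + 1L),
    stringsAsFactors = FALSE)

  ## ---- write everything --------------------------------------------------
  files <- c(
    intact = "intact_mitab27.tsv", biogrid = "biogrid_tab2.tsv",
    obo = "ontology.obo", gaf = "annotations.gaf",
    bed = "genes.bed", snps = "snps.tsv",
    symbolMap = "symbol_map.tsv", candidates = "candidate_genes.tsv",
    familyMap = "family_map.tsv", pubGroups = "publication_groups.tsv",
    grouping = "term_groups.tsv", config = "config.yaml",
    truth = "truth.json")
  paths <- stats::setNames(file.path(dir, files), names(files))
  writeLines(c(paste0("#", paste(rep("col", 36L), collapse = "\t")),
    intactLines), paths[["intact"]])
  writeLines(biogridLines, paths[["biogrid"]])
  writeLines(oboLines, paths[["obo"]])
  writeLines(gafLines, paths[["gaf"]])
  writeLines(bedRows, paths[["bed"]])
  writeLines(c("rsid\tchrom\tposition\ttrait", snpRows), paths[["snps"]])
  writeLines(c("protein\tsymbol",
    paste(partners, unname(symbols), sep = "\t")), paths[["symbolMap"]])
  writeLines(c("symbol", candidates), paths[["candidates"]])
  writeLines(c("protein\tfamily",
    paste(famMap$protein, famMap$family, sep = "\t")), paths[["familyMap"]])
  writeLines(c("publication\tgroup",
    paste(pubGroups$publication, pubGroups$group, sep = "\t")),
    paths[["pubGroups"]])
  writeLines(c("term\tgroup",
    paste(grouping$term, grouping$group, sep = "\t")), paths[["grouping"]])
  config <- list(
    query = query,
    intact_file = files[["intact"]], biogrid_file = files[["biogrid"]],
    obo_file = files[["obo"]], gaf_file = files[["gaf"]],
    gene_bed = files[["bed"]], snp_table = files[["snps"]],
    symbol_map = files[["symbolMap"]], candidate_list = files[["candidates"]],
    family_map = files[["familyMap"]],
    pub_group_map = files[["pubGroups"]],
    term_grouping = files[["grouping"]],
    enrichment = list(mode = "threshold", min_genes = spec$minGenes,
      top_n = 10L, p_threshold = spec$pThreshold),
    window_bp = spec$windowBp,
    protein_length = spec$proteinLength,
    output_dir = "out")
  yaml::write_yaml(config, paths[["config"]])

  tierHistogram <- vapply(c("low", "medium_low", "medium_high", "high"),
    function(t) sum(tierOf == t), integer(1L))
  truth <- list(
    query = query,
    perSource = list(
      intact = list(
        raw = length(intactLines),
        postSpoke = length(intactLines) - jI[["spoke"]],
        postFilter1 = nCleanIntact + jI[["duplicate"]],
        postFilter2 = nCleanIntact,
        hetero = nrow(hetIntact), homo = length(selfIntact)),
      biogrid = list(
        raw = length(biogridLines),
        postSpoke = length(biogridLines),
        postFilter1 = nCleanBiogrid + jB[["duplicate"]],
        postFilter2 = nCleanBiogrid,
        hetero = nrow(hetBiogrid), homo = length(selfBiogrid))),
    merged = list(
      heteroAnnotations = nrow(het),
      homoAnnotations = length(selfRows),
      interactomeSize = nPartners,
      filteredSize = length(filteredAccs),
      tierHistogram = as.list(tierHistogram),
      tiers = as.list(tierOf),
      filteredInteractome = filteredAccs),
    enrichedTerms = sort(plTerms),
    profileProbes = data.frame(residue = probes, coverage = probeCoverage),
    gwasHits = gwasTruth)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  invisible(list(files = paths, truth = truth))
}
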