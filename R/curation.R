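#' Default harmonization map for interaction detection methods
#'
#' Maps source-vocabulary method names (lower-cased for lookup) onto the
#' harmonized categories used for method counting, merged deduplication and
#' edge-list export. The defaults cover the equivalences between the IntAct
#' and BioGRID vocabularies (e.g. Protein Kinase Assay and Biochemical
#' Activity are the same category; the co-immunoprecipitation, pull-down and
#' affinity-capture variants collapse to Affinity Capture; the microscopy
#' variants collapse to Co-localization). Extend or replace it for inputs
#' using other vocabularies: [harmonizeMethods()] refuses unmapped methods.
#'
#' @return named character vector, lower-cased source method -> category.
#' @export
defaultHarmonizationMap <- function() {
  c(
    "protein kinase assay"             = "Biochemical Activity",
    "biochemical activity"             = "Biochemical Activity",
    "anti bait coimmunoprecipitation"  = "Affinity Capture",
    "anti tag coimmunoprecipitation"   = "Affinity Capture",
    "coimmunoprecipitation"            = "Affinity Capture",
    "pull down"                        = "Affinity Capture",
    "affinity chromatography technology" = "Affinity Capture",
    "affinity capture-western"         = "Affinity Capture",
    "affinity capture-ms"              = "Affinity Capture",
    "tandem affinity purification"     = "Affinity Capture",
    "confocal microscopy"              = "Co-localization",
    "fluorescence microscopy"          = "Co-localization",
    "co-localization"                  = "Co-localization",
    "two hybrid"                       = "Two-hybrid",
    "two-hybrid"                       = "Two-hybrid",
    "protein array"                    = "Protein Array",
    "proximity ligation assay"         = "Protein Array",
    "reconstituted complex"            = "Reconstituted Complex",
    "x-ray crystallography"            = "Reconstituted Complex"
  )
}

#' Fill the harmonized method column
#'
#' Looks every source-vocabulary detection method up in `map`
#' (case-insensitively) and writes the harmonized category into
#' `harmonizedMethod`. The map must be total on the methods present.
#'
#' @param records record table.
#' @param map named character vector as in [defaultHarmonizationMap()].
#' @return record table with `harmonizedMethod` filled.
#' @export
harmonizeMethods <- function(records, map = defaultHarmonizationMap()) {
  if (!nrow(records)) return(records)
  names(map) <- tolower(names(map))
  key <- tolower(records$detectionMethod)
  unmapped <- setdiff(unique(key), names(map))
  if (length(unmapped))
    stop("no harmonized category for method(s): ",
      paste(unmapped, collapse = ", "))
  records$harmonizedMethod <- unname(map[key])
  records
}

#' Filter #0: drop spoke-expanded co-complex rows
#'
#' Annotations derived by expanding an n-member co-complex into
#' query-centred binary pairs may not reflect direct contact and are
#' removed.
#'
#' @param records record table.
#' @return record table with `expansion == ""` everywhere.
#' @export
removeSpokeExpanded <- function(records) {
  records[records$expansion == "", , drop = FALSE]
}

#' Filter #1: retain same-taxon protein pairs
#'
#' Keeps records whose two interactors both carry `allowedTaxid`; records
#' with a chemical partner (the `"chemical"` taxon sentinel) or any other
#' taxon are dropped.
#'
#' @param records record table.
#' @param allowedTaxid taxon identifier as string (default human, 9606).
#' @return filtered record table.
#' @export
filterTaxid <- function(records, allowedTaxid = "9606") {
  keep <- records$taxidA == allowedTaxid & records$taxidB == allowedTaxid
  records[keep, , drop = FALSE]
}

.pairKey <- function(records) {
  a <- pmin(records$interactorA, records$interactorB)
  b <- pmax(records$interactorA, records$interactorB)
  paste(a, b, sep = "\r")
}

#' Filter #2: within-publication deduplication
#'
#' Two records are duplicates iff they share the publication, the unordered
#' canonical interactor pair (so bait/prey swaps and tag variants collapse),
#' the detection method AND the host organism. The first record in input
#' order represents each duplicate class. Setting
#' `useHarmonized = TRUE` keys on the harmonized method category instead;
#' `hostWildcard` names a host sentinel that matches any host (used by the
#' cross-database merge, where one source lacks host information).
#'
#' @param records record table.
#' @param useHarmonized key on `harmonizedMethod` instead of
#'   `detectionMethod`.
#' @param hostWildcard optional host string treated as matching any host.
#' @return deduplicated record table.
#' @export
dedupWithinPublication <- function(records, useHarmonized = FALSE,
    hostWildcard = NULL) {
  if (!nrow(records)) return(records)
  methodCol <- if (useHarmonized) "harmonizedMethod" else "detectionMethod"
  if (useHarmonized && any(!nzchar(records$harmonizedMethod)))
    stop("harmonizedMethod is empty; run harmonizeMethods() first")
  base <- paste(records$publicationId, .pairKey(records),
    records[[methodCol]], sep = "\r")
  if (is.null(hostWildcard)) {
    key <- paste(base, records$hostOrganism, sep = "\r")
    return(records[!duplicated(key), , drop = FALSE])
  }
  ## wildcard hosts: greedy first-representative scan within each
  ## (publication, pair, method) group
  keep <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), base)) {
    keptHosts <- character(0)
    for (i in idx) {
      h <- records$hostOrganism[i]
      dup <- length(keptHosts) > 0 &&
        (h == hostWildcard || any(keptHosts == h | keptHosts == hostWildcard))
      if (!dup) {
        keep[i] <- TRUE
        keptHosts <- c(keptHosts, h)
      }
    }
  }
  records[keep, , drop = FALSE]
}

#' Run the full curation filter chain on one source
#'
#' Applies spoke removal, the taxon filter and within-publication
#' deduplication in that fixed order, recording the annotation count after
#' each stage, and checks that every surviving record involves the query
#' protein.
#'
#' @param records parsed record table.
#' @param query canonical query accession.
#' @param allowedTaxid taxon retained by filter #1.
#' @return a [CuratedDataset-class].
#' @export
curateDataset <- function(records, query, allowedTaxid = "9606") {
  .validateRecords(records)
  r1 <- removeSpokeExpanded(records)
  r2 <- filterTaxid(r1, allowedTaxid)
  r3 <- dedupWithinPublication(r2)
  if (nrow(r3) && !all(r3$interactorA == query | r3$interactorB == query))
    stop("curated records must all involve the query protein ", query)
  src <- if (nrow(records)) unique(records$sourceDb) else "unknown"
  prov <- data.frame(
    stage = .curationStages,
    count = c(nrow(records), nrow(r1), nrow(r2), nrow(r3)),
    sourceDb = paste(src, collapse = "+"),
    stringsAsFactors = FALSE
  )
  new("CuratedDataset", records = r3, provenance = prov, queryProtein = query)
}

#' Split a curated dataset into heterologous and homologous records
#'
#' Homologous records are query self-interactions (both canonical
#' interactors equal the query); everything else is heterologous. The two
#' parts partition the input. A record not involving the query violates the
#' dataset contract and raises an error.
#'
#' @param x a [CuratedDataset-class] or a record table.
#' @param query query accession (taken from the dataset when omitted).
#' @return list with elements `hetero` and `homo` (record tables).
#' @export
splitHomoHetero <- function(x, query = NULL) {
  rec <- if (is(x, "CuratedDataset")) records(x) else x
  if (is.null(query)) {
    if (!is(x, "CuratedDataset")) stop("query must be given for a record table")
    query <- queryProtein(x)
  }
  if (nrow(rec) && !all(rec$interactorA == query | rec$interactorB == query))
    stop("record not involving the query protein ", query)
  homo <- rec$interactorA == query & rec$interactorB == query
  list(hetero = rec[!homo, , drop = FALSE], homo = rec[homo, , drop = FALSE])
}

.subsetDataset <- function(ds, rec, stage) {
  prov <- data.frame(stage = stage, count = nrow(rec),
    sourceDb = if (nrow(rec)) paste(unique(rec$sourceDb), collapse = "+") else "none",
    stringsAsFactors = FALSE)
  new("CuratedDataset", records = rec, provenance = prov,
    queryProtein = queryProtein(ds), log = ds@log)
}

#' Merge two curated datasets publication by publication
#'
#' Publications present in only one dataset are copied verbatim. For a
#' publication present in both, the source contributing more annotations is
#' selected wholesale; on a tie the union of the two record sets is taken
#' and re-deduplicated with filter #2 keyed on the harmonized method (and
#' with the `"unspecified"` host sentinel acting as a wildcard, since one
#' source carries no host information). The per-publication source choices
#' are recorded in the merge log.
#'
#' @param dsA,dsB [CuratedDataset-class] objects for the same query protein
#'   (records of `dsA` take precedence in tie unions).
#' @param harmonization method harmonization map; must cover both inputs.
#' @return merged [CuratedDataset-class] with a `mergeChoices` log entry.
#' @export
mergeDatasets <- function(dsA, dsB, harmonization = defaultHarmonizationMap()) {
  if (queryProtein(dsA) != queryProtein(dsB))
    stop("cannot merge datasets for different query proteins (",
      queryProtein(dsA), " vs ", queryProtein(dsB), ")")
  recA <- harmonizeMethods(records(dsA), harmonization)
  recB <- harmonizeMethods(records(dsB), harmonization)
  pubs <- sort(unique(c(recA$publicationId, recB$publicationId)))
  out <- list()
  choices <- data.frame(publication = pubs,
    nA = integer(length(pubs)), nB = integer(length(pubs)),
    source = character(length(pubs)), stringsAsFactors = FALSE)
  for (i in seq_along(pubs)) {
    p <- pubs[i]
    a <- recA[recA$publicationId == p, , drop = FALSE]
    b <- recB[recB$publicationId == p, , drop = FALSE]
    choices$nA[i] <- nrow(a)
    choices$nB[i] <- nrow(b)
    if (nrow(b) == 0L) {
      out[[i]] <- a; choices$source[i] <- "A"
    } else if (nrow(a) == 0L) {
      out[[i]] <- b; choices$source[i] <- "B"
    } else if (nrow(a) > nrow(b)) {
      out[[i]] <- a; choices$source[i] <- "A"
    } else if (nrow(b) > nrow(a)) {
      out[[i]] <- b; choices$source[i] <- "B"
    } else {
      out[[i]] <- dedupWithinPublication(rbind(a, b), useHarmonized = TRUE,
        hostWildcard = "unspecified")
      choices$source[i] <- "union"
    }
  }
  rec <- do.call(rbind, c(out, list(recA[0, , drop = FALSE])))
  rownames(rec) <- NULL
  prov <- data.frame(stage = "merged", count = nrow(rec),
    sourceDb = "intact+biogrid", stringsAsFactors = FALSE)
  new("CuratedDataset", records = rec, provenance = prov,
    queryProtein = queryProtein(dsA), log = list(mergeChoices = choices))
}
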