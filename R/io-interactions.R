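#' Canonicalize a protein accession
#'
#' Strips isoform suffixes (`-2`) and fragment chain identifiers
#' (`-PRO_0000018605`) so that all forms of one protein share a single
#' identifier; any other string is returned unchanged. Idempotent.
#'
#' @param x character vector of accessions.
#' @return character vector of canonical accessions.
#' @examples
#' canonicalizeAccession(c("O14641-2", "P46821-PRO_0000018605", "Q5S007"))
#' @export
canonicalizeAccession <- function(x) {
  if (!is.character(x) || length(x) == 0L || anyNA(x) || any(!nzchar(x)))
    stop("accession must be a non-empty character string")
  x <- sub("-PRO_[0-9]+$", "", x)
  sub("-[0-9]+$", "", x)
}

#' Default column maps for the supported delimited layouts
#'
#' Named integer vectors giving the 1-based column index of each field the
#' pipeline uses, plus `ncol`, the expected total column count. Pass a
#' modified copy to the readers to accommodate other dialects (e.g. a
#' 42-column PSI-MI TAB export with feature columns at 37/38).
#'
#' @return named integer vector.
#' @export
mitabColumnMap <- function() {
  c(idA = 1L, idB = 2L, detectionMethod = 7L, firstAuthor = 8L,
    publication = 9L, taxidA = 10L, taxidB = 11L, sourceDb = 13L,
    expansion = 16L, hostOrganism = 29L, featureA = 33L, featureB = 34L,
    ncol = 36L)
}

#' @rdname mitabColumnMap
#' @export
biogridColumnMap <- function() {
  c(idA = 8L, idB = 9L, detectionMethod = 12L, firstAuthor = 14L,
    publication = 15L, taxidA = 16L, taxidB = 17L, throughput = 18L,
    ncol = 24L)
}

## --- field parsers -------------------------------------------------------

.firstToken <- function(x) sub("\\|.*$", "", x)

.isChemicalId <- function(id) grepl("^chebi\\b", tolower(.firstToken(id)))

.stripNamespace <- function(id) {
  id <- .firstToken(id)
  sub("^[A-Za-z0-9_.-]+:", "", id)
}

.parseTaxid <- function(field, id) {
  if (.isChemicalId(id)) return("chemical")
  m <- regmatches(field, regexpr("taxid:-?[0-9]+", field))
  if (length(m) && nzchar(m)) return(sub("^taxid:", "", m))
  f <- .firstToken(field)
  if (grepl("^-?[0-9]+$", f)) f else "unspecified"
}

.parseHost <- function(field) {
  m <- regmatches(field, regexpr("taxid:-?[0-9]+", field))
  if (length(m) && nzchar(m)) sub("^taxid:", "", m) else "unspecified"
}

.parseMethod <- function(field) {
  f <- .firstToken(field)
  m <- regmatches(f, regexpr("\\(([^()]*)\\)[^()]*$", f))
  if (length(m) && nzchar(m)) sub("\\)$", "", sub("^\\(", "", m)) else f
}

.parsePublication <- function(field) {
  m <- regmatches(field, regexpr("pubmed:[^|]+", field))
  if (length(m) && nzchar(m)) sub("^pubmed:", "", m) else .firstToken(field)
}

## Feature columns carry tokens like "binding-associated region:1300-2100";
## every "<start>-<end>" numeric range is collected.
.parseRegions <- function(...) {
  fields <- c(...)
  out <- matrix(integer(), ncol = 2L)
  for (f in fields) {
    if (!nzchar(f) || f == "-") next
    m <- regmatches(f, gregexpr("[0-9]+-[0-9]+", f))[[1L]]
    if (!length(m)) next
    se <- do.call(rbind, strsplit(m, "-", fixed = TRUE))
    out <- rbind(out, matrix(as.integer(se), ncol = 2L))
  }
  colnames(out) <- c("start", "end")
  out
}

## --- record table construction -------------------------------------------

#' Build an interaction-record table
#'
#' Low-level constructor for the flat record table used throughout the
#' package: one row per curated annotation. Accessions are canonicalized;
#' the raw forms are retained. All arguments are recycled to a common
#' length.
#'
#' @param rawIdA,rawIdB accessions as printed in the source file.
#' @param taxidA,taxidB taxon identifiers as strings, or the `"chemical"`
#'   sentinel.
#' @param detectionMethod source-vocabulary method name.
#' @param harmonizedMethod harmonized method category (empty until
#'   [harmonizeMethods()] is applied).
#' @param hostOrganism host taxon string or the `"unspecified"` sentinel.
#' @param publicationId PubMed identifier.
#' @param firstAuthor first-author string.
#' @param sourceDb `"intact"` or `"biogrid"`.
#' @param expansion `""` or `"spoke expansion"`.
#' @param throughput `"high"`, `"low"` or `"unknown"`.
#' @param regions list of two-column integer matrices of 1-based inclusive
#'   residue intervals (possibly zero-row).
#' @return data.frame with one row per annotation.
#' @export
interactionRecords <- function(rawIdA, rawIdB, taxidA = "9606", taxidB = "9606",
    detectionMethod = "unknown", harmonizedMethod = "",
    hostOrganism = "unspecified", publicationId = "0",
    firstAuthor = "", sourceDb = "intact", expansion = "",
    throughput = "unknown", regions = NULL) {
  n <- max(length(rawIdA), length(rawIdB), length(taxidA), length(taxidB),
    length(detectionMethod), length(harmonizedMethod), length(hostOrganism),
    length(publicationId), length(firstAuthor), length(sourceDb),
    length(expansion), length(throughput))
  rec <- data.frame(
    interactorA = canonicalizeAccession(rep_len(as.character(rawIdA), n)),
    interactorB = canonicalizeAccession(rep_len(as.character(rawIdB), n)),
    rawIdA = rep_len(as.character(rawIdA), n),
    rawIdB = rep_len(as.character(rawIdB), n),
    taxidA = rep_len(as.character(taxidA), n),
    taxidB = rep_len(as.character(taxidB), n),
    detectionMethod = rep_len(as.character(detectionMethod), n),
    harmonizedMethod = rep_len(as.character(harmonizedMethod), n),
    hostOrganism = rep_len(as.character(hostOrganism), n),
    publicationId = rep_len(as.character(publicationId), n),
    firstAuthor = rep_len(as.character(firstAuthor), n),
    sourceDb = rep_len(as.character(sourceDb), n),
    expansion = rep_len(as.character(expansion), n),
    throughput = rep_len(as.character(throughput), n),
    stringsAsFactors = FALSE
  )
  if (is.null(regions))
    regions <- rep(list(.parseRegions("")), n)
  rec$regions <- rep_len(regions, n)
  .validateRecords(rec)
  rec
}

.emptyRegions <- function(n) rep(list(.parseRegions("")), n)

.validateRecords <- function(rec) {
  stopifnot(is.data.frame(rec))
  missing <- setdiff(.recordColumns, names(rec))
  if (length(missing))
    stop("record table lacks columns: ", paste(missing, collapse = ", "))
  if (any(!nzchar(rec$interactorA)) || any(!nzchar(rec$interactorB)))
    stop("interactor accessions must be non-empty")
  if (any(!nzchar(rec$publicationId)))
    stop("publication identifiers must be non-empty")
  for (m in rec$regions) {
    if (nrow(m) && any(m[, 1L] < 1L | m[, 1L] > m[, 2L]))
      stop("regions must satisfy 1 <= start <= end")
  }
  invisible(rec)
}

.splitFields <- function(path, ncol, comment = "#") {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, comment) & nzchar(lines)
  lineNo <- which(keep)
  ## count separators directly so trailing empty fields are not lost
  nFields <- lengths(gregexpr("\t", lines[keep], fixed = TRUE)) + 1L
  nFields[!grepl("\t", lines[keep], fixed = TRUE)] <- 1L
  bad <- which(nFields != ncol)
  if (length(bad))
    stop("malformed row at line ", lineNo[bad[1L]], ": expected ", ncol,
      " tab-separated columns, found ", nFields[bad[1L]])
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lapply(fields, function(f) c(f, rep("", ncol - length(f))))
}

#' Read a PSI-MI TAB 2.7 style interaction file
#'
#' Parses one interaction record per data row. Taxon identifiers are taken
#' from `taxid:NNNN` tokens; chemical interactors (ChEBI namespace) receive
#' the `"chemical"` taxon sentinel; accessions are canonicalized with the
#' raw forms retained; the expansion column and residue-region features are
#' preserved. Throughput defaults to `"unknown"` unless `throughputMap`
#' (named character, source-vocabulary method -> `"high"`/`"low"`) is given.
#'
#' @param path file path.
#' @param columnMap see [mitabColumnMap()].
#' @param throughputMap optional named character vector.
#' @return data.frame of interaction records.
#' @export
readMitab <- function(path, columnMap = mitabColumnMap(), throughputMap = NULL) {
  fields <- .splitFields(path, columnMap[["ncol"]])
  if (!length(fields)) return(interactionRecords(character(0), character(0))[0, ])
  get <- function(row, key) row[[columnMap[[key]]]]
  rows <- lapply(fields, function(f) {
    rawA <- .stripNamespace(get(f, "idA"))
    rawB <- .stripNamespace(get(f, "idB"))
    method <- .parseMethod(get(f, "detectionMethod"))
    expansion <- if (grepl("spoke expansion", get(f, "expansion"), fixed = TRUE))
      "spoke expansion" else ""
    thr <- "unknown"
    if (!is.null(throughputMap) && tolower(method) %in% names(throughputMap))
      thr <- unname(throughputMap[[tolower(method)]])
    list(
      rawIdA = rawA, rawIdB = rawB,
      taxidA = .parseTaxid(get(f, "taxidA"), get(f, "idA")),
      taxidB = .parseTaxid(get(f, "taxidB"), get(f, "idB")),
      detectionMethod = method,
      hostOrganism = .parseHost(get(f, "hostOrganism")),
      publicationId = .parsePublication(get(f, "publication")),
      firstAuthor = .firstToken(get(f, "firstAuthor")),
      expansion = expansion,
      throughput = thr,
      regions = .parseRegions(get(f, "featureA"), get(f, "featureB"))
    )
  })
  .rowsToRecords(rows, sourceDb = "intact")
}

#' Read a BioGRID TAB 2.0 style interaction file
#'
#' The detection method is taken from the Experimental System column and the
#' Throughput column is mapped to `"high"`/`"low"`. The layout carries no
#' host-organism column, so every record receives the `"unspecified"` host
#' sentinel (within-publication deduplication then keys on publication, pair
#' and method alone).
#'
#' @param path file path.
#' @param columnMap see [biogridColumnMap()].
#' @return data.frame of interaction records.
#' @export
readBiogridTab2 <- function(path, columnMap = biogridColumnMap()) {
  fields <- .splitFields(path, columnMap[["ncol"]])
  if (!length(fields)) return(interactionRecords(character(0), character(0))[0, ])
  get <- function(row, key) row[[columnMap[[key]]]]
  rows <- lapply(fields, function(f) {
    thrField <- tolower(get(f, "throughput"))
    thr <- if (grepl("high", thrField)) "high"
      else if (grepl("low", thrField)) "low" else "unknown"
    list(
      rawIdA = .stripNamespace(get(f, "idA")),
      rawIdB = .stripNamespace(get(f, "idB")),
      taxidA = .parseTaxid(get(f, "taxidA"), get(f, "idA")),
      taxidB = .parseTaxid(get(f, "taxidB"), get(f, "idB")),
      detectionMethod = .firstToken(get(f, "detectionMethod")),
      hostOrganism = "unspecified",
      publicationId = .parsePublication(get(f, "publication")),
      firstAuthor = .firstToken(get(f, "firstAuthor")),
      expansion = "",
      throughput = thr,
      regions = .parseRegions("")
    )
  })
  .rowsToRecords(rows, sourceDb = "biogrid")
}

.rowsToRecords <- function(rows, sourceDb) {
  pull <- function(key) vapply(rows, function(r) r[[key]], character(1L))
  interactionRecords(
    rawIdA = pull("rawIdA"), rawIdB = pull("rawIdB"),
    taxidA = pull("taxidA"), taxidB = pull("taxidB"),
    detectionMethod = pull("detectionMethod"),
    hostOrganism = pull("hostOrganism"),
    publicationId = pull("publicationId"),
    firstAuthor = pull("firstAuthor"),
    sourceDb = sourceDb,
    expansion = pull("expansion"),
    throughput = pull("throughput"),
    regions = lapply(rows, function(r) r$regions)
  )
}

## --- flat record serialization -------------------------------------------

#' Write / read the flat record TSV used for reports and round-trips
#'
#' Serializes every field the pipeline uses; `regions` are encoded as
#' `start-end` pairs joined with `;`. `readRecordsTsv(writeRecordsTsv(x))`
#' reproduces `x` exactly.
#'
#' @param records record table.
#' @param path file path.
#' @return `writeRecordsTsv` returns `path` invisibly; `readRecordsTsv`
#'   returns a record table.
#' @export
writeRecordsTsv <- function(records, path) {
  flat <- records[, setdiff(.recordColumns, "regions"), drop = FALSE]
  flat$regions <- vapply(records$regions, function(m) {
    if (!nrow(m)) "" else paste(sprintf("%d-%d", m[, 1L], m[, 2L]), collapse = ";")
  }, character(1L))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecordsTsv
#' @export
readRecordsTsv <- function(path) {
  flat <- utils::read.delim(path, colClasses = "character")
  regions <- lapply(flat$regions, function(s) {
    if (!nzchar(s)) return(.parseRegions(""))
    se <- do.call(rbind, strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE))
    m <- matrix(as.integer(se), ncol = 2L)
    colnames(m) <- c("start", "end")
    m
  })
  rec <- interactionRecords(
    rawIdA = flat$rawIdA, rawIdB = flat$rawIdB,
    taxidA = flat$taxidA, taxidB = flat$taxidB,
    detectionMethod = flat$detectionMethod,
    harmonizedMethod = flat$harmonizedMethod,
    hostOrganism = flat$hostOrganism,
    publicationId = flat$publicationId,
    firstAuthor = flat$firstAuthor,
    sourceDb = flat$sourceDb,
    expansion = flat$expansion,
    throughput = flat$throughput,
    regions = regions
  )
  if (nrow(rec)) {
    rec$interactorA <- flat$interactorA
    rec$interactorB <- flat$interactorB
  }
  rec
}

#' Export curated annotations as a SIF edge list
#'
#' Writes one `query <method> partner` line per annotation, using the
#' harmonized method where available and the source vocabulary otherwise.
#' Lines are sorted for deterministic output.
#'
#' @param records record table.
#' @param path file path.
#' @param query canonical query accession; defaults to the most frequent
#'   interactor.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(records, path, query = NULL) {
  if (!nrow(records)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(query)) {
    tab <- sort(table(c(records$interactorA, records$interactorB)), decreasing = TRUE)
    query <- names(tab)[1L]
  }
  partner <- ifelse(records$interactorA == query, records$interactorB, records$interactorA)
  method <- ifelse(nzchar(records$harmonizedMethod), records$harmonizedMethod,
    records$detectionMethod)
  method <- gsub(" ", "_", method)
  writeLines(sort(paste(query, method, partner)), path)
  invisible(path)
}
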