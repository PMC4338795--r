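.tiers <- c("low", "medium_low", "medium_high", "high")

#' Classify occurrence tiers from evidence counts
#'
#' The four-level evidence ranking of an interactor:
#' \itemize{
#'   \item \strong{low} — reported by a single annotation;
#'   \item \strong{medium_low} — one publication, two or more annotations
#'     (normally two or more methods);
#'   \item \strong{medium_high} — two or more publications, one method;
#'   \item \strong{high} — two or more publications and two or more methods.
#' }
#' The corner case of one publication, one method but several annotations
#' (possible when host systems differ) has within-publication replication
#' and is assigned medium_low; [summarizeInteractors()] flags it.
#'
#' @param nAnnotations,nPublications,nMethods integer vectors (recycled).
#' @return character vector of tiers.
#' @export
classifyOccurrence <- function(nAnnotations, nPublications, nMethods) {
  n <- max(length(nAnnotations), length(nPublications), length(nMethods))
  a <- rep_len(as.integer(nAnnotations), n)
  p <- rep_len(as.integer(nPublications), n)
  m <- rep_len(as.integer(nMethods), n)
  if (any(a < 1L) || any(p < 1L) || any(m < 1L))
    stop("evidence counts must be positive")
  if (any(p > a) || any(m > a))
    stop("one annotation carries one publication and one method, so ",
      "nAnnotations must bound nPublications and nMethods")
  ifelse(a == 1L, "low",
    ifelse(p >= 2L & m >= 2L, "high",
      ifelse(p >= 2L, "medium_high", "medium_low")))
}

#' Summarize evidence per interaction partner
#'
#' One summary row per distinct partner (the non-query interactor of each
#' heterologous record): the number of supporting annotations, distinct
#' publications and distinct harmonized methods, the occurrence tier, and
#' whether any supporting annotation was high-throughput. `flagged` marks
#' the undefined corner case (1 publication, 1 method, >1 annotation)
#' assigned to medium_low.
#'
#' @param records heterologous record table with `harmonizedMethod` filled.
#' @param query canonical query accession.
#' @return data.frame with columns `protein`, `nAnnotations`,
#'   `nPublications`, `nMethods`, `methods`, `tier`, `htp`, `flagged`,
#'   ordered by decreasing annotation count then accession.
#' @export
summarizeInteractors <- function(records, query) {
  if (!nrow(records)) {
    return(data.frame(protein = character(0), nAnnotations = integer(0),
      nPublications = integer(0), nMethods = integer(0),
      methods = character(0), tier = character(0), htp = logical(0),
      flagged = logical(0), stringsAsFactors = FALSE))
  }
  if (any(!nzchar(records$harmonizedMethod)))
    stop("harmonizedMethod is empty; run harmonizeMethods() first")
  partner <- ifelse(records$interactorA == query,
    records$interactorB, records$interactorA)
  idx <- split(seq_len(nrow(records)), partner)
  out <- data.frame(
    protein = names(idx),
    nAnnotations = lengths(idx),
    nPublications = vapply(idx, function(i)
      length(unique(records$publicationId[i])), integer(1L)),
    nMethods = vapply(idx, function(i)
      length(unique(records$harmonizedMethod[i])), integer(1L)),
    methods = vapply(idx, function(i)
      paste(sort(unique(records$harmonizedMethod[i])), collapse = "; "),
      character(1L)),
    htp = vapply(idx, function(i)
      any(records$throughput[i] == "high"), logical(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$tier <- classifyOccurrence(out$nAnnotations, out$nPublications, out$nMethods)
  out$flagged <- out$nAnnotations >= 2L & out$nPublications == 1L & out$nMethods == 1L
  out <- out[order(-out$nAnnotations, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("protein", "nAnnotations", "nPublications", "nMethods",
    "methods", "tier", "htp", "flagged")]
}

#' The filtered interactome: partners with replicated evidence
#'
#' Exactly the interactors supported by two or more annotations, i.e. the
#' complement of the low tier.
#'
#' @param summaries output of [summarizeInteractors()].
#' @return character vector of accessions.
#' @export
filteredInteractome <- function(summaries) {
  summaries$protein[summaries$nAnnotations >= 2L]
}

#' Group filtered interactors into protein families and test independence
#'
#' Members of a family are the filtered interactors mapped to it by
#' `familyMap`. A family counts as independently described when the
#' research groups behind its members' supporting publications number at
#' least two (`pubGroupMap` maps each publication to a research-group
#' label; a missing publication is an error). Filtered interactors absent
#' from `familyMap` are skipped and reported via the `"unassigned"`
#' attribute.
#'
#' @param summaries output of [summarizeInteractors()].
#' @param records heterologous record table (for the supporting
#'   publications).
#' @param query canonical query accession.
#' @param familyMap named character vector, accession -> family name.
#' @param pubGroupMap named character vector, publication -> group label.
#' @return data.frame with columns `family`, `nMembers`, `members`,
#'   `nPublications`, `independent`; attribute `unassigned` lists filtered
#'   interactors without a family.
#' @export
groupFamilies <- function(summaries, records, query, familyMap, pubGroupMap) {
  filtered <- filteredInteractome(summaries)
  unassigned <- setdiff(filtered, names(familyMap))
  if (length(unassigned))
    message(length(unassigned), " filtered interactor(s) have no family assignment")
  members <- intersect(filtered, names(familyMap))
  partner <- ifelse(records$interactorA == query,
    records$interactorB, records$interactorA)
  fam <- if (length(members))
    split(members, unname(familyMap[members])) else list()
  rows <- lapply(names(fam), function(f) {
    pubs <- unique(records$publicationId[partner %in% fam[[f]]])
    missing <- setdiff(pubs, names(pubGroupMap))
    if (length(missing))
      stop("publication(s) missing from the research-group map: ",
        paste(missing, collapse = ", "))
    groups <- unique(unname(pubGroupMap[pubs]))
    data.frame(family = f, nMembers = length(fam[[f]]),
      members = paste(sort(fam[[f]]), collapse = "; "),
      nPublications = length(pubs),
      independent = length(groups) >= 2L,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), nMembers = integer(0),
      members = character(0), nPublications = integer(0),
      independent = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}
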