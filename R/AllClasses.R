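#' @import methods
NULL

## Canonical column layout of an interaction-record table. A record table is a
## plain data.frame with one row per curated annotation; `regions` is a list
## column of two-column integer matrices (start, end; 1-based inclusive).
.recordColumns <- c(
  "interactorA", "interactorB", "rawIdA", "rawIdB",
  "taxidA", "taxidB", "detectionMethod", "harmonizedMethod",
  "hostOrganism", "publicationId", "firstAuthor", "sourceDb",
  "expansion", "throughput", "regions"
)

.curationStages <- c("raw", "post_spoke", "post_filter1", "post_filter2")

#' CuratedDataset: filtered annotations for one query protein
#'
#' Holds the interaction records that survive curation for a single query
#' protein, together with a provenance table counting the annotations at each
#' filter stage (raw input, after spoke-expansion removal, after the taxon
#' filter, after within-publication deduplication) and a free-form log (for
#' example the per-publication source choices made during a cross-database
#' merge).
#'
#' @slot records data.frame of interaction records (see [interactionRecords()]).
#' @slot provenance data.frame with columns `stage`, `count` and optionally
#'   `sourceDb`.
#' @slot queryProtein canonical accession of the query protein.
#' @slot log list of auxiliary bookkeeping (e.g. `mergeChoices`).
#'
#' @seealso [curateDataset()], [mergeDatasets()]
#' @exportClass CuratedDataset
setClass("CuratedDataset",
  slots = c(
    records = "data.frame",
    provenance = "data.frame",
    queryProtein = "character",
    log = "list"
  ),
  prototype = prototype(log = list())
)

setValidity("CuratedDataset", function(object) {
  msg <- character()
  rec <- object@records
  missing <- setdiff(.recordColumns, names(rec))
  if (length(missing))
    msg <- c(msg, paste("records lack columns:", paste(missing, collapse = ", ")))
  if (length(object@queryProtein) != 1L || !nzchar(object@queryProtein))
    msg <- c(msg, "queryProtein must be a single non-empty string")
  if (!length(msg) && nrow(rec)) {
    q <- object@queryProtein
    if (!all(rec$interactorA == q | rec$interactorB == q))
      msg <- c(msg, "every record must mention the query protein")
  }
  prov <- object@provenance
  if (!length(msg) && nrow(prov) && all(c("stage", "count") %in% names(prov))) {
    src <- if ("sourceDb" %in% names(prov)) prov$sourceDb else rep("all", nrow(prov))
    for (s in unique(src)) {
      p <- prov[src == s, , drop = FALSE]
      p <- p[match(.curationStages, p$stage, nomatch = 0L), , drop = FALSE]
      if (nrow(p) > 1L && any(diff(p$count) > 0))
        msg <- c(msg, "provenance counts must be non-increasing along the filter stages")
    }
  }
  if (length(msg)) msg else TRUE
})

#' OntologyDag: a directed acyclic term hierarchy
#'
#' A minimal ontology container: a table of terms (id, name, namespace) and a
#' table of child-to-parent edges (`is_a` and `part_of`). Acyclicity is part
#' of the class validity.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#' @exportClass OntologyDag
setClass("OntologyDag",
  slots = c(terms = "data.frame", edges = "data.frame")
)

setValidity("OntologyDag", function(object) {
  msg <- character()
  if (!all(c("id", "name", "namespace") %in% names(object@terms)))
    msg <- c(msg, "terms needs columns id, name, namespace")
  if (!all(c("child", "parent", "relation") %in% names(object@edges)))
    msg <- c(msg, "edges needs columns child, parent, relation")
  if (!length(msg)) {
    ids <- object@terms$id
    if (anyDuplicated(ids)) msg <- c(msg, "duplicated term ids")
    bad <- setdiff(c(object@edges$child, object@edges$parent), ids)
    if (length(bad))
      msg <- c(msg, paste("edge endpoints not in term set:", paste(head(bad, 3L), collapse = ", ")))
    if (nrow(object@edges)) {
      g <- igraph::graph_from_data_frame(object@edges[, c("child", "parent")],
        directed = TRUE, vertices = data.frame(name = ids))
      if (!igraph::is_dag(g)) msg <- c(msg, "ontology contains a cycle")
    }
  }
  if (length(msg)) msg else TRUE
})

#' AnnotationTable: gene-to-term assignments over a reference universe
#'
#' @slot annotations named list mapping gene identifier to a character vector
#'   of term ids.
#' @slot referenceGenes character vector: the full reference gene universe
#'   used as the sampling frame of the over-representation test.
#' @exportClass AnnotationTable
setClass("AnnotationTable",
  slots = c(annotations = "list", referenceGenes = "character")
)

setValidity("AnnotationTable", function(object) {
  msg <- character()
  ann <- object@annotations
  if (length(ann) && is.null(names(ann)))
    msg <- c(msg, "annotations must be a named list")
  bad <- setdiff(names(ann), object@referenceGenes)
  if (length(bad))
    msg <- c(msg, paste("annotated genes outside the reference universe:",
      paste(head(bad, 3L), collapse = ", ")))
  if (anyDuplicated(object@referenceGenes))
    msg <- c(msg, "duplicated reference genes")
  if (length(msg)) msg else TRUE
})

#' ResidueProfile: per-residue publication support for self-interaction
#'
#' `coverage[i]` counts the distinct publications with at least one annotated
#' region covering residue `i` (overlapping fragments from one publication
#' count once). Single-residue annotations are additionally tallied in
#' `pointResidues`.
#'
#' @slot proteinLength integer, number of residues.
#' @slot coverage integer vector of length `proteinLength`.
#' @slot pointResidues data.frame with columns `residue`, `count`.
#' @slot countBy `"publications"` or `"annotations"`.
#' @exportClass ResidueProfile
setClass("ResidueProfile",
  slots = c(
    proteinLength = "integer",
    coverage = "integer",
    pointResidues = "data.frame",
    countBy = "character"
  )
)

setValidity("ResidueProfile", function(object) {
  msg <- character()
  if (length(object@coverage) != object@proteinLength)
    msg <- c(msg, "coverage length must equal proteinLength")
  if (length(object@coverage) && min(object@coverage) < 0L)
    msg <- c(msg, "coverage must be non-negative")
  if (!all(c("residue", "count") %in% names(object@pointResidues)))
    msg <- c(msg, "pointResidues needs columns residue, count")
  if (length(msg)) msg else TRUE
})
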