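#' @describeIn CuratedDataset interaction records
#' @param x a `CuratedDataset`
#' @export
setMethod("records", "CuratedDataset", function(x) x@records)

#' @describeIn CuratedDataset stage-count provenance table
#' @export
setMethod("provenance", "CuratedDataset", function(x) x@provenance)

#' @describeIn CuratedDataset query protein accession
#' @export
setMethod("queryProtein", "CuratedDataset", function(x) x@queryProtein)

setMethod("show", "CuratedDataset", function(object) {
  rec <- object@records
  cat("CuratedDataset for query", object@queryProtein, "\n")
  cat("  ", nrow(rec), " annotations, ",
    length(unique(rec$publicationId)), " publications, ",
    length(unique(c(rec$interactorA, rec$interactorB))) - 1L,
    " partner proteins\n", sep = "")
  if (nrow(object@provenance)) {
    p <- object@provenance
    cat("  provenance: ",
      paste(sprintf("%s=%d", p$stage, p$count), collapse = ", "), "\n", sep = "")
  }
  invisible(NULL)
})

#' @describeIn OntologyDag term table
#' @param x an `OntologyDag`
#' @export
setMethod("ontologyTerms", "OntologyDag", function(x) x@terms)

#' @describeIn OntologyDag edge table
#' @export
setMethod("ontologyEdges", "OntologyDag", function(x) x@edges)

setMethod("show", "OntologyDag", function(object) {
  cat("OntologyDag with", nrow(object@terms), "terms and",
    nrow(object@edges), "edges\n")
  invisible(NULL)
})

#' @describeIn AnnotationTable gene-to-term list
#' @param x an `AnnotationTable`
#' @export
setMethod("annotations", "AnnotationTable", function(x) x@annotations)

#' @describeIn AnnotationTable reference universe
#' @export
setMethod("referenceGenes", "AnnotationTable", function(x) x@referenceGenes)

setMethod("show", "AnnotationTable", function(object) {
  cat("AnnotationTable:", length(object@annotations), "annotated genes over a",
    length(object@referenceGenes), "gene reference universe\n")
  invisible(NULL)
})

#' @describeIn ResidueProfile per-residue support; returns the integer
#'   coverage vector
#' @param x a `ResidueProfile`
#' @param ... ignored
#' @importFrom IRanges coverage
#' @export
setMethod("coverage", "ResidueProfile", function(x, ...) x@coverage)

#' @describeIn ResidueProfile single-residue annotation tally
#' @export
setMethod("pointResidues", "ResidueProfile", function(x) x@pointResidues)

#' @describeIn ResidueProfile number of residues
#' @export
setMethod("proteinLength", "ResidueProfile", function(x) x@proteinLength)

setMethod("show", "ResidueProfile", function(object) {
  cat("ResidueProfile over ", object@proteinLength, " residues (",
    object@countBy, ")\n", sep = "")
  cat("  max support ", max(object@coverage), ", ",
    sum(object@coverage > 0L), " residues covered, ",
    nrow(object@pointResidues), " point residues\n", sep = "")
  invisible(NULL)
})
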