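#' Access the interaction records of a dataset
#' @param x a [CuratedDataset-class]
#' @return data.frame of interaction records
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Access the provenance (stage count) table
#' @param x a [CuratedDataset-class]
#' @return data.frame with columns `stage`, `count` (and possibly `sourceDb`)
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Access the query protein accession
#' @param x a [CuratedDataset-class]
#' @return single character accession
#' @export
setGeneric("queryProtein", function(x) standardGeneric("queryProtein"))

#' Access the term table of an ontology
#' @param x an [OntologyDag-class]
#' @return data.frame with columns `id`, `name`, `namespace`
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))

#' Access the edge table of an ontology
#' @param x an [OntologyDag-class]
#' @return data.frame with columns `child`, `parent`, `relation`
#' @export
setGeneric("ontologyEdges", function(x) standardGeneric("ontologyEdges"))

#' Access gene-to-term annotations
#' @param x an [AnnotationTable-class]
#' @return named list mapping gene to character vector of term ids
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' Access the reference gene universe
#' @param x an [AnnotationTable-class]
#' @return character vector of gene identifiers
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))

#' Access the point-residue tally of a residue profile
#' @param x a [ResidueProfile-class]
#' @return data.frame with columns `residue`, `count`
#' @export
setGeneric("pointResidues", function(x) standardGeneric("pointResidues"))

#' Access the protein length of a residue profile
#' @param x a [ResidueProfile-class]
#' @return integer residue count
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))
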