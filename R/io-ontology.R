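#' Read a minimal OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas: `id`, `name`, `namespace`, `is_a` parents and
#' `relationship: part_of` parents. Obsolete terms are skipped. An error is
#' raised if the resulting graph is cyclic or an edge points at an unknown
#' term.
#'
#' @param path file path to an OBO file.
#' @return an [OntologyDag-class].
#' @export
readObo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  termStarts <- which(lines == "[Term]")
  if (!length(termStarts)) stop("no [Term] stanzas found in ", path)
  stanzaEnds <- c(termStarts[-1L] - 1L, length(lines))
  ids <- names <- ns <- character(0)
  edges <- list()
  for (i in seq_along(termStarts)) {
    stanza <- lines[(termStarts[i] + 1L):stanzaEnds[i]]
    stanza <- stanza[nzchar(stanza) & !startsWith(stanza, "[")]
    val <- function(key) {
      hit <- stanza[startsWith(stanza, paste0(key, ": "))]
      if (!length(hit)) return(character(0))
      sub(" !.*$", "", substring(hit, nchar(key) + 3L))
    }
    if (length(val("is_obsolete")) && any(val("is_obsolete") == "true")) next
    id <- val("id")[1L]
    if (is.na(id) || !length(id)) next
    ids <- c(ids, id)
    names <- c(names, if (length(val("name"))) val("name")[1L] else id)
    ns <- c(ns, if (length(val("namespace"))) val("namespace")[1L] else "unknown")
    for (p in val("is_a"))
      edges[[length(edges) + 1L]] <- c(id, trimws(p), "is_a")
    for (r in val("relationship")) {
      parts <- strsplit(trimws(r), "[[:space:]]+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of")
        edges[[length(edges) + 1L]] <- c(id, parts[2L], "part_of")
    }
  }
  edgeDf <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(child = m[, 1L], parent = m[, 2L], relation = m[, 3L],
      stringsAsFactors = FALSE)
  } else {
    data.frame(child = character(0), parent = character(0),
      relation = character(0), stringsAsFactors = FALSE)
  }
  new("OntologyDag",
    terms = data.frame(id = ids, name = names, namespace = ns,
      stringsAsFactors = FALSE),
    edges = edgeDf)
}

#' Read a GAF 2.x gene-association table
#'
#' Lines starting with `!` are skipped. By default the gene identifier is
#' taken from column 2 (DB Object ID) and the term from column 5. When a
#' `dag` is supplied, annotations to terms absent from it are skipped with a
#' warning reporting how many were dropped. The reference universe is the
#' set of annotated genes (the standard over-representation sampling frame),
#' optionally extended via `referenceGenes`.
#'
#' @param path file path.
#' @param dag optional [OntologyDag-class] used to validate term ids.
#' @param geneColumn 1-based column holding the gene identifier.
#' @param referenceGenes optional character vector extending the universe.
#' @return an [AnnotationTable-class].
#' @export
readGaf <- function(path, dag = NULL, geneColumn = 2L, referenceGenes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(fields, `[`, character(1L), geneColumn)
  term <- vapply(fields, `[`, character(1L), 5L)
  if (!is.null(dag)) {
    known <- term %in% ontologyTerms(dag)$id
    if (any(!known)) {
      warning(sum(!known), " annotation(s) to unknown terms skipped (e.g. ",
        term[!known][1L], ")")
      gene <- gene[known]
      term <- term[known]
    }
  }
  ann <- lapply(split(term, gene), function(x) sort(unique(x)))
  universe <- sort(unique(c(names(ann), referenceGenes)))
  new("AnnotationTable", annotations = ann, referenceGenes = universe)
}

#' Read a term-to-group assignment table
#'
#' Two-column TSV (term id, group label) used to sort enriched terms into
#' functional groups.
#'
#' @param path file path.
#' @return named character vector mapping term id to group label.
#' @export
readTermGrouping <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  stats::setNames(df[[2L]], df[[1L]])
}
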