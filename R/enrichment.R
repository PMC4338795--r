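#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term becomes annotated to every ancestor reachable
#' through the selected relations (`is_a` and `part_of` by default).
#' Idempotent; errors on a cyclic ontology.
#'
#' @param dag an [OntologyDag-class].
#' @param table an [AnnotationTable-class].
#' @param relations edge relations to traverse.
#' @return an [AnnotationTable-class] with propagated annotations.
#' @export
propagateAnnotations <- function(dag, table,
    relations = c("is_a", "part_of")) {
  edges <- ontologyEdges(dag)
  edges <- edges[edges$relation %in% relations, , drop = FALSE]
  ids <- ontologyTerms(dag)$id
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
    directed = TRUE, vertices = data.frame(name = ids))
  if (!igraph::is_dag(g)) stop("ontology contains a cycle")
  ancestors <- lapply(ids, function(t)
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t))
  names(ancestors) <- ids
  ann <- lapply(annotations(table), function(terms) {
    terms <- intersect(terms, ids)
    sort(unique(c(terms, unlist(ancestors[terms], use.names = FALSE))))
  })
  new("AnnotationTable", annotations = ann,
    referenceGenes = referenceGenes(table))
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the number of annotated genes in a study sample of size
#' `n` drawn without replacement from a reference of `N` genes of which `K`
#' are annotated. Computed with the numerically stable tail of
#' [stats::phyper()]. Arguments are recycled.
#'
#' @param N reference size.
#' @param K annotated genes in the reference.
#' @param n study size.
#' @param k annotated genes in the study.
#' @return numeric vector of probabilities.
#' @examples
#' hypergeomUpperTail(10, 4, 5, 3)  # 66/252
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  len <- max(length(N), length(K), length(n), length(k))
  N <- rep_len(N, len); K <- rep_len(K, len)
  n <- rep_len(n, len); k <- rep_len(k, len)
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k > K) || any(k > n)) stop("k must not exceed min(K, n)")
  if (any(k < 0) || any(K < 0) || any(n < 0)) stop("counts must be non-negative")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene Ontology over-representation analysis
#'
#' Tests every term annotated to at least `minGenes` study genes with the
#' hypergeometric upper tail against the reference universe of the
#' annotation table, applies a Bonferroni correction over the tested terms,
#' and reports either the `topN` smallest adjusted p-values
#' (`mode = "top10"`) or all terms with `pAdj < pThreshold`
#' (`mode = "threshold"`). Study genes outside the reference are dropped
#' with a warning (count in attribute `nDropped`). Ties are broken by
#' `(pAdj, pRaw, termId)` so output is deterministic under input
#' permutation.
#'
#' @param study character vector of study gene identifiers.
#' @param table an [AnnotationTable-class] (already propagated, or supply
#'   `dag`).
#' @param dag optional [OntologyDag-class]; when given, annotations are
#'   propagated before testing.
#' @param mode `"top10"` or `"threshold"`.
#' @param minGenes minimum study genes annotated to a term for it to be
#'   tested.
#' @param topN number of hits returned in top-N mode.
#' @param pThreshold adjusted-p cut-off in threshold mode.
#' @param relations propagation relations, see [propagateAnnotations()].
#' @return data.frame with columns `termId`, `termName`, `refCount`,
#'   `studyCount`, `pRaw`, `pAdj` and list column `contributors`, sorted by
#'   ascending adjusted p; attributes `nTested` (Bonferroni family size)
#'   and `nDropped`.
#' @export
enrichGO <- function(study, table, dag = NULL,
    mode = c("threshold", "top10"), minGenes = 2L, topN = 10L,
    pThreshold = 1e-7, relations = c("is_a", "part_of")) {
  mode <- match.arg(mode)
  if (!length(study)) stop("study set is empty")
  study <- unique(study)
  if (!is.null(dag)) table <- propagateAnnotations(dag, table, relations)
  universe <- referenceGenes(table)
  dropped <- setdiff(study, universe)
  if (length(dropped)) {
    warning(length(dropped), " study gene(s) not in the reference universe ",
      "were dropped")
    study <- intersect(study, universe)
  }
  if (!length(study)) stop("no study genes remain inside the reference universe")
  ann <- annotations(table)
  byTerm <- split(rep(names(ann), lengths(ann)),
    unlist(ann, use.names = FALSE))
  termIds <- names(byTerm)
  refCount <- lengths(byTerm)
  contributors <- lapply(byTerm, function(g) sort(intersect(g, study)))
  studyCount <- lengths(contributors)
  tested <- studyCount >= minGenes
  m <- sum(tested)
  if (!m) {
    res <- data.frame(termId = character(0), termName = character(0),
      refCount = integer(0), studyCount = integer(0),
      pRaw = numeric(0), pAdj = numeric(0))
    res$contributors <- list()
    attr(res, "nTested") <- 0L
    attr(res, "nDropped") <- length(dropped)
    return(res)
  }
  N <- length(universe)
  n <- length(study)
  pRaw <- hypergeomUpperTail(N, refCount[tested], n, studyCount[tested])
  pAdj <- pmin(1, m * pRaw)
  termTab <- ontologyTerms(if (!is.null(dag)) dag else
    new("OntologyDag",
      terms = data.frame(id = termIds, name = termIds,
        namespace = "unknown", stringsAsFactors = FALSE),
      edges = data.frame(child = character(0), parent = character(0),
        relation = character(0))))
  nameOf <- stats::setNames(termTab$name, termTab$id)
  tid <- termIds[tested]
  res <- data.frame(
    termId = tid,
    termName = ifelse(tid %in% names(nameOf), unname(nameOf[tid]), tid),
    refCount = unname(refCount[tested]),
    studyCount = unname(studyCount[tested]),
    pRaw = unname(pRaw),
    pAdj = unname(pAdj),
    stringsAsFactors = FALSE
  )
  res$contributors <- unname(contributors[tested])
  ord <- order(res$pAdj, res$pRaw, res$termId)
  res <- res[ord, , drop = FALSE]
  if (mode == "top10") res <- utils::head(res, topN)
  else res <- res[res$pAdj < pThreshold, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nTested") <- m
  attr(res, "nDropped") <- length(dropped)
  res
}

#' Per-group contributor sets
#'
#' The contributor set of a functional group is the union of the
#' contributing study genes over the group's enriched terms. Every enriched
#' term must be mapped by `grouping`.
#'
#' @param results output of [enrichGO()].
#' @param grouping named character vector, term id -> group label.
#' @return named list of sorted gene vectors, one per group present.
#' @export
contributorSets <- function(results, grouping) {
  unmapped <- setdiff(results$termId, names(grouping))
  if (length(unmapped))
    stop("enriched term(s) missing from the grouping: ",
      paste(unmapped, collapse = ", "))
  groups <- unname(grouping[results$termId])
  sets <- lapply(split(results$contributors, groups),
    function(l) sort(unique(unlist(l, use.names = FALSE))))
  sets[sort(names(sets))]
}

#' Pairwise intersection matrix of group contributor sets
#'
#' Entry `[i, j]` is `100 * |P_i (intersect) P_j| / |P_i|`: the percentage
#' of the row group's contributors that also contribute to the column
#' group. A final row `all_interactors` reports each group's contributor
#' share of the full study set. Rows for empty groups are `NA` (undefined,
#' not zero).
#'
#' @param P named list of per-group gene sets.
#' @param studySize size of the full study set.
#' @return numeric matrix with `length(P) + 1` rows.
#' @export
intersectionMatrix <- function(P, studySize) {
  if (!length(P) || all(lengths(P) == 0L))
    stop("at least one non-empty group is required")
  g <- names(P)
  M <- matrix(NA_real_, nrow = length(g) + 1L, ncol = length(g),
    dimnames = list(c(g, "all_interactors"), g))
  for (i in seq_along(g)) {
    if (!length(P[[i]])) next
    M[i, ] <- vapply(P, function(q)
      100 * length(intersect(P[[i]], q)) / length(P[[i]]), numeric(1L))
  }
  M["all_interactors", ] <- vapply(P, function(q)
    100 * length(q) / studySize, numeric(1L))
  M
}

#' Significance-level composition of enriched term groups
#'
#' Each enriched term is assigned the significance level
#' `N = ceiling(-log10(pAdj))`, clamped into `levelRange`; a zero adjusted
#' p-value is assigned the top level (with a message). Terms of the
#' `generalLabel` group are excluded. Within each level the contribution of
#' group G is `100 * g / n`, where `g` counts the group's terms at that
#' level and `n` all terms at that level.
#'
#' @param results threshold-mode output of [enrichGO()].
#' @param grouping named character vector, term id -> group label.
#' @param levelRange integer range of levels (default 7 to 16).
#' @param generalLabel group label excluded from the composition.
#' @return data.frame with columns `level`, `group`, `nTerms`,
#'   `levelTotal`, `percentage`.
#' @export
significanceComposition <- function(results, grouping,
    levelRange = c(7L, 16L), generalLabel = "general terms") {
  unmapped <- setdiff(results$termId, names(grouping))
  if (length(unmapped))
    stop("enriched term(s) missing from the grouping: ",
      paste(unmapped, collapse = ", "))
  group <- unname(grouping[results$termId])
  keep <- group != generalLabel
  res <- results[keep, , drop = FALSE]
  group <- group[keep]
  if (!nrow(res)) {
    return(data.frame(level = integer(0), group = character(0),
      nTerms = integer(0), levelTotal = integer(0),
      percentage = numeric(0), stringsAsFactors = FALSE))
  }
  lo <- min(levelRange); hi <- max(levelRange)
  zero <- res$pAdj == 0
  if (any(zero))
    message(sum(zero), " term(s) with zero adjusted p assigned to level ", hi)
  level <- rep(hi, nrow(res))
  level[!zero] <- pmin(hi, pmax(lo, ceiling(-log10(res$pAdj[!zero]))))
  rows <- list()
  for (lv in sort(unique(level), decreasing = TRUE)) {
    at <- level == lv
    n <- sum(at)
    tab <- table(group[at])
    rows[[length(rows) + 1L]] <- data.frame(
      level = lv, group = names(tab), nTerms = as.integer(tab),
      levelTotal = n, percentage = 100 * as.integer(tab) / n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
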