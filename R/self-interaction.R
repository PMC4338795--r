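#' Build a residue-level profile of self-interaction evidence
#'
#' For each residue, counts the distinct publications with at least one
#' annotated region covering it; overlapping fragments reported by the same
#' publication are unioned first, so they count once. Single-residue
#' annotations (start == end) contribute to coverage like any region and
#' are additionally tallied per residue in the point channel.
#' `countBy = "annotations"` counts annotated regions instead of
#' publications (no per-publication union), for comparison.
#'
#' @param records homologous record table; rows without region data are
#'   ignored.
#' @param proteinLength number of residues of the query protein.
#' @param countBy `"publications"` (default) or `"annotations"`.
#' @return a [ResidueProfile-class].
#' @export
buildResidueProfile <- function(records, proteinLength,
    countBy = c("publications", "annotations")) {
  countBy <- match.arg(countBy)
  proteinLength <- as.integer(proteinLength)
  withRegions <- which(vapply(records$regions, nrow, integer(1L)) > 0L)
  starts <- integer(0); ends <- integer(0)
  pub <- character(0); rowIdx <- integer(0)
  for (i in withRegions) {
    m <- records$regions[[i]]
    starts <- c(starts, m[, 1L]); ends <- c(ends, m[, 2L])
    pub <- c(pub, rep(records$publicationId[i], nrow(m)))
    rowIdx <- c(rowIdx, rep(i, nrow(m)))
  }
  bad <- which(starts < 1L | ends > proteinLength)
  if (length(bad))
    stop("region ", starts[bad[1L]], "-", ends[bad[1L]], " of record ",
      rowIdx[bad[1L]], " (publication ", pub[bad[1L]],
      ") lies outside residues 1-", proteinLength)
  cov <- integer(proteinLength)
  if (length(starts)) {
    ir <- IRanges::IRanges(starts, ends)
    if (countBy == "publications") {
      for (p in unique(pub)) {
        u <- IRanges::reduce(ir[pub == p])
        cov <- cov + as.integer(IRanges::coverage(u, width = proteinLength))
      }
    } else {
      cov <- as.integer(IRanges::coverage(ir, width = proteinLength))
    }
  }
  isPoint <- starts == ends
  points <- if (any(isPoint)) {
    key <- if (countBy == "publications")
      unique(data.frame(residue = starts[isPoint], pub = pub[isPoint]))
    else data.frame(residue = starts[isPoint])
    tab <- table(key$residue)
    data.frame(residue = as.integer(names(tab)), count = as.integer(tab))
  } else {
    data.frame(residue = integer(0), count = integer(0))
  }
  new("ResidueProfile", proteinLength = proteinLength, coverage = cov,
    pointResidues = points[order(points$residue), , drop = FALSE],
    countBy = countBy)
}

#' Write a residue profile as TSV reports
#'
#' @param profile a [ResidueProfile-class].
#' @param coveragePath TSV of (residue, coverage) for all residues.
#' @param pointsPath optional TSV of the point-residue tally.
#' @return `coveragePath`, invisibly.
#' @export
writeProfileTsv <- function(profile, coveragePath, pointsPath = NULL) {
  utils::write.table(
    data.frame(residue = seq_len(proteinLength(profile)),
      coverage = coverage(profile)),
    coveragePath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pointsPath))
    utils::write.table(pointResidues(profile), pointsPath, sep = "\t",
      quote = FALSE, row.names = FALSE)
  invisible(coveragePath)
}
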