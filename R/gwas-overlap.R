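#' Genes inside the window around a SNP
#'
#' Returns the genes on the SNP's chromosome whose interval intersects the
#' closed window `[position - windowBp, position + windowBp]`.
#'
#' @param snp a width-1 [GenomicRanges::GRanges] (see [readSnpTable()]).
#' @param genes a [GenomicRanges::GRanges] of gene intervals.
#' @param windowBp half-width of the window in base pairs.
#' @return the overlapping subset of `genes`.
#' @export
genesNearSnp <- function(snp, genes, windowBp = 200000L) {
  stopifnot(length(snp) == 1L)
  onChrom <- genes[as.character(GenomicRanges::seqnames(genes)) ==
    as.character(GenomicRanges::seqnames(snp))]
  pos <- GenomicRanges::start(snp)
  window <- IRanges::IRanges(pos - windowBp, pos + windowBp)
  hits <- IRanges::findOverlaps(GenomicRanges::ranges(onChrom), window)
  onChrom[S4Vectors::queryHits(hits)]
}

#' Distance in kilobases between a SNP and a gene interval
#'
#' Zero when the SNP lies within the interval, otherwise the distance to the
#' nearer interval boundary, in kbp. The interval semantics are the
#' caller's: supply CDS intervals to measure to the coding region.
#'
#' @param snp a width-1 [GenomicRanges::GRanges].
#' @param gene a length-1 [GenomicRanges::GRanges].
#' @return non-negative numeric (kbp).
#' @export
snpGeneDistance <- function(snp, gene) {
  stopifnot(length(snp) == 1L, length(gene) == 1L)
  if (as.character(GenomicRanges::seqnames(snp)) !=
      as.character(GenomicRanges::seqnames(gene)))
    stop("SNP and gene lie on different chromosomes")
  pos <- GenomicRanges::start(snp)
  s <- GenomicRanges::start(gene)
  e <- GenomicRanges::end(gene)
  if (s <= pos && pos <= e) return(0)
  min(abs(pos - s), abs(pos - e)) / 1000
}

#' Overlap the complete interactome with GWAS risk loci
#'
#' For every (interactor, SNP) pair whose gene interval lies within the
#' window around the SNP, reports the trait, the SNP, the SNP-gene distance
#' and whether the gene is a GWAS candidate. This operation takes the
#' complete interactome (replicated interactors plus singletons), not the
#' filtered set. Interactors with no symbol mapping are skipped with a
#' message; their count is in attribute `nUnmapped`.
#'
#' @param interactome character vector of interactor accessions (the
#'   complete interactome).
#' @param snps [GenomicRanges::GRanges] from [readSnpTable()].
#' @param genes [GenomicRanges::GRanges] from [readGeneBed()].
#' @param symbolMap named character vector, accession -> gene symbol.
#' @param candidateList character vector of candidate gene symbols.
#' @param summaries optional output of [summarizeInteractors()], used to
#'   attach annotation/publication counts and the high-throughput flag.
#' @param windowBp half-width of the locus window in base pairs.
#' @return data.frame with one row per hit, sorted by `(trait,
#'   distanceKbp)`: `protein`, `geneSymbol`, `nAnnotations`,
#'   `nPublications`, `htp`, `trait`, `rsid`, `distanceKbp`, `candidate`.
#' @export
matchInteractome <- function(interactome, snps, genes, symbolMap,
    candidateList = character(0), summaries = NULL, windowBp = 200000L) {
  unmappedAcc <- setdiff(interactome, names(symbolMap))
  if (length(unmappedAcc))
    message(length(unmappedAcc), " interactor(s) without a symbol mapping skipped")
  mapped <- intersect(interactome, names(symbolMap))
  symbols <- unname(symbolMap[mapped])
  keep <- genes$geneSymbol %in% symbols
  interGenes <- genes[keep]
  accOf <- stats::setNames(mapped, symbols)
  rows <- list()
  for (i in seq_along(snps)) {
    near <- genesNearSnp(snps[i], interGenes, windowBp)
    for (j in seq_along(near)) {
      sym <- near$geneSymbol[j]
      rows[[length(rows) + 1L]] <- data.frame(
        protein = unname(accOf[sym]),
        geneSymbol = sym,
        trait = snps$trait[i],
        rsid = snps$rsid[i],
        distanceKbp = snpGeneDistance(snps[i], near[j]),
        candidate = sym %in% candidateList,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(0), geneSymbol = character(0),
      trait = character(0), rsid = character(0),
      distanceKbp = numeric(0), candidate = logical(0),
      stringsAsFactors = FALSE)
  if (!is.null(summaries) && nrow(out)) {
    m <- match(out$protein, summaries$protein)
    out$nAnnotations <- summaries$nAnnotations[m]
    out$nPublications <- summaries$nPublications[m]
    out$htp <- summaries$htp[m]
  } else {
    out$nAnnotations <- integer(nrow(out))
    out$nPublications <- integer(nrow(out))
    out$htp <- logical(nrow(out))
  }
  out <- out[order(out$trait, out$distanceKbp, out$geneSymbol, out$rsid),
    c("protein", "geneSymbol", "nAnnotations", "nPublications", "htp",
      "trait", "rsid", "distanceKbp", "candidate"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nUnmapped") <- length(unmappedAcc)
  out
}
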