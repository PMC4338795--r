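#' Read gene intervals from a BED file
#'
#' BED half-open 0-based coordinates are converted to the 1-based inclusive
#' convention used internally (a line `chr4 999 2000 GENE1` yields the
#' interval 1000..2000). The BED name column supplies the gene symbol.
#'
#' @param path file path.
#' @return a [GenomicRanges::GRanges] with a `geneSymbol` metadata column.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  sym <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(geneSymbol = sym)
  gr
}

#' Read a SNP table
#'
#' Expects a TSV with header columns `rsid`, `chrom`, `position`, `trait`
#' (base-pair positions, 1-based).
#'
#' @param path file path.
#' @return a width-1 [GenomicRanges::GRanges] with `rsid` and `trait`
#'   metadata columns.
#' @export
readSnpTable <- function(path) {
  df <- utils::read.delim(path, colClasses = c(position = "numeric"))
  need <- c("rsid", "chrom", "position", "trait")
  if (!all(need %in% names(df)))
    stop("SNP table needs columns: ", paste(need, collapse = ", "))
  if (any(df$position < 1)) stop("SNP positions must be positive")
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$position, df$position),
    rsid = as.character(df$rsid), trait = as.character(df$trait))
}

#' Read simple two-column key/value maps
#'
#' Helpers for the user-supplied lookup tables: protein-to-family,
#' publication-to-research-group, accession-to-gene-symbol and
#' method-to-harmonized-category maps. All are two-column TSVs with a
#' header.
#'
#' @param path file path.
#' @return named character vector.
#' @export
readKeyValueTsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("expected a two-column TSV: ", path)
  stats::setNames(df[[2L]], df[[1L]])
}
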