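snpAt <- function(chrom, pos, rsid = "rs1", trait = "PD") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
    rsid = rsid, trait = trait)
}
geneAt <- function(chrom, start, end, symbol = "GENE1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
    geneSymbol = symbol)
}

test_that("the locus window includes nearby genes and excludes distant ones", {
  snp <- snpAt("chr1", 1000000)
  genes <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(1020000, 1250000, 1020000),
      c(1030000, 1300000, 1030000)),
    geneSymbol = c("GENE1", "GENE3", "GENE2"))
  hit <- genesNearSnp(snp, genes)
  expect_equal(hit$geneSymbol, "GENE1")
  expect_equal(GenomicRanges::start(hit), 1020000L)
})

test_that("window overlap equals a brute-force closed-interval scan", {
  set.seed(88)
  for (i in 1:25) {
    nGenes <- sample(10:60, 1)
    df <- data.frame(
      chrom = sample(paste0("chr", 1:3), nGenes, replace = TRUE),
      start = sample(1:3000000, nGenes),
      symbol = sprintf("G%03d", seq_len(nGenes)))
    df$end <- df$start + sample(1000:300000, nGenes)
    genes <- GenomicRanges::GRanges(df$chrom,
      IRanges::IRanges(df$start, df$end), geneSymbol = df$symbol)
    pos <- sample(1:3000000, 1)
    chrom <- sample(paste0("chr", 1:3), 1)
    w <- sample(c(50000L, 200000L), 1)
    got <- sort(genesNearSnp(snpAt(chrom, pos), genes, w)$geneSymbol)
    expect_equal(got, sort(oracleGenesNear(chrom, pos, df, w)))
  }
})

test_that("SNP-gene distances are zero inside the interval and boundary-based outside", {
  gene <- geneAt("chr1", 1020000, 1030000)
  expect_equal(snpGeneDistance(snpAt("chr1", 1025000), gene), 0)
  expect_equal(snpGeneDistance(snpAt("chr1", 1000000), gene), 20)
  expect_equal(snpGeneDistance(snpAt("chr1", 1050000), gene), 20)
  expect_error(snpGeneDistance(snpAt("chr2", 1000000), gene), "chromosome")
  ## symmetric under reflecting the gene about the SNP
  expect_equal(
    snpGeneDistance(snpAt("chr1", 2000000), geneAt("chr1", 2100000, 2200000)),
    snpGeneDistance(snpAt("chr1", 2000000), geneAt("chr1", 1800000, 1900000)))
})

test_that("interactome matching reports one hit per interactor-SNP pair", {
  genes <- GenomicRanges::GRanges(c("chr1", "chr2"),
    IRanges::IRanges(c(1040000, 5000000), c(1060000, 5050000)),
    geneSymbol = c("GENE1", "GENE2"))
  snps <- snpAt("chr1", 990000, "rs10", "PD")
  hits <- matchInteractome(c("P1", "P2"), snps, genes,
    symbolMap = c(P1 = "GENE1", P2 = "GENE2"),
    candidateList = "GENE1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$distanceKbp, 50)
  expect_true(hits$candidate)
  expect_true(all(hits$distanceKbp <= 200))
  ## empty SNP list gives no hits
  none <- matchInteractome("P1", snps[0], genes, c(P1 = "GENE1"))
  expect_equal(nrow(none), 0L)
  ## unmapped interactors are counted, not fatal
  expect_message(um <- matchInteractome(c("P1", "P9"), snps, genes,
    c(P1 = "GENE1")), "without a symbol")
  expect_equal(attr(um, "nUnmapped"), 1L)
})

test_that("matching output is invariant under gene-list permutation", {
  set.seed(12)
  genes <- GenomicRanges::GRanges(
    sample(paste0("chr", 1:2), 20, replace = TRUE),
    IRanges::IRanges(sample(1:2000000, 20), width = 50000),
    geneSymbol = sprintf("G%02d", 1:20))
  snps <- GenomicRanges::GRanges(c("chr1", "chr2"),
    IRanges::IRanges(c(500000, 1500000), width = 1),
    rsid = c("rs1", "rs2"), trait = c("PD", "IBD"))
  symbolMap <- stats::setNames(sprintf("G%02d", 1:20), sprintf("P%02d", 1:20))
  interactome <- sprintf("P%02d", 1:20)
  a <- matchInteractome(interactome, snps, genes, symbolMap)
  b <- matchInteractome(interactome, snps, genes[sample(20)], symbolMap)
  expect_equal(a, b, ignore_attr = TRUE)
  ## every hit respects the window bound
  expect_true(all(a$distanceKbp <= 200))
})
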