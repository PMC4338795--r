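## Independent oracles used by the property and acceptance tests. These are
## deliberately written as naive, brute-force computations, separate from the
## implementation paths they check.

## ---- exact binomial coefficients ----------------------------------------
## Pascal's triangle built by exact big-integer addition (little-endian digit
## vectors, base 1e7), converted to double only at the end (<= 1 ulp).

bigAdd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e7
    s[i] <- s[i] %% 1e7
  }
  if (carry > 0) s <- c(s, carry)
  s
}

bigToDouble <- function(a) sum(a * 1e7^(seq_along(a) - 1))

## rows 0..maxN of Pascal's triangle as doubles converted from exact bignums
chooseTableExact <- function(maxN) {
  rows <- vector("list", maxN + 1)
  rows[[1]] <- list(1)
  for (N in seq_len(maxN)) {
    prev <- rows[[N]]
    row <- vector("list", N + 1)
    row[[1]] <- 1
    row[[N + 1]] <- 1
    if (N > 1) for (k in 2:N) row[[k]] <- bigAdd(prev[[k - 1]], prev[[k]])
    rows[[N + 1]] <- row
  }
  lapply(rows, function(r) vapply(r, bigToDouble, numeric(1)))
}

## upper-tail hypergeometric probabilities for all k = 0..min(K, n) from the
## exact coefficient table: P(X >= k) = sum_{j>=k} C(K,j) C(N-K,n-j) / C(N,n)
oracleHyperTails <- function(N, K, n, CD) {
  js <- 0:min(K, n)
  t <- numeric(length(js))
  ok <- (n - js) <= (N - K)
  t[ok] <- CD[[K + 1]][js[ok] + 1] * CD[[N - K + 1]][n - js[ok] + 1]
  rev(cumsum(rev(t))) / CD[[N + 1]][n + 1]
}

## ---- O(n^2) duplicate-class oracle --------------------------------------
## pairwise application of the duplicate rule + union-find; returns the
## number of equivalence classes

oracleDedupClasses <- function(rec) {
  n <- nrow(rec)
  if (!n) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      pairI <- sort(c(rec$interactorA[i], rec$interactorB[i]))
      pairJ <- sort(c(rec$interactorA[j], rec$interactorB[j]))
      same <- rec$publicationId[i] == rec$publicationId[j] &&
        identical(pairI, pairJ) &&
        rec$detectionMethod[i] == rec$detectionMethod[j] &&
        rec$hostOrganism[i] == rec$hostOrganism[j]
      if (same) parent[find(i)] <- find(j)
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

## ---- per-residue brute-force profile oracle ------------------------------

oracleProfile <- function(records, L) {
  cov <- integer(L)
  withRegions <- which(vapply(records$regions, nrow, integer(1)) > 0)
  for (r in seq_len(L)) {
    pubs <- character(0)
    for (i in withRegions) {
      m <- records$regions[[i]]
      if (any(m[, 1] <= r & r <= m[, 2]))
        pubs <- c(pubs, records$publicationId[i])
    }
    cov[r] <- length(unique(pubs))
  }
  cov
}

## ---- brute-force SNP window scan ----------------------------------------

oracleGenesNear <- function(snpChrom, snpPos, genes, windowBp) {
  hit <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit[i] <- genes$chrom[i] == snpChrom &&
      genes$start[i] <= snpPos + windowBp &&
      genes$end[i] >= snpPos - windowBp
  }
  genes$symbol[hit]
}

## ---- random record tables for curation properties ------------------------

randomRecordSet <- function(n, nPubs = 4, nPartners = 5, nMethods = 3,
    nHosts = 2, query = "Q00001") {
  rec <- interactionRecords(
    rawIdA = query,
    rawIdB = sample(sprintf("P%02d", seq_len(nPartners)), n, replace = TRUE),
    detectionMethod = sample(paste0("method", seq_len(nMethods)), n,
      replace = TRUE),
    hostOrganism = sample(paste0("host", seq_len(nHosts)), n, replace = TRUE),
    publicationId = sample(paste0("90000", seq_len(nPubs)), n, replace = TRUE)
  )
  ## randomly swap bait and prey to exercise unordered-pair matching
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  if (any(swap)) {
    tmp <- rec$interactorA[swap]
    rec$interactorA[swap] <- rec$interactorB[swap]
    rec$interactorB[swap] <- tmp
    tmp <- rec$rawIdA[swap]
    rec$rawIdA[swap] <- rec$rawIdB[swap]
    rec$rawIdB[swap] <- tmp
  }
  rec
}
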