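#' Read a pipeline run configuration
#'
#' YAML with keys: `query`, `intact_file`, `biogrid_file`, `obo_file`,
#' `gaf_file`, `gene_bed`, `snp_table`, `symbol_map`, `candidate_list`,
#' `family_map`, `pub_group_map`, `term_grouping`, `harmonization_map`
#' (optional), `enrichment` (`mode`, `min_genes`, `top_n`, `p_threshold`),
#' `window_bp`, `protein_length`, `output_dir`. Relative paths are resolved
#' against the configuration file's directory.
#'
#' @param path YAML file path.
#' @return named list with attribute `baseDir`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  attr(cfg, "baseDir") <- dirname(normalizePath(path))
  cfg
}

.resolve <- function(cfg, key, baseDir, required = TRUE) {
  p <- cfg[[key]]
  if (is.null(p)) {
    if (required) stop("configuration key missing: ", key)
    return(NULL)
  }
  if (!startsWith(p, "/") && !is.null(baseDir)) p <- file.path(baseDir, p)
  if (required && !file.exists(p))
    stop("input for '", key, "' does not exist: ", p)
  p
}

#' Run the complete curation and analysis pipeline
#'
#' Executes, in order: per-source curation (spoke removal, taxon filter,
#' within-publication deduplication), the heterologous/homologous split,
#' the cross-database merges, per-interactor evidence summaries and tiers,
#' the filtered interactome, GO over-representation with contributor-set
#' intersection and (in threshold mode) significance-level composition,
#' family grouping when the maps are supplied, the self-interaction residue
#' profile, and the GWAS locus overlap of the complete interactome. Every
#' stage's table is written as TSV under `output_dir` together with a SIF
#' edge list; reruns on identical inputs are byte-identical. An empty
#' filtered interactome skips the enrichment stage with a message.
#'
#' @param config a configuration list or the path of a YAML file (see
#'   [readRunConfig()]).
#' @param baseDir directory against which relative paths are resolved
#'   (defaults to the configuration file's directory).
#' @return invisibly, a list with elements `heteroDataset`, `homoDataset`,
#'   `summaries`, `filtered`, `complete`, `families`, `enrichment`,
#'   `contributorSets`, `intersection`, `composition`, `profile`,
#'   `gwasHits` and `counts` (the stage-count ledger).
#' @export
runPipeline <- function(config, baseDir = NULL) {
  if (is.character(config)) {
    baseDir <- if (is.null(baseDir)) dirname(normalizePath(config)) else baseDir
    config <- readRunConfig(config)
  }
  query <- config$query
  if (is.null(query)) stop("configuration key missing: query")
  harmonization <- if (!is.null(config$harmonization_map))
    readKeyValueTsv(.resolve(config, "harmonization_map", baseDir))
  else defaultHarmonizationMap()

  ## -- curation ------------------------------------------------------------
  dsI <- curateDataset(readMitab(.resolve(config, "intact_file", baseDir)),
    query)
  dsB <- curateDataset(
    readBiogridTab2(.resolve(config, "biogrid_file", baseDir)), query)
  splitI <- splitHomoHetero(dsI)
  splitB <- splitHomoHetero(dsB)
  postI <- provenance(dsI)$count[provenance(dsI)$stage == "post_filter2"]
  postB <- provenance(dsB)$count[provenance(dsB)$stage == "post_filter2"]
  stopifnot(nrow(splitI$hetero) + nrow(splitI$homo) == postI,
    nrow(splitB$hetero) + nrow(splitB$homo) == postB)

  mergedHet <- mergeDatasets(
    .subsetDataset(dsI, splitI$hetero, "hetero"),
    .subsetDataset(dsB, splitB$hetero, "hetero"),
    harmonization)
  mergedHomo <- mergeDatasets(
    .subsetDataset(dsI, splitI$homo, "homo"),
    .subsetDataset(dsB, splitB$homo, "homo"),
    harmonization)

  ## -- evidence ------------------------------------------------------------
  summaries <- summarizeInteractors(records(mergedHet), query)
  filtered <- filteredInteractome(summaries)
  complete <- summaries$protein
  stopifnot(length(filtered) + sum(summaries$tier == "low") == length(complete))

  families <- NULL
  if (!is.null(config$family_map) && !is.null(config$pub_group_map)) {
    families <- groupFamilies(summaries, records(mergedHet), query,
      readKeyValueTsv(.resolve(config, "family_map", baseDir)),
      readKeyValueTsv(.resolve(config, "pub_group_map", baseDir)))
  }

  ## -- enrichment ----------------------------------------------------------
  enr <- config$enrichment
  mode <- if (is.null(enr$mode)) "threshold" else enr$mode
  enrichment <- csets <- interMat <- composition <- NULL
  if (!length(filtered)) {
    message("filtered interactome is empty; enrichment stage skipped")
  } else {
    dag <- readObo(.resolve(config, "obo_file", baseDir))
    table <- readGaf(.resolve(config, "gaf_file", baseDir), dag)
    enrichment <- enrichGO(filtered, table, dag = dag, mode = mode,
      minGenes = if (is.null(enr$min_genes)) 2L else enr$min_genes,
      topN = if (is.null(enr$top_n)) 10L else enr$top_n,
      pThreshold = if (is.null(enr$p_threshold)) 1e-7 else enr$p_threshold)
    if (!is.null(config$term_grouping) && nrow(enrichment)) {
      grouping <- readTermGrouping(.resolve(config, "term_grouping", baseDir))
      csets <- contributorSets(enrichment, grouping)
      analytic <- csets[names(csets) != "general terms"]
      if (length(analytic) && any(lengths(analytic) > 0L))
        interMat <- intersectionMatrix(analytic, length(filtered))
      if (mode == "threshold")
        composition <- significanceComposition(enrichment, grouping)
    }
  }

  ## -- self-interaction profile -------------------------------------------
  protLen <- if (is.null(config$protein_length)) 2527L else config$protein_length
  profile <- buildResidueProfile(records(mergedHomo), protLen)

  ## -- GWAS overlap (complete interactome, not the filtered set) ----------
  gwasHits <- NULL
  if (!is.null(config$snp_table) && !is.null(config$gene_bed)) {
    snps <- readSnpTable(.resolve(config, "snp_table", baseDir))
    genes <- readGeneBed(.resolve(config, "gene_bed", baseDir))
    symbolMap <- readKeyValueTsv(.resolve(config, "symbol_map", baseDir))
    candidates <- character(0)
    if (!is.null(config$candidate_list)) {
      candidates <- readLines(.resolve(config, "candidate_list", baseDir))
      candidates <- setdiff(candidates, c("symbol", ""))
    }
    gwasHits <- matchInteractome(complete, snps, genes, symbolMap,
      candidates, summaries,
      windowBp = if (is.null(config$window_bp)) 200000L else config$window_bp)
  }

  counts <- list(
    intact = .stageCounts(dsI, splitI),
    biogrid = .stageCounts(dsB, splitB),
    merged = list(
      heteroAnnotations = nrow(records(mergedHet)),
      homoAnnotations = nrow(records(mergedHomo)),
      interactomeSize = length(complete),
      filteredSize = length(filtered),
      tierHistogram = as.list(vapply(.tiers, function(t)
        sum(summaries$tier == t), integer(1L))),
      tiers = as.list(stats::setNames(summaries$tier, summaries$protein)),
      filteredInteractome = sort(filtered)))

  result <- list(heteroDataset = mergedHet, homoDataset = mergedHomo,
    summaries = summaries, filtered = sort(filtered), complete = complete,
    families = families, enrichment = enrichment, contributorSets = csets,
    intersection = interMat, composition = composition, profile = profile,
    gwasHits = gwasHits, counts = counts)

  if (!is.null(config$output_dir)) {
    outDir <- config$output_dir
    if (!startsWith(outDir, "/") && !is.null(baseDir))
      outDir <- file.path(baseDir, outDir)
    .writeReports(result, outDir, query)
  }
  invisible(result)
}

.stageCounts <- function(ds, split) {
  prov <- provenance(ds)
  list(
    raw = prov$count[prov$stage == "raw"],
    postSpoke = prov$count[prov$stage == "post_spoke"],
    postFilter1 = prov$count[prov$stage == "post_filter1"],
    postFilter2 = prov$count[prov$stage == "post_filter2"],
    hetero = nrow(split$hetero), homo = nrow(split$homo))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.writeReports <- function(result, outDir, query) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counts <- result$counts
  prov <- do.call(rbind, lapply(c("intact", "biogrid"), function(s)
    data.frame(sourceDb = s,
      stage = c("raw", "post_spoke", "post_filter1", "post_filter2",
        "hetero", "homo"),
      count = unlist(counts[[s]], use.names = FALSE))))
  prov <- rbind(prov, data.frame(sourceDb = "merged",
    stage = c("hetero", "homo"),
    count = c(counts$merged$heteroAnnotations, counts$merged$homoAnnotations)))
  .writeTsv(prov, file.path(outDir, "provenance.tsv"))
  writeRecordsTsv(records(result$heteroDataset),
    file.path(outDir, "merged_hetero.tsv"))
  writeRecordsTsv(records(result$homoDataset),
    file.path(outDir, "merged_homo.tsv"))
  writeEdgeList(records(result$heteroDataset),
    file.path(outDir, "edges_hetero.sif"), query)
  writeEdgeList(records(result$homoDataset),
    file.path(outDir, "edges_homo.sif"), query)
  .writeTsv(result$summaries, file.path(outDir, "interactors.tsv"))
  if (!is.null(result$families))
    .writeTsv(result$families, file.path(outDir, "families.tsv"))
  if (!is.null(result$enrichment)) {
    flat <- result$enrichment
    flat$contributors <- vapply(flat$contributors, paste,
      character(1L), collapse = "; ")
    .writeTsv(flat, file.path(outDir, "enrichment.tsv"))
  }
  if (!is.null(result$intersection)) {
    m <- data.frame(group = rownames(result$intersection),
      result$intersection, check.names = FALSE)
    .writeTsv(m, file.path(outDir, "intersection_matrix.tsv"))
  }
  if (!is.null(result$composition))
    .writeTsv(result$composition,
      file.path(outDir, "significance_composition.tsv"))
  writeProfileTsv(result$profile, file.path(outDir, "profile.tsv"),
    file.path(outDir, "point_residues.tsv"))
  if (!is.null(result$gwasHits))
    .writeTsv(result$gwasHits, file.path(outDir, "gwas_hits.tsv"))
  invisible(outDir)
}
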