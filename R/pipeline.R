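#' Assemble a pipeline configuration
#'
#' Collects every stage's parameters into one list, either pointing at
#' three existing VCFs plus metadata/layout tables or (default) at the
#' simulator. All tabular outputs are plain tab-separated text for
#' auditability.
#'
#' @param simulate run the simulator to produce inputs (default TRUE).
#' @param vcfPaths named list (\code{S1}, \code{S2}, \code{L}) of input
#'   VCFs when \code{simulate = FALSE}.
#' @param metaPath,layoutPath metadata/layout TSVs when not simulating.
#' @param nVariants,fst,profiles simulator parameters (see
#'   \code{\link{simulateStudy}}).
#' @param filterConfigs optional named list (\code{S1}, \code{S2},
#'   \code{L}) of \linkS4class{FilterConfig} objects overriding the
#'   per-dataset defaults (e.g. to disable QC for a lossless run).
#' @param thresholds a \linkS4class{SelectionThresholds}.
#' @param mergeRules merge-rule table (see
#'   \code{\link{defaultMergeRules}}).
#' @param densityWindowBp,chipWindowBp window widths for density maps
#'   (1 Mbp) and chip budgeting (100 kbp).
#' @param chipQuota,chipMinSpacing,chipWeights chip-selection knobs.
#' @param pcaComponents number of principal components.
#' @param stages character vector of optional stages to run; any of
#'   \code{"chip"}, \code{"pca"}.
#' @param seed top-level seed (mandatory when simulating).
#' @return A named list understood by \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(simulate = TRUE, vcfPaths = NULL,
                           metaPath = NULL, layoutPath = NULL,
                           nVariants = 3000,
                           fst = c(MED = 0.05, RIV = 0.10, SWA = 0.35),
                           profiles = defaultDatasetProfiles(),
                           filterConfigs = NULL,
                           thresholds = SelectionThresholds(),
                           mergeRules = defaultMergeRules(),
                           densityWindowBp = 1e6, chipWindowBp = 1e5,
                           chipQuota = 3, chipMinSpacing = 0,
                           chipWeights = c(0.5, 0.5),
                           pcaComponents = 10,
                           stages = c("chip", "pca"), seed = 1) {
  list(simulate = simulate, vcfPaths = vcfPaths, metaPath = metaPath,
       layoutPath = layoutPath, nVariants = nVariants, fst = fst,
       profiles = profiles, filterConfigs = filterConfigs,
       thresholds = thresholds,
       mergeRules = mergeRules, densityWindowBp = densityWindowBp,
       chipWindowBp = chipWindowBp, chipQuota = chipQuota,
       chipMinSpacing = chipMinSpacing, chipWeights = chipWeights,
       pcaComponents = pcaComponents, stages = stages, seed = seed)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full catalog pipeline
#'
#' Executes, in order: simulate (or load) the three call sets; apply
#' each dataset's QC chain; intersect and apply the
#' chromosome-class merge rules; merge genotypes; compute per-group
#' call rates and allele frequencies; select the high-confidence
#' polymorphic set; window density summaries; optionally chip
#' budgeting and PCA/clustering. Every stage's table is written under
#' \code{outDir} as tab-separated text, together with a manifest
#' recording the configuration, seed and row counts. Two runs with
#' identical config and seed produce identical outputs.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results:
#'   \code{layout}, \code{meta}, \code{filtered}, \code{partition},
#'   \code{finalKeys}, \code{merged}, \code{stats}, \code{selected},
#'   \code{chromSummary}, \code{windowCounts}, \code{density},
#'   \code{carryover}, and (when enabled) \code{chip}, \code{pca}.
#' @export
runPipeline <- function(config, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logmsg <- function(...) message("[pipeline] ", sprintf(...))

  if (isTRUE(config$simulate)) {
    logmsg("simulate: %d variants, seed %d", config$nVariants,
           config$seed)
    sim <- simulateStudy(nVariants = config$nVariants,
                         fst = config$fst,
                         profiles = config$profiles,
                         seed = config$seed,
                         dir = file.path(outDir, "inputs"))
    layout <- sim$layout; meta <- sim$meta; vsets <- sim$vsets
    truth <- sim$truth
  } else {
    layout <- readGenomeLayout(config$layoutPath)
    meta <- utils::read.delim(config$metaPath,
                              stringsAsFactors = FALSE)
    validateSampleMeta(meta)
    vsets <- lapply(config$vcfPaths, readVcfFile, layout = layout)
    names(vsets) <- names(config$vcfPaths)
    truth <- NULL
  }

  filtered <- list()
  for (tag in DATASET_TAGS) {
    filtered[[tag]] <- datasetPipeline(tag, vsets[[tag]], meta,
                                       config = config$filterConfigs[[tag]])
    logmsg("filter %s: %d sites in, %d out", tag,
           numVariants(vsets[[tag]]), numVariants(filtered[[tag]]))
  }

  partition <- partitionMembership(variantKeys(filtered$S1),
                                   variantKeys(filtered$S2),
                                   variantKeys(filtered$L))
  finalKeys <- applyMergeRules(partition, layout, config$mergeRules)
  logmsg("merge: %d keys in union, %d retained", nrow(partition),
         length(finalKeys))
  .writeTsv(partition, file.path(outDir, "membership.tsv"))

  merged <- mergeGenotypes(finalKeys, filtered$S1, filtered$S2,
                           filtered$L, meta, layout)
  writeVcfFile(merged, file.path(outDir, "catalog.vcf"), layout)

  stats <- computeGroupStats(merged, meta, layout = layout)
  .writeTsv(stats, file.path(outDir, "group_stats.tsv"))
  medStats <- stats[stats$group == "MED", ]
  selected <- selectHighConfidence(medStats, config$thresholds)
  logmsg("stats: %d catalog sites, %d high-confidence in MED",
         numVariants(merged), length(selected))

  carry <- vapply(c("RIV", "SWA"), function(g)
    crossGroupCarryover(selected, stats[stats$group == g, ],
                        config$thresholds), numeric(1))

  keys <- sort(variantKeys(merged))
  chromSummary <- chromosomeSummaries(keys, layout)
  .writeTsv(chromSummary, file.path(outDir, "chrom_summary.tsv"))
  wins <- makeWindows(layout, config$densityWindowBp)
  wc <- windowCounts(keys, wins)
  .writeTsv(wc, file.path(outDir, "window_counts.tsv"))
  dens <- genomeMeanDensity(wc)

  res <- list(layout = layout, meta = meta, truth = truth,
              filtered = filtered, partition = partition,
              finalKeys = finalKeys, merged = merged, stats = stats,
              selected = selected, chromSummary = chromSummary,
              windowCounts = wc, density = dens, carryover = carry)

  if ("chip" %in% config$stages) {
    sel <- medStats[medStats$key %in% selected, ]
    scores <- scoreMarkers(sel, weights = config$chipWeights)
    cw <- makeWindows(layout, config$chipWindowBp)
    budget <- windowBudget(scores, cw, quota = config$chipQuota,
                           minSpacing = config$chipMinSpacing)
    .writeTsv(budget, file.path(outDir, "chip_selection.tsv"))
    .writeTsv(attr(budget, "windowSummary"),
              file.path(outDir, "chip_availability.tsv"))
    res$chip <- budget
    logmsg("chip: %d markers selected", nrow(budget))
  }

  if ("pca" %in% config$stages) {
    ind <- meta$sample_id[!meta$is_pool]
    hc <- merged[variantKeys(merged) %in% selected,
                 intersect(sampleNames(merged), ind)]
    sm <- sampleMissingness(hc)
    keepS <- names(sm)[sm <= config$thresholds@sampleMissingMax]
    dosage <- buildDosageMatrix(hc[, keepS])
    pca <- pcaDosage(dosage, nComponents = config$pcaComponents)
    coords <- data.frame(sample_id = rownames(pca$coordinates),
                         pca$coordinates)
    .writeTsv(coords, file.path(outDir, "pca_coordinates.tsv"))
    .writeTsv(data.frame(component = seq_along(pca$varianceExplained),
                         variance_explained = pca$varianceExplained),
              file.path(outDir, "pca_variance.tsv"))
    hcl <- hierarchicalClusters(
      dosage, newickPath = file.path(outDir, "dendrogram.nwk"))
    res$pca <- pca; res$hclust <- hcl
    logmsg("pca: %d samples, PC1 %.1f%%", nrow(dosage),
           100 * pca$varianceExplained[1])
  }

  manifest <- c(
    sprintf("seed\t%d", config$seed),
    sprintf("simulate\t%s", isTRUE(config$simulate)),
    sprintf("n_variants_config\t%s", config$nVariants),
    sprintf("catalog_size\t%d", numVariants(merged)),
    sprintf("high_confidence_med\t%d", length(selected)),
    sprintf("carryover_RIV\t%.6f", carry[["RIV"]]),
    sprintf("carryover_SWA\t%.6f", carry[["SWA"]]),
    sprintf("stages\t%s", paste(config$stages, collapse = ",")),
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("VariantCatalog"))))
  writeLines(manifest, file.path(outDir, "manifest.tsv"))
  invisible(res)
}
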