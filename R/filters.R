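#' FilterConfig: per-dataset genotype and site QC thresholds
#'
#' Encodes the per-dataset quality-control rules applied to each call
#' set before intersection: genotype-level depth/quality masks, the
#' site-level missingness filter, and the minimum-carrier rule used for
#' the long-read set.
#'
#' @slot minDp minimum per-genotype read depth, or \code{NA} to skip.
#' @slot minGq minimum genotype quality, or \code{NA} to skip.
#' @slot maxMissing site-level missing-data threshold, or \code{NA}.
#' @slot minCarriers minimum number of alt-carrying samples, or
#'   \code{NA}.
#' @slot exemptSamples samples never masked (e.g. DNA pools, which carry
#'   no genotypes and are depth-filtered differently upstream).
#' @slot missingDialect \code{"PROSE"} (keep sites whose missing
#'   fraction is <= \code{maxMissing}) or \code{"VCFTOOLS"} (the
#'   vcftools \code{--max-missing} convention: keep sites whose
#'   \emph{called} fraction is >= the threshold).
#' @slot strict if \code{TRUE}, depth/quality comparisons are strict
#'   (keep requires value > threshold) rather than >=.
#' @slot carrierMode \code{"alt"} counts samples whose called genotype
#'   carries the alt allele; \code{"called"} counts any genotyped
#'   sample.
#'
#' @export
setClass("FilterConfig",
  representation(minDp = "numeric", minGq = "numeric",
                 maxMissing = "numeric", minCarriers = "numeric",
                 exemptSamples = "character",
                 missingDialect = "character", strict = "logical",
                 carrierMode = "character"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (!object@missingDialect %in% c("PROSE", "VCFTOOLS"))
    msg <- c(msg, "missingDialect must be PROSE or VCFTOOLS")
  if (!object@carrierMode %in% c("alt", "called"))
    msg <- c(msg, "carrierMode must be 'alt' or 'called'")
  for (sl in c("minDp", "minGq", "maxMissing", "minCarriers")) {
    v <- slot(object, sl)
    if (!is.na(v) && v < 0)
      msg <- c(msg, paste0(sl, " must be nonnegative"))
  }
  if (all(is.na(c(object@minDp, object@minGq, object@maxMissing,
                  object@minCarriers))))
    msg <- c(msg, "at least one filter criterion must be set")
  if (length(msg)) msg else TRUE
})

#' Construct a FilterConfig
#'
#' @param minDp,minGq,maxMissing,minCarriers thresholds (\code{NA}
#'   disables the corresponding filter).
#' @param exemptSamples sample ids never genotype-masked.
#' @param missingDialect \code{"PROSE"} or \code{"VCFTOOLS"}; see
#'   \linkS4class{FilterConfig}.
#' @param strict use strict (>) comparisons for depth/quality.
#' @param carrierMode \code{"alt"} or \code{"called"}.
#' @return A \linkS4class{FilterConfig}.
#' @export
FilterConfig <- function(minDp = NA, minGq = NA, maxMissing = NA,
                         minCarriers = NA, exemptSamples = character(),
                         missingDialect = "PROSE", strict = FALSE,
                         carrierMode = "alt") {
  new("FilterConfig", minDp = as.numeric(minDp),
      minGq = as.numeric(minGq), maxMissing = as.numeric(maxMissing),
      minCarriers = as.numeric(minCarriers),
      exemptSamples = as.character(exemptSamples),
      missingDialect = missingDialect, strict = strict,
      carrierMode = carrierMode)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:",
      sprintf("minDp=%s minGq=%s maxMissing=%s minCarriers=%s %s%s\n",
              object@minDp, object@minGq, object@maxMissing,
              object@minCarriers, object@missingDialect,
              if (object@strict) " (strict)" else ""))
})

#' Per-dataset default filter configurations
#'
#' \code{"S1"}: minimum depth 5 (pools exempt) then site missingness
#' 0.1. \code{"S2"}: minimum GQ 30 and depth 10 (inclusive
#' comparisons), site missingness 0.1. \code{"L"}: GQ > 20, depth > 5
#' (strict comparisons), then presence of the alt allele in at least 2
#' samples.
#'
#' @param tag dataset tag: \code{"S1"}, \code{"S2"} or \code{"L"}.
#' @param exemptSamples sample ids exempt from genotype masks (S1
#'   pools).
#' @return A \linkS4class{FilterConfig}.
#' @export
defaultFilterConfig <- function(tag, exemptSamples = character()) {
  switch(tag,
    S1 = FilterConfig(minDp = 5, maxMissing = 0.1,
                      exemptSamples = exemptSamples),
    S2 = FilterConfig(minGq = 30, minDp = 10, maxMissing = 0.1),
    L  = FilterConfig(minGq = 20, minDp = 5, minCarriers = 2,
                      strict = TRUE),
    stop("unknown dataset tag: ", tag)
  )
}

#' Mask genotypes failing depth/quality thresholds
#'
#' Sets to missing any genotype whose DP or GQ fails the configured
#' threshold. A genotype whose targeted field is absent is masked too
#' (conservative: silent pass-through would inflate call rates) and
#' counted separately. AD/DP fields are retained — masking affects the
#' genotype call only, so read-based allele frequencies are unchanged
#' unless recomputed with masking respected. Site count never changes.
#'
#' @param x a \linkS4class{VariantSet}.
#' @param config a \linkS4class{FilterConfig}; only \code{minDp},
#'   \code{minGq}, \code{strict} and \code{exemptSamples} are used.
#' @return \code{x} with failing genotypes set to \code{NA}. The
#'   attribute \code{"maskLog"} holds the number of genotypes masked and
#'   how many of those were masked for a missing field.
#' @export
maskGenotypes <- function(x, config) {
  cmp <- if (config@strict) `>` else `>=`
  fail <- matrix(FALSE, numVariants(x), length(x@samples))
  absent <- matrix(FALSE, numVariants(x), length(x@samples))
  if (!is.na(config@minDp)) {
    f <- !cmp(x@dp, config@minDp)
    a <- is.na(x@dp)
    fail <- fail | (f & !a) | a
    absent <- absent | a
  }
  if (!is.na(config@minGq)) {
    f <- !cmp(x@gq, config@minGq)
    a <- is.na(x@gq)
    fail <- fail | (f & !a) | a
    absent <- absent | a
  }
  if (length(config@exemptSamples)) {
    ex <- x@samples %in% config@exemptSamples
    fail[, ex] <- FALSE
    absent[, ex] <- FALSE
  }
  masked <- fail & !is.na(x@gt)
  out <- x
  out@gt[fail] <- NA_character_
  attr(out, "maskLog") <- c(nMasked = sum(masked),
                            nMaskedAbsentField = sum(absent & masked))
  out
}

#' Filter sites on missing-data fraction
#'
#' @param x a \linkS4class{VariantSet}.
#' @param maxMissing the threshold. Under dialect \code{"PROSE"} a site
#'   is kept when its missing fraction among eligible samples is <=
#'   \code{maxMissing}; under \code{"VCFTOOLS"} (the vcftools
#'   \code{--max-missing} convention, whose argument is a minimum
#'   \emph{called} fraction) a site is kept when its called fraction is
#'   >= \code{maxMissing}.
#' @param eligibleSamples samples whose genotypes enter the fraction
#'   (pools, which carry no genotypes, are excluded by the S1 default).
#' @param dialect \code{"PROSE"} (default) or \code{"VCFTOOLS"}.
#' @return The surviving subset of \code{x}; genotypes are untouched.
#' @export
siteMissingnessFilter <- function(x, maxMissing,
                                  eligibleSamples = sampleNames(x),
                                  dialect = "PROSE") {
  if (!length(eligibleSamples))
    stop("eligibleSamples must be nonempty")
  if (!dialect %in% c("PROSE", "VCFTOOLS"))
    stop("unknown missingness dialect: ", dialect)
  sel <- x@samples %in% eligibleSamples
  if (!any(sel)) stop("no eligible samples present in the VariantSet")
  miss <- rowMeans(is.na(x@gt[, sel, drop = FALSE]))
  keep <- if (dialect == "PROSE") miss <= maxMissing
          else (1 - miss) >= maxMissing
  x[keep, ]
}

#' Filter sites on minimum carrier count
#'
#' Keeps sites where at least \code{minCarriers} samples carry the
#' variant. With \code{mode = "alt"} (default, the stricter reading of
#' "presence in at least k individuals") a carrier is a sample whose
#' called genotype contains the alt allele; with \code{mode = "called"}
#' any non-missing genotype counts.
#'
#' @param x a \linkS4class{VariantSet}.
#' @param minCarriers minimum number of carriers (>= 1).
#' @param mode \code{"alt"} or \code{"called"}.
#' @return The surviving subset of \code{x}.
#' @export
minCarrierFilter <- function(x, minCarriers, mode = "alt") {
  .assertCount(minCarriers, "minCarriers", min = 1)
  carrier <- if (mode == "alt") {
    !is.na(x@gt) & x@gt %in% c("0/1", "1/1")
  } else if (mode == "called") {
    !is.na(x@gt)
  } else stop("unknown carrier mode: ", mode)
  x[rowSums(carrier) >= minCarriers, ]
}

#' Per-sample missing-genotype fraction
#'
#' @param x a \linkS4class{VariantSet} with at least one site.
#' @return Named numeric vector: for each sample, the fraction of sites
#'   at which its genotype is missing. Pools, which carry no GT, report
#'   1 by construction.
#' @export
sampleMissingness <- function(x) {
  if (!numVariants(x)) stop("no records")
  colMeans(is.na(x@gt))
}

#' Run the per-dataset QC pipeline
#'
#' Applies the dataset-specific rule chain: \describe{
#'   \item{S1}{depth mask (minDP 5; pools exempt), then the site
#'     missingness filter at 0.1 over non-pool samples.}
#'   \item{S2}{MNP decomposition into SNPs, then GQ 30 / DP 10 masks,
#'     then the site missingness filter at 0.1.}
#'   \item{L}{strict GQ > 20 / DP > 5 masks, biallelic-SNP restriction,
#'     then presence of the alt allele in at least 2 samples.}
#' } All three chains end by retaining biallelic SNP records only.
#'
#' @param tag dataset tag (\code{"S1"}, \code{"S2"}, \code{"L"}).
#' @param x a \linkS4class{VariantSet}.
#' @param meta sample metadata \code{data.frame} with at least
#'   \code{sample_id} and \code{is_pool} columns (see
#'   \code{\link{simulateStudy}}).
#' @param config optional \linkS4class{FilterConfig} overriding the
#'   dataset default.
#' @return The filtered \linkS4class{VariantSet}.
#' @export
datasetPipeline <- function(tag, x, meta, config = NULL) {
  if (!tag %in% DATASET_TAGS) stop("unknown dataset tag: ", tag)
  pools <- meta$sample_id[meta$is_pool]
  pools <- intersect(pools, x@samples)
  if (is.null(config))
    config <- defaultFilterConfig(tag, exemptSamples = pools)
  nonPool <- setdiff(x@samples, pools)
  if (tag == "S2") x <- decomposeMnp(x)
  anyMask <- !is.na(config@minDp) || !is.na(config@minGq)
  if (anyMask) x <- maskGenotypes(x, config)
  if (tag == "L") x <- keepBiallelicSnps(x)
  if (!is.na(config@maxMissing))
    x <- siteMissingnessFilter(x, config@maxMissing,
                               eligibleSamples = nonPool,
                               dialect = config@missingDialect)
  if (!is.na(config@minCarriers))
    x <- minCarrierFilter(x, config@minCarriers,
                          mode = config@carrierMode)
  keepBiallelicSnps(x)
}
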