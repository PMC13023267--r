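#' SelectionThresholds: reliability and polymorphism cutoffs
#'
#' Defaults follow the study design: call rate strictly greater than
#' 0.9, alternative allele frequency within [0.02, 0.98], and sample
#' exclusion above 0.5 missingness.
#'
#' @slot crMin minimum call rate (exclusive bound).
#' @slot aafLo,aafHi inclusive AAF polymorphism bounds.
#' @slot sampleMissingMax samples above this missing fraction are
#'   excluded from structure analyses.
#' @export
setClass("SelectionThresholds",
  representation(crMin = "numeric", aafLo = "numeric", aafHi = "numeric",
                 sampleMissingMax = "numeric"))

setValidity("SelectionThresholds", function(object) {
  v <- c(object@crMin, object@aafLo, object@aafHi,
         object@sampleMissingMax)
  if (any(v < 0 | v > 1)) return("all thresholds must be in [0, 1]")
  if (object@aafLo >= object@aafHi) return("aafLo must be < aafHi")
  TRUE
})

#' @rdname SelectionThresholds-class
#' @param crMin,aafLo,aafHi,sampleMissingMax see slots.
#' @return A \linkS4class{SelectionThresholds}.
#' @export
SelectionThresholds <- function(crMin = 0.9, aafLo = 0.02, aafHi = 0.98,
                                sampleMissingMax = 0.5) {
  new("SelectionThresholds", crMin = crMin, aafLo = aafLo,
      aafHi = aafHi, sampleMissingMax = sampleMissingMax)
}

#' Per-variant, per-group call rate and read-based allele frequency
#'
#' For each site and genetic group this computes two statistics with
#' deliberately different denominators: the call rate (CR) is the
#' fraction of the group's \emph{individuals} (pools carry no
#' genotypes) with a non-missing GT, while the alternative allele
#' frequency (AAF) is the ratio of summed alt read depth to summed
#' total depth over \emph{all} group members including pools — allele
#' counts rather than called genotypes, so low-coverage samples and
#' pools still contribute frequency information. Samples with absent AD
#' or DP at a site are skipped in the AAF sums (absence is not zero).
#'
#' @param x a \linkS4class{VariantSet} (typically the merged catalog).
#' @param meta sample metadata with columns \code{sample_id},
#'   \code{group}, \code{dataset}, \code{is_pool}.
#' @param groups group labels to report (default MED/RIV/SWA order).
#' @param layout optional \linkS4class{GenomeLayout}; required when
#'   \code{excludeByRule} is non-empty.
#' @param excludeByRule named list mapping a dataset tag to chromosome
#'   classes its samples cannot observe (default: the female-only
#'   short-read set has no Y, the long-read set no MT). Those samples
#'   are excluded from the CR denominator at such sites instead of
#'   counting as missing.
#' @param aafRespectsMasking if \code{TRUE}, AD/DP of individuals whose
#'   genotype is missing are excluded from the AAF sums; the default
#'   keeps them, since the read counts are reported in the VCF
#'   regardless of the genotype call.
#' @return A \code{data.frame} with one row per (key, group):
#'   \code{key}, \code{group}, \code{n_eligible}, \code{n_called},
#'   \code{call_rate}, \code{sum_ad_alt}, \code{sum_dp}, \code{aaf}
#'   (\code{NA} when \code{sum_dp} is 0: zero depth carries no
#'   frequency information).
#' @export
computeGroupStats <- function(x, meta, groups = GROUP_LABELS,
                              layout = NULL,
                              excludeByRule = list(S2 = "Y", L = "MT"),
                              aafRespectsMasking = FALSE) {
  m <- match(x@samples, meta$sample_id)
  if (anyNA(m)) stop("sample(s) missing from metadata")
  grp <- meta$group[m]
  pool <- meta$is_pool[m]
  ds <- meta$dataset[m]
  n <- numVariants(x)

  ## site x sample eligibility for the CR denominator
  elig <- matrix(TRUE, n, length(x@samples))
  if (length(excludeByRule)) {
    if (is.null(layout))
      stop("excludeByRule requires a layout")
    siteCls <- chromClasses(layout)[x@chrom]
    for (tag in names(excludeByRule)) {
      cols <- which(ds == tag)
      rows <- siteCls %in% excludeByRule[[tag]]
      if (length(cols) && any(rows)) elig[rows, cols] <- FALSE
    }
  }

  keys <- variantKeys(x)
  called <- !is.na(x@gt)
  adA <- x@adAlt; dp <- x@dp
  use <- !(is.na(adA) | is.na(dp))
  if (aafRespectsMasking) {
    use <- use & (called | matrix(pool, n, length(pool), byrow = TRUE))
  }
  adA[!use] <- 0L; dp2 <- dp; dp2[!use] <- 0L

  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gcols <- which(grp == g)
    if (!length(gcols)) stop("group with zero members: ", g)
    icols <- gcols[!pool[gcols]]
    nElig <- rowSums(elig[, icols, drop = FALSE])
    nCalled <- rowSums(called[, icols, drop = FALSE] &
                         elig[, icols, drop = FALSE])
    sumAlt <- rowSums(adA[, gcols, drop = FALSE])
    sumDp <- rowSums(dp2[, gcols, drop = FALSE])
    res[[gi]] <- data.frame(
      key = keys, group = g,
      n_eligible = nElig, n_called = nCalled,
      call_rate = ifelse(nElig > 0, nCalled / nElig, NA_real_),
      sum_ad_alt = sumAlt, sum_dp = sumDp,
      aaf = ifelse(sumDp > 0, sumAlt / sumDp, NA_real_),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Select reliable, polymorphic markers in the reference group
#'
#' Retains keys whose call rate exceeds \code{crMin} (strict, per the
#' "greater than 90\%" rule) and whose read-based AAF lies within the
#' inclusive polymorphism bounds. Keys with undefined AAF (zero summed
#' depth) are excluded.
#'
#' @param stats rows of \code{\link{computeGroupStats}} for one group
#'   (typically MED).
#' @param thresholds a \linkS4class{SelectionThresholds}.
#' @return Character vector of retained keys.
#' @export
selectHighConfidence <- function(stats, thresholds = SelectionThresholds()) {
  keep <- !is.na(stats$call_rate) &
    stats$call_rate > thresholds@crMin &
    !is.na(stats$aaf) &
    stats$aaf >= thresholds@aafLo & stats$aaf <= thresholds@aafHi
  stats$key[keep]
}

#' Fraction of selected markers polymorphic in another group
#'
#' Given the keys selected in the reference group, computes the
#' fraction whose AAF in another group still lies within the
#' polymorphism bounds. Keys with undefined AAF in the other group
#' count in the denominator but never the numerator.
#'
#' @param selectedKeys keys from \code{\link{selectHighConfidence}}.
#' @param statsOther \code{\link{computeGroupStats}} rows for the other
#'   group.
#' @param thresholds a \linkS4class{SelectionThresholds}.
#' @return The carry-over fraction in [0, 1].
#' @export
crossGroupCarryover <- function(selectedKeys, statsOther,
                                thresholds = SelectionThresholds()) {
  if (!length(selectedKeys)) stop("selectedKeys must be nonempty")
  aaf <- statsOther$aaf[match(selectedKeys, statsOther$key)]
  if (all(is.na(aaf)))
    warning("no defined AAF in the other group at any selected key")
  poly <- !is.na(aaf) & aaf >= thresholds@aafLo & aaf <= thresholds@aafHi
  sum(poly) / length(selectedKeys)
}

#' Histogram table over configurable bins
#'
#' Bins are closed on the left and open on the right, except the last
#' bin which is closed on both sides, so values equal to the final edge
#' (e.g. CR = 1) land in the last bin.
#'
#' @param values numeric vector (\code{NA} values are dropped and
#'   reported in the \code{n_na} attribute).
#' @param edges strictly increasing bin edges.
#' @return \code{data.frame} with \code{lower}, \code{upper},
#'   \code{count}.
#' @export
histogramTable <- function(values, edges) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  v <- values[!is.na(values)]
  k <- length(edges) - 1L
  idx <- findInterval(v, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx < 1L | idx > k] <- NA_integer_
  out <- data.frame(lower = edges[-length(edges)], upper = edges[-1L],
                    count = as.integer(tabulate(idx, nbins = k)))
  attr(out, "n_na") <- sum(is.na(values)) + sum(is.na(idx))
  out
}

#' Call-rate and AAF spectra
#'
#' Convenience wrappers binning one group's call rates or allele
#' frequencies, mirroring the per-SNP CR histogram and AAF spectrum
#' summaries of the catalog.
#'
#' @param stats \code{\link{computeGroupStats}} rows for one group.
#' @param edges bin edges (default 20 equal bins on [0, 1]).
#' @return A histogram table; see \code{\link{histogramTable}}.
#' @export
crDistribution <- function(stats, edges = seq(0, 1, by = 0.05)) {
  histogramTable(stats$call_rate, edges)
}

#' @rdname crDistribution
#' @export
aafSpectrum <- function(stats, edges = seq(0, 1, by = 0.05)) {
  histogramTable(stats$aaf, edges)
}
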