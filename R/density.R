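#' Per-chromosome marker density and spacing summaries
#'
#' For every chromosome carrying at least one marker: the marker count,
#' the density per Mbp (count over assembly length), the empirical mean
#' gap between successive markers, and the density-implied gap
#' \code{10^6 / density}, rounded to the nearest bp for reporting. The
#' two gap notions differ when markers cluster; headline spacing
#' figures conventionally use the density-implied form, which is the
#' exact reciprocal of the printed density.
#'
#' @param keys character vector of canonical key strings, sorted.
#' @param layout a \linkS4class{GenomeLayout}.
#' @return \code{data.frame} with columns \code{chrom}, \code{n_snps},
#'   \code{length_bp}, \code{density_per_mbp}, \code{mean_gap_bp}
#'   (\code{NA} when fewer than two markers), \code{implied_gap_bp}.
#' @export
chromosomeSummaries <- function(keys, layout) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  lens <- chromLengths(layout)
  chroms <- intersect(layout@chrom, unique(chrom))
  rows <- lapply(chroms, function(ch) {
    p <- sort(pos[chrom == ch])
    dens <- length(p) / (lens[[ch]] / 1e6)
    data.frame(chrom = ch, n_snps = length(p),
               length_bp = lens[[ch]],
               density_per_mbp = dens,
               mean_gap_bp = if (length(p) >= 2) mean(diff(p)) else NA_real_,
               implied_gap_bp = impliedGapBp(dens),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Density-implied inter-marker distance
#'
#' The mean spacing implied by a marker density: \code{10^6 / density},
#' rounded to the nearest bp. E.g. 6282 markers/Mbp implies a 159-bp
#' gap.
#'
#' @param densityPerMbp markers per Mbp (vectorized).
#' @return Implied gap(s) in bp, rounded to integer.
#' @export
impliedGapBp <- function(densityPerMbp) {
  round(1e6 / densityPerMbp)
}

#' Count markers per window
#'
#' @param keys sorted canonical key strings.
#' @param windows windows from \code{\link{makeWindows}}.
#' @return \code{data.frame} with \code{chrom}, \code{start},
#'   \code{end}, \code{width_bp}, \code{n_snps}; one row per window, in
#'   window order. Keys on tiled chromosomes but outside every window
#'   raise a coordinate error; keys on untiled chromosomes (e.g. sex
#'   chromosomes when only autosomes are tiled) are ignored.
#' @export
windowCounts <- function(keys, windows) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  onTiled <- chrom %in%
    as.character(unique(GenomicRanges::seqnames(windows)))
  counts <- integer(length(windows))
  if (any(onTiled)) {
    idx <- assignWindow(chrom[onTiled], pos[onTiled], windows)
    counts <- tabulate(idx, nbins = length(windows))
  }
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(windows)),
    start = GenomicRanges::start(windows),
    end = GenomicRanges::end(windows),
    width_bp = GenomicRanges::width(windows),
    n_snps = counts,
    stringsAsFactors = FALSE)
}

#' Top and bottom windows by marker count
#'
#' @param counts output of \code{\link{windowCounts}}.
#' @param kTop,kBottom how many windows to report at each extreme.
#'   Bottom ranking considers only windows with at least one marker.
#'   Ties break by (chromosome order, start). Requests larger than the
#'   number of rankable windows are truncated with a message.
#' @return List with \code{top} and \code{bottom} data frames.
#' @export
extremeWindows <- function(counts, kTop = 3, kBottom = 3) {
  if (!nrow(counts)) stop("counts must be nonempty")
  chromOrd <- match(counts$chrom, unique(counts$chrom))
  topOrd <- order(-counts$n_snps, chromOrd, counts$start)
  nz <- counts$n_snps > 0
  botIdx <- which(nz)
  botOrd <- botIdx[order(counts$n_snps[nz], chromOrd[nz],
                         counts$start[nz])]
  if (kTop > nrow(counts) || kBottom > length(botOrd))
    message("fewer rankable windows than requested; lists truncated")
  list(top = counts[utils::head(topOrd, kTop), ],
       bottom = counts[utils::head(botOrd, kBottom), ])
}

#' Genome-wide mean window density
#'
#' Mean and population standard deviation of per-window marker density.
#' With \code{perMbp = TRUE} each window's count is scaled to a per-Mbp
#' rate using its actual width (the terminal window of a chromosome may
#' be short); with \code{perMbp = FALSE} raw window counts are
#' summarized, the convention behind headline "count +/- SD" figures
#' computed on nominal 1-Mbp windows.
#'
#' @param counts output of \code{\link{windowCounts}}.
#' @param perMbp scale counts by actual window width (default TRUE).
#' @return Named numeric vector \code{c(mean, sd)}.
#' @export
genomeMeanDensity <- function(counts, perMbp = TRUE) {
  if (!nrow(counts)) stop("counts must be nonempty")
  v <- if (perMbp) counts$n_snps / (counts$width_bp / 1e6)
       else counts$n_snps
  mu <- mean(v)
  c(mean = mu, sd = sqrt(mean((v - mu)^2)))
}
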