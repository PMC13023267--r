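#' Score candidate array markers
#'
#' Scores each high-confidence marker for array suitability from its
#' reference-group statistics: \code{informativeness = 1 - |2*aaf - 1|}
#' (maximal at AAF 0.5, where a biallelic marker is most informative)
#' and a composite \code{w_cr * call_rate + w_inf * informativeness}
#' with weights summing to 1.
#'
#' @param stats \code{\link{computeGroupStats}} rows for the reference
#'   group, restricted to the high-confidence set.
#' @param weights length-2 numeric \code{c(callRate, informativeness)}
#'   summing to 1 (default 0.5/0.5).
#' @return \code{data.frame} with \code{key}, \code{cr}, \code{aaf},
#'   \code{informativeness}, \code{composite}.
#' @export
scoreMarkers <- function(stats, weights = c(0.5, 0.5)) {
  if (length(weights) != 2L || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be two numbers summing to 1")
  info <- 1 - abs(2 * stats$aaf - 1)
  data.frame(key = stats$key, cr = stats$call_rate, aaf = stats$aaf,
             informativeness = info,
             composite = weights[1] * stats$call_rate + weights[2] * info,
             stringsAsFactors = FALSE)
}

#' Per-window marker budgeting with a spacing constraint
#'
#' Within each window, markers are picked greedily in decreasing
#' composite score (ties by position, then ref, then alt) subject to a
#' minimum spacing from already-picked markers, until the per-window
#' quota is met or candidates run out. Greedy selection may be slightly
#' suboptimal in total score but is adequate at array quotas; the
#' selection is deterministic because the tie-break is total.
#'
#' @param scores output of \code{\link{scoreMarkers}}.
#' @param windows windows from \code{\link{makeWindows}} (typically
#'   100-kbp windows over autosomes).
#' @param quota markers requested per window.
#' @param minSpacing minimum bp between consecutive selected markers in
#'   a window (0 disables).
#' @return \code{data.frame} with one row per selected marker:
#'   \code{window_index}, \code{chrom}, \code{start}, \code{end},
#'   \code{rank}, \code{key}, \code{pos}, \code{composite}, plus the
#'   attribute \code{"windowSummary"}, a per-window \code{data.frame}
#'   (\code{candidates_available}, \code{n_selected},
#'   \code{deficit_flag}).
#' @export
windowBudget <- function(scores, windows, quota = 3, minSpacing = 0) {
  .assertCount(quota, "quota", min = 1)
  .assertCount(minSpacing, "minSpacing", min = 0)
  parts <- strsplit(scores$key, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  ref <- vapply(parts, `[`, character(1), 3L)
  alt <- vapply(parts, `[`, character(1), 4L)
  tiled <- chrom %in%
    as.character(unique(GenomicRanges::seqnames(windows)))
  widx <- rep(NA_integer_, length(chrom))
  if (any(tiled))
    widx[tiled] <- assignWindow(chrom[tiled], pos[tiled], windows)

  nw <- length(windows)
  selRows <- list()
  summ <- data.frame(window_index = seq_len(nw),
                     candidates_available = 0L, n_selected = 0L,
                     deficit_flag = FALSE)
  for (w in seq_len(nw)) {
    cand <- which(widx == w)
    summ$candidates_available[w] <- length(cand)
    if (!length(cand)) {
      summ$deficit_flag[w] <- TRUE
      next
    }
    ord <- cand[order(-scores$composite[cand], pos[cand], ref[cand],
                      alt[cand])]
    chosen <- integer(0)
    for (i in ord) {
      if (length(chosen) >= quota) break
      if (minSpacing > 0 && length(chosen) &&
          any(abs(pos[chosen] - pos[i]) < minSpacing)) next
      chosen <- c(chosen, i)
    }
    summ$n_selected[w] <- length(chosen)
    summ$deficit_flag[w] <- length(chosen) < quota
    if (length(chosen)) {
      selRows[[length(selRows) + 1L]] <- data.frame(
        window_index = w,
        chrom = as.character(GenomicRanges::seqnames(windows)[w]),
        start = GenomicRanges::start(windows)[w],
        end = GenomicRanges::end(windows)[w],
        rank = seq_along(chosen),
        key = scores$key[chosen], pos = pos[chosen],
        composite = scores$composite[chosen],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(selRows)) do.call(rbind, selRows) else
    data.frame(window_index = integer(), chrom = character(),
               start = integer(), end = integer(), rank = integer(),
               key = character(), pos = integer(),
               composite = numeric(), stringsAsFactors = FALSE)
  attr(out, "windowSummary") <- summ
  out
}

#' Candidate availability per window
#'
#' Counts high-confidence markers in each (by default 100-kbp) window
#' and summarizes the mean availability per window — the quantity an
#' array budget is judged against (e.g. a 90K design needs roughly 3
#' markers per 100-kbp window; availability in the hundreds leaves
#' ample design freedom).
#'
#' @param keys sorted canonical key strings of the high-confidence set.
#' @param layout a \linkS4class{GenomeLayout}.
#' @param widthBp window width (default 1e5).
#' @param classes chromosome classes to tile (default autosomes).
#' @return The per-window \code{data.frame} of
#'   \code{\link{windowCounts}} with attribute
#'   \code{"meanAvailable"} (mean markers per window).
#' @export
availabilityReport <- function(keys, layout, widthBp = 1e5,
                               classes = "AUTOSOME") {
  w <- makeWindows(layout, widthBp, classes = classes)
  counts <- windowCounts(keys, w)
  attr(counts, "meanAvailable") <- mean(counts$n_snps)
  counts
}
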