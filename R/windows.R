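#' Tile chromosomes into non-overlapping windows
#'
#' Each selected chromosome is tiled with consecutive windows of
#' \code{widthBp} base pairs, 1-based and inclusive at both ends
#' (VCF convention). The final window of a chromosome is truncated at the
#' chromosome end, so window widths sum exactly to the selected genome
#' length; density statistics downstream use each window's actual width.
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param widthBp window width in bp (default 1 Mbp, the width used for
#'   genome-wide marker-density maps).
#' @param classes chromosome classes to tile (default autosomes only).
#' @return A \link[GenomicRanges]{GRanges} of windows, ordered by layout
#'   chromosome order then start, with seqlengths set from the layout.
#' @examples
#' gl <- GenomeLayout("chr1", 2.5e6, "AUTOSOME")
#' makeWindows(gl, 1e6)
#' @export
makeWindows <- function(layout, widthBp = 1e6, classes = "AUTOSOME") {
  .assertCount(widthBp, "widthBp", min = 1)
  bad <- setdiff(classes, CHROM_CLASSES)
  if (length(bad))
    stop("unknown chromosome class: ", paste(bad, collapse = ", "))
  keep <- layout@chromClass %in% classes
  chroms <- layout@chrom[keep]
  lens <- layout@length[keep]
  if (!length(chroms)) {
    return(GenomicRanges::GRanges(seqinfo = GenomeInfoDb::Seqinfo(
      layout@chrom, layout@length)))
  }
  starts <- ends <- chr <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    s <- seq.int(1L, lens[i], by = as.integer(widthBp))
    e <- pmin(s + as.integer(widthBp) - 1L, lens[i])
    starts[[i]] <- s; ends[[i]] <- e
    chr[[i]] <- rep(chroms[i], length(s))
  }
  GenomicRanges::GRanges(
    seqnames = unlist(chr),
    ranges = IRanges::IRanges(start = unlist(starts), end = unlist(ends)),
    seqinfo = GenomeInfoDb::Seqinfo(layout@chrom, layout@length)
  )
}

#' Map positions to their containing window
#'
#' @param chrom chromosome name(s), recycled against \code{pos}.
#' @param pos 1-based position(s).
#' @param windows windows from \code{\link{makeWindows}}.
#' @return Integer index into \code{windows} for each position.
#'   Positions on a chromosome absent from \code{windows}, or outside the
#'   chromosome bounds, raise a coordinate error.
#' @export
assignWindow <- function(chrom, pos, windows) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  if (any(pos < 1L)) stop("positions must be >= 1")
  lv <- GenomeInfoDb::seqlevels(windows)
  bad <- setdiff(unique(chrom), lv)
  if (length(bad))
    stop("chromosome(s) with no windows: ", paste(bad, collapse = ", "))
  q <- GenomicRanges::GRanges(factor(chrom, levels = lv),
                              IRanges::IRanges(pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, windows)
  idx <- rep(NA_integer_, n)
  idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop(sprintf("position %s:%d falls in no window (outside bounds?)",
                 chrom[i], pos[i]))
  }
  idx
}
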