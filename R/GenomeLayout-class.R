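#' GenomeLayout: chromosome names, lengths and ploidy classes
#'
#' A \code{GenomeLayout} defines the coordinate system every other stage
#' works in: an ordered set of chromosomes, each with a length in base
#' pairs and a class (\code{AUTOSOME}, \code{X}, \code{Y} or \code{MT}).
#' The class drives the chromosome-specific merge rules and the
#' sex-consistency rules of the simulator; the lengths are the
#' denominators of all density statistics.
#'
#' @slot chrom character vector of unique chromosome names, in order.
#' @slot length integer vector of chromosome lengths (bp, >= 1).
#' @slot chromClass character vector drawn from
#'   \code{c("AUTOSOME", "X", "Y", "MT")}; at most one chromosome each of
#'   class X, Y and MT.
#'
#' @examples
#' gl <- GenomeLayout(
#'   chrom  = c("chr1", "chr2", "chrX", "chrMT"),
#'   length = c(5e6, 3e6, 4e6, 16500),
#'   class  = c("AUTOSOME", "AUTOSOME", "X", "MT")
#' )
#' chromLengths(gl)
#'
#' @export
setClass("GenomeLayout",
  representation(chrom = "character", length = "integer",
                 chromClass = "character"))

setValidity("GenomeLayout", function(object) {
  msg <- character()
  n <- length(object@chrom)
  if (length(object@length) != n || length(object@chromClass) != n)
    msg <- c(msg, "chrom, length and class must have equal length")
  if (anyDuplicated(object@chrom))
    msg <- c(msg, "chromosome names must be unique")
  if (any(is.na(object@length)) || any(object@length < 1L))
    msg <- c(msg, "chromosome lengths must be >= 1")
  bad <- setdiff(object@chromClass, CHROM_CLASSES)
  if (length(bad))
    msg <- c(msg, paste0("unknown chromosome class: ",
                         paste(bad, collapse = ", ")))
  for (cl in c("X", "Y", "MT")) {
    if (sum(object@chromClass == cl) > 1L)
      msg <- c(msg, paste0("at most one chromosome of class ", cl))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeLayout
#'
#' @param chrom character vector of chromosome names.
#' @param length numeric vector of chromosome lengths in bp.
#' @param class character vector of chromosome classes
#'   (\code{"AUTOSOME"}, \code{"X"}, \code{"Y"}, \code{"MT"}).
#' @return A \linkS4class{GenomeLayout}.
#' @export
GenomeLayout <- function(chrom, length, class) {
  new("GenomeLayout", chrom = as.character(chrom),
      length = as.integer(length), chromClass = as.character(class))
}

#' @describeIn GenomeLayout-class chromosome names, in layout order.
#' @param x a \code{GenomeLayout}.
#' @export
#' @aliases chromNames
setMethod("chromNames", "GenomeLayout", function(x) x@chrom)

#' @describeIn GenomeLayout-class named vector of chromosome lengths (bp).
#' @export
#' @aliases chromLengths
setMethod("chromLengths", "GenomeLayout",
          function(x) stats::setNames(x@length, x@chrom))

#' @describeIn GenomeLayout-class named vector of chromosome classes.
#' @export
#' @aliases chromClasses
setMethod("chromClasses", "GenomeLayout",
          function(x) stats::setNames(x@chromClass, x@chrom))

setMethod("length", "GenomeLayout", function(x) length(x@chrom))

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout with", length(object@chrom), "chromosomes\n")
  tab <- data.frame(chrom = object@chrom, length = object@length,
                    class = object@chromClass)
  print(utils::head(tab, 10), row.names = FALSE)
  if (nrow(tab) > 10) cat("...", nrow(tab) - 10, "more\n")
})

#' Read a genome layout from a tab-separated file
#'
#' The file has three columns, with or without a header line:
#' chromosome name, length in bp, and class
#' (\code{AUTOSOME}/\code{X}/\code{Y}/\code{MT}).
#'
#' @param path path to the TSV file.
#' @return A \linkS4class{GenomeLayout}.
#' @export
readGenomeLayout <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- is.na(suppressWarnings(as.numeric(first[2])))
  tab <- utils::read.delim(path, header = header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("layout file must have 3 columns: chrom, length, class")
  GenomeLayout(tab[[1]], tab[[2]], tab[[3]])
}

#' Write a genome layout
#'
#' \code{writeGenomeLayout} writes the three-column TSV that
#' \code{readGenomeLayout} reads back; \code{writeFai} writes a
#' FASTA-index-compatible subset (name and length columns) usable by
#' standard genome tools.
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGenomeLayout <- function(layout, path) {
  tab <- data.frame(chrom = layout@chrom, length = layout@length,
                    class = layout@chromClass)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenomeLayout
#' @export
writeFai <- function(layout, path) {
  ## .fai columns: name, length, offset, linebases, linewidth; only the
  ## first two are meaningful for a sequence-free layout.
  tab <- data.frame(layout@chrom, layout@length, 0L, 60L, 61L)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
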