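#' VariantSet: a multi-sample variant call set
#'
#' A \code{VariantSet} holds one call set: an ordered list of sites
#' (chrom, 1-based pos, ref, alt) and, per site and sample, the standard
#' per-genotype VCF fields GT, AD (split into ref and alt depths), DP
#' and GQ. Absent fields are \code{NA}, never zero: a caller that did
#' not emit AD yields \code{NA} allele depths, which excludes the sample
#' from read-based allele-frequency sums rather than silently diluting
#' them.
#'
#' Genotypes are unphased diploid strings \code{"0/0"}, \code{"0/1"},
#' \code{"1/1"}, with \code{NA} for missing. Haploid calls (male X, Y,
#' MT) are carried as homozygous diploid genotypes, the common caller
#' convention.
#'
#' @slot chrom,pos,ref,alt parallel vectors defining each site's key.
#' @slot samples ordered sample names (the matrix columns).
#' @slot gt character matrix (sites x samples) of genotype strings.
#' @slot adRef,adAlt,dp,gq integer matrices of per-genotype fields.
#'
#' @export
setClass("VariantSet",
  representation(chrom = "character", pos = "integer", ref = "character",
                 alt = "character", samples = "character",
                 gt = "matrix", adRef = "matrix", adAlt = "matrix",
                 dp = "matrix", gq = "matrix"))

setValidity("VariantSet", function(object) {
  msg <- character()
  n <- length(object@chrom)
  m <- length(object@samples)
  if (length(object@pos) != n || length(object@ref) != n ||
      length(object@alt) != n)
    msg <- c(msg, "chrom, pos, ref, alt must have equal length")
  for (sl in c("gt", "adRef", "adAlt", "dp", "gq")) {
    mat <- slot(object, sl)
    if (!identical(dim(mat), c(n, m)))
      msg <- c(msg, sprintf("%s matrix must be %d x %d", sl, n, m))
  }
  if (n && any(object@ref == object@alt & !grepl(",", object@alt)))
    msg <- c(msg, "ref and alt alleles must differ")
  ok <- is.na(object@gt) | object@gt %in% c("0/0", "0/1", "1/1")
  if (!all(ok))
    msg <- c(msg, "genotypes must be 0/0, 0/1, 1/1 or NA")
  if (length(msg)) msg else TRUE
})

.emptyIntMat <- function(n, m, samples) {
  matrix(NA_integer_, n, m, dimnames = list(NULL, samples))
}

#' Construct a VariantSet
#'
#' @param chrom,pos,ref,alt site keys (parallel vectors). Alleles are
#'   upper-cased; a comma-separated \code{alt} marks a multiallelic site.
#' @param samples ordered sample names.
#' @param gt character matrix of genotypes (\code{"0/0"}, \code{"0/1"},
#'   \code{"1/1"}, \code{NA}); defaults to all-missing.
#' @param adRef,adAlt,dp,gq integer matrices; default all-absent.
#' @return A \linkS4class{VariantSet}.
#' @export
VariantSet <- function(chrom, pos, ref, alt, samples = character(),
                       gt = NULL, adRef = NULL, adAlt = NULL,
                       dp = NULL, gq = NULL) {
  n <- length(chrom)
  m <- length(samples)
  mk <- function(x, mode) {
    if (is.null(x)) {
      if (mode == "character")
        matrix(NA_character_, n, m, dimnames = list(NULL, samples))
      else .emptyIntMat(n, m, samples)
    } else {
      x <- as.matrix(x)
      storage.mode(x) <- mode
      dimnames(x) <- list(NULL, samples)
      x
    }
  }
  new("VariantSet", chrom = as.character(chrom), pos = as.integer(pos),
      ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
      samples = as.character(samples),
      gt = mk(gt, "character"), adRef = mk(adRef, "integer"),
      adAlt = mk(adAlt, "integer"), dp = mk(dp, "integer"),
      gq = mk(gq, "integer"))
}

#' @describeIn VariantSet-class number of sites.
#' @param x a \code{VariantSet}.
#' @export
#' @aliases numVariants
setMethod("numVariants", "VariantSet", function(x) length(x@chrom))

#' @describeIn VariantSet-class ordered sample names.
#' @export
#' @aliases sampleNames
setMethod("sampleNames", "VariantSet", function(x) x@samples)

#' @describeIn VariantSet-class canonical key strings
#'   (\code{"chrom:pos:ref:alt"}), the identity used for intersection.
#' @export
#' @aliases variantKeys
setMethod("variantKeys", "VariantSet",
          function(x) .keyString(x@chrom, x@pos, x@ref, x@alt))

#' @describeIn VariantSet-class per-site variant class
#'   (SNP/INDEL/MNP/MULTIALLELIC/OTHER).
#' @export
#' @aliases variantClass
setMethod("variantClass", "VariantSet",
          function(x) classifyVariant(x@ref, x@alt))

#' @describeIn VariantSet-class genotype matrix.
#' @export
#' @aliases gtMatrix
setMethod("gtMatrix", "VariantSet", function(x) x@gt)

#' @describeIn VariantSet-class alternative allele depth matrix.
#' @export
#' @aliases adAlt
setMethod("adAlt", "VariantSet", function(x) x@adAlt)

#' @describeIn VariantSet-class reference allele depth matrix.
#' @export
#' @aliases adRef
setMethod("adRef", "VariantSet", function(x) x@adRef)

#' @describeIn VariantSet-class total depth matrix.
#' @export
#' @aliases dpMatrix
setMethod("dpMatrix", "VariantSet", function(x) x@dp)

#' @describeIn VariantSet-class genotype quality matrix.
#' @export
#' @aliases gqMatrix
setMethod("gqMatrix", "VariantSet", function(x) x@gq)

#' @export
setMethod("show", "VariantSet", function(object) {
  cat("VariantSet:", length(object@chrom), "sites x",
      length(object@samples), "samples\n")
  if (length(object@chrom)) {
    cls <- table(classifyVariant(object@ref, object@alt))
    cat("  classes:",
        paste(names(cls), as.integer(cls), sep = "=", collapse = ", "),
        "\n")
    cat("  chromosomes:",
        paste(unique(object@chrom), collapse = ", "), "\n")
  }
})

#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@chrom)
  if (missing(j)) j <- seq_along(x@samples)
  if (is.character(j)) j <- match(j, x@samples)
  new("VariantSet",
      chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i], alt = x@alt[i],
      samples = x@samples[j],
      gt = x@gt[i, j, drop = FALSE], adRef = x@adRef[i, j, drop = FALSE],
      adAlt = x@adAlt[i, j, drop = FALSE], dp = x@dp[i, j, drop = FALSE],
      gq = x@gq[i, j, drop = FALSE])
})

#' Classify variants by allele shape
#'
#' SNP: both alleles single bases. MNP: equal-length multi-base
#' substitution. INDEL: length-changing alleles. MULTIALLELIC: more than
#' one ALT allele (comma-separated; not split, and excluded from the
#' final biallelic catalog). OTHER: symbolic or non-ACGT alleles.
#'
#' @param ref,alt character vectors of alleles; \code{alt} may contain
#'   comma-separated lists.
#' @return Character vector of classes.
#' @examples
#' classifyVariant(c("A", "AT", "A", "A"), c("G", "GC", "AT", "G,T"))
#' @export
classifyVariant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("empty allele string")
  out <- character(length(ref))
  multi <- grepl(",", alt)
  acgt <- grepl("^[ACGT]+$", ref) &
    (multi | grepl("^[ACGT]+$", alt))
  lr <- nchar(ref); la <- nchar(alt)
  out[multi] <- "MULTIALLELIC"
  out[!multi & acgt & lr == 1L & la == 1L] <- "SNP"
  out[!multi & acgt & lr == la & lr > 1L] <- "MNP"
  out[!multi & acgt & lr != la] <- "INDEL"
  out[!acgt & !multi] <- "OTHER"
  out
}

#' Keep only biallelic SNP records
#'
#' @param x a \linkS4class{VariantSet}.
#' @return The subset of \code{x} with \code{variantClass == "SNP"}.
#' @export
keepBiallelicSnps <- function(x) {
  x[variantClass(x) == "SNP", ]
}

## Order sites by layout chromosome order, then position, ref, alt.
.orderVariants <- function(x, layout) {
  ord <- order(match(x@chrom, layout@chrom), x@pos, x@ref, x@alt)
  x[ord, ]
}
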