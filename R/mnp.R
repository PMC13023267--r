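#' Decompose an MNP record into per-base SNPs
#'
#' A multi-nucleotide polymorphism (equal-length multi-base
#' substitution, as emitted e.g. by haplotype-based callers) is
#' normalized into one SNP per position at which the ref and alt bases
#' differ; positions where the bases agree emit nothing. Every emitted
#' SNP inherits the parent record's genotype entries verbatim (perfect
#' linkage within the MNP is assumed).
#'
#' @param x a \linkS4class{VariantSet} whose rows at \code{which} are
#'   MNPs.
#' @param which integer indices of the MNP rows to decompose; defaults
#'   to all rows of class \code{MNP}.
#' @return A \linkS4class{VariantSet} in which each selected MNP is
#'   replaced, in place, by its component SNPs (sorted by position);
#'   other rows are untouched.
#' @examples
#' v <- VariantSet("chr1", 100, "AT", "GC", samples = "s1",
#'                 gt = matrix("0/1"))
#' variantKeys(decomposeMnp(v))
#' @export
decomposeMnp <- function(x, which = NULL) {
  cls <- variantClass(x)
  if (is.null(which)) which <- base::which(cls == "MNP")
  if (!length(which)) return(x)
  if (any(cls[which] != "MNP"))
    stop("decomposeMnp called on non-MNP record(s)")
  pieces <- vector("list", numVariants(x))
  for (i in seq_len(numVariants(x))) {
    if (!(i %in% which)) {
      pieces[[i]] <- list(pos = x@pos[i], ref = x@ref[i], alt = x@alt[i])
      next
    }
    rb <- strsplit(x@ref[i], "")[[1]]
    ab <- strsplit(x@alt[i], "")[[1]]
    d <- base::which(rb != ab)
    pieces[[i]] <- list(pos = x@pos[i] + d - 1L, ref = rb[d],
                        alt = ab[d])
  }
  reps <- vapply(pieces, function(p) length(p$pos), integer(1))
  idx <- rep(seq_along(pieces), reps)
  out <- x[idx, ]
  out@pos <- as.integer(unlist(lapply(pieces, `[[`, "pos")))
  out@ref <- as.character(unlist(lapply(pieces, `[[`, "ref")))
  out@alt <- as.character(unlist(lapply(pieces, `[[`, "alt")))
  out
}
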