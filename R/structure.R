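#' Build an alt-allele dosage matrix
#'
#' Converts called genotypes to alt-allele dosages (0/0 -> 0, 0/1 -> 1,
#' 1/1 -> 2). Missing entries are replaced by the per-variant mean
#' dosage over called samples (mean imputation, the common default for
#' genotype PCA); variants with no called sample are dropped.
#'
#' @param x a \linkS4class{VariantSet} of biallelic SNPs.
#' @param samples samples to include (non-pool individuals; defaults to
#'   all samples of \code{x}).
#' @return Numeric matrix (samples x variants) of dosages, with
#'   attribute \code{"imputed"} giving the count of imputed entries.
#' @export
buildDosageMatrix <- function(x, samples = sampleNames(x)) {
  v <- x[, samples]
  d <- matrix(NA_real_, numVariants(v), length(samples))
  d[v@gt == "0/0"] <- 0
  d[v@gt == "0/1"] <- 1
  d[v@gt == "1/1"] <- 2
  called <- rowSums(!is.na(d))
  keep <- called > 0
  if (!any(keep)) stop("all variants have zero called samples")
  d <- d[keep, , drop = FALSE]
  rowMu <- rowMeans(d, na.rm = TRUE)
  nImp <- sum(is.na(d))
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- rowMu[idx[, 1]]
  out <- t(d)
  dimnames(out) <- list(samples, variantKeys(x)[keep])
  attr(out, "imputed") <- nImp
  out
}

#' Principal components of the dosage matrix
#'
#' Columns (variants) are centered and scaled by their standard
#' deviation (zero-variance columns dropped), and the decomposition is
#' computed by SVD. Variance explained per component is the squared
#' singular value over the total. For a reproducible sign convention,
#' each component's largest-magnitude variant loading is made positive.
#'
#' @param dosage samples x variants matrix from
#'   \code{\link{buildDosageMatrix}}.
#' @param nComponents number of components to return (truncated to the
#'   matrix rank bound with a message if larger).
#' @param scale divide columns by their SD (default TRUE, standard
#'   practice so common and rare variants weigh comparably).
#' @return List with \code{coordinates} (samples x components),
#'   \code{varianceExplained} (fraction per returned component), and
#'   \code{loadings}.
#' @export
pcaDosage <- function(dosage, nComponents = 10, scale = TRUE) {
  if (nrow(dosage) < 2L || ncol(dosage) < 2L)
    stop("need at least 2 samples and 2 variants")
  sds <- apply(dosage, 2L, stats::sd)
  keep <- sds > 0
  m <- scale(dosage[, keep, drop = FALSE], center = TRUE,
             scale = if (scale) sds[keep] else FALSE)
  kmax <- min(dim(m)) - 1L   # centering removes one dimension
  kmax <- max(kmax, 1L)
  if (nComponents > kmax) {
    message("nComponents truncated to ", kmax)
    nComponents <- kmax
  }
  sv <- svd(m)
  tot <- sum(sv$d^2)
  k <- seq_len(nComponents)
  u <- sv$u[, k, drop = FALSE]
  vv <- sv$v[, k, drop = FALSE]
  for (j in k) {
    s <- sign(vv[which.max(abs(vv[, j])), j])
    if (s < 0) { vv[, j] <- -vv[, j]; u[, j] <- -u[, j] }
  }
  coords <- sweep(u, 2L, sv$d[k], `*`)
  dimnames(coords) <- list(rownames(dosage), paste0("PC", k))
  list(coordinates = coords,
       varianceExplained = sv$d[k]^2 / tot,
       loadings = vv)
}

#' Allele-sharing distance between samples
#'
#' Pairwise distance \code{1 - similarity}, where similarity is the
#' mean over variants of \code{1 - |d_i - d_j| / 2} on alt dosages —
#' identical genotypes share both alleles (distance 0), opposite
#' homozygotes none (distance 1).
#'
#' @param dosage samples x variants matrix.
#' @return A \code{dist} object.
#' @export
alleleSharingDist <- function(dosage) {
  ## mean(|d_i - d_j| / 2) == manhattan distance / (2 * n_variants)
  stats::dist(dosage, method = "manhattan") / (2 * ncol(dosage))
}

#' Hierarchical clustering of samples
#'
#' Average-linkage clustering on the allele-sharing distance. The
#' result is deterministic given the input and can be exported as a
#' Newick tree for external viewers.
#'
#' @param dosage samples x variants matrix from
#'   \code{\link{buildDosageMatrix}}.
#' @param newickPath optional path; when given, the dendrogram is also
#'   written in Newick format (via \pkg{ape}).
#' @return An \code{hclust} object.
#' @export
hierarchicalClusters <- function(dosage, newickPath = NULL) {
  hc <- stats::hclust(alleleSharingDist(dosage), method = "average")
  if (!is.null(newickPath))
    ape::write.tree(ape::as.phylo(hc), file = newickPath)
  hc
}
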