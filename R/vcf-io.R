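#' Read a multi-sample VCF into a VariantSet
#'
#' Parses a VCF 4.x file (plain or gzipped) and extracts the GT, AD, DP
#' and GQ per-genotype fields. Fields absent from FORMAT come back as
#' \code{NA}, never as zero. Multi-allelic ALT fields are kept as single
#' records of class \code{MULTIALLELIC} (their genotypes involving
#' allele indices above 1 are unrepresentable in the biallelic model and
#' read as missing); they are classified and excluded downstream, not
#' split.
#'
#' @param path path to the VCF file.
#' @param layout a \linkS4class{GenomeLayout}; records on chromosomes
#'   not in the layout are rejected, and records must be sorted by
#'   (layout chromosome order, position).
#' @return A \linkS4class{VariantSet}.
#' @export
readVcfFile <- function(path, layout) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- v@fix
  n <- nrow(fix)
  has_gt <- ncol(v@gt) > 1L
  samples <- if (has_gt) colnames(v@gt)[-1L] else character()
  if (n == 0L) {
    return(VariantSet(character(), integer(), character(), character(),
                      samples = samples))
  }
  chrom <- as.character(fix[, "CHROM"])
  unknown <- setdiff(unique(chrom), layout@chrom)
  if (length(unknown))
    stop("VCF contains chromosomes not in the layout: ",
         paste(unknown, collapse = ", "))
  pos <- as.integer(fix[, "POS"])
  co <- match(chrom, layout@chrom)
  if (any(diff(co) < 0) || any(diff(pos)[diff(co) == 0] < 0))
    stop("VCF records are not sorted by (chromosome, position)")
  ref <- toupper(as.character(fix[, "REF"]))
  alt <- toupper(as.character(fix[, "ALT"]))

  ext <- function(el, numeric = FALSE) {
    fmts <- unique(v@gt[, 1L])
    present <- any(vapply(strsplit(fmts, ":"), function(f) el %in% f,
                          logical(1)))
    if (!present) {
      if (numeric) return(.emptyIntMat(n, length(samples), samples))
      return(matrix(NA_character_, n, length(samples),
                    dimnames = list(NULL, samples)))
    }
    m <- suppressWarnings(
      vcfR::extract.gt(v, element = el, as.numeric = numeric))
    dimnames(m) <- list(NULL, samples)
    m
  }

  gt <- ext("GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt %in% c(".", "./.")] <- NA_character_
  gt[gt == "1/0"] <- "0/1"
  gt[!is.na(gt) & !gt %in% c("0/0", "0/1", "1/1")] <- NA_character_

  ad <- ext("AD")
  adRef <- adAlt <- .emptyIntMat(n, length(samples), samples)
  ok <- !is.na(ad) & ad != "."
  if (any(ok)) {
    parts <- strsplit(ad[ok], ",", fixed = TRUE)
    two <- lengths(parts) == 2L
    r <- suppressWarnings(
      as.integer(vapply(parts, `[`, character(1), 1L)))
    a <- suppressWarnings(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, character(1)))
    a <- suppressWarnings(as.integer(a))
    r[!two] <- NA_integer_; a[!two] <- NA_integer_
    adRef[ok] <- r; adAlt[ok] <- a
  }

  dp <- ext("DP", numeric = TRUE); storage.mode(dp) <- "integer"
  gq <- ext("GQ", numeric = TRUE); storage.mode(gq) <- "integer"

  VariantSet(chrom, pos, ref, alt, samples = samples, gt = gt,
             adRef = adRef, adAlt = adAlt, dp = dp, gq = gq)
}

#' Write a VariantSet as VCF 4.2
#'
#' Emits a plain-text VCF with contig header lines taken from the
#' layout, a fixed \code{GT:AD:DP:GQ} FORMAT, and \code{"."} for every
#' absent value. Output is deterministic: writing, reading and writing
#' again produces a byte-identical file.
#'
#' @param x a \linkS4class{VariantSet}, sorted by (layout chromosome
#'   order, position).
#' @param path output path.
#' @param layout a \linkS4class{GenomeLayout} supplying contig headers.
#' @return The path, invisibly.
#' @export
writeVcfFile <- function(x, path, layout) {
  co <- match(x@chrom, layout@chrom)
  if (anyNA(co))
    stop("VariantSet contains chromosomes not in the layout")
  if (any(diff(co) < 0) || any(diff(x@pos)[diff(co) == 0] < 0))
    stop("records must be sorted by (chromosome, position) before writing")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", layout@chrom, layout@length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", x@samples), collapse = "\t")
  )
  n <- length(x@chrom)
  body <- character(0)
  if (n) {
    dot <- function(m) ifelse(is.na(m), ".", as.character(m))
    gt <- ifelse(is.na(x@gt), "./.", x@gt)
    ad <- ifelse(is.na(x@adRef) | is.na(x@adAlt), ".",
                 paste(x@adRef, x@adAlt, sep = ","))
    dim(ad) <- dim(x@gt)
    cells <- matrix(paste(gt, ad, dot(x@dp), dot(x@gq), sep = ":"),
                    n, length(x@samples))
    geno <- if (length(x@samples))
      apply(cells, 1L, paste, collapse = "\t") else character(n)
    lead <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:AD:DP:GQ",
                    x@chrom, x@pos, x@ref, x@alt)
    body <- if (length(x@samples)) paste(lead, geno, sep = "\t") else lead
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
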