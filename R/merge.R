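#' Partition variant keys by dataset membership
#'
#' Reimplements allele-aware intersection (bcftools-isec semantics): a
#' key matches across call sets iff chromosome, position, ref and alt
#' are all equal. Returns the exact set-union partition.
#'
#' @param s1Keys,s2Keys,lKeys character vectors of canonical key strings
#'   (\code{"chrom:pos:ref:alt"}, see \code{\link{variantKeys}}), each
#'   duplicate-free.
#' @return A \code{data.frame} with columns \code{key}, \code{S1},
#'   \code{S2}, \code{L} (logical membership flags), one row per key in
#'   the union, in first-seen order.
#' @export
partitionMembership <- function(s1Keys, s2Keys, lKeys) {
  for (nm in c("s1Keys", "s2Keys", "lKeys")) {
    k <- get(nm)
    if (anyDuplicated(k))
      stop(sprintf("duplicate key within %s: %s", nm,
                   k[duplicated(k)][1]))
  }
  all <- unique(c(s1Keys, s2Keys, lKeys))
  data.frame(key = all,
             S1 = all %in% s1Keys,
             S2 = all %in% s2Keys,
             L = all %in% lKeys,
             stringsAsFactors = FALSE)
}

#' Chromosome-class-specific merge rules
#'
#' The final catalog's inclusion rule depends on the chromosome class,
#' reflecting which datasets can observe each class: autosomes and X
#' require a variant in all three call sets; Y only in the
#' individual-short-read set (the other sets are female-only or
#' Y-poor); MT in both short-read sets (long reads do not map to the
#' short mitochondrial sequence). Rules are data: each class maps to the
#' set of datasets that must all contain the key (an empty requirement
#' accepts any key).
#'
#' @return Named list mapping chromosome class to required dataset tags.
#' @export
defaultMergeRules <- function() {
  list(AUTOSOME = c("S1", "S2", "L"),
       X = c("S1", "S2", "L"),
       Y = "S1",
       MT = c("S1", "S2"))
}

#' Apply merge rules to a membership partition
#'
#' @param partition output of \code{\link{partitionMembership}}.
#' @param layout a \linkS4class{GenomeLayout} mapping each key's
#'   chromosome to its class.
#' @param rules named list as from \code{\link{defaultMergeRules}}: for
#'   each chromosome class, the dataset tags that must all contain the
#'   key for it to be retained.
#' @return Character vector of retained keys, in partition order.
#' @export
applyMergeRules <- function(partition, layout, rules = defaultMergeRules()) {
  chrom <- sub(":.*", "", partition$key)
  cls <- chromClasses(layout)[chrom]
  if (anyNA(cls))
    stop("key(s) on chromosomes absent from the layout: ",
         partition$key[which(is.na(cls))[1]])
  noRule <- setdiff(unique(cls), names(rules))
  if (length(noRule))
    stop("no merge rule for chromosome class: ",
         paste(noRule, collapse = ", "))
  memb <- as.matrix(partition[, c("S1", "S2", "L")])
  keep <- vapply(seq_len(nrow(partition)), function(i) {
    req <- rules[[cls[i]]]
    all(memb[i, req])
  }, logical(1))
  partition$key[keep]
}

#' Merge filtered call sets into one genotype matrix
#'
#' Builds one record per retained key with one column per sample across
#' all datasets. A sample's entry is taken from its dataset of origin;
#' samples whose dataset lacks the key get all-absent entries. No
#' cross-dataset genotype reconciliation is attempted: each sample
#' belongs to exactly one dataset.
#'
#' @param finalKeys keys retained by \code{\link{applyMergeRules}}.
#' @param s1,s2,l the three filtered \linkS4class{VariantSet}s.
#' @param meta sample metadata with \code{sample_id} and \code{dataset}
#'   columns; every sample must occur in exactly one input.
#' @param layout a \linkS4class{GenomeLayout} used to order the output.
#' @return A unified \linkS4class{VariantSet} over all samples, sorted
#'   by (layout chromosome order, position, ref, alt).
#' @export
mergeGenotypes <- function(finalKeys, s1, s2, l, meta, layout) {
  sets <- list(S1 = s1, S2 = s2, L = l)
  allSamp <- unlist(lapply(sets, sampleNames), use.names = FALSE)
  if (anyDuplicated(allSamp))
    stop("sample present in more than one dataset: ",
         allSamp[duplicated(allSamp)][1])
  ds <- meta$dataset[match(allSamp, meta$sample_id)]
  if (anyNA(ds)) stop("sample(s) missing from metadata")

  parts <- strsplit(finalKeys, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  ref <- vapply(parts, `[`, character(1), 3L)
  alt <- vapply(parts, `[`, character(1), 4L)
  out <- VariantSet(chrom, pos, ref, alt, samples = allSamp)
  for (tag in names(sets)) {
    v <- sets[[tag]]
    if (!numVariants(v) || !length(v@samples)) next
    hit <- match(finalKeys, variantKeys(v))
    rows <- which(!is.na(hit))
    if (!length(rows)) next
    cols <- match(v@samples, allSamp)
    out@gt[rows, cols] <- v@gt[hit[rows], , drop = FALSE]
    out@adRef[rows, cols] <- v@adRef[hit[rows], , drop = FALSE]
    out@adAlt[rows, cols] <- v@adAlt[hit[rows], , drop = FALSE]
    out@dp[rows, cols] <- v@dp[hit[rows], , drop = FALSE]
    out@gq[rows, cols] <- v@gq[hit[rows], , drop = FALSE]
  }
  .orderVariants(out, layout)
}
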