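## Shared desk-scale fixtures, all built in code.

tinyLayout <- function() {
  GenomeLayout(
    chrom = c("c1", "c2", "cX", "cY", "cM"),
    length = c(2e6, 1e6, 8e5, 5e5, 16000),
    class = c("AUTOSOME", "AUTOSOME", "X", "Y", "MT"))
}

## A VariantSet of n autosomal SNPs on one chromosome with explicit
## field matrices (recycled scalars allowed).
snpSet <- function(pos, samples, gt = NULL, dp = NULL, gq = NULL,
                   adRef = NULL, adAlt = NULL, chrom = "c1") {
  n <- length(pos)
  m <- length(samples)
  fill <- function(x, default) {
    if (is.null(x)) return(NULL)
    matrix(x, n, m)
  }
  VariantSet(rep(chrom, n), pos, rep("A", n), rep("G", n),
             samples = samples, gt = fill(gt), dp = fill(dp),
             gq = fill(gq), adRef = fill(adRef), adAlt = fill(adAlt))
}

## Minimal metadata for hand-built call sets.
miniMeta <- function(samples, group = "MED", dataset = "S1",
                     is_pool = FALSE, sex = "M") {
  data.frame(sample_id = samples,
             group = rep_len(group, length(samples)),
             sex = rep_len(sex, length(samples)),
             dataset = rep_len(dataset, length(samples)),
             is_pool = rep_len(is_pool, length(samples)),
             pool_size = ifelse(rep_len(is_pool, length(samples)),
                                5L, 1L),
             depth = 30)
}

## Disabled-QC config: no genotype masks, vacuous missingness filter.
noQcConfig <- function() FilterConfig(maxMissing = 1)

losslessPipelineConfig <- function(nVariants = 400, seed = 11) {
  pipelineConfig(
    nVariants = nVariants, seed = seed,
    profiles = losslessProfiles(),
    filterConfigs = list(S1 = noQcConfig(), S2 = noQcConfig(),
                         L = noQcConfig()),
    stages = character(0))
}

key4 <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
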