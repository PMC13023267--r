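#' Miniature default genome layout
#'
#' A desk-scale layout used by the simulator: five autosomes of 3-8
#' Mbp, an X, a Y and a mitochondrial chromosome. A full-size layout
#' (e.g. 24 autosomes + X + Y + MT) is expressible through the same
#' table and \code{\link{readGenomeLayout}}.
#'
#' @return A \linkS4class{GenomeLayout}.
#' @export
defaultGenomeLayout <- function() {
  GenomeLayout(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chr5", "chrX", "chrY",
              "chrMT"),
    length = c(8e6, 6e6, 5e6, 4e6, 3e6, 5e6, 2e6, 16500),
    class = c(rep("AUTOSOME", 5), "X", "Y", "MT"))
}

#' Default sample metadata for the three simulated call sets
#'
#' Mirrors the study composition: dataset S1 holds 22 male individuals
#' (11 MED, 5 RIV, 6 SWA) with depths spread evenly over 3-40x plus two
#' male MED DNA pools (18 and 3 animals, 30x); S2 holds 24 MED females
#' at 28-56x; L holds 8 MED males at 25-63x.
#'
#' @return \code{data.frame} with columns \code{sample_id},
#'   \code{group}, \code{sex}, \code{dataset}, \code{is_pool},
#'   \code{pool_size}, \code{depth}.
#' @export
defaultSampleMeta <- function() {
  s1i <- data.frame(
    sample_id = c(sprintf("MED_S1_%02d", 1:11),
                  sprintf("RIV_S1_%02d", 1:5),
                  sprintf("SWA_S1_%02d", 1:6)),
    group = c(rep("MED", 11), rep("RIV", 5), rep("SWA", 6)),
    sex = "M", dataset = "S1", is_pool = FALSE, pool_size = 1L,
    depth = seq(3, 40, length.out = 22))
  s1p <- data.frame(
    sample_id = c("S1_POOL1", "S1_POOL2"), group = "MED", sex = "M",
    dataset = "S1", is_pool = TRUE, pool_size = c(18L, 3L), depth = 30)
  s2 <- data.frame(
    sample_id = sprintf("MED_S2_%02d", 1:24), group = "MED", sex = "F",
    dataset = "S2", is_pool = FALSE, pool_size = 1L,
    depth = seq(28, 56, length.out = 24))
  l <- data.frame(
    sample_id = sprintf("MED_L_%02d", 1:8), group = "MED", sex = "M",
    dataset = "L", is_pool = FALSE, pool_size = 1L,
    depth = seq(25, 63, length.out = 8))
  rbind(s1i, s1p, s2, l)
}

#' Validate a sample metadata table
#'
#' @param meta a \code{data.frame} as from \code{\link{defaultSampleMeta}}.
#' @return \code{meta}, invisibly; errors describe the violation.
#' @export
validateSampleMeta <- function(meta) {
  need <- c("sample_id", "group", "sex", "dataset", "is_pool",
            "pool_size")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id")
  if (!all(meta$group %in% GROUP_LABELS)) stop("unknown group label")
  if (!all(meta$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (!all(meta$dataset %in% DATASET_TAGS)) stop("unknown dataset tag")
  if (any(meta$pool_size > 1L & !meta$is_pool))
    stop("pool_size > 1 requires is_pool = TRUE")
  if (any(meta$is_pool & meta$pool_size < 2L))
    stop("pools must have pool_size >= 2")
  if (any(meta$dataset == "S2" & meta$sex != "F"))
    stop("dataset S2 samples must all be female")
  invisible(meta)
}

#' Per-dataset noise and dropout profiles
#'
#' Each profile sets the noise regime of one call set: the genotype
#' error rate (probability an emitted GT differs from truth), the base
#' error rate (probability a read carries the wrong allele), whether
#' GT/GQ are withheld (pools), whether the dataset drops MT records
#' (long reads do not map to the short mitochondrial sequence), and
#' the site dropout rate (fraction of truth sites the dataset fails to
#' discover, making intersections nontrivial). Depth ranges follow the
#' three sequencing regimes (3-40x, 28-56x, 25-63x) and live in the
#' sample metadata.
#'
#' @return Named list of profiles for \code{S1}, \code{S2}, \code{L}.
#' @export
defaultDatasetProfiles <- function() {
  list(
    S1 = list(genotypeErrorRate = 0.02, baseErrorRate = 0.005,
              dropMt = FALSE, dropoutRate = 0.05, mnpFraction = 0),
    S2 = list(genotypeErrorRate = 0.01, baseErrorRate = 0.005,
              dropMt = FALSE, dropoutRate = 0.05, mnpFraction = 0.02),
    L  = list(genotypeErrorRate = 0.02, baseErrorRate = 0.01,
              dropMt = TRUE, dropoutRate = 0.05, mnpFraction = 0)
  )
}

#' Noise-free dataset profiles for the lossless limit
#'
#' All error, dropout and MNP-encoding rates set to zero. With QC
#' disabled, a study simulated under these profiles conserves the
#' truth list exactly through filtering and merging — the end-to-end
#' conservation check.
#'
#' @return Named list of profiles for \code{S1}, \code{S2}, \code{L}.
#' @export
losslessProfiles <- function() {
  p <- list(genotypeErrorRate = 0, baseErrorRate = 0, dropMt = FALSE,
            dropoutRate = 0, mnpFraction = 0)
  list(S1 = p, S2 = p, L = c(p[setdiff(names(p), "dropMt")],
                             list(dropMt = TRUE)))
}

#' Simulate ground-truth variants under a Balding-Nichols model
#'
#' Draws \code{nVariants} biallelic SNP sites: positions uniform
#' without replacement within chromosomes, chromosomes chosen
#' proportional to length; ancestral frequencies uniform on
#' [0.05, 0.95]; each group's frequency from a Beta distribution with
#' mean equal to the ancestral frequency p and variance
#' \code{fst * p * (1 - p)} (the standard minimal FST divergence
#' model; \code{fst = 0} degenerates to the ancestral frequency).
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param nVariants number of sites (>= 1).
#' @param fst named vector of FST values in [0, 1) per group.
#' @param seed integer seed; identical seeds give identical tables.
#' @return \code{data.frame}: \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{key}, \code{chrom_class},
#'   \code{ancestral_freq}, and one \code{freq_<group>} column per
#'   group, sorted by (layout order, position).
#' @export
simulateTruth <- function(layout, nVariants,
                          fst = c(MED = 0.05, RIV = 0.10, SWA = 0.35),
                          seed = 1) {
  .assertCount(nVariants, "nVariants", min = 1)
  if (any(fst < 0 | fst >= 1)) stop("fst values must be in [0, 1)")
  if (nVariants > sum(as.numeric(layout@length)))
    stop("nVariants exceeds the number of available positions")
  .withSeed(seed, {
    chromIdx <- sample.int(length(layout@chrom), nVariants,
                           replace = TRUE,
                           prob = as.numeric(layout@length))
    counts <- tabulate(chromIdx, nbins = length(layout@chrom))
    if (any(counts > layout@length))
      stop("a chromosome was allocated more variants than positions")
    chrom <- pos <- vector("list", length(layout@chrom))
    for (i in seq_along(layout@chrom)) {
      if (!counts[i]) next
      pos[[i]] <- sort(sample.int(layout@length[i], counts[i]))
      chrom[[i]] <- rep(layout@chrom[i], counts[i])
    }
    chrom <- unlist(chrom); pos <- as.integer(unlist(pos))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nVariants, replace = TRUE)
    shift <- sample.int(3L, nVariants, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + shift) %% 4L + 1L]
    p <- stats::runif(nVariants, 0.05, 0.95)
    out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      key = .keyString(chrom, pos, ref, alt),
                      chrom_class = unname(chromClasses(layout)[chrom]),
                      ancestral_freq = p, stringsAsFactors = FALSE)
    for (g in names(fst)) {
      f <- fst[[g]]
      out[[paste0("freq_", g)]] <- if (f == 0) p else
        stats::rbeta(nVariants, p * (1 - f) / f,
                     (1 - p) * (1 - f) / f)
    }
    out
  })
}

## True dosages for one individual across all truth sites, honoring
## sex/chromosome ploidy: diploid HWE on autosomes (and female X),
## haploid {0,2} on male X, Y and MT; NA on Y for females.
.drawTrueDosage <- function(truth, freqCol, sex) {
  p <- truth[[freqCol]]
  n <- nrow(truth)
  cls <- truth$chrom_class
  dos <- stats::rbinom(n, 2L, p)
  haploid <- cls == "MT" | (sex == "M" & cls %in% c("X", "Y"))
  dos[haploid] <- 2L * stats::rbinom(sum(haploid), 1L, p[haploid])
  if (sex == "F") dos[cls == "Y"] <- NA_integer_
  dos
}

#' Simulate noisy per-individual calls
#'
#' For each individual: the true genotype is drawn from Hardy-Weinberg
#' proportions at its group's frequency (haploid on male X, Y and MT;
#' Y missing for females); per-site depth is Poisson at the sample's
#' mean depth; the alt read count is Binomial(DP, q) with
#' \code{q = (d/2)(1-e) + (1-d/2)e} for dosage d and base error e; the
#' emitted genotype equals the truth with probability
#' \code{1 - genotypeErrorRate}, otherwise a random other genotype;
#' zero depth yields a missing genotype; GQ rises stochastically with
#' depth (\code{3*DP} plus Gaussian noise, clamped to [0, 99]) so the
#' GQ 20/30 thresholds bite at the intended depth regimes.
#'
#' @param truth output of \code{\link{simulateTruth}}.
#' @param samples metadata rows for individuals (\code{is_pool} all
#'   FALSE) with a \code{depth} column.
#' @param profile one element of \code{\link{defaultDatasetProfiles}}.
#' @param seed integer seed.
#' @return List: \code{vset}, a \linkS4class{VariantSet} over the
#'   truth sites, and \code{trueDosage}, the sites x samples matrix of
#'   true alt dosages (NA where no genotype exists, e.g. female Y).
#' @export
simulateIndividualCalls <- function(truth, samples, profile, seed = 1) {
  if (any(samples$is_pool))
    stop("simulateIndividualCalls takes individuals only")
  n <- nrow(truth); m <- nrow(samples)
  e <- profile$baseErrorRate
  ge <- profile$genotypeErrorRate
  .withSeed(seed, {
    trueDos <- matrix(NA_integer_, n, m,
                      dimnames = list(NULL, samples$sample_id))
    gt <- matrix(NA_character_, n, m)
    adR <- adA <- dp <- gq <- matrix(NA_integer_, n, m)
    gtStr <- c("0/0", "0/1", "1/1")
    for (j in seq_len(m)) {
      dos <- .drawTrueDosage(truth, paste0("freq_", samples$group[j]),
                             samples$sex[j])
      trueDos[, j] <- dos
      ok <- !is.na(dos)
      dpj <- stats::rpois(n, samples$depth[j])
      q <- (dos / 2) * (1 - e) + (1 - dos / 2) * e
      aa <- integer(n)
      aa[ok] <- stats::rbinom(sum(ok), dpj[ok], q[ok])
      g <- gtStr[dos + 1L]
      flip <- ok & stats::runif(n) < ge
      if (any(flip)) {
        g[flip] <- vapply(g[flip], function(cur)
          sample(setdiff(gtStr, cur), 1L), character(1))
      }
      g[!ok | dpj == 0L] <- NA_character_
      gqj <- as.integer(pmax(0, pmin(99, round(
        3 * dpj + stats::rnorm(n, 0, 6)))))
      gt[, j] <- g
      dp[ok, j] <- dpj[ok]
      adA[ok, j] <- aa[ok]
      adR[ok, j] <- dpj[ok] - aa[ok]
      gq[ok, j] <- gqj[ok]
    }
    list(vset = VariantSet(truth$chrom, truth$pos, truth$ref,
                           truth$alt, samples = samples$sample_id,
                           gt = gt, adRef = adR, adAlt = adA, dp = dp,
                           gq = gq),
         trueDosage = trueDos)
  })
}

#' Simulate pool-seq calls
#'
#' A DNA pool of N animals contributes haplotypes, not genotypes:
#' per site the pool's alt-haplotype count is Binomial(H, p) with H
#' haplotypes (2N on autosomes and female X; N on male-pool X, Y and
#' MT), depth is Poisson at the pool's mean depth, and the alt read
#' count is Binomial(DP, q) with q the alt-haplotype fraction adjusted
#' by the base error rate. GT is emitted missing and GQ absent —
#' pools carry AD/DP only and therefore enter allele-frequency sums
#' but never call rates.
#'
#' @param truth output of \code{\link{simulateTruth}}.
#' @param poolMeta one metadata row with \code{is_pool = TRUE} and
#'   \code{pool_size >= 2}.
#' @param profile one element of \code{\link{defaultDatasetProfiles}}.
#' @param seed integer seed.
#' @return A one-sample \linkS4class{VariantSet} over the truth sites.
#' @export
simulatePoolCalls <- function(truth, poolMeta, profile, seed = 1) {
  if (!isTRUE(poolMeta$is_pool[1]) || poolMeta$pool_size[1] < 2L)
    stop("simulatePoolCalls requires a pool with pool_size >= 2")
  n <- nrow(truth)
  e <- profile$baseErrorRate
  N <- poolMeta$pool_size[1]
  p <- truth[[paste0("freq_", poolMeta$group[1])]]
  cls <- truth$chrom_class
  .withSeed(seed, {
    H <- rep(2L * N, n)
    if (poolMeta$sex[1] == "M") H[cls %in% c("X", "Y")] <- N
    H[cls == "MT"] <- N
    altHap <- stats::rbinom(n, H, p)
    qhap <- altHap / H
    dpv <- stats::rpois(n, poolMeta$depth[1])
    q <- qhap * (1 - e) + (1 - qhap) * e
    aa <- stats::rbinom(n, dpv, q)
    VariantSet(truth$chrom, truth$pos, truth$ref, truth$alt,
               samples = poolMeta$sample_id[1],
               gt = matrix(NA_character_, n, 1),
               adRef = matrix(as.integer(dpv - aa)),
               adAlt = matrix(as.integer(aa)),
               dp = matrix(as.integer(dpv)),
               gq = matrix(NA_integer_, n, 1))
  })
}

## Re-encode a fraction of SNP rows as 2-bp MNPs whose decomposition
## restores the original SNP (a shared trailing base is appended), so
## the MNP-normalization step of the S2 chain is exercised without
## changing the site content.
.mnpEncode <- function(x, fraction, seed) {
  if (fraction <= 0) return(x)
  .withSeed(seed, {
    snp <- which(classifyVariant(x@ref, x@alt) == "SNP")
    k <- floor(length(snp) * fraction)
    if (!k) return(x)
    pick <- sort(sample(snp, k))
    pad <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    x@ref[pick] <- paste0(x@ref[pick], pad)
    x@alt[pick] <- paste0(x@alt[pick], pad)
    x
  })
}

#' Simulate the full three-dataset study
#'
#' Generates the truth table and the three call sets with their
#' characteristic structure: S1 carries individuals of all three
#' groups across the 3-40x depth range plus two MED pools; S2 carries
#' MED females only (so no Y records); L carries 8 MED males and no MT
#' records. Each dataset's site list is the truth list minus its
#' random dropouts; a fraction of S2 records is MNP-encoded to
#' exercise normalization. Fully deterministic given the seed.
#'
#' @param layout a \linkS4class{GenomeLayout}.
#' @param meta sample metadata (validated).
#' @param nVariants number of truth sites.
#' @param fst named per-group FST vector.
#' @param profiles per-dataset noise profiles.
#' @param seed top-level seed, fanned out to per-stage seeds.
#' @param dir optional output directory; when given, writes
#'   \code{wgs_s1.vcf}, \code{wgs_s2.vcf}, \code{wgs_l.vcf},
#'   \code{samples.tsv}, \code{truth.tsv} and \code{layout.tsv}.
#' @return List: \code{layout}, \code{meta}, \code{truth},
#'   \code{vsets} (named list of the three \linkS4class{VariantSet}s),
#'   \code{trueDosage} (sites x individuals matrix), and \code{paths}
#'   when \code{dir} was given.
#' @export
simulateStudy <- function(layout = defaultGenomeLayout(),
                          meta = defaultSampleMeta(),
                          nVariants = 3000,
                          fst = c(MED = 0.05, RIV = 0.10, SWA = 0.35),
                          profiles = defaultDatasetProfiles(),
                          seed = 1, dir = NULL) {
  validateSampleMeta(meta)
  truth <- simulateTruth(layout, nVariants, fst = fst,
                         seed = .stageSeed(seed, "truth"))
  vsets <- list()
  trueDos <- NULL
  tagSeeds <- c(S1 = .stageSeed(seed, "s1"), S2 = .stageSeed(seed, "s2"),
                L = .stageSeed(seed, "l"))
  for (tag in DATASET_TAGS) {
    prof <- profiles[[tag]]
    dsMeta <- meta[meta$dataset == tag, , drop = FALSE]
    ind <- dsMeta[!dsMeta$is_pool, , drop = FALSE]
    sim <- simulateIndividualCalls(truth, ind, prof,
                                   seed = tagSeeds[[tag]])
    v <- sim$vset
    trueDos <- if (is.null(trueDos)) sim$trueDosage else
      cbind(trueDos, sim$trueDosage)
    pools <- dsMeta[dsMeta$is_pool, , drop = FALSE]
    if (nrow(pools)) {
      for (pi in seq_len(nrow(pools))) {
        pv <- simulatePoolCalls(truth, pools[pi, , drop = FALSE], prof,
                                seed = tagSeeds[[tag]] + pi)
        v <- .cbindSamples(v, pv)
      }
    }
    ## dataset-specific site dropouts and structural absences
    keep <- rep(TRUE, nrow(truth))
    if (prof$dropoutRate > 0) {
      keep <- .withSeed(tagSeeds[[tag]] + 97L,
                        stats::runif(nrow(truth)) >= prof$dropoutRate)
    }
    if (all(dsMeta$sex == "F")) keep <- keep & truth$chrom_class != "Y"
    if (isTRUE(prof$dropMt)) keep <- keep & truth$chrom_class != "MT"
    v <- v[keep, ]
    if (prof$mnpFraction > 0)
      v <- .mnpEncode(v, prof$mnpFraction, tagSeeds[[tag]] + 131L)
    vsets[[tag]] <- v
  }
  out <- list(layout = layout, meta = meta, truth = truth,
              vsets = vsets, trueDosage = trueDos)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      S1 = file.path(dir, "wgs_s1.vcf"),
      S2 = file.path(dir, "wgs_s2.vcf"),
      L = file.path(dir, "wgs_l.vcf"),
      meta = file.path(dir, "samples.tsv"),
      truth = file.path(dir, "truth.tsv"),
      layout = file.path(dir, "layout.tsv"))
    for (tag in DATASET_TAGS)
      writeVcfFile(vsets[[tag]], paths[[tag]], layout)
    utils::write.table(meta, paths$meta, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeGenomeLayout(layout, paths$layout)
    out$paths <- paths
  }
  out
}

## Column-bind two VariantSets over identical sites.
.cbindSamples <- function(a, b) {
  stopifnot(identical(variantKeys(a), variantKeys(b)))
  VariantSet(a@chrom, a@pos, a@ref, a@alt,
             samples = c(a@samples, b@samples),
             gt = cbind(a@gt, b@gt), adRef = cbind(a@adRef, b@adRef),
             adAlt = cbind(a@adAlt, b@adAlt), dp = cbind(a@dp, b@dp),
             gq = cbind(a@gq, b@gq))
}
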