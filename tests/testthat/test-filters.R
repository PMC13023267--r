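test_that("genotype masking honors DP/GQ thresholds and exemptions", {
  v <- snpSet(1:3, c("s1", "s2"),
              gt = "0/1",
              dp = matrix(c(4L, 12L, 8L, 10L, 12L, 9L), 3, 2),
              gq = matrix(c(50L, 25L, 40L, 35L, 31L, NA), 3, 2))
  ## minDP 5 masks the DP=4 genotype only
  m1 <- maskGenotypes(v, FilterConfig(minDp = 5))
  expect_true(is.na(gtMatrix(m1)[1, "s1"]))
  expect_equal(sum(is.na(gtMatrix(m1))), 1L)
  expect_equal(numVariants(m1), 3L)          # masking never drops sites
  expect_identical(dpMatrix(m1), dpMatrix(v)) # AD/DP retained

  ## S2-style GQ 30 + DP 10: GQ 25 masked, absent GQ masked too
  m2 <- maskGenotypes(v, FilterConfig(minGq = 30, minDp = 10))
  expect_true(is.na(gtMatrix(m2)[2, "s1"]))  # GQ 25
  expect_true(is.na(gtMatrix(m2)[3, "s2"]))  # GQ absent
  expect_equal(attr(m2, "maskLog")[["nMaskedAbsentField"]], 1)

  ## exempt samples untouched
  m3 <- maskGenotypes(v, FilterConfig(minDp = 5,
                                      exemptSamples = "s1"))
  expect_false(anyNA(gtMatrix(m3)[, "s1"]))

  ## no applicable mask -> identity
  m4 <- maskGenotypes(v, FilterConfig(maxMissing = 0.1))
  expect_identical(gtMatrix(m4), gtMatrix(v))
})

test_that("strict comparisons keep only values above the threshold", {
  v <- snpSet(1:2, "s1", gt = "0/1", dp = matrix(c(5L, 6L)),
              gq = matrix(c(20L, 21L)))
  lax <- maskGenotypes(v, FilterConfig(minDp = 5, minGq = 20))
  expect_false(anyNA(gtMatrix(lax)))
  strict <- maskGenotypes(v, FilterConfig(minDp = 5, minGq = 20,
                                          strict = TRUE))
  expect_true(is.na(gtMatrix(strict)[1, 1]))
  expect_false(is.na(gtMatrix(strict)[2, 1]))
})

test_that("site missingness dialects implement both conventions", {
  samples <- paste0("s", 1:10)
  gt <- matrix("0/1", 3, 10)
  gt[2, 1:2] <- NA          # 0.2 missing
  gt[3, 1:5] <- NA          # 0.5 missing
  v <- snpSet(c(10, 20, 30), samples, gt = gt)
  ## prose reading: missing fraction <= 0.1
  kept <- siteMissingnessFilter(v, 0.1, dialect = "PROSE")
  expect_equal(variantKeys(kept), variantKeys(v)[1])
  ## vcftools convention: called fraction >= 0.1 keeps all three
  kept2 <- siteMissingnessFilter(v, 0.1, dialect = "VCFTOOLS")
  expect_equal(numVariants(kept2), 3L)
  ## vacuous prose threshold keeps everything
  expect_equal(numVariants(siteMissingnessFilter(v, 1, dialect = "PROSE")),
               3L)
  expect_error(siteMissingnessFilter(v, 0.1, eligibleSamples = character()),
               "nonempty")
})

test_that("carrier filter counts alt-bearing samples", {
  gt <- matrix("0/0", 3, 8)
  gt[1, 1:2] <- "0/1"       # 2 carriers -> kept at minCarriers 2
  gt[2, 1] <- "1/1"         # 1 carrier  -> dropped
  v <- snpSet(c(5, 6, 7), paste0("s", 1:8), gt = gt)
  kept <- minCarrierFilter(v, 2)
  expect_equal(variantKeys(kept), variantKeys(v)[1])
  ## minCarriers = 1 removes exactly the all-reference sites
  kept1 <- minCarrierFilter(v, 1)
  bruteCarriers <- apply(gt, 1, function(g)
    sum(g %in% c("0/1", "1/1"), na.rm = TRUE))
  expect_equal(variantKeys(kept1), variantKeys(v)[bruteCarriers >= 1])
})

test_that("sample missingness reports per-sample fractions; pools are 1", {
  gt <- matrix("0/1", 10, 2)
  gt[1:3, 1] <- NA
  v <- snpSet(1:10, c("ind", "pool"), gt = gt)
  v@gt[, "pool"] <- NA_character_
  miss <- sampleMissingness(v)
  expect_equal(miss[["ind"]], 0.3)
  expect_equal(miss[["pool"]], 1.0)
})

test_that("masking and site filtering are separable and monotone", {
  set.seed(5)
  n <- 40; samples <- paste0("s", 1:6)
  gt <- matrix(sample(c("0/0", "0/1", "1/1"), n * 6, replace = TRUE),
               n, 6)
  dp <- matrix(rpois(n * 6, 8), n, 6)
  v <- snpSet(seq_len(n) * 100, samples, gt = gt, dp = dp)
  cfg <- FilterConfig(minDp = 5)
  ## masking is per-genotype: masking commutes with taking the kept
  ## subset, so the two effects compose in either order
  keepKeys <- variantKeys(siteMissingnessFilter(maskGenotypes(v, cfg),
                                                0.2))
  idx <- match(keepKeys, variantKeys(v))
  a <- maskGenotypes(v, cfg)[idx, ]
  b <- maskGenotypes(v[idx, ], cfg)
  expect_identical(gtMatrix(a), gtMatrix(b))
  expect_identical(variantKeys(a), variantKeys(b))
  ## monotonicity: stricter minDP never keeps more sites
  surv <- function(t) variantKeys(
    siteMissingnessFilter(maskGenotypes(v, FilterConfig(minDp = t)),
                          0.2))
  expect_true(all(surv(10) %in% surv(5)))
  expect_true(all(surv(5) %in% surv(2)))
})

test_that("filter survivors match a brute-force reference on a fixture", {
  set.seed(9)
  n <- 20; m <- 8
  samples <- paste0("s", seq_len(m))
  gt <- matrix(sample(c("0/0", "0/1", "1/1", NA), n * m, replace = TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)), n, m)
  dp <- matrix(sample(0:20, n * m, replace = TRUE), n, m)
  v <- snpSet(seq_len(n) * 50, samples, gt = gt, dp = dp)
  got <- siteMissingnessFilter(maskGenotypes(v, FilterConfig(minDp = 5)),
                               0.25)
  ## independent per-record loop
  keep <- logical(n)
  for (i in seq_len(n)) {
    g <- gt[i, ]
    g[dp[i, ] < 5] <- NA
    keep[i] <- mean(is.na(g)) <= 0.25
  }
  expect_equal(variantKeys(got), variantKeys(v)[keep])
})

test_that("dataset pipelines compose their stage chains", {
  meta8 <- miniMeta(paste0("L", 1:8), dataset = "L")
  gt <- matrix("0/0", 2, 8)
  gt[1, 1] <- "0/1"         # singleton carrier
  gt[2, 1:3] <- "0/1"
  v <- snpSet(c(100, 200), paste0("L", 1:8), gt = gt, dp = 20L,
              gq = 50L)
  out <- datasetPipeline("L", v, meta8)
  ## singleton survives the masks but dies at the 2-of-8 carrier rule
  expect_equal(variantKeys(out), variantKeys(v)[2])

  ## S2: an MNP is decomposed and each child obeys the masks
  metaS2 <- miniMeta(c("F1", "F2"), dataset = "S2", sex = "F")
  mv <- VariantSet("c1", 300, "AT", "GC", samples = c("F1", "F2"),
                   gt = matrix(c("0/1", "1/1"), 1, 2),
                   dp = matrix(c(30L, 4L), 1, 2),
                   gq = matrix(c(60L, 60L), 1, 2))
  out2 <- datasetPipeline("S2", mv, metaS2,
                          config = FilterConfig(minGq = 30, minDp = 10,
                                                maxMissing = 1))
  expect_equal(variantKeys(out2), c("c1:300:A:G", "c1:301:T:C"))
  expect_true(all(is.na(gtMatrix(out2)[, "F2"])))  # DP 4 masked

  ## disabled thresholds reduce to the biallelic-SNP subset
  mixed <- VariantSet(c("c1", "c1", "c1"), c(10, 20, 30),
                      c("A", "A", "AT"), c("G", "G,T", "A"),
                      samples = "L1",
                      gt = matrix(c("0/1", NA, NA), 3, 1))
  out3 <- datasetPipeline("L", mixed, miniMeta("L1", dataset = "L"),
                          config = noQcConfig())
  expect_equal(variantKeys(out3), "c1:10:A:G")
})
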