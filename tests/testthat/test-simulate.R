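test_that("truth tables are deterministic with Balding-Nichols structure", {
  gl <- tinyLayout()
  t1 <- simulateTruth(gl, 500, seed = 5)
  t2 <- simulateTruth(gl, 500, seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulateTruth(gl, 500, seed = 6)))

  ## zero divergence: group frequency equals the ancestral frequency
  t0 <- simulateTruth(gl, 200, fst = c(MED = 0, RIV = 0.2), seed = 2)
  expect_identical(t0$freq_MED, t0$ancestral_freq)
  expect_false(identical(t0$freq_RIV, t0$ancestral_freq))

  ## positions legal and unique per chromosome; frequencies in range
  expect_true(all(t1$pos >= 1 &
                    t1$pos <= chromLengths(gl)[t1$chrom]))
  expect_false(any(duplicated(paste(t1$chrom, t1$pos))))
  expect_true(all(t1$freq_SWA >= 0 & t1$freq_SWA <= 1))
  expect_true(all(t1$ref != t1$alt))
  expect_error(simulateTruth(gl, 1e9, seed = 1), "exceeds")
  expect_error(simulateTruth(gl, 10, fst = c(MED = 1), seed = 1),
               "fst")
})

test_that("group-frequency variance matches fst * p * (1 - p)", {
  tr <- simulateTruth(GenomeLayout("c1", 5e7, "AUTOSOME"), 10000,
                      fst = c(MED = 0.2), seed = 33)
  z <- (tr$freq_MED - tr$ancestral_freq)^2 /
    (tr$ancestral_freq * (1 - tr$ancestral_freq))
  se <- sd(z) / sqrt(length(z))
  expect_lt(abs(mean(z) - 0.2), 3 * se)
})

test_that("individual call noise follows the error model", {
  gl <- tinyLayout()
  tr <- simulateTruth(gl, 300, fst = c(MED = 0.05), seed = 9)
  prof0 <- list(genotypeErrorRate = 0, baseErrorRate = 0)
  meta <- miniMeta(c("i1", "i2")); meta$depth <- 30

  sim <- simulateIndividualCalls(tr, meta, prof0, seed = 4)
  v <- sim$vset
  ## error-free homozygote reference: zero alt reads
  hom0 <- sim$trueDosage == 0L & !is.na(sim$trueDosage)
  expect_true(all(adAlt(v)[hom0] == 0L))
  ## noise-free limit: called genotypes equal truth wherever DP >= 1
  gtStr <- c("0/0", "0/1", "1/1")
  ok <- !is.na(gtMatrix(v))
  expect_identical(gtMatrix(v)[ok],
                   gtStr[sim$trueDosage[ok] + 1L])
  ## ... and the only missing calls are DP = 0 or structural (female Y)
  expect_true(all(dpMatrix(v)[!ok & !is.na(sim$trueDosage)] == 0L))

  ## low depth loses more genotypes than high depth, near Poisson mass
  meta3 <- meta; meta3$depth <- 3
  v3 <- simulateIndividualCalls(tr, meta3, prof0, seed = 4)$vset
  miss3 <- mean(is.na(gtMatrix(v3)))
  miss30 <- mean(is.na(gtMatrix(v)))
  expect_gt(miss3, miss30)
  expect_lt(abs(miss3 - exp(-3)), 0.05)
  expect_error(simulateIndividualCalls(
    tr, miniMeta("p", is_pool = TRUE), prof0, 1), "individuals only")
})

test_that("pool calls expose depths but no genotypes", {
  gl <- tinyLayout()
  tr <- simulateTruth(gl, 400, fst = c(MED = 0.05), seed = 14)
  prof0 <- list(baseErrorRate = 0)
  pm <- miniMeta("pool1", is_pool = TRUE); pm$pool_size <- 18L
  pm$depth <- 40
  pv <- simulatePoolCalls(tr, pm, prof0, seed = 3)
  expect_true(all(is.na(gtMatrix(pv))))
  expect_true(all(is.na(gqMatrix(pv))))
  expect_false(anyNA(dpMatrix(pv)))
  expect_false(anyNA(adAlt(pv)))
  ## pooled AAF is unbiased for the group frequency: aggregate over
  ## sites and compare at 3 binomial standard errors
  dp <- as.vector(dpMatrix(pv)); aa <- as.vector(adAlt(pv))
  est <- sum(aa) / sum(dp)
  expected <- mean(tr$freq_MED)
  se <- sqrt(expected * (1 - expected) / sum(dp)) +
    sd(tr$freq_MED) / sqrt(nrow(tr))
  expect_lt(abs(est - expected), 3 * se)
  expect_error(simulatePoolCalls(tr, miniMeta("x"), prof0, 1),
               "pool_size >= 2")
})

test_that("the simulated study has its structural signatures", {
  sim <- simulateStudy(nVariants = 600, seed = 19)
  gl <- sim$layout
  cls <- chromClasses(gl)
  ## S2 is female-only: no Y records
  expect_false(any(cls[sim$vsets$S2@chrom] == "Y"))
  expect_true(any(cls[sim$vsets$S1@chrom] == "Y"))
  ## long reads carry no MT
  expect_false(any(cls[sim$vsets$L@chrom] == "MT"))
  ## females never carry Y genotypes; MT dosages homoplasmic
  fem <- sim$meta$sample_id[sim$meta$sex == "F" & !sim$meta$is_pool]
  yrows <- which(cls[sim$truth$chrom] == "Y")
  expect_true(all(is.na(sim$trueDosage[yrows, fem])))
  mtrows <- which(cls[sim$truth$chrom] == "MT")
  expect_true(all(sim$trueDosage[mtrows, ] %in% c(0L, 2L, NA)))
  ## determinism of the full study, including written VCFs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulateStudy(nVariants = 150, seed = 77, dir = d1)
  s2 <- simulateStudy(nVariants = 150, seed = 77, dir = d2)
  for (f in c("wgs_s1.vcf", "wgs_s2.vcf", "wgs_l.vcf", "truth.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("group AAF recovers truth frequencies (slope near 1)", {
  gl <- GenomeLayout(c("a1", "a2"), c(2e7, 2e7), rep("AUTOSOME", 2))
  tr <- simulateTruth(gl, 2000, fst = c(MED = 0.05), seed = 101)
  meta <- miniMeta(sprintf("m%02d", 1:20)); meta$depth <- 30
  prof <- list(genotypeErrorRate = 0.01, baseErrorRate = 0.005)
  v <- simulateIndividualCalls(tr, meta, prof, seed = 55)$vset
  st <- computeGroupStats(v, meta, groups = "MED",
                          excludeByRule = list())
  fit <- lm(st$aaf ~ tr$freq_MED[match(st$key, tr$key)])
  expect_gt(coef(fit)[2], 0.95)
  expect_lt(coef(fit)[2], 1.05)
})
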