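test_that("membership partition is allele-aware and exact", {
  p <- partitionMembership(
    s1Keys = c("c1:100:A:G", "c1:200:A:G", "c1:300:A:T"),
    s2Keys = c("c1:100:A:G", "c1:300:A:G"),
    lKeys = c("c1:100:A:G"))
  expect_equal(p$key[p$S1 & p$S2 & p$L], "c1:100:A:G")
  ## same chrom/pos, different alleles: two distinct keys
  expect_true(all(c("c1:300:A:T", "c1:300:A:G") %in% p$key))
  expect_equal(sum(p$key == "c1:300:A:T"), 1L)
  expect_error(partitionMembership(c("a:1:A:G", "a:1:A:G"),
                                   character(), character()),
               "duplicate key")
})

test_that("partition sizes match brute-force set algebra on random keys", {
  set.seed(21)
  pool <- key4("c1", sample.int(5e5, 1000),
                     sample(c("A", "C"), 1000, TRUE), "G")
  pool <- unique(pool)
  s1 <- sample(pool, 600); s2 <- sample(pool, 500)
  l <- sample(pool, 400)
  p <- partitionMembership(s1, s2, l)
  expect_equal(nrow(p), length(union(union(s1, s2), l)))
  expect_equal(sum(p$S1 & p$S2 & p$L),
               length(intersect(intersect(s1, s2), l)))
  expect_equal(sum(p$S1 & !p$S2 & !p$L),
               length(setdiff(setdiff(s1, s2), l)))
  expect_equal(sum(p$S2 & p$L & !p$S1),
               length(setdiff(intersect(s2, l), s1)))
  ## symmetric under relabeling and idempotent
  p2 <- partitionMembership(s2, s1, l)
  expect_equal(sort(p2$key), sort(p$key))
  expect_equal(sum(p2$S1 & p2$S2 & p2$L), sum(p$S1 & p$S2 & p$L))
})

test_that("chromosome-class merge rules reproduce the study design", {
  gl <- tinyLayout()
  subsets <- list("S1", "S2", "L", c("S1", "S2"), c("S1", "L"),
                  c("S2", "L"), c("S1", "S2", "L"))
  classChrom <- c(AUTOSOME = "c1", X = "cX", Y = "cY", MT = "cM")
  rules <- defaultMergeRules()
  for (cl in names(classChrom)) {
    for (ss in subsets) {
      key <- key4(classChrom[[cl]], 100, "A", "G")
      part <- data.frame(key = key, S1 = "S1" %in% ss,
                         S2 = "S2" %in% ss, L = "L" %in% ss)
      kept <- length(applyMergeRules(part, gl, rules)) == 1L
      want <- switch(cl,
        AUTOSOME = setequal(ss, c("S1", "S2", "L")),
        X = setequal(ss, c("S1", "S2", "L")),
        Y = "S1" %in% ss,
        MT = all(c("S1", "S2") %in% ss))
      expect_identical(kept, want,
                       label = sprintf("class %s, subset {%s}", cl,
                                       paste(ss, collapse = ",")))
    }
  }
})

test_that("rules are data: 'any' keeps all, 'all three' the triple core", {
  gl <- tinyLayout()
  set.seed(4)
  keys <- key4("c1", sort(sample.int(1e5, 50)), "A", "G")
  p <- partitionMembership(sample(keys, 30), sample(keys, 25),
                           sample(keys, 20))
  anyRule <- list(AUTOSOME = character(), X = character(),
                  Y = character(), MT = character())
  expect_equal(applyMergeRules(p, gl, anyRule), p$key)
  allRule <- list(AUTOSOME = c("S1", "S2", "L"))
  expect_equal(applyMergeRules(p, gl, allRule),
               p$key[p$S1 & p$S2 & p$L])
  expect_error(applyMergeRules(p, gl, list(X = "S1")), "no merge rule")
})

test_that("genotype merging pulls each sample from its own dataset", {
  gl <- tinyLayout()
  meta <- rbind(miniMeta("a1", dataset = "S1"),
                miniMeta("b1", dataset = "S2", sex = "F"),
                miniMeta("c1s", dataset = "L"))
  mk <- function(chrom, pos, sample, gt) {
    n <- length(pos)
    VariantSet(chrom, pos, rep("A", n), rep("G", n), samples = sample,
               gt = matrix(gt, n, 1), dp = matrix(9L, n, 1))
  }
  s1 <- mk(c("c1", "cY"), c(100, 50), "a1", c("0/1", "1/1"))
  s2 <- mk("c1", 100, "b1", "0/0")
  l <- mk("c1", 100, "c1s", "1/1")
  part <- partitionMembership(variantKeys(s1), variantKeys(s2),
                              variantKeys(l))
  final <- applyMergeRules(part, gl)
  expect_setequal(final, c("c1:100:A:G", "cY:50:A:G"))
  merged <- mergeGenotypes(final, s1, s2, l, meta, gl)
  expect_equal(sampleNames(merged), c("a1", "b1", "c1s"))
  auto <- which(variantKeys(merged) == "c1:100:A:G")
  expect_equal(unname(gtMatrix(merged)[auto, ]),
               c("0/1", "0/0", "1/1"))
  yrow <- which(variantKeys(merged) == "cY:50:A:G")
  expect_equal(unname(gtMatrix(merged)[yrow, ]),
               c("1/1", NA, NA))          # S2/L lack the Y key
  expect_true(all(is.na(dpMatrix(merged)[yrow, c("b1", "c1s")])))

  dup <- mk("c1", 100, "a1", "0/0")
  expect_error(mergeGenotypes(final, s1, dup, l, meta, gl),
               "more than one dataset")
})

test_that("merged entry counts match a brute-force join on 50 keys", {
  set.seed(31)
  gl <- tinyLayout()
  pos <- sort(sample.int(1e6, 50))
  keys <- key4("c1", pos, "A", "G")
  sets <- list()
  meta <- NULL
  for (tag in c("S1", "S2", "L")) {
    take <- sort(sample(50, 35))
    samp <- paste0(tag, "_", 1:3)
    sets[[tag]] <- VariantSet(rep("c1", 35), pos[take], rep("A", 35),
                              rep("G", 35), samples = samp,
                              gt = matrix("0/1", 35, 3),
                              dp = matrix(7L, 35, 3))
    meta <- rbind(meta, miniMeta(samp, dataset = tag,
                                 sex = if (tag == "S2") "F" else "M"))
  }
  part <- partitionMembership(variantKeys(sets$S1),
                              variantKeys(sets$S2),
                              variantKeys(sets$L))
  final <- applyMergeRules(part, gl, list(AUTOSOME = character()))
  merged <- mergeGenotypes(final, sets$S1, sets$S2, sets$L, meta, gl)
  expect_equal(numVariants(merged), length(final))
  expect_equal(length(sampleNames(merged)), 9L)
  ## per-sample non-missing counts == per-dataset key hits
  for (tag in c("S1", "S2", "L")) {
    inSet <- sum(final %in% variantKeys(sets[[tag]]))
    for (s in paste0(tag, "_", 1:3)) {
      expect_equal(sum(!is.na(gtMatrix(merged)[, s])), inSet)
    }
  }
})
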