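## Internal helpers shared across modules.

CHROM_CLASSES <- c("AUTOSOME", "X", "Y", "MT")
DATASET_TAGS <- c("S1", "S2", "L")
GROUP_LABELS <- c("MED", "RIV", "SWA")

## Canonical string form of a variant key: "chrom:pos:ref:alt".
.keyString <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

## Deterministic per-stage seeds fanned out from a single top-level seed.
## Offsets keep derived seeds well below .Machine$integer.max.
.stageSeed <- function(seed, stage) {
  offsets <- c(
    truth = 101L, s1 = 211L, s2 = 307L, l = 401L, pools = 503L,
    noise = 601L, pca = 701L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}

## Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
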