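# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user randomness.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fold a (seed, n) pair into a single small integer seed, kept below 2^31.
.foldSeed <- function(seed, n) {
  as.integer((as.double(seed) * 48271 + as.double(n) * 16807) %% 2147483587)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Lossless decimal rendering of doubles (17 significant digits), so written
# files round-trip bit-for-bit through the readers.
.fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

# stop() with a consistent prefix naming the offending file
.fileError <- function(path, msg) {
  stop(sprintf("%s: %s", basename(path), msg), call. = FALSE)
}
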