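# Independent oracles and fixture builders used across the suite. These are
# deliberately naive re-implementations (loops, closed forms, enumeration),
# kept separate from the package's own code paths.

# All permutations of 1..n, built iteratively by lexicographic succession.
permOracle <- function(n) {
  cur <- seq_len(n)
  out <- matrix(NA_integer_, factorial(n), n)
  out[1L, ] <- cur
  row <- 1L
  repeat {
    i <- n - 1L
    while (i >= 1L && cur[i] >= cur[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (cur[j] <= cur[i]) j <- j - 1L
    tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
    cur[(i + 1L):n] <- rev(cur[(i + 1L):n])
    row <- row + 1L
    out[row, ] <- cur
  }
  out
}

# One-sided (greater) exact Spearman p by enumeration over permutations.
spearmanPermOracle <- function(x, y, two.sided = FALSE) {
  perms <- permOracle(length(y))
  obs <- cor(x, y, method = "spearman")
  rp <- apply(perms, 1L, function(ix) cor(x, y[ix], method = "spearman"))
  if (two.sided) mean(abs(rp) >= abs(obs) - 1e-12)
  else mean(rp >= obs - 1e-12)
}

# Textbook BH step-up: sort ascending, q_(i) = min_{j>=i} m p_(j)/j, clip.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Naive copy-number load: explicit loop over a segment data.frame.
naiveCnLoad <- function(df, threshold = 0, meanOver = "altered") {
  samples <- unique(df$sample)
  out <- numeric(0)
  for (s in samples) {
    rows <- df[df$sample == s, ]
    vols <- c(); nAll <- 0
    for (k in seq_len(nrow(rows))) {
      nAll <- nAll + 1
      if (abs(rows$log2[k]) > threshold)
        vols <- c(vols, abs(rows$log2[k]) * (rows$end[k] - rows$start[k] + 1))
    }
    out[s] <- if (!length(vols)) 0
              else if (meanOver == "altered") sum(vols) / length(vols)
              else sum(vols) / nAll
  }
  out
}

# Naive mutation load: filter-then-count loop.
naiveMutLoad <- function(df, drivers = character(), afMin = 0.1) {
  out <- integer(0)
  for (s in unique(df$sample_id)) {
    n <- 0L
    rows <- df[df$sample_id == s, ]
    for (k in seq_len(nrow(rows)))
      if (rows$allelic_fraction[k] >= afMin && !(rows$gene[k] %in% drivers))
        n <- n + 1L
    out[s] <- n
  }
  out
}

# Random toy segment data.frame for oracle-equivalence checks.
randomSegmentFrame <- function(nSamples, maxSeg = 10) {
  rows <- do.call(rbind, lapply(seq_len(nSamples), function(i) {
    k <- sample(1:maxSeg, 1)
    start <- sample(1e6, k)
    data.frame(sample = sprintf("S%02d", i), chrom = sample(1:5, k, TRUE),
               start = start, end = start + sample(1e5, k),
               log2 = round(rnorm(k, 0, 0.6), 3))
  }))
  # sprinkle exact zeros to exercise the neutral path
  zero <- sample(nrow(rows), ceiling(nrow(rows) / 5))
  rows$log2[zero] <- 0
  rows
}

segFrameToGRanges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    sample_id = df$sample, log2_ratio = df$log2)
}

# Hand-built LoadTable for screen tests (z-scores computed per tissue).
makeLoadTable <- function(cn, mut, tissue, minTissue = 2L) {
  samples <- sprintf("S%03d", seq_along(cn))
  zc <- zNormalizeByGroup(cn, tissue, minTissue)
  zm <- zNormalizeByGroup(mut, tissue, minTissue)
  new("LoadTable", S4Vectors::DataFrame(
    sample_id = samples, tissue = tissue, cn_load = cn,
    mut_load = as.integer(mut), cn_load_z = zc$z, mut_load_z = zm$z,
    included = zc$included))
}

# Small simulated cohort configs reused by screen/acceptance tests.
nullCohortConfig <- function(nTissues = 5, cells = 12, nDrugs = 6)
  cohortConfig(nTissues = nTissues, cellsPerTissue = c(cells, cells),
               nDrugs = nDrugs, missingFrac = 0)
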