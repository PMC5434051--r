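test_that("segment volume is |log2| times 1-based inclusive length", {
  gr <- segFrameToGRanges(data.frame(
    sample = "A", chrom = 1, start = c(1, 1, 11), end = c(500, 100, 20),
    log2 = c(0, 1, -0.5)))
  expect_equal(segmentVolume(gr), c(0, 100, 5))
})

test_that("copy-number load averages altered segments, with 'all' option", {
  gr <- segFrameToGRanges(data.frame(
    sample = "A", chrom = 1, start = c(1, 1, 1), end = c(100, 300, 50),
    log2 = c(1, 1, 0)))
  # volumes 100, 300 over two altered segments
  expect_equal(unname(copyNumberLoad(gr)), 200)
  # 'all' divides by all three segments
  expect_equal(unname(copyNumberLoad(gr, meanOver = "all")), 400 / 3)
  # single altered segment -> its own volume
  one <- segFrameToGRanges(data.frame(sample = "A", chrom = 1, start = 1,
                                      end = 100, log2 = -2))
  expect_equal(unname(copyNumberLoad(one)), 200)
  # all neutral -> 0 (not missing)
  flat <- segFrameToGRanges(data.frame(sample = "A", chrom = 1,
                                       start = c(1, 5), end = c(10, 20),
                                       log2 = c(0, 0)))
  expect_equal(unname(copyNumberLoad(flat)), 0)
  # neutral threshold: |log2| must exceed it
  thr <- segFrameToGRanges(data.frame(sample = "A", chrom = 1,
                                      start = c(1, 1), end = c(10, 10),
                                      log2 = c(0.1, 0.5)))
  expect_equal(unname(copyNumberLoad(thr, neutralThreshold = 0.3)), 5)
})

test_that("mutation load filters by allelic fraction and driver list", {
  v <- S4Vectors::DataFrame(
    sample_id = rep("A", 5),
    gene = c("TP53", "KRAS", "G1", "G2", "G3"),
    allelic_fraction = c(0.5, 0.9, 0.10, 0.3, 0.2),
    classification = c("missense", "missense", "silent", "nonsense", "missense"))
  empty <- v[0, ]
  expect_length(mutationLoad(empty), 0L)
  # single sub-threshold variant counts zero
  low <- v[3, ]; low$allelic_fraction <- 0.05
  expect_equal(unname(mutationLoad(low)), 0L)
  # boundary: exactly 10% is kept ("< 10% filtered out")
  expect_equal(unname(mutationLoad(v[3, ])), 1L)
  # 5 variants, 2 in driver genes -> 3
  expect_equal(unname(mutationLoad(v, driverGenes = c("TP53", "KRAS"))), 3L)
  # classification presets
  expect_equal(unname(mutationLoad(v, classes = "missense")), 3L)
})

test_that("within-group z-normalisation excludes small and degenerate groups", {
  z <- zNormalizeByGroup(c(2, 4, 6), rep("t", 3), minGroupSize = 2)
  expect_equal(z$z, c(-1, 0, 1))
  expect_true(all(z$included))

  # group of 7 below the default minimum of 8 -> excluded, z missing
  z7 <- zNormalizeByGroup(rnorm(7), rep("t", 7))
  expect_false(any(z7$included))
  expect_true(all(is.na(z7$z)))

  # retained group: mean 0, sample SD 1
  set.seed(1)
  v <- rnorm(20)
  z20 <- zNormalizeByGroup(v, rep("t", 20), minGroupSize = 8)
  expect_equal(mean(z20$z), 0, tolerance = 1e-9)
  expect_equal(sd(z20$z), 1, tolerance = 1e-9)

  # zero-variance group warns and yields missing z
  expect_warning(zd <- zNormalizeByGroup(rep(5, 10), rep("t", 10)),
                 "zero variance")
  expect_true(all(is.na(zd$z)))
  expect_true(all(zd$included))
})

test_that("load scores obey scale covariance, sign symmetry and filter monotonicity", {
  set.seed(7)
  for (i in 1:10) {
    df <- randomSegmentFrame(4)
    gr <- segFrameToGRanges(df)
    base <- copyNumberLoad(gr)
    # scale covariance: log2 * c scales loads by c
    df2 <- df; df2$log2 <- df2$log2 * 2.5
    expect_equal(copyNumberLoad(segFrameToGRanges(df2)), base * 2.5)
    # sign symmetry: negation leaves loads unchanged
    df3 <- df; df3$log2 <- -df3$log2
    expect_equal(copyNumberLoad(segFrameToGRanges(df3)), base)
  }
  mut <- data.frame(sample_id = sample(LETTERS[1:4], 60, TRUE),
                    gene = sprintf("G%02d", sample(30, 60, TRUE)),
                    allelic_fraction = runif(60), classification = "m")
  afGrid <- seq(0, 1, by = 0.1)
  counts <- sapply(afGrid, function(a) sum(mutationLoad(mut, afMin = a)))
  expect_true(all(diff(counts) <= 0)) # non-increasing in afMin
  small <- mutationLoad(mut, driverGenes = "G01")
  big <- mutationLoad(mut, driverGenes = c("G01", "G02", "G03"))
  expect_true(all(big[names(small)] <= small)) # non-increasing in driver list

  # z-scores invariant to per-tissue affine transform of raw loads
  tissue <- rep(c("a", "b"), each = 10)
  vals <- rnorm(20)
  z1 <- zNormalizeByGroup(vals, tissue, 2)$z
  shifted <- ifelse(tissue == "a", 3 * vals + 7, 0.5 * vals - 2)
  expect_equal(zNormalizeByGroup(shifted, tissue, 2)$z, z1)
})

test_that("computeLoads assembles the table and flags missing profiles", {
  gen <- generateCohort(nullCohortConfig(nTissues = 3, cells = 9, nDrugs = 2),
                        seed = 5)
  loads <- computeLoads(gen$cohort, minTissue = 8)
  expect_s4_class(loads, "LoadTable")
  expect_equal(nrow(loads), 27L)
  expect_equal(loads$cn_load, gen$truth$loads$cn_load)
  expect_equal(loads$mut_load, gen$truth$loads$mut_load)
  for (t in unique(loads$tissue)) {
    i <- loads$tissue == t
    expect_equal(mean(loads$cn_load_z[i]), 0, tolerance = 1e-9)
    expect_equal(sd(loads$mut_load_z[i]), 1, tolerance = 1e-9)
  }
  # a sample with no segments gets NA cn_load, not zero
  cohort <- gen$cohort
  seg <- cnSegments(cohort)
  drop <- sampleAnnotations(cohort)$sample_id[1]
  cohort@segments <- seg[S4Vectors::mcols(seg)$sample_id != drop]
  expect_message(l2 <- computeLoads(cohort, minTissue = 8), "no copy-number")
  expect_true(is.na(l2$cn_load[l2$sample_id == drop]))
})
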