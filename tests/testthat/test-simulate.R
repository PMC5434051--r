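test_that("activity area and Hill curves behave per their definitions", {
  expect_equal(activityArea(rep(0, 8)), 0)
  expect_equal(activityArea(rep(1, 8)), 8)
  expect_equal(activityArea(c(0, 0, .1, .2, .4, .7, .9, 1)), 3.3)
  expect_error(activityArea(rep(0.5, 7)), "eight-point")
  expect_error(activityArea(c(rep(0.5, 7), 1.2)), "\\[0, 1\\]")

  conc <- 8 * 3.1623^(-(7:0))
  expect_equal(hillInhibition(2, 2, 1.5, 0.9), 0.45) # c = ec50 -> emax/2
  expect_equal(hillInhibition(conc, 1, 2, 0), rep(0, 8))
  # steep slope limit: a step function about ec50
  steep <- hillInhibition(conc, 0.1, 400, 0.95)
  away <- abs(log10(conc / 0.1)) >= log10(3.1623)
  expect_true(all(abs(steep[away] - ifelse(conc[away] > 0.1, 0.95, 0))
                  < 1e-6))
  # monotone non-decreasing in concentration
  expect_true(all(diff(hillInhibition(conc, 0.5, 1.2, 0.8)) >= 0))

  # pointwise-larger inhibition never yields a smaller area
  set.seed(30)
  for (i in 1:20) {
    a <- runif(8, 0, 0.9)
    b <- pmin(1, a + runif(8, 0, 0.1))
    expect_gte(activityArea(b), activityArea(a))
  }
})

test_that("generation is byte-identical for identical config and seed", {
  cfg <- nullCohortConfig(nTissues = 3, cells = 8, nDrugs = 2)
  g1 <- generateCohort(cfg, seed = 33)
  g2 <- generateCohort(cfg, seed = 33)
  expect_identical(g1$truth, g2$truth)
  expect_identical(as.data.frame(cnSegments(g1$cohort)),
                   as.data.frame(cnSegments(g2$cohort)))
  expect_identical(drugResponse(g1$cohort), drugResponse(g2$cohort))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  p1 <- writeCohort(g1$cohort, d1, g1$truth)
  p2 <- writeCohort(g2$cohort, d2, g2$truth)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  # a different seed changes the data
  g3 <- generateCohort(cfg, seed = 34)
  expect_false(identical(drugResponse(g1$cohort), drugResponse(g3$cohort)))
})

test_that("generated cohorts round-trip losslessly through the file readers", {
  gen <- generateCohort(cohortConfig(
    nTissues = 3, cellsPerTissue = c(8, 10), nDrugs = 3,
    expressionModel = list(nGenes = 50, nSets = 3, setSize = c(5, 10),
                           baseMean = 6, noiseSd = 1, setCouplings = NULL,
                           geneCouplings = NULL)), seed = 35)
  dir <- file.path(tempdir(), "roundtrip")
  paths <- writeCohort(gen$cohort, dir)
  back <- readCohort(paths["seg"], paths["variants"], paths["annotations"],
                     paths["response"], expression = paths["expression"],
                     geneSets = paths["gene_sets"], drivers = paths["drivers"])
  expect_identical(as.data.frame(cnSegments(back)),
                   as.data.frame(cnSegments(gen$cohort)))
  expect_equal(as.data.frame(variantTable(back)),
               as.data.frame(variantTable(gen$cohort)))
  expect_equal(drugResponse(back), drugResponse(gen$cohort))
  expect_equal(exprMatrix(back), exprMatrix(gen$cohort))
  expect_identical(geneSets(back), geneSets(gen$cohort))
  l1 <- suppressMessages(computeLoads(gen$cohort, minTissue = 8))
  l2 <- suppressMessages(computeLoads(back, minTissue = 8))
  expect_equal(as.data.frame(l1), as.data.frame(l2))
})

test_that("null drugs show no load-sensitivity correlation beyond sampling noise", {
  gen <- generateCohort(cohortConfig(nTissues = 1, cellsPerTissue = c(60, 60),
                                     nDrugs = 10, missingFrac = 0), seed = 36)
  tl <- gen$truth$loads
  resp <- drugResponse(gen$cohort)
  cors <- abs(apply(resp, 2, function(y) cor(tl$cn_load_z, y,
                                             method = "spearman")))
  expect_lt(median(cors), 0.15)
  expect_true(all(cors < 0.4))
})

test_that("a planted effect realizes its target rank correlation", {
  # analytic/Monte-Carlo oracle for the bivariate-normal Spearman value
  beta <- 0.5; noise <- 0.8
  rhoP <- beta / sqrt(beta^2 + noise^2)
  set.seed(37)
  zx <- rnorm(2e5); zy <- rhoP * zx + sqrt(1 - rhoP^2) * rnorm(2e5)
  oracle <- cor(zx, zy, method = "spearman")
  reps <- 120
  em <- data.frame(tissue = "TISSUE01", drug = "DRUG01", beta = beta,
                   load_type = "cn")
  got <- vapply(seq_len(reps), function(i) {
    gen <- generateCohort(cohortConfig(nTissues = 1,
                                       cellsPerTissue = c(30, 30),
                                       nDrugs = 1, missingFrac = 0,
                                       effectMap = em, noiseSd = noise),
                          seed = 5000 + i)
    cor(gen$truth$loads$cn_load_z, drugResponse(gen$cohort)[, 1],
        method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(got) - oracle), 0.05)
})

test_that("infeasible configurations are rejected up front", {
  expect_error(cohortConfig(effectMap = data.frame(
    tissue = "TISSUE01", drug = "DRUG01", beta = 4, load_type = "cn")),
    "infeasible")
  expect_error(cohortConfig(nDrugs = 0), "nDrugs")
  expect_error(cohortConfig(responseModel = list(
    concentrations = 1:4, hill = 1, emax = 0.9, drugMeanRange = c(1, 4),
    tissueShiftSd = 0.5, areaSd = 0.7)))
})

test_that("the optional 7-cell tissue exercises the exclusion path", {
  gen <- generateCohort(cohortConfig(nTissues = 2, cellsPerTissue = c(9, 9),
                                     nDrugs = 2, addSmallTissue = TRUE),
                        seed = 38)
  loads <- suppressMessages(computeLoads(gen$cohort, minTissue = 8))
  small <- loads$tissue == "TISSUE_SMALL"
  expect_equal(sum(small), 7L)
  expect_false(any(loads$included[small]))
  expect_true(all(is.na(loads$cn_load_z[small])))
  expect_true(all(loads$included[!small]))
})
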