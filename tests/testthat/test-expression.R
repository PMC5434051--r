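test_that("enrichment score matches its closed form at the extremes", {
  G <- 50; m <- 5
  genes <- sprintf("G%02d", 1:G)
  expr <- matrix(seq_len(G), G, 1, dimnames = list(genes, "s1"))
  top <- genes[(G - m + 1):G] # set occupies exactly the top m ranks
  sc <- enrichmentScores(expr, list(top = top))
  rbar <- G - (m - 1) / 2
  expected <- (rbar - (G + 1) / 2) / sqrt((G + 1) * (G - m) / (12 * m))
  expect_equal(sc["top", "s1"], expected)

  # member ranks symmetric about (G+1)/2 -> score 0
  sym <- genes[c(10, G + 1 - 10, 20, G + 1 - 20)]
  expect_equal(unname(enrichmentScores(expr, list(s = sym))[1, 1]), 0)

  # reversing the expression profile negates the score (antisymmetry)
  scRev <- enrichmentScores(-expr, list(top = top))
  expect_equal(scRev["top", "s1"], -expected)
})

test_that("enrichment score is rank-based and standardized", {
  set.seed(15)
  G <- 400
  genes <- sprintf("G%03d", 1:G)
  expr <- matrix(rnorm(G * 10), G, 10,
                 dimnames = list(genes, sprintf("s%02d", 1:10)))
  sets <- lapply(1:200, function(i) sample(genes, 20))
  names(sets) <- sprintf("SET%03d", 1:200)
  sc <- enrichmentScores(expr, sets)
  # invariant under strictly monotone transform of expression
  sc2 <- enrichmentScores(exp(expr / 2), sets)
  expect_equal(sc, sc2)
  # random sets: mean ~ 0, variance ~ 1
  expect_lt(abs(mean(sc)), 0.05)
  expect_gt(var(as.vector(sc)), 0.8)
  expect_lt(var(as.vector(sc)), 1.2)
  # sets with < 2 measured members are skipped with a message
  expect_message(
    scSkip <- enrichmentScores(expr, c(sets[1], list(gone = c("X1", "X2")))),
    "gone")
  expect_equal(nrow(scSkip), 1L)
})

test_that("pathway screen equals the panel screen run on score rows", {
  gen <- generateCohort(cohortConfig(
    nTissues = 3, cellsPerTissue = c(10, 10), nDrugs = 2, missingFrac = 0,
    expressionModel = list(nGenes = 300, nSets = 6, setSize = c(10, 20),
                           baseMean = 6, noiseSd = 1, setCouplings = NULL,
                           geneCouplings = NULL)), seed = 21)
  loads <- suppressMessages(computeLoads(gen$cohort, minTissue = 8))
  sc <- enrichmentScores(exprMatrix(gen$cohort), geneSets(gen$cohort))
  a <- pathwayLoadScreen(sc, loads, "mut")
  b <- genePanelLoadScreen(sc, rownames(sc), loads, "mut") # scores as "genes"
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_rho, b$p_rho)
  expect_equal(a$q_rho, b$q_rho)
})

test_that("panel screen handles single genes, constants and missing panels", {
  gen <- generateCohort(cohortConfig(
    nTissues = 3, cellsPerTissue = c(10, 10), nDrugs = 2, missingFrac = 0,
    expressionModel = list(nGenes = 100, nSets = 2, setSize = c(5, 10),
                           baseMean = 6, noiseSd = 1, setCouplings = NULL,
                           geneCouplings = NULL)), seed = 22)
  loads <- suppressMessages(computeLoads(gen$cohort, minTissue = 8))
  expr <- exprMatrix(gen$cohort)
  # panel of one gene: q = p (m = 1 family)
  one <- genePanelLoadScreen(expr, rownames(expr)[1], loads, "mut")
  expect_equal(one$q_rho, one$p_rho)
  # constant gene excluded with a message
  expr2 <- expr
  expr2[2, ] <- 3
  expect_message(
    res <- genePanelLoadScreen(expr2, rownames(expr2)[1:3], loads, "mut"),
    "constant")
  expect_equal(nrow(res), 2L)
  # entirely missing panel errors, naming genes
  expect_error(genePanelLoadScreen(expr, c("NOPE1", "NOPE2"), loads, "mut"),
               "NOPE1")
})

test_that("a planted gene-load coupling is recovered with the right sign", {
  em <- list(nGenes = 500, nSets = 4, setSize = c(10, 20), baseMean = 6,
             noiseSd = 1, setCouplings = NULL,
             geneCouplings = data.frame(gene = "G0007", load_type = "mut",
                                        gamma = 0.9))
  gen <- generateCohort(cohortConfig(nTissues = 4, cellsPerTissue = c(12, 12),
                                     nDrugs = 2, missingFrac = 0,
                                     expressionModel = em), seed = 23)
  loads <- suppressMessages(computeLoads(gen$cohort, minTissue = 8))
  panel <- c("G0007", "G0010", "G0020", "G0030")
  res <- genePanelLoadScreen(exprMatrix(gen$cohort), panel, loads, "mut")
  hit <- res[res$unit == "G0007", ]
  expect_gt(hit$rho, 0)
  expect_lte(hit$q_rho, 0.10)
})
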