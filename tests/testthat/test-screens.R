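# Screen tests run on small hand-built load tables or seeded synthetic
# cohorts, so every expectation has a known data-generating truth.

test_that("pan-cancer screen is deterministic and respects minN", {
  set.seed(42)
  tissue <- rep(c("T1", "T2", "T3"), each = 10)
  lt <- makeLoadTable(runif(30, 1, 5), rpois(30, 20), tissue)
  resp <- matrix(rnorm(90), 30, 3,
                 dimnames = list(lt$sample_id, c("d1", "d2", "d2copy")))
  resp[, "d2copy"] <- resp[, "d2"] # duplicated drug column
  res <- panCancerScreen(lt, resp, "cn", minN = 10)
  expect_equal(nrow(res), 3L)
  a <- res[res$unit == "d2", c("rho", "p_rho", "r", "p_r", "n")]
  b <- res[res$unit == "d2copy", c("rho", "p_rho", "r", "p_r", "n")]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)

  # a drug observed on too few lines is skipped with a message
  resp2 <- resp
  resp2[6:30, "d1"] <- NA
  expect_message(res2 <- panCancerScreen(lt, resp2, "cn", minN = 10),
                 "skipped")
  expect_false("d1" %in% res2$unit)
})

test_that("pan-drug pooling counts (cell, drug) pairs and degenerates to plain correlation", {
  set.seed(43)
  tissue <- rep("T1", 30)
  lt <- makeLoadTable(runif(30, 1, 5), rpois(30, 20), tissue)
  resp <- matrix(rnorm(30 * 24), 30, 24,
                 dimnames = list(lt$sample_id, sprintf("d%02d", 1:24)))
  res <- panDrugScreen(lt, resp, "cn", minPairs = 30)
  expect_equal(res$n, 30L * 24L) # complete data: n = cells x drugs

  # single drug: pooled result equals the pairwise correlation on that column
  one <- resp[, 1, drop = FALSE]
  res1 <- panDrugScreen(lt, one, "cn", minPairs = 3)
  z <- lt$cn_load_z
  direct <- corTest(z, (one[, 1] - mean(one[, 1])) / sd(one[, 1]))
  expect_equal(res1$rho, direct$estimate)
  expect_equal(res1$p_rho, direct$p.value)
})

test_that("pair screen enforces min sample size and empty candidates", {
  set.seed(44)
  tissue <- rep(c("T1", "T2"), each = 8)
  lt <- makeLoadTable(runif(16, 1, 5), rpois(16, 20), tissue)
  resp <- matrix(rnorm(32), 16, 2,
                 dimnames = list(lt$sample_id, c("d1", "d2")))
  resp[1:2, "d1"] <- NA # T1/d1 has only 6 observations
  res <- pairScreen(lt, resp, tissues = c("T1", "T2"), drugs = c("d1", "d2"),
                    loadType = "cn", minN = 7)
  expect_false("T1|d1" %in% res$unit)
  expect_setequal(res$unit, c("T1|d2", "T2|d1", "T2|d2"))

  expect_warning(e <- pairScreen(lt, resp, tissues = character(0),
                                 drugs = "d1", loadType = "cn"),
                 "empty candidate")
  expect_equal(nrow(e), 0L)
})

test_that("removing one pair from the candidates leaves other pairs' statistics unchanged", {
  gen <- generateCohort(nullCohortConfig(nTissues = 3, cells = 10, nDrugs = 3),
                        seed = 9)
  loads <- suppressMessages(computeLoads(gen$cohort, minTissue = 8))
  resp <- drugResponse(gen$cohort)
  tissues <- unique(loads$tissue)
  drugs <- colnames(resp)
  full <- pairScreen(loads, resp, tissues, drugs, "cn", minN = 5)
  reduced <- pairScreen(loads, resp, tissues, drugs[-1], "cn", minN = 5)
  shared <- intersect(full$unit, reduced$unit)
  expect_gt(length(shared), 0)
  for (u in shared) {
    expect_equal(full$rho[full$unit == u], reduced$rho[reduced$unit == u])
    expect_equal(full$p_rho[full$unit == u], reduced$p_rho[reduced$unit == u])
  }
})

test_that("a planted tissue-wide effect ranks first among tissues in the pan-drug screen", {
  drugs <- sprintf("DRUG%02d", 1:8)
  em <- data.frame(tissue = "TISSUE02", drug = drugs,
                   beta = betaForRankCor(0.5), load_type = "mut")
  cfg <- cohortConfig(nTissues = 6, cellsPerTissue = c(15, 15), nDrugs = 8,
                      missingFrac = 0, effectMap = em)
  gen <- generateCohort(cfg, seed = 77)
  loads <- suppressMessages(computeLoads(gen$cohort, minTissue = 8))
  res <- panDrugScreen(loads, drugResponse(gen$cohort), "mut")
  expect_equal(res$unit[which.min(res$q_rho)], "TISSUE02")
  expect_true(res$q_rho[res$unit == "TISSUE02"] <= 0.10)
})

test_that("untestable units are dropped from the FDR family with a warning", {
  tissue <- rep("T1", 10)
  lt <- makeLoadTable(runif(10, 1, 5), rpois(10, 10), tissue)
  resp <- matrix(c(rep(2, 10), rnorm(10)), 10, 2,
                 dimnames = list(lt$sample_id, c("flat", "ok")))
  # a constant column cannot be z-scored, hence NA -> too few observations
  expect_message(res <- panCancerScreen(lt, resp, "cn", minN = 5), "skipped")
  expect_false("flat" %in% res$unit)
})
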