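test_that("the zero-penalty fit equals ordinary least squares", {
  set.seed(2)
  n <- 40
  cn <- rnorm(n); mut <- rnorm(n)
  y <- 0.5 * cn - 0.2 * mut + rnorm(n, 0, 0.3)
  m <- fitCombined(cn, mut, y, lambda = 0)
  X <- cbind(1, cn, mut)
  beta <- solve(crossprod(X), crossprod(X, y)) # normal-equations oracle
  expect_equal(m@intercept, beta[1], tolerance = 1e-4)
  expect_equal(m@wCn, beta[2], tolerance = 1e-4)
  expect_equal(m@wMut, beta[3], tolerance = 1e-4)
})

test_that("a pure copy-number signal is recovered with the mutation weight at zero", {
  set.seed(3)
  n <- 100
  cn <- rnorm(n); mut <- rnorm(n)
  m <- fitCombined(cn, mut, cn, seed = 10)
  expect_true(m@usable)
  expect_gt(m@wCn, 0)
  expect_equal(m@wMut, 0)
  expect_gte(cor(m@predictions, m@observed, method = "spearman"), 0.95)
})

test_that("increasing the penalty never increases the coefficient L1 norm", {
  set.seed(4)
  n <- 60
  cn <- rnorm(n); mut <- rnorm(n)
  y <- 0.6 * cn + 0.3 * mut + rnorm(n, 0, 0.4)
  lambdas <- c(0, 0.01, 0.05, 0.1, 0.3, 0.6)
  l1 <- sapply(lambdas, function(l) {
    m <- fitCombined(cn, mut, y, lambda = l)
    abs(m@wCn) + abs(m@wMut)
  })
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("exchanging the two predictors exchanges their weights", {
  set.seed(6)
  n <- 50
  a <- rnorm(n); b <- rnorm(n)
  y <- 0.7 * a + 0.2 * b + rnorm(n, 0, 0.3)
  m1 <- fitCombined(a, b, y, seed = 3)
  m2 <- fitCombined(b, a, y, seed = 3)
  # coordinate descent is order-dependent only at convergence-tolerance level
  expect_equal(m1@wCn, m2@wMut, tolerance = 1e-5)
  expect_equal(m1@wMut, m2@wCn, tolerance = 1e-5)
  expect_equal(m1@predictions, m2@predictions, tolerance = 1e-5)
})

test_that("fits are deterministic given (seed, n) and flag small units unusable", {
  set.seed(12)
  cn <- rnorm(30); mut <- rnorm(30); y <- 0.5 * cn + rnorm(30, 0, 0.5)
  m1 <- fitCombined(cn, mut, y, seed = 99)
  m2 <- fitCombined(cn, mut, y, seed = 99)
  expect_identical(m1@penalty, m2@penalty)
  expect_identical(m1@wCn, m2@wCn)

  small <- fitCombined(rnorm(5), rnorm(5), rnorm(5))
  expect_false(small@usable)
  expect_match(small@reason, "too few")
})

test_that("holdout evaluation stores out-of-fold predictions", {
  set.seed(18)
  n <- 80
  cn <- rnorm(n); mut <- rnorm(n)
  y <- 0.8 * cn + rnorm(n, 0, 0.4)
  mi <- fitCombined(cn, mut, y, seed = 4)
  mh <- fitCombined(cn, mut, y, seed = 4, evaluation = "holdout")
  expect_identical(mi@penalty, mh@penalty) # same selection, different preds
  expect_false(isTRUE(all.equal(mi@predictions, mh@predictions)))
  # out-of-sample correlation cannot beat in-sample on the same fit
  expect_lte(cor(mh@predictions, y), cor(mi@predictions, y) + 0.05)
})

test_that("combined screen covers usable units only and degenerates to single-load correlation", {
  set.seed(13)
  n <- 60
  cn <- rnorm(n); mut <- rnorm(n)
  y1 <- cn + rnorm(n, 0, 0.2)       # cn-only signal
  ynull <- rnorm(n)                 # no signal -> should be unusable
  models <- list(sig = fitCombined(cn, mut, y1, seed = 5, unit = "sig"),
                 null = fitCombined(cn, mut, ynull, seed = 5, unit = "null"))
  expect_false(models$null@usable)
  res <- suppressWarnings(combinedScreen(models))
  expect_identical(res$unit, "sig")
  # with wMut = 0 the combined correlation equals the cn-only correlation
  if (models$sig@wMut == 0) {
    direct <- corTest(cn, y1)
    expect_equal(res$rho, direct$estimate)
    expect_equal(res$p_rho, direct$p.value)
  }
  expect_warning(combinedScreen(list(null = models$null)), "no usable")
})

test_that("independence check recovers perfect dependence and runs per tissue", {
  tissue <- rep(c("T1", "T2"), each = 10)
  set.seed(14)
  cn <- as.numeric(sample(1:100, 20))
  lt <- makeLoadTable(cn, cn * 10, tissue) # mut duplicates cn exactly
  res <- loadIndependenceCheck(lt)
  expect_equal(res$r[res$values == "raw"], 1, tolerance = 1e-12)
  perT <- loadIndependenceCheck(lt, perTissue = TRUE)
  expect_equal(nrow(perT), 2L)
  expect_equal(perT$rho, rep(1, 2), tolerance = 1e-12)
})
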