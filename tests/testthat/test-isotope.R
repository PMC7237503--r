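test_that("parseFormula reads Hill-notation formulas exactly", {
  expect_identical(parseFormula("C16H32O2"),
                   c(C = 16L, H = 32L, O = 2L))
  expect_identical(parseFormula("C3H4O3"), c(C = 3L, H = 4L, O = 3L))
  expect_identical(sum(parseFormula("C16H32O2")), 50L)
  expect_identical(parseFormula("C6H12O6Si2N"),
                   c(C = 6L, H = 12L, O = 6L, Si = 2L, N = 1L))
  expect_error(parseFormula("C3XeO3"), "unsupported element")
  expect_error(parseFormula("abc"), "malformed|unsupported")
  expect_error(parseFormula(""), "malformed")
})

test_that("correctionMatrix reduces to identity and binomial terms", {
  zeroAb <- lapply(naturalAbundances(), function(d) {
    d[] <- 0; d[1] <- 1; d
  })
  M <- correctionMatrix("C4H8O2", zeroAb, mode = "all-elements")
  expect_equal(unname(M), diag(5))

  ab <- naturalAbundances()
  a <- ab$C[2]
  M2 <- correctionMatrix("C2H4O2", ab, mode = "carbon-only")
  # column 0 before renormalisation is the full binomial, so exact here
  expect_equal(M2[2, 1], 2 * a * (1 - a))
  expect_equal(M2[1, 1], (1 - a)^2)
  expect_equal(M2[3, 1], a^2)

  # columns sum to 1 after truncation renormalisation, both modes
  for (mode in c("carbon-only", "all-elements")) {
    M3 <- correctionMatrix("C10H20O4S", mode = mode)
    expect_equal(unname(colSums(M3)), rep(1, 11))
  }
  # carbon-only operator is lower triangular
  expect_true(all(M2[upper.tri(M2)] == 0))
  expect_error(correctionMatrix("H2O"), "carbon")
})

test_that("correctMid recovers forward-convolved MIDs to 1e-9 L1", {
  withr::with_seed(77, {
    for (i in 1:12) {
      nC <- sample(2:30, 1)
      formula <- sprintf("C%dH%dO%d", nC, 2 * nC, sample(1:4, 1))
      mid <- runif(nC + 1)
      mid <- mid / sum(mid)
      mode <- sample(c("carbon-only", "all-elements"), 1)
      M <- correctionMatrix(formula, mode = mode)
      y <- as.vector(M %*% mid) * 1e6
      out <- correctMid(y, formula, mode = mode)
      expect_lt(sum(abs(out$mid - mid)), 1e-9)
      expect_equal(sum(out$mid), 1)
      expect_true(all(out$mid >= 0))
    }
  })
})

test_that("carbon-only back-substitution equals the constrained solve", {
  # lower-triangular system: direct forward solve is an independent route
  withr::with_seed(5, {
    nC <- 6
    M <- correctionMatrix("C6H12O6", mode = "carbon-only")
    mid <- runif(nC + 1); mid <- mid / sum(mid)
    y <- as.vector(M %*% mid)
    xFS <- forwardsolve(M, y)
    expect_true(all(xFS > -1e-12))
    out <- correctMid(y, "C6H12O6", mode = "carbon-only")
    expect_lt(sum(abs(out$mid - xFS / sum(xFS))), 1e-9)
  })
})

test_that("unlabelled samples have near-zero labelled fraction", {
  for (nC in c(3, 8, 14, 20)) {
    formula <- sprintf("C%dH%dO2", nC, 2 * nC)
    mid0 <- c(1, rep(0, nC))
    raw <- simTracingSamples(formula, mid0, nReps = 1, noiseCv = 0,
                             mode = "all-elements", seed = 1)
    out <- correctMid(raw$intensity, formula, mode = "all-elements")
    expect_lte(enrichmentMetrics(out$mid)$labelledFraction, 0.005)
  }
})

test_that("correction tolerates multiplicative noise", {
  withr::with_seed(100, {
    l1 <- vapply(1:60, function(s) {
      mid <- c(0.4, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
      raw <- simTracingSamples("C6H12O6", mid, nReps = 1, noiseCv = 0.05,
                               mode = "all-elements", seed = s)
      out <- correctMid(raw$intensity, "C6H12O6", mode = "all-elements")
      sum(abs(out$mid - mid))
    }, numeric(1))
    # recovery error stays well below the 5% noise scale
    expect_lt(median(l1), 0.05)
  })
})

test_that("in-package NNLS agrees with an independent solver", {
  skip_if_not_installed("pracma")
  withr::with_seed(41, {
    for (i in 1:10) {
      n <- sample(3:12, 1)
      A <- matrix(runif(n * n), n, n) + diag(n)
      b <- runif(n)
      mine <- nnlsSolve(A, b)
      ref <- pracma::lsqnonneg(A, b)
      expect_equal(mine$x, ref$x, tolerance = 1e-8)
      expect_true(all(mine$x >= 0))
    }
  })
})

test_that("correctMid input validation", {
  expect_error(correctMid(c(0, 0, 0), "C2H4O2"), "empty signal")
  expect_error(correctMid(c(1, 1), "C2H4O2"), "length")
  expect_error(correctMid(c(1, -1, 0), "C2H4O2"), "non-negative")
})

test_that("enrichment metrics match their definitions", {
  m <- enrichmentMetrics(c(1, 0, 0))
  expect_equal(m$labelledFraction, 0)
  expect_equal(m$fractionalEnrichment, 0)
  m2 <- enrichmentMetrics(c(0, 0, 1))
  expect_equal(m2$labelledFraction, 1)
  expect_equal(m2$fractionalEnrichment, 1)
  withr::with_seed(2, {
    x <- runif(7); x <- x / sum(x)
    m3 <- enrichmentMetrics(x)
    expect_equal(m3$labelledFraction, 1 - x[1])
    expect_equal(m3$labelledFraction, sum(x[-1]))
  })
  expect_error(enrichmentMetrics(c(0.7, 0.7)), "not normalised")
})

test_that("normalizeAbundance arithmetic and homogeneity", {
  expect_equal(unname(normalizeAbundance(c(a = 100), 2, 5)), 10)
  expect_equal(normalizeAbundance(c(x = 3, y = 4)),
               c(x = 3, y = 4))
  v <- c(10, 20, 30); std <- c(1, 2, 4); prot <- c(2, 2, 2)
  expect_equal(normalizeAbundance(v, 3 * std, prot),
               normalizeAbundance(v, std, prot) / 3)
  expect_error(normalizeAbundance(c(s1 = 1), internalStandard = 0), "s1")
})

test_that("correctTracingTable corrects every compound/sample record", {
  raw <- rbind(
    simTracingSamples("C3H4O3", c(0.5, 0.2, 0.1, 0.2), nReps = 2,
                      noiseCv = 0, compound = "pyruvate", seed = 1),
    simTracingSamples("C6H12O6", c(0.9, rep(0, 5), 0.1), nReps = 2,
                      noiseCv = 0, compound = "glucose", seed = 2))
  out <- correctTracingTable(raw)
  expect_setequal(unique(out$compound), c("pyruvate", "glucose"))
  pyr <- out[out$compound == "pyruvate" & out$sample == "rep1", ]
  expect_equal(pyr$mid, c(0.5, 0.2, 0.1, 0.2), tolerance = 1e-9)
  glc <- out[out$compound == "glucose" & out$sample == "rep2", ]
  expect_equal(glc$labelledFraction[1], 0.1, tolerance = 1e-9)
  expect_error(correctTracingTable(raw[, -5]), "missing column")
})
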