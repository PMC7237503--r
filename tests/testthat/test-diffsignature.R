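test_that("differentialTable computes exact fold changes and sane p-values", {
  # identical group and reference: log2fc 0, t = 0, p = 1
  om <- makeToyMatrix(c(4, 8, 16), c(4, 8, 16))
  res <- differentialTable(om)
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)

  # noiseless planted twofold shift: log2fc exactly 1
  om2 <- makeToyMatrix(c(8, 16, 32), c(4, 8, 16))
  res2 <- differentialTable(om2)
  expect_equal(res2$log2fc, 1)
  expect_identical(res2$sign, 1)

  expect_error(differentialTable(om, comparisons = "nope"),
               "unknown group")
})

test_that("q-values match an independent BH recomputation", {
  sim <- simProteome(nFeatures = 400, repsPerGroup = 3, seed = 12)
  res <- differentialTable(sim$matrix)
  for (key in split(res, paste(res$group, res$format))) {
    expect_equal(key$q, bhOracle(key$p), tolerance = 1e-12)
    expect_true(all(key$q >= key$p))
    # BH q is monotone non-decreasing in sorted p order
    o <- order(key$p)
    expect_true(all(diff(key$q[o]) >= -1e-12))
  }
})

test_that("features with missing replicates are dropped, not imputed", {
  m <- matrix(2^c(10, 11, 10.5, 12, 12.5, 13,
                  0, 0, 10, 12, 12.5, 13), 2, 6, byrow = TRUE,
              dimnames = list(c("ok", "sparse"), paste0("s", 1:6)))
  m[2, 1:2] <- 0  # -> non-finite on the log scale
  om <- OmicsMatrix(m, group = rep(c("G", "REF"), each = 3),
                    replicate = rep(1:3, 2), reference = "REF")
  res <- differentialTable(om)
  expect_true(is.na(res$p[res$feature == "sparse"]))
  expect_false(is.na(res$p[res$feature == "ok"]))
})

test_that("selectConsistent applies the k-of-n rule with sign consistency", {
  empty <- selectConsistent(data.frame(feature = character(),
                                       log2fc = numeric(), p = numeric(),
                                       sign = integer()))
  expect_identical(nrow(empty), 0L)
  expect_error(selectConsistent(empty, fcThreshold = 1), "invalid threshold")

  res <- data.frame(feature = rep(c("a", "b", "c"), each = 3),
                    log2fc = c(1, 1, 1,  1, 1, -1,  1, 1, 0.2),
                    p = 0.01, sign = sign(c(1, 1, 1, 1, 1, -1, 1, 1, 0.2)))
  # all three comparisons required
  sel <- selectConsistent(res, fcThreshold = 1.5, kOfN = 3)
  expect_identical(sel$feature, "a")
  # with k = 2, b fails the sign rule until it is relaxed
  sel2 <- selectConsistent(res, fcThreshold = 1.5, kOfN = 2)
  expect_setequal(sel2$feature, c("a", "c"))
  sel3 <- selectConsistent(res, fcThreshold = 1.5, kOfN = 2,
                           requireSign = FALSE)
  expect_setequal(sel3$feature, c("a", "b", "c"))
})

test_that("tightening thresholds never enlarges the selection", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 60
      res <- data.frame(feature = rep(sprintf("f%02d", 1:n), each = 4),
                        log2fc = rnorm(4 * n, sd = 1.5),
                        p = runif(4 * n, 0, 0.2))
      res$sign <- sign(res$log2fc)
      # monotonicity is a property of the threshold/count rule; the sign
      # filter can interact with shrinking qualifying sets, so it is off
      base <- selectConsistent(res, fcThreshold = 1.3, pThreshold = 0.1,
                               kOfN = 2, requireSign = FALSE)$feature
      expect_true(all(
        selectConsistent(res, fcThreshold = 1.8, pThreshold = 0.1,
                         kOfN = 2, requireSign = FALSE)$feature %in% base))
      expect_true(all(
        selectConsistent(res, fcThreshold = 1.3, pThreshold = 0.02,
                         kOfN = 2, requireSign = FALSE)$feature %in% base))
      expect_true(all(
        selectConsistent(res, fcThreshold = 1.3, pThreshold = 0.1,
                         kOfN = 4, requireSign = FALSE)$feature %in% base))
    }
  })
})

test_that("intersectContexts returns a subset of every input selection", {
  disjoint <- list(`2D` = data.frame(feature = "a", nQualify = 3L,
                                     direction = 1L),
                   `3D` = data.frame(feature = "b", nQualify = 3L,
                                     direction = 1L))
  expect_identical(nrow(intersectContexts(disjoint)), 0L)
  expect_error(intersectContexts(disjoint[1]), "at least 2")

  withr::with_seed(17, {
    for (rep in 1:5) {
      feats <- sprintf("f%02d", 1:30)
      mk <- function() {
        f <- sample(feats, 12)
        data.frame(feature = f, nQualify = 3L,
                   direction = sample(c(-1L, 1L), 12, replace = TRUE))
      }
      sels <- list(`2D` = mk(), `3D` = mk())
      panel <- intersectContexts(sels)
      for (s in sels) expect_true(all(panel$feature %in% s$feature))
    }
  })
})

test_that("scoreSelection matches its definition and random expectation", {
  sim <- simProteome(nFeatures = 200, fracSignature = 0.1, seed = 5)
  sig <- sim$truth$feature[sim$truth$isSignature]
  expect_equal(scoreSelection(sig, sim$truth),
               list(sensitivity = 1, observedFdr = 0))
  expect_equal(scoreSelection(character(), sim$truth),
               list(sensitivity = 0, observedFdr = 0))
  expect_error(scoreSelection("nonexistent", sim$truth), "unknown feature")

  # random selections of size s recover on average s/n of the signature
  withr::with_seed(23, {
    s <- 40
    sens <- replicate(400, scoreSelection(
      sample(sim$truth$feature, s), sim$truth)$sensitivity)
    expect_equal(mean(sens), s / 200, tolerance = 0.1)
  })
})

test_that("permutation mode gives calibrated p-values under the null", {
  sim <- simProteome(nFeatures = 300, fracSignature = 0, repsPerGroup = 4,
                     seed = 8)
  res <- differentialTable(sim$matrix, method = "permutation",
                           nPerm = 60, seed = 2)
  p <- res$p[res$group == "BicalutR" & res$format == "2D"]
  expect_true(all(p > 0 & p <= 1))
  expect_gt(mean(p < 0.1), 0.04)
  expect_lt(mean(p < 0.1), 0.18)
})
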