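test_that("despike removes planted cosmic spikes and nothing else", {
  sim <- simRamanMap(nx = 6, ny = 6, nSpikes = 4, seed = 14)
  pre <- preprocessMap(sim$map, baselineOrder = NA)
  sp <- sim$truth$spikes
  s <- spectraMatrix(pre)
  for (k in seq_len(nrow(sp))) {
    v <- s[, sp$pixel[k]]
    med <- runmed(v, 5, endrule = "median")
    dev <- abs(v - med)
    localMad <- runmed(dev, 5, endrule = "median") * 1.4826
    # post-despike deviation at the planted channel is below 2 local MADs
    expect_lt(dev[sp$channel[k]],
              2 * max(localMad[sp$channel[k]], mad(v)))
  }
  # spike-free spectra pass through unchanged
  sim0 <- simRamanMap(nx = 4, ny = 4, nSpikes = 0, fracBackground = 0,
                      seed = 3)
  pre0 <- preprocessMap(sim0$map, baselineOrder = NA)
  expect_equal(spectraMatrix(pre0), spectraMatrix(sim0$map))
})

test_that("an exact order-11 polynomial is removed to numerical zero", {
  wn <- seq(2700, 3100, 2)
  x <- (wn - mean(wn)) / diff(range(wn))
  pol <- 500 + 300 * x - 200 * x^2 + 120 * x^7 - 50 * x^11
  mp <- RamanMap(wn, cbind(pol, 2 * pol),
                 data.frame(x = c(0, 100), y = 0))
  out <- preprocessMap(mp, spikeK = 50)
  expect_lt(max(abs(spectraMatrix(out))), 1e-8)
})

test_that("cropMap point counts and range checks", {
  wn <- 2700:3100
  mp <- RamanMap(wn, matrix(1, length(wn), 2),
                 data.frame(x = c(0, 100), y = 0))
  crp <- cropMap(mp, 2800, 3020)
  expect_identical(length(wavenumbers(crp)), 221L)
  expect_error(cropMap(mp, 2500, 3020), "range error")
  expect_error(cropMap(mp, 3020, 2800), "range error")
})

test_that("tissue mask keeps high-intensity pixels only", {
  wn <- seq(2800, 3020, 2)
  s <- matrix(0, length(wn), 4)
  s[, 3] <- 5; s[, 4] <- 6
  mp <- RamanMap(wn, s, data.frame(x = 1:4 * 100, y = 0))
  expect_identical(unname(tissueMask(mp, 0.25)),
                   c(FALSE, FALSE, TRUE, TRUE))
  zero <- RamanMap(wn, matrix(0, length(wn), 3),
                   data.frame(x = 1:3, y = 0))
  expect_true(!any(tissueMask(zero)))
})

test_that("qcFilter applies the absolute floor and the 1-SD rule", {
  wn <- seq(2800, 3020, 2)  # 111 points
  mk <- function(tot) matrix(tot / length(wn), length(wn), 1)
  s <- cbind(mk(59999), mk(60000), mk(80000), mk(80000))
  mp <- RamanMap(wn, s, data.frame(x = 1:4 * 100, y = 0))
  out <- qcFilter(mp, intensityFloor = 60000, sdK = 1)
  expect_identical(out$report$droppedStage1, 1L)
  expect_true("px1" %in% setdiff(colnames(spectraMatrix(mp)),
                                 colnames(spectraMatrix(out$map))))
  # identical surviving spectra: stage 2 drops none
  same <- RamanMap(wn, cbind(mk(7e4), mk(7e4), mk(7e4)),
                   data.frame(x = 1:3, y = 0))
  rep2 <- qcFilter(same)$report
  expect_identical(rep2$droppedStage2, 0L)
  expect_identical(rep2$retained + rep2$droppedStage1 +
                     rep2$droppedStage2, rep2$nInput)
  expect_error(qcFilter(RamanMap(wn, mk(10), data.frame(x = 1, y = 0))),
               "empty map")
})

test_that("planted background pixels are all removed at the floor stage", {
  for (s in 1:4) {
    sim <- simRamanMap(nx = 7, ny = 7, fracBackground = 0.2, seed = s)
    crp <- cropMap(preprocessMap(sim$map))
    out <- qcFilter(crp, intensityFloor = 60000)
    expect_identical(out$report$droppedStage1,
                     sum(sim$truth$background))
    expect_true(!any(colnames(spectraMatrix(out$map)) %in%
                       colnames(spectraMatrix(crp))[sim$truth$background]))
  }
})

test_that("normalisation is affine-invariant and flags degenerate pixels", {
  sim <- simRamanMap(nx = 4, ny = 4, fracBackground = 0, seed = 6)
  crp <- cropMap(preprocessMap(sim$map))
  n1 <- normalizeSpectra(crp)
  aff <- RamanMap(wavenumbers(crp), 2.5 * spectraMatrix(crp) + 300,
                  pixelCoords(crp))
  n2 <- normalizeSpectra(aff)
  expect_equal(spectraMatrix(n1), spectraMatrix(n2))
  ai <- which.min(abs(wavenumbers(n1) - 2933))
  expect_equal(unname(spectraMatrix(n1)[ai, ]),
               rep(1, ncol(spectraMatrix(n1))))

  wn <- wavenumbers(crp)
  degen <- RamanMap(wn, cbind(spectraMatrix(crp)[, 1], 5),
                    data.frame(x = c(0, 100), y = 0))
  nd <- normalizeSpectra(degen)
  expect_identical(attr(nd, "flaggedPixels"), "px2")
  expect_identical(ncol(spectraMatrix(nd)), 1L)
  expect_error(normalizeSpectra(crp, anchor = 5000), "range error")
})

test_that("band ratios: symmetry, monotonicity and range checks", {
  wn <- seq(2800, 3020, 1)
  g <- function(c0, a) a * exp(-(wn - c0)^2 / (2 * 9^2))
  mk <- function(a1, a2, a3) g(2845, a1) + g(2880, a2) + g(2935, a3)
  mp <- RamanMap(wn, cbind(mk(1, 0, 1), mk(2, 0, 1), mk(3, 0, 1)),
                 data.frame(x = 1:3, y = 0))
  br <- bandRatios(mp)
  expect_equal(br$perPixel$rLipid[1], 1, tolerance = 1e-6)
  expect_true(all(diff(br$perPixel$rLipid) > 0))
  expect_error(bandRatios(cropMap(mp, 2900, 3000)), "range error")
})

test_that("full pipeline recovers a planted group ratio difference", {
  d0 <- vapply(1:6, function(s)
    ramanPipeline(simRamanMap(nx = 6, ny = 6, groupDelta = 0,
                              seed = s)$map)$ratios$summary$mean[1],
    numeric(1))
  d1 <- vapply(1:6, function(s)
    ramanPipeline(simRamanMap(nx = 6, ny = 6, groupDelta = 0.3,
                              seed = 100 + s)$map)$ratios$summary$mean[1],
    numeric(1))
  expect_equal(mean(d1) - mean(d0), 0.3, tolerance = 0.1 * 0.3)
  # pipeline order is logged
  lg <- processingLog(ramanPipeline(simRamanMap(nx = 4, ny = 4,
                                                seed = 1)$map)$map)
  expect_true(grepl("despike", lg[2]))
  expect_true(grepl("baseline", lg[3]))
  expect_true(grepl("crop", lg[4]))
  expect_true(grepl("tissueMask", lg[5]))
  expect_true(grepl("qc", lg[6]))
  expect_true(grepl("normalise", lg[7]))
})

test_that("Mann-Whitney comparison matches brute-force U on small inputs", {
  withr::with_seed(9, {
    for (i in 1:10) {
      x <- round(runif(sample(3:8, 1), 0, 4), 1)
      y <- round(runif(sample(3:8, 1), 0, 4), 1)
      out <- compareRatioGroups(c(x, y),
                                rep(c("A", "B"), c(length(x), length(y))))
      expect_equal(out$U, mannWhitneyBruteU(x, y))
    }
  })
  same <- compareRatioGroups(rep(1, 8), rep(c("A", "B"), 4))
  expect_equal(same$p, 1)
  expect_error(compareRatioGroups(1:4, rep("A", 4)), "grouping error")
})
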