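test_that("stratifyKmeans recovers separated point masses and labels", {
  x <- rep(c(-5, 0, 5), each = 10)
  s <- stratifyKmeans(x + rnorm(30, sd = 1e-3), k = 3, seed = 1)
  expect_identical(as.character(s$stratum),
                   rep(c("low", "mid", "high"), each = 10))
  expect_true(all(diff(s$centroids) > 0))
  expect_error(stratifyKmeans(rep(1, 10), k = 3), "degenerate")
})

test_that("stratification is invariant to input row order", {
  withr::with_seed(4, {
    x <- c(rnorm(20, -2), rnorm(20, 0), rnorm(20, 2))
    perm <- sample(60)
  })
  s1 <- stratifyKmeans(x, seed = 11)
  s2 <- stratifyKmeans(x[perm], seed = 11)
  expect_identical(as.character(s1$stratum)[perm],
                   as.character(s2$stratum))
  expect_equal(s1$centroids, s2$centroids)
})

test_that("DP k-means equals brute-force enumeration of partitions", {
  # exhaustive search over contiguous 3-way splits of the sorted values
  bruteWss <- function(x) {
    xs <- sort(x); n <- length(xs); best <- Inf
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) {
      w <- sum(vapply(list(xs[1:a], xs[(a + 1):b], xs[(b + 1):n]),
                      function(v) sum((v - mean(v))^2), numeric(1)))
      if (w < best) best <- w
    }
    best
  }
  withr::with_seed(51, {
    for (i in 1:6) {
      n <- sample(6:12, 1)
      x <- rnorm(n, mean = sample(0:2, n, replace = TRUE) * 2)
      exact <- stratifyKmeans(x, k = 3, method = "exact")
      expect_equal(exact$withinSS, bruteWss(x - mean(x)),
                   tolerance = 1e-10)
    }
  })
})

test_that("multi-restart k-means attains the DP-optimal clustering", {
  withr::with_seed(8, {
    for (i in 1:12) {
      n <- sample(10:50, 1)
      x <- rnorm(n, mean = sample(0:3, n, replace = TRUE) * 2)
      if (length(unique(x)) < 3) next
      heur <- stratifyKmeans(x, k = 3, restarts = 50, seed = i)
      exact <- stratifyKmeans(x, k = 3, method = "exact")
      expect_equal(heur$withinSS, exact$withinSS, tolerance = 1e-8)
      expect_identical(as.character(heur$stratum),
                       as.character(exact$stratum))
    }
  })
})

test_that("KM curve equals the closed form and the product oracle", {
  km <- kmCurve(c(2, 5, 7, 9), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(kmCurve(c(3, 6, 8), c(0, 0, 0))$surv, c(1, 1, 1))
  withr::with_seed(19, {
    for (i in 1:8) {
      n <- sample(5:15, 1)
      time <- sample(1:10, n, replace = TRUE)
      event <- rbinom(n, 1, 0.7)
      if (!any(event == 1)) next
      km <- kmCurve(time, event)
      orc <- kmProductOracle(time, event)
      expect_equal(km$surv[km$nEvent > 0], orc$surv, tolerance = 1e-12)
    }
  })
  expect_error(kmCurve(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM estimate is a non-increasing step function in [0,1]", {
  withr::with_seed(33, {
    for (i in 1:5) {
      coh <- simCohort(n = 40, seed = i)
      km <- kmCurve(coh$time, coh$event)
      expect_true(all(diff(km$surv) <= 1e-12))
      expect_true(all(km$surv >= 0 & km$surv <= 1))
    }
  })
})

test_that("logrank equals the textbook O-E/V computation", {
  time <- c(1, 3, 4, 2, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("A", "B"), each = 3)
  out <- logrankTest(group, time, event)
  expect_equal(out$chi2, logrankOracle2(time, event, group),
               tolerance = 1e-12)
  expect_identical(out$df, 1L)
  withr::with_seed(55, {
    for (i in 1:6) {
      n <- 14
      time <- sample(1:12, n, replace = TRUE)
      event <- rbinom(n, 1, 0.8)
      group <- sample(c("A", "B"), n, replace = TRUE)
      if (length(unique(group)) < 2 || sum(event) == 0) next
      expect_equal(logrankTest(group, time, event)$chi2,
                   logrankOracle2(time, event, group), tolerance = 1e-9)
    }
  })
})

test_that("logrank separates extreme strata and needs 2+ strata", {
  time <- c(1:20 / 10, 10 + 1:20 / 10)
  event <- rep(1, 40)
  group <- rep(c("early", "late"), each = 20)
  expect_lt(logrankTest(group, time, event)$p, 1e-4)
  expect_error(logrankTest(rep("A", 10), 1:10, rep(1, 10)), "df error")
})

test_that("logrank is invariant under monotone time transforms", {
  coh <- simCohort(n = 80, seed = 2)
  a <- logrankTest(coh$component, coh$time, coh$event)
  b <- logrankTest(coh$component, log1p(coh$time), coh$event)
  expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
})

test_that("signed-rank test: exact enumeration, ties, and extremes", {
  # all 14 differences positive: two-sided exact p = 2 / 2^14
  out <- wilcoxonSignedRank(rep(1, 14))
  expect_equal(out$p, 2 / 2^14)
  expect_identical(out$method, "exact")

  # symmetric differences give p near 1
  sym <- wilcoxonSignedRank(c(-3, 3, -2, 2, -1, 1))
  expect_gt(sym$p, 0.8)

  # exact p equals full enumeration for n <= 12, with and without ties
  withr::with_seed(66, {
    for (i in 1:10) {
      n <- sample(5:12, 1)
      d <- round(rnorm(n, 0.4), sample(0:1, 1))
      d <- d[d != 0]
      if (length(d) < 5) next
      expect_equal(wilcoxonSignedRank(d)$p, signedRankEnumP(d),
                   tolerance = 1e-12)
    }
  })

  # matches wilcox.test's exact p when there are no ties or zeros
  withr::with_seed(67, {
    d <- rnorm(10, 0.5)
    ref <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(wilcoxonSignedRank(d)$p, ref, tolerance = 1e-12)
  })

  expect_error(wilcoxonSignedRank(c(0, 0, 0, 0, 0)), "degenerate")
  expect_error(wilcoxonSignedRank(c(1, 2)), "at least 5")
  # pre/post interface
  expect_equal(wilcoxonSignedRank(pre = rep(0, 14), post = rep(1, 14))$p,
               2 / 2^14)
})

test_that("stratified survival analysis detects planted hazard ratios", {
  hits <- vapply(1:20, function(s) {
    coh <- simCohort(n = 300, hazardRatios = c(1, 1.4, 2), seed = s)
    strat <- stratifyKmeans(coh$expression, k = 3, seed = s)
    logrankTest(strat, coh$time, coh$event)$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
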