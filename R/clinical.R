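#' Stratify patients by expression with 1-D k-means
#'
#' Mean-centres a single gene's expression values and clusters them into
#' `k` groups with one-dimensional k-means. The default engine is
#' [stats::kmeans()] (Hartigan-Wong) with `restarts` seeded random starts,
#' keeping the solution with the lowest within-cluster sum of squares;
#' `method = "exact"` computes the provably optimal clustering by
#' dynamic programming over the sorted values (contiguity of optimal 1-D
#' clusters). Clusters are relabelled by ascending centroid as
#' low / mid / high (for k = 3; `stratum1..k` otherwise), so labels do not
#' depend on initialisation or input order.
#'
#' @param expression numeric vector of expression values (or a cohort
#'   data.frame with an `expression` column).
#' @param k number of strata (default 3).
#' @param restarts number of k-means++ restarts (heuristic engine).
#' @param seed integer seed for the restarts.
#' @param method `"restarts"` (default) or `"exact"` dynamic programming.
#' @return List with `stratum` (factor, ordered low to high), `centroids`
#'   (ascending, on the centred scale), `withinSS` and `center` (the
#'   subtracted mean).
#' @examples
#' x <- c(rnorm(20, -3), rnorm(20, 0), rnorm(20, 3))
#' s <- stratifyKmeans(x, k = 3, seed = 1)
#' table(s$stratum)
#' @export
stratifyKmeans <- function(expression, k = 3, restarts = 20, seed = 1,
                           method = c("restarts", "exact")) {
  if (is.data.frame(expression)) expression <- expression$expression
  method <- match.arg(method)
  x <- as.numeric(expression)
  if (anyNA(x)) stop("expression values must not be missing")
  if (length(unique(x)) < k)
    stop("degenerate data: fewer than k distinct expression values")
  ctr <- mean(x)
  xc <- x - ctr
  if (method == "exact") {
    fit <- kmeans1dExact(xc, k)
  } else {
    km <- withr::with_seed(seed,
      kmeans(xc, centers = k, nstart = restarts, iter.max = 100))
    fit <- list(cluster = km$cluster, centroids = as.vector(km$centers),
                withinSS = km$tot.withinss)
  }
  ord <- order(fit$centroids)
  lab <- if (k == 3) c("low", "mid", "high") else paste0("stratum", 1:k)
  relab <- integer(k); relab[ord] <- seq_len(k)
  stratum <- factor(lab[relab[fit$cluster]], levels = lab)
  list(stratum = stratum, centroids = sort(fit$centroids),
       withinSS = fit$withinSS, center = ctr)
}

# exact 1-D k-means by dynamic programming on sorted values; O(k n^2)
kmeans1dExact <- function(x, k) {
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  segCost <- function(i, j) { # within-SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) { D[1, j] <- segCost(1, j); B[1, j] <- 1L }
  if (k > 1) for (q in 2:k) for (j in q:n) {
    for (i in q:j) {
      c <- D[q - 1, i - 1] + segCost(i, j)
      if (c < D[q, j]) { D[q, j] <- c; B[q, j] <- i }
    }
  }
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (q in k:1) { bounds[q] <- B[q, j] - 1L; j <- B[q, j] - 1L }
  clSorted <- rep(seq_len(k), diff(bounds))
  cl <- integer(n); cl[ord] <- clSorted
  centroids <- vapply(seq_len(k), function(q) mean(x[cl == q]), numeric(1))
  list(cluster = cl, centroids = centroids, withinSS = D[k, n])
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function with right censoring,
#' computed with [survival::survfit()]. The curve starts at 1, is
#' non-increasing and drops only at event times.
#'
#' @param time non-negative follow-up times.
#' @param event event indicator (1 = event, 0 = censored).
#' @return data.frame with `time`, `nRisk`, `nEvent`, `surv`.
#' @examples
#' kmCurve(c(2, 5, 7, 9), c(1, 1, 1, 1))$surv  # 0.75 0.50 0.25 0.00
#' @export
kmCurve <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up times")
  if (!length(time)) stop("at least one subject is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
             surv = fit$surv)
}

#' k-sample logrank test
#'
#' Standard logrank chi-square comparing the survival of two or more
#' strata (observed minus expected events over the pooled risk sets, with
#' the hypergeometric variance for ties), via [survival::survdiff()];
#' `df = strata - 1`.
#'
#' @param strata stratum label per subject (or a [stratifyKmeans()]
#'   result, from which the `stratum` factor is taken).
#' @param time,event follow-up times and event indicators.
#' @return List with `chi2`, `df` and `p`.
#' @examples
#' coh <- simCohort(n = 60, hazardRatios = c(1, 4), censorRate = 0,
#'                  componentMeans = c(0, 2), seed = 1)
#' logrankTest(coh$component, coh$time, coh$event)
#' @export
logrankTest <- function(strata, time, event) {
  if (is.list(strata) && !is.null(strata$stratum)) strata <- strata$stratum
  strata <- factor(strata)
  if (nlevels(droplevels(strata)) < 2)
    stop("df error: at least 2 non-empty strata are required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ strata)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Wilcoxon matched-pair signed-rank test
#'
#' Signed-rank test for paired scores (e.g. post- minus pre-treatment
#' histoscores). Zero differences are dropped, tied absolute differences
#' receive average ranks, and the two-sided p-value is exact for up to 25
#' non-zero pairs -- computed from the full permutation distribution of
#' the positive-rank sum over all sign assignments (ties included, via a
#' generating-function convolution) -- and a normal approximation with
#' continuity correction otherwise.
#'
#' @param pre,post paired score vectors; alternatively pass the paired
#'   differences as `pre` and omit `post`.
#' @param exactLimit maximum number of pairs for the exact distribution.
#' @return List with `W` (positive-rank sum), `n` (non-zero pairs), `p`
#'   (two-sided) and `method`.
#' @examples
#' wilcoxonSignedRank(rep(1, 14))$p  # 2 / 2^14
#' @export
wilcoxonSignedRank <- function(pre, post = NULL, exactLimit = 25) {
  d <- if (is.null(post)) as.numeric(pre) else as.numeric(post) -
    as.numeric(pre)
  d <- d[!is.na(d)]
  if (length(d) < 5) stop("need at least 5 pairs")
  d <- d[d != 0]
  if (!length(d)) stop("degenerate: all paired differences are zero")
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactLimit) {
    # distribution of W over the 2^n sign assignments, on a half-rank grid
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- c(1, rep(0, tot))    # f[w+1] = #assignments with 2W = w
    for (ri in r2) {
      g <- f
      g[(ri + 1):(tot + 1)] <- g[(ri + 1):(tot + 1)] + f[1:(tot + 1 - ri)]
      f <- g
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    pLo <- sum(probs[1:(w2 + 1)])
    pHi <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(pLo, pHi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tieAdj <- sum(table(r)^3 - table(r)) / 48
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tieAdj)
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(W = W, n = n, p = p, method = method)
}
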