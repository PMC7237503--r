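#' Despike and baseline-correct a Raman map
#'
#' Two preprocessing steps applied to every pixel spectrum, in order:
#' cosmic-ray removal by median-window replacement (a point is a spike when
#' it exceeds the running median by more than `spikeK` local MADs, and is
#' replaced by that median), followed by subtraction of a polynomial
#' baseline of order `baselineOrder` (default 11). The baseline is fitted
#' by iterative peak exclusion (the scheme behind "intelligent" baseline
#' routines): after each least-squares fit, points lying more than
#' `baselineTol` noise SDs above the fit are excluded and the polynomial is
#' refitted to the remaining baseline-like points, so Raman bands exert no
#' upward pull. A spike-free spectrum passes through the despike stage
#' unchanged, and a spectrum that is exactly a polynomial of the baseline
#' order is reduced to zero (the first fit is already exact).
#'
#' @param map a [RamanMap-class].
#' @param despikeWindow odd window width for the running median (default 5).
#' @param spikeK MAD multiplier above which a point is a spike (default 5).
#' @param baselineOrder polynomial order of the baseline (default 11); must
#'   be smaller than the axis length. Use `NA` to skip baseline removal.
#' @param baselineTol noise tolerance of the peak exclusion, in
#'   high-frequency noise SDs (default 1.5).
#' @param baselineIter maximum refit iterations.
#' @return The preprocessed [RamanMap-class]; the number of replaced spike
#'   points is appended to the processing log.
#' @examples
#' sim <- simRamanMap(nx = 4, ny = 4, seed = 1)
#' pre <- preprocessMap(sim$map)
#' processingLog(pre)
#' @export
preprocessMap <- function(map, despikeWindow = 5, spikeK = 5,
                          baselineOrder = 11, baselineTol = 1.5,
                          baselineIter = 30) {
  stopifnot(is(map, "RamanMap"))
  s <- map@spectra
  nSpike <- 0L
  for (i in seq_len(ncol(s))) {
    v <- s[, i]
    med <- runmed(v, despikeWindow, endrule = "median")
    dev <- abs(v - med)
    localMad <- runmed(dev, despikeWindow, endrule = "median") * 1.4826
    # floor keeps smooth band apexes (curvature, not spikes) unflagged:
    # cosmic rays dwarf both the noise and a few percent of the range
    noise <- mad(diff(v)) / sqrt(2)
    thr <- spikeK * pmax(localMad,
                         pmax(noise, 0.05 * diff(range(v)), 1e-12))
    spikes <- dev > thr
    if (any(spikes)) {
      v[spikes] <- med[spikes]
      nSpike <- nSpike + sum(spikes)
      s[, i] <- v
    }
  }
  steps <- sprintf("despike(window=%d,k=%g,replaced=%d)", despikeWindow,
                   spikeK, nSpike)
  if (!is.na(baselineOrder)) {
    if (baselineOrder >= length(map@wavenumber))
      stop("baseline order must be smaller than the axis length")
    x <- (map@wavenumber - mean(map@wavenumber)) /
      diff(range(map@wavenumber))
    X <- outer(x, 0:baselineOrder, `^`)
    for (i in seq_len(ncol(s))) {
      v <- s[, i]
      # high-frequency noise estimate, fixed across iterations
      tol <- baselineTol * mad(diff(v)) / sqrt(2)
      inc <- rep(TRUE, length(v))
      for (it in seq_len(baselineIter)) {
        fit <- stats::.lm.fit(X[inc, , drop = FALSE], v[inc])
        B <- drop(X %*% fit$coefficients)
        newInc <- v < B + tol
        if (sum(newInc) <= baselineOrder + 1L || all(newInc == inc))
          break
        inc <- newInc
      }
      s[, i] <- v - B
    }
    steps <- c(steps, sprintf("baseline(order=%d,tol=%g)", baselineOrder,
                              baselineTol))
  }
  RamanMap(map@wavenumber, s, map@coords, log = c(map@log, steps))
}

#' Crop a Raman map to an analysis window
#'
#' Restricts the wavenumber axis to `[lo, hi]` (inclusive), by default the
#' 2800-3020 cm^-1 high-wavenumber window that contains the lipid,
#' cholesterol-associated and protein bands.
#'
#' @param map a [RamanMap-class].
#' @param lo,hi window bounds in reciprocal centimetres.
#' @return The cropped [RamanMap-class].
#' @export
cropMap <- function(map, lo = 2800, hi = 3020) {
  stopifnot(is(map, "RamanMap"))
  if (lo >= hi) stop("range error: need lo < hi")
  if (lo < min(map@wavenumber) || hi > max(map@wavenumber))
    stop("range error: crop window outside the spectral axis")
  keep <- map@wavenumber >= lo & map@wavenumber <= hi
  RamanMap(map@wavenumber[keep], map@spectra[keep, , drop = FALSE],
           map@coords, log = c(map@log, sprintf("crop(%g-%g)", lo, hi)))
}

#' Tissue mask from total spectral intensity
#'
#' Flags a pixel as tissue when its total (summed) intensity over the
#' current axis lies strictly above the `tissueQuantile` quantile of all
#' pixel totals, the simple intensity-based tissue selection used for
#' mapped tissue sections.
#'
#' @param map a [RamanMap-class] (typically cropped).
#' @param tissueQuantile quantile in \[0, 1) below which pixels are called
#'   background (default 0.25).
#' @return Named logical vector, TRUE for tissue pixels.
#' @export
tissueMask <- function(map, tissueQuantile = 0.25) {
  stopifnot(is(map, "RamanMap"))
  totals <- colSums(map@spectra)
  totals > quantile(totals, tissueQuantile)
}

#' Two-stage quality-control filter for map spectra
#'
#' Stage 1 drops pixels whose total spectral intensity is below
#' `intensityFloor` (default 60,000, on the scale of vendor counts;
#' configurable because the floor is absolute, not relative). Stage 2
#' computes the mean spectrum of the stage-1 survivors and drops pixels
#' whose distance to it exceeds the mean distance plus `sdK` standard
#' deviations of the distances; with `metric = "distance"` (default) the
#' Euclidean distance between spectra is used, with `metric = "total"`
#' the absolute deviation of the pixel total from the mean total.
#'
#' @param map a [RamanMap-class].
#' @param intensityFloor stage-1 absolute total-intensity floor; pixels
#'   with totals strictly below it are dropped.
#' @param sdK stage-2 standard-deviation multiplier (default 1).
#' @param metric `"distance"` (spectrum-to-mean-spectrum Euclidean
#'   distance) or `"total"` (total intensity).
#' @return List with `map` (retained pixels) and `report` (counts
#'   `nInput`, `droppedStage1`, `droppedStage2`, `retained`, plus the
#'   parameters used). `retained + droppedStage1 + droppedStage2 =
#'   nInput`.
#' @export
qcFilter <- function(map, intensityFloor = 60000, sdK = 1,
                     metric = c("distance", "total")) {
  stopifnot(is(map, "RamanMap"))
  metric <- match.arg(metric)
  totals <- colSums(map@spectra)
  pass1 <- totals >= intensityFloor
  if (!any(pass1)) stop("empty map: all pixels fall below the QC floor")
  s1 <- map@spectra[, pass1, drop = FALSE]
  if (metric == "distance") {
    mu <- rowMeans(s1)
    d <- sqrt(colSums((s1 - mu)^2))
  } else {
    d <- abs(colSums(s1) - mean(colSums(s1)))
  }
  pass2 <- if (length(d) < 2) rep(TRUE, length(d)) else
    d <= mean(d) + sdK * sd(d)
  if (all(!pass2)) stop("empty map: QC stage 2 removed every pixel")
  keep <- which(pass1)[pass2]
  report <- list(nInput = ncol(map@spectra),
                 droppedStage1 = sum(!pass1),
                 droppedStage2 = sum(!pass2),
                 retained = length(keep),
                 intensityFloor = intensityFloor, sdK = sdK,
                 metric = metric)
  list(map = subsetPixels(map, keep,
                          sprintf("qc(floor=%g,sdK=%g,%s)", intensityFloor,
                                  sdK, metric)),
       report = report)
}

#' Min-max scale and anchor-normalise map spectra
#'
#' Per pixel: the spectrum is min-max scaled to \[0, 1\] and then divided by
#' its value at the axis point nearest the anchor wavenumber (default
#' 2933 cm^-1, with 2935 available by argument), so the anchor intensity
#' becomes 1. The combined transform is invariant to any positive affine
#' transform of the input spectrum. Pixels with a degenerate range or a
#' zero anchor value after scaling are dropped and reported.
#'
#' @param map a [RamanMap-class] (cropped and QC-filtered).
#' @param anchor anchor wavenumber in reciprocal centimetres.
#' @return The normalised [RamanMap-class]; ids of any dropped degenerate
#'   pixels are stored in `attr(, "flaggedPixels")`.
#' @export
normalizeSpectra <- function(map, anchor = 2933) {
  stopifnot(is(map, "RamanMap"))
  if (anchor < min(map@wavenumber) || anchor > max(map@wavenumber))
    stop("range error: anchor outside the spectral axis")
  ai <- which.min(abs(map@wavenumber - anchor))
  s <- map@spectra
  mins <- apply(s, 2, min)
  rng <- apply(s, 2, max) - mins
  bad <- rng <= 0
  s <- sweep(sweep(s, 2, mins), 2, pmax(rng, 1e-300), "/")
  av <- s[ai, ]
  bad <- bad | av <= 0
  if (all(bad)) stop("all pixels degenerate under normalisation")
  s <- sweep(s[, !bad, drop = FALSE], 2, av[!bad], "/")
  out <- RamanMap(map@wavenumber, s, map@coords[!bad, , drop = FALSE],
                  log = c(map@log,
                          sprintf("normalise(minmax+anchor@%g)", anchor)))
  attr(out, "flaggedPixels") <- colnames(map@spectra)[bad]
  out
}

#' Per-pixel Raman band ratios
#'
#' Reads the intensity at the axis points nearest each band position and
#' forms the two diagnostic ratios: `rLipid` = I(2845)/I(2935), the
#' lipid-CH2 to protein-CH3 ratio, and `rChol` = I(2880)/I(2935), the
#' cholesterol-associated ratio. Intended to run on normalised spectra.
#'
#' @param map a [RamanMap-class].
#' @param lipidBand,cholBand,proteinBand band positions in reciprocal
#'   centimetres.
#' @return List with `perPixel` (data.frame: pixel, x, y, rLipid, rChol)
#'   and `summary` (per-map mean and SD of each ratio).
#' @export
bandRatios <- function(map, lipidBand = 2845, cholBand = 2880,
                       proteinBand = 2935) {
  stopifnot(is(map, "RamanMap"))
  for (b in c(lipidBand, cholBand, proteinBand))
    if (b < min(map@wavenumber) || b > max(map@wavenumber))
      stop("range error: band ", b, " cm^-1 outside the spectral axis")
  at <- function(b) map@spectra[which.min(abs(map@wavenumber - b)), ]
  den <- at(proteinBand)
  perPixel <- data.frame(pixel = colnames(map@spectra),
                         x = map@coords$x, y = map@coords$y,
                         rLipid = at(lipidBand) / den,
                         rChol = at(cholBand) / den, row.names = NULL)
  summary <- data.frame(
    ratio = c("rLipid", "rChol"),
    mean = c(mean(perPixel$rLipid), mean(perPixel$rChol)),
    sd = c(sd(perPixel$rLipid), sd(perPixel$rChol)))
  list(perPixel = perPixel, summary = summary)
}

#' Run the full Raman band-ratio pipeline on one map
#'
#' Fixed stage order: despike, polynomial baseline subtraction, crop to
#' the analysis window, intensity-based tissue mask, QC stage 1 (absolute
#' floor), QC stage 2 (distance to mean spectrum), min-max plus anchor
#' normalisation, band ratios.
#'
#' @param map a raw [RamanMap-class].
#' @param cropLo,cropHi analysis window (default 2800-3020 cm^-1).
#' @param tissueQuantile tissue-mask quantile (see [tissueMask()]).
#' @param intensityFloor,sdK,metric QC parameters (see [qcFilter()]).
#' @param anchor normalisation anchor (see [normalizeSpectra()]).
#' @param despikeWindow,spikeK,baselineOrder preprocessing parameters
#'   (see [preprocessMap()]).
#' @return List with `ratios` (see [bandRatios()]), `qcReport`, `mask`
#'   (tissue mask), and `map` (the final normalised map).
#' @examples
#' sim <- simRamanMap(nx = 6, ny = 6, seed = 1)
#' out <- ramanPipeline(sim$map)
#' out$ratios$summary
#' @export
ramanPipeline <- function(map, cropLo = 2800, cropHi = 3020,
                          tissueQuantile = 0.25, intensityFloor = 60000,
                          sdK = 1, metric = "distance", anchor = 2933,
                          despikeWindow = 5, spikeK = 5,
                          baselineOrder = 11) {
  pre <- preprocessMap(map, despikeWindow, spikeK, baselineOrder)
  crp <- cropMap(pre, cropLo, cropHi)
  mask <- tissueMask(crp, tissueQuantile)
  tis <- subsetPixels(crp, which(mask), "tissueMask")
  qc <- qcFilter(tis, intensityFloor, sdK, metric)
  nrm <- normalizeSpectra(qc$map, anchor)
  list(ratios = bandRatios(nrm), qcReport = qc$report, mask = mask,
       map = nrm)
}

#' Compare band ratios between conditions (Mann-Whitney)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on per-map summary
#' ratios between two conditions. The experimental unit is the map (one
#' animal/section each), not the pixel, to respect independence.
#'
#' @param values numeric vector of per-map mean ratios.
#' @param groups condition label per map (exactly two levels).
#' @return List with `U` (Mann-Whitney U for the first level), `p`
#'   (two-sided; exact when there are no ties and both groups have < 50
#'   observations) and the group `levels`.
#' @examples
#' compareRatioGroups(c(1.1, 1.2, 1.3, 0.8, 0.7, 0.9),
#'                    rep(c("CTL", "KO"), each = 3))
#' @export
compareRatioGroups <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2)
    stop("grouping error: exactly two conditions are required")
  x <- values[groups == lev[1]]
  y <- values[groups == lev[2]]
  if (!length(x) || !length(y))
    stop("grouping error: a condition has zero maps")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied groups carry no evidence
  list(U = unname(wt$statistic), p = p, levels = lev)
}
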