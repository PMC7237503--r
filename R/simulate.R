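#' Simulate a label-free proteome with planted differential signature
#'
#' Generates log-normal LFQ-style intensity matrices for a multi-group,
#' multi-format design (by default four groups -- a wild-type reference and
#' three resistant derivatives -- each profiled in 2D and 3D culture) with a
#' known fraction of signature proteins. Signature features are shifted by
#' their true log2 fold change in every non-reference group, with the same
#' sign in all comparisons and identically in both formats, mirroring the
#' structure of a consistent cross-inhibitor resistance panel. The returned
#' truth table scores any downstream selection without re-simulation.
#'
#' @param nFeatures number of proteins.
#' @param groups ordered group labels, reference first.
#' @param formats format labels (e.g. `c("2D", "3D")`).
#' @param repsPerGroup replicates per group and format (>= 2).
#' @param effectLog2Range interval of planted absolute log2 fold changes;
#'   lower bound must be > 0.
#' @param fracSignature fraction of features planted as signature, in
#'   \[0, 1\].
#' @param noiseSdLog replicate noise SD on the log2 scale (>= 0).
#' @param meanLog2Range range of baseline log2 intensities.
#' @param seed integer seed; runs are bit-reproducible given the seed.
#' @return List with `matrix` (an [OmicsMatrix-class] spanning all formats)
#'   and `truth`, a data.frame with `feature`, `isSignature`, `sign` and one
#'   `lfc_<group>` column of true log2 fold changes per non-reference group.
#' @examples
#' sim <- simProteome(nFeatures = 50, repsPerGroup = 3, seed = 1)
#' table(sim$truth$isSignature)
#' @export
simProteome <- function(nFeatures = 2000,
                        groups = c("WT", "BicalutR", "ApalutR", "EnzalutR"),
                        formats = c("2D", "3D"),
                        repsPerGroup = 4,
                        effectLog2Range = c(1, 2),
                        fracSignature = 0.05,
                        noiseSdLog = 0.3,
                        meanLog2Range = c(20, 30),
                        seed = 1) {
  if (nFeatures < 1 || repsPerGroup < 2)
    stop("invalid design: need nFeatures >= 1 and repsPerGroup >= 2")
  if (effectLog2Range[1] <= 0 || effectLog2Range[2] < effectLog2Range[1])
    stop("invalid design: effectLog2Range lower bound must be > 0")
  if (fracSignature < 0 || fracSignature > 1)
    stop("invalid design: fracSignature must lie in [0, 1]")
  if (noiseSdLog < 0) stop("invalid design: noiseSdLog must be >= 0")
  withr::with_seed(seed, {
    feats <- sprintf("prot%04d", seq_len(nFeatures))
    nonRef <- groups[-1L]
    nSig <- round(fracSignature * nFeatures)
    sigIdx <- if (nSig > 0) sort(sample.int(nFeatures, nSig)) else integer()
    sgn <- integer(nFeatures)
    sgn[sigIdx] <- sample(c(-1L, 1L), nSig, replace = TRUE)
    lfc <- matrix(0, nFeatures, length(nonRef),
                  dimnames = list(feats, nonRef))
    if (nSig > 0) {
      mag <- matrix(runif(nSig * length(nonRef), effectLog2Range[1],
                          effectLog2Range[2]), nSig)
      lfc[sigIdx, ] <- mag * sgn[sigIdx]
    }
    mu <- runif(nFeatures, meanLog2Range[1], meanLog2Range[2])
    cols <- expand.grid(replicate = seq_len(repsPerGroup), group = groups,
                        format = formats, stringsAsFactors = FALSE)
    shift <- cbind(0, lfc)[, match(cols$group, groups), drop = FALSE]
    logm <- matrix(mu, nFeatures, nrow(cols)) + shift +
      matrix(rnorm(nFeatures * nrow(cols), 0, noiseSdLog), nFeatures)
    mat <- 2^logm
    colnames(mat) <- sprintf("%s_%s_r%d", cols$group, cols$format,
                             cols$replicate)
    rownames(mat) <- feats
    om <- OmicsMatrix(mat, group = cols$group, format = cols$format,
                      replicate = cols$replicate, reference = groups[1])
    truth <- data.frame(feature = feats,
                        isSignature = seq_len(nFeatures) %in% sigIdx,
                        sign = sgn)
    for (g in nonRef) truth[[paste0("lfc_", g)]] <- lfc[, g]
    list(matrix = om, truth = truth)
  })
}

#' Simulate raw isotopologue replicates by forward convolution
#'
#' Generates raw isotopologue intensity vectors from a known tracer mass
#' isotopomer distribution by applying the exact forward natural-abundance
#' operator of [correctionMatrix()], scaling, and multiplicative log-normal
#' noise. At zero noise, [correctMid()] recovers the input MID exactly
#' (round-trip identity), which anchors the correctness of the correction.
#'
#' @param formula elemental formula (string or [parseFormula()] output).
#' @param trueMid probability vector over M+0 ... M+C, summing to 1.
#' @param nReps number of replicate samples.
#' @param noiseCv multiplicative coefficient of variation (0 = noiseless).
#' @param seed integer seed.
#' @param scale total raw signal per replicate.
#' @param compound compound id used in the output table.
#' @param abundances,mode,purity forward-model parameters, see
#'   [correctionMatrix()].
#' @return Long-format data.frame with columns `compound`, `formula`,
#'   `sample`, `isotopologue`, `intensity`.
#' @examples
#' tab <- simTracingSamples("C3H4O3", c(0.6, 0.1, 0.1, 0.2), nReps = 2,
#'                          noiseCv = 0, seed = 1)
#' head(tab)
#' @export
simTracingSamples <- function(formula, trueMid, nReps = 3, noiseCv = 0.05,
                              seed = 1, scale = 1e6, compound = "compound1",
                              abundances = naturalAbundances(),
                              mode = c("carbon-only", "all-elements"),
                              purity = 1) {
  mode <- match.arg(mode)
  if (is.character(formula)) formula <- parseFormula(formula)
  nC <- unname(formula["C"])
  trueMid <- as.numeric(trueMid)
  if (length(trueMid) != nC + 1L)
    stop("MID length (", length(trueMid), ") must equal C + 1 = ", nC + 1L)
  if (any(trueMid < 0) || abs(sum(trueMid) - 1) > 1e-8)
    stop("trueMid must be a probability vector")
  M <- correctionMatrix(formula, abundances, mode, purity)
  expected <- as.vector(M %*% trueMid) * scale
  fstr <- paste0(names(formula)[formula > 0], formula[formula > 0],
                 collapse = "")
  withr::with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nReps), function(r) {
      noisy <- expected * exp(rnorm(nC + 1L, 0, noiseCv))
      data.frame(compound = compound, formula = fstr,
                 sample = sprintf("rep%d", r), isotopologue = 0:nC,
                 intensity = noisy)
    }))
    rownames(out) <- NULL
    out
  })
}

# supported lipid class grammar with plausible total-carbon / double-bond
# ranges for name generation (chain form for sphingolipids)
lipidClassSpecs <- function() {
  list(
    Cer    = list(carbons = seq(32, 42, 2), db = 0:3, chain = TRUE),
    SM     = list(carbons = seq(32, 42, 2), db = 0:3, chain = TRUE),
    CL     = list(carbons = seq(64, 72, 2), db = 2:8, chain = FALSE),
    DG     = list(carbons = seq(32, 38, 2), db = 0:6, chain = FALSE),
    LysoPC = list(carbons = 16:20,          db = 0:4, chain = FALSE),
    PC     = list(carbons = seq(30, 40, 2), db = 0:6, chain = FALSE),
    PE     = list(carbons = seq(32, 40, 2), db = 0:6, chain = FALSE),
    PG     = list(carbons = seq(32, 38, 2), db = 0:5, chain = FALSE),
    PI     = list(carbons = seq(34, 40, 2), db = 0:6, chain = FALSE),
    PS     = list(carbons = seq(34, 40, 2), db = 0:6, chain = FALSE),
    TG     = list(carbons = seq(48, 58, 2), db = 0:8, chain = FALSE),
    BMP    = list(carbons = seq(34, 40, 2), db = 0:6, chain = FALSE)
  )
}

#' Simulate a lipidome with a planted saturation-dependent knockout effect
#'
#' Generates a control-vs-knockout lipidomics matrix whose group effect is
#' tied to the double-bond count of each species: in the KO group, species
#' with more than two double bonds (highly unsaturated) are scaled up by
#' `koEffect` and species with two or fewer double bonds scaled down by
#' `1/koEffect`. This emulates the saturation imbalance seen when an
#' auxiliary PUFA-degradation enzyme is lost. All generated names round-trip
#' through [parseLipidName()].
#'
#' @param classes lipid class labels drawn from the supported grammar (see
#'   [parseLipidName()]).
#' @param nPerClass species per class.
#' @param koEffect linear fold effect (> 0); 1 plants no difference.
#' @param groups group labels, reference (control) first.
#' @param repsPerGroup replicates per group.
#' @param noiseSdLog replicate noise SD on the log2 scale.
#' @param seed integer seed.
#' @return List with `matrix` (an [OmicsMatrix-class]), `species` (the
#'   parsed [parseLipidName()] table) and `truth` (per-species saturation
#'   class and planted direction in KO).
#' @examples
#' sim <- simLipidome(classes = c("PC", "TG"), nPerClass = 4, seed = 1)
#' sim$truth
#' @export
simLipidome <- function(classes = c("PC", "PE", "TG", "Cer", "SM", "DG"),
                        nPerClass = 10, koEffect = 2,
                        groups = c("CTL", "KO"), repsPerGroup = 3,
                        noiseSdLog = 0.2, seed = 1) {
  specs <- lipidClassSpecs()
  bad <- setdiff(classes, names(specs))
  if (length(bad))
    stop("unsupported lipid class(es): ", paste(bad, collapse = ", "))
  if (koEffect <= 0) stop("koEffect must be > 0")
  withr::with_seed(seed, {
    names_ <- unlist(lapply(classes, function(cl) {
      sp <- specs[[cl]]
      combos <- expand.grid(carbons = as.integer(sp$carbons),
                            db = as.integer(sp$db))
      pick <- combos[sample.int(nrow(combos), min(nPerClass, nrow(combos))), ]
      vapply(seq_len(nrow(pick)), function(i) {
        if (sp$chain) {
          # split into a d18:x sphingoid base and an N-acyl chain
          baseDb <- min(pick$db[i], 1L)
          sprintf("%s d18:%d/%d:%d", cl, baseDb, pick$carbons[i] - 18L,
                  pick$db[i] - baseDb)
        } else {
          sprintf("%s %d:%d", cl, pick$carbons[i], pick$db[i])
        }
      }, character(1))
    }))
    species <- parseLipidName(names_)
    n <- nrow(species)
    highUnsat <- species$doubleBonds > 2
    mu <- runif(n, 15, 25)
    cols <- expand.grid(replicate = seq_len(repsPerGroup), group = groups,
                        stringsAsFactors = FALSE)
    shift <- outer(ifelse(highUnsat, log2(koEffect), -log2(koEffect)),
                   as.numeric(cols$group != groups[1]))
    logm <- matrix(mu, n, nrow(cols)) + shift +
      matrix(rnorm(n * nrow(cols), 0, noiseSdLog), n)
    mat <- 2^logm
    rownames(mat) <- species$name
    colnames(mat) <- sprintf("%s_r%d", cols$group, cols$replicate)
    om <- OmicsMatrix(mat, group = cols$group, format = "lipidomics",
                      replicate = cols$replicate, reference = groups[1])
    truth <- data.frame(feature = species$name,
                        saturationClass = ifelse(highUnsat, "high_unsat",
                                                 "low_unsat"),
                        trueDirection = ifelse(koEffect == 1, 0L,
                                               ifelse(highUnsat, 1L, -1L)))
    list(matrix = om, species = species, truth = truth)
  })
}

#' Simulate a hyperspectral Raman tissue map with known truth
#'
#' Generates a gridded Raman map over the high-wavenumber window: tissue
#' pixels are the sum of a smooth low-order polynomial baseline, Gaussian
#' bands centred at 2845 (lipid CH2), 2880 (cholesterol-associated) and
#' 2935 cm^-1 (protein CH3), and Gaussian noise. A fraction of pixels is
#' background (near-zero intensity, below any realistic QC floor), and
#' single-channel cosmic spikes are planted at recorded positions. The
#' planted per-pixel 2845/2935 amplitude ratio (`baseRatio + groupDelta`
#' plus pixel-level jitter) is returned as ground truth.
#'
#' @param nx,ny grid dimensions (pixels).
#' @param groupDelta shift added to the base lipid/protein amplitude ratio;
#'   use 0 for a control map and a positive value for a contrast group.
#' @param fracBackground fraction of background pixels in \[0, 1).
#' @param nSpikes number of planted cosmic spikes.
#' @param seed integer seed.
#' @param baseRatio base 2845/2935 amplitude ratio of tissue pixels.
#' @param cholRatio 2880/2935 amplitude ratio.
#' @param amplitude mean 2935-band amplitude (vendor-like counts).
#' @param bandSd Gaussian band SD in reciprocal centimetres.
#' @param noiseSd additive spectral noise SD.
#' @param ratioJitterSd SD of the per-pixel jitter on the planted ratio.
#' @param wavenumberRange,wavenumberStep spectral axis specification; must
#'   cover at least 2700-3100 cm^-1.
#' @param step grid step in micrometres.
#' @return List with `map` (a [RamanMap-class]) and `truth`: `background`
#'   (logical per pixel), `spikes` (data.frame of pixel/channel positions),
#'   `ratioLipid` (planted per-pixel amplitude ratio, NA for background)
#'   and `meanRatio` (mean planted tissue ratio).
#' @examples
#' sim <- simRamanMap(nx = 5, ny = 5, seed = 1)
#' sim$map
#' @export
simRamanMap <- function(nx = 10, ny = 10, groupDelta = 0,
                        fracBackground = 0.2, nSpikes = 3, seed = 1,
                        baseRatio = 0.8, cholRatio = 0.6, amplitude = 4000,
                        bandSd = 8, noiseSd = 8, ratioJitterSd = 0.02,
                        wavenumberRange = c(2600, 3200), wavenumberStep = 2,
                        step = 100) {
  if (fracBackground < 0 || fracBackground >= 1)
    stop("invalid design: fracBackground must lie in [0, 1)")
  if (wavenumberRange[1] > 2700 || wavenumberRange[2] < 3100)
    stop("axis must cover at least 2700-3100 cm^-1")
  wn <- seq(wavenumberRange[1], wavenumberRange[2], by = wavenumberStep)
  npx <- nx * ny
  coords <- expand.grid(x = (seq_len(nx) - 1) * step,
                        y = (seq_len(ny) - 1) * step)
  gauss <- function(centre) dnorm(wn, centre, bandSd) / dnorm(0, 0, bandSd)
  g2845 <- gauss(2845); g2880 <- gauss(2880); g2935 <- gauss(2935)
  withr::with_seed(seed, {
    nBg <- round(fracBackground * npx)
    bg <- logical(npx)
    bg[sample.int(npx, nBg)] <- TRUE
    ratio <- rep(NA_real_, npx)
    ratio[!bg] <- baseRatio + groupDelta +
      rnorm(sum(!bg), 0, ratioJitterSd)
    amp <- amplitude * runif(npx, 0.8, 1.2)
    wnc <- (wn - mean(wn)) / diff(range(wn)) * 2
    spectra <- vapply(seq_len(npx), function(i) {
      if (bg[i]) return(rnorm(length(wn), 0, noiseSd / 4))
      base <- amp[i] * 0.05 *
        (runif(1, 0.5, 1.5) + runif(1, -0.5, 0.5) * wnc +
           runif(1, -0.5, 0.5) * wnc^2 + runif(1, -0.5, 0.5) * wnc^3)
      base + amp[i] * (ratio[i] * g2845 + cholRatio * g2880 + g2935) +
        rnorm(length(wn), 0, noiseSd)
    }, numeric(length(wn)))
    spikes <- data.frame(pixel = integer(), channel = integer())
    if (nSpikes > 0) {
      tissueIdx <- which(!bg)
      px <- sample(tissueIdx, min(nSpikes, length(tissueIdx)))
      ch <- sample.int(length(wn), length(px), replace = TRUE)
      for (k in seq_along(px))
        spectra[ch[k], px[k]] <- spectra[ch[k], px[k]] + 25 * amplitude
      spikes <- data.frame(pixel = px, channel = ch)
    }
    map <- RamanMap(wn, spectra, coords, log = "simulated")
    list(map = map,
         truth = list(background = bg, spikes = spikes, ratioLipid = ratio,
                      meanRatio = mean(ratio, na.rm = TRUE)))
  })
}

#' Simulate a survival cohort with expression-dependent hazards
#'
#' Draws patients from a three-component location mixture of expression
#' values (emulating low/intermediate/high expressor subpopulations) and
#' assigns exponential event times whose hazard is scaled per component by
#' `hazardRatios`. Censoring is independent exponential, calibrated so that
#' roughly `censorRate` of subjects are censored when all hazards are equal.
#'
#' @param n number of patients (>= 3 x number of components).
#' @param hazardRatios positive hazard multipliers, one per expression
#'   component (low to high).
#' @param censorRate target censoring fraction in \[0, 1).
#' @param seed integer seed.
#' @param componentMeans expression means of the mixture components.
#' @param componentSd within-component expression SD.
#' @param baseHazard baseline exponential event rate (per time unit).
#' @return data.frame with `id`, `expression`, `time`, `event` (1 = event,
#'   0 = censored) and the true generating `component`.
#' @examples
#' coh <- simCohort(n = 30, hazardRatios = c(1, 1, 1), seed = 1)
#' mean(coh$event)
#' @export
simCohort <- function(n = 300, hazardRatios = c(1, 1.5, 2),
                      censorRate = 0.2, seed = 1,
                      componentMeans = c(-2, 0, 2), componentSd = 0.5,
                      baseHazard = 0.02) {
  k <- length(hazardRatios)
  if (any(hazardRatios <= 0)) stop("invalid design: hazards must be > 0")
  if (length(componentMeans) != k)
    stop("need one component mean per hazard ratio")
  if (n < 3 * k) stop("invalid design: need n >= 3 x number of components")
  if (censorRate < 0 || censorRate >= 1)
    stop("invalid design: censorRate must lie in [0, 1)")
  withr::with_seed(seed, {
    comp <- sample.int(k, n, replace = TRUE)
    expr <- rnorm(n, componentMeans[comp], componentSd)
    tEvent <- rexp(n, rate = baseHazard * hazardRatios[comp])
    if (censorRate > 0) {
      cRate <- baseHazard * censorRate / (1 - censorRate)
      tCens <- rexp(n, rate = cRate)
    } else tCens <- rep(Inf, n)
    data.frame(id = sprintf("pt%03d", seq_len(n)), expression = expr,
               time = pmin(tEvent, tCens),
               event = as.integer(tEvent <= tCens), component = comp)
  })
}
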