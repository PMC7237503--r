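#' Default natural isotope abundances
#'
#' Per-element mass-shift distributions of the naturally occurring heavy
#' isotopes used by [correctionMatrix()]. For each supported element the
#' vector gives the probability of a +0, +1 (and, where relevant, +2)
#' nominal-mass shift per atom. IUPAC representative values are used:
#' 13C 0.0107, 2H 0.000115, 15N 0.00364, 17O 0.00038, 18O 0.00205,
#' 33S 0.0075, 34S 0.0425, 29Si 0.0468, 30Si 0.0310. All values can be
#' overridden by passing a modified copy of this list to the correction
#' functions.
#'
#' @return Named list of per-atom shift-probability vectors for C, H, N, O,
#'   S and Si, each summing to 1.
#' @examples
#' ab <- naturalAbundances()
#' ab$C  # 12C and 13C fractions
#' @export
naturalAbundances <- function() {
  list(
    C  = c(1 - 0.0107, 0.0107),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    S  = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425),
    Si = c(1 - 0.0468 - 0.0310, 0.0468, 0.0310)
  )
}

#' Parse an elemental formula
#'
#' Parses a Hill-notation-like molecular formula restricted to the elements
#' relevant for small-molecule and fatty-acid-derivative mass spectrometry
#' (C, H, N, O, S, Si). Tracer compounds must contain at least one carbon.
#'
#' @param text character(1), e.g. `"C16H32O2"` (palmitic acid) or
#'   `"C3H4O3"` (pyruvate).
#' @return Named integer vector of atom counts.
#' @examples
#' parseFormula("C16H32O2")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text) || grepl("\\s", text))
    stop("malformed formula: '", text, "'")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula: '", text, "'")
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Za-z]+", "", toks)
  ct <- ifelse(ct == "", 1L, suppressWarnings(as.integer(ct)))
  bad <- setdiff(el, c("C", "H", "N", "O", "S", "Si"))
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  counts <- tapply(ct, factor(el, levels = unique(el)), sum)
  out <- setNames(as.integer(counts), names(counts))
  if (any(is.na(out)) || any(out < 0))
    stop("malformed formula: '", text, "'")
  out
}

# n-fold convolution of a per-atom shift distribution, truncated to maxShift
convolveAtoms <- function(dist, n, maxShift) {
  out <- 1
  for (i in seq_len(n)) {
    out <- convolveTrunc(out, dist, maxShift)
  }
  out
}

convolveTrunc <- function(a, b, maxShift) {
  la <- length(a); lb <- length(b)
  out <- numeric(min(la + lb - 1L, maxShift + 1L))
  for (j in seq_len(lb)) {
    idx <- seq_len(la) + j - 1L
    keep <- idx <= length(out)
    out[idx[keep]] <- out[idx[keep]] + a[keep] * b[j]
  }
  out
}

#' Natural-abundance correction matrix
#'
#' Builds the forward convolution operator M mapping a mass isotopomer
#' distribution (MID) over tracer carbons to the observed isotopologue
#' intensity distribution. Column `j` (0-based) is the mass-shift
#' distribution of a molecule carrying `j` tracer carbons: the binomial
#' natural 13C distribution over the `C - j` unlabelled carbons, convolved
#' (in `"all-elements"` mode) with the +1/+2 shift distributions of the
#' natural H, N, O, S and Si isotopes, and with the tracer-purity binomial
#' over the `j` labelled positions. Distributions are truncated at shift
#' `C` (measured vectors stop at M+C) and each column is renormalised to
#' sum 1.
#'
#' In `"carbon-only"` mode (high-resolution instruments where only 13C is
#' isobaric with the tracer shift) the matrix is lower-triangular.
#'
#' @param formula an elemental formula string or the output of
#'   [parseFormula()].
#' @param abundances isotope abundance list, see [naturalAbundances()].
#' @param mode `"carbon-only"` or `"all-elements"`.
#' @param purity tracer isotopic purity in \[0, 1\] (default 1; 0.99 matches
#'   typical commercial U-13C glucose).
#' @return A `(C+1) x (C+1)` matrix with columns summing to 1.
#' @examples
#' M <- correctionMatrix("C2H4O2", mode = "carbon-only")
#' M[2, 1]  # 2 * a13C * (1 - a13C)
#' @export
correctionMatrix <- function(formula, abundances = naturalAbundances(),
                             mode = c("carbon-only", "all-elements"),
                             purity = 1) {
  mode <- match.arg(mode)
  if (is.character(formula)) formula <- parseFormula(formula)
  nC <- unname(formula["C"])
  if (is.na(nC) || nC < 1L) stop("tracer compounds need at least 1 carbon")
  stopifnot(purity >= 0, purity <= 1)
  M <- matrix(0, nC + 1L, nC + 1L)
  otherDist <- 1
  if (mode == "all-elements") {
    for (el in c("H", "N", "O", "S", "Si")) {
      n <- formula[el]
      if (!is.na(n) && n > 0L)
        otherDist <- convolveTrunc(
          otherDist, convolveAtoms(abundances[[el]], n, nC), nC)
    }
  }
  for (j in 0:nC) {
    d <- dbinom(0:j, j, purity)                     # labelled positions
    d <- convolveTrunc(d, dbinom(0:(nC - j), nC - j, abundances$C[2]), nC)
    if (mode == "all-elements") d <- convolveTrunc(d, otherDist, nC)
    col <- numeric(nC + 1L)
    col[seq_along(d)] <- d
    M[, j + 1L] <- col / sum(col)
  }
  dimnames(M) <- list(paste0("M+", 0:nC), paste0("x", 0:nC))
  M
}

#' Correct a raw isotopologue vector for natural abundance
#'
#' Recovers the tracer-derived mass isotopomer distribution from a raw
#' isotopologue intensity vector by constrained least squares: it solves
#' `min || M x - y ||_2` subject to `x >= 0` (Lawson-Hanson NNLS, see
#' [nnlsSolve()]) and normalises the solution to sum 1.
#' Non-negativity is enforced because plain matrix inversion can return
#' negative isotopologue fractions on noisy data.
#'
#' @param y numeric vector of raw intensities, length `C + 1`
#'   (M+0 ... M+C), non-negative, not all zero.
#' @param formula elemental formula (string or [parseFormula()] output).
#' @param abundances isotope abundance list.
#' @param mode correction mode, see [correctionMatrix()].
#' @param purity tracer purity.
#' @return List with `mid` (corrected MID, sums to 1), `total` (corrected
#'   total signal, the L1 norm of the unnormalised solution), and
#'   `residual` (L2 norm of `M x - y`).
#' @examples
#' M <- correctionMatrix("C3H4O3", mode = "all-elements")
#' y <- as.vector(M %*% c(0.5, 0.2, 0.1, 0.2)) * 1e6
#' correctMid(y, "C3H4O3", mode = "all-elements")$mid
#' @export
correctMid <- function(y, formula, abundances = naturalAbundances(),
                       mode = c("carbon-only", "all-elements"),
                       purity = 1) {
  mode <- match.arg(mode)
  if (is.character(formula)) formula <- parseFormula(formula)
  nC <- unname(formula["C"])
  y <- as.numeric(y)
  if (length(y) != nC + 1L)
    stop("raw vector length (", length(y), ") must be C + 1 = ", nC + 1L)
  if (any(y < 0)) stop("raw intensities must be non-negative")
  if (all(y == 0)) stop("empty signal: all isotopologue intensities are zero")
  M <- correctionMatrix(formula, abundances, mode, purity)
  kap <- kappa(M, exact = FALSE)
  if (kap > 1e8)
    warning(sprintf("correction matrix is ill-conditioned (kappa ~ %.3g)",
                    kap))
  fit <- nnlsSolve(M, y)
  x <- pmax(fit$x, 0)
  total <- sum(x)
  if (total <= 0)
    stop("correction produced an all-zero solution")
  list(mid = x / total, total = total,
       residual = sqrt(sum((M %*% x - y)^2)))
}

#' Labelling metrics from a corrected MID
#'
#' Computes the standard tracing summaries from a corrected mass isotopomer
#' distribution: the labelled fraction `1 - x0` (the proportion of molecules
#' carrying at least one tracer carbon) and the fractional enrichment
#' `sum(i * x_i) / C` (the average fraction of carbon positions that are
#' labelled).
#'
#' @param mid numeric probability vector over M+0 ... M+C
#'   (must sum to 1 within 1e-6).
#' @return List with `labelledFraction`, `fractionalEnrichment` and
#'   `distribution` (the input MID).
#' @examples
#' enrichmentMetrics(c(0.25, 0.5, 0.25))
#' @export
enrichmentMetrics <- function(mid) {
  mid <- as.numeric(mid)
  if (any(mid < -1e-12)) stop("MID must be non-negative")
  if (abs(sum(mid) - 1) > 1e-6)
    stop("MID is not normalised (sum = ", format(sum(mid)), ")")
  nC <- length(mid) - 1L
  list(labelledFraction = sum(mid[-1L]),
       fractionalEnrichment = sum((0:nC) * mid) / nC,
       distribution = mid)
}

#' Normalise abundances to an internal standard and protein content
#'
#' Divides per-sample totals by the internal-standard signal and/or the
#' protein (or cell-number) content of each sample, the standard
#' normalisation for GC-MS fatty-acid and intracellular metabolite data.
#' Either denominator may be omitted (treated as 1).
#'
#' @param values numeric vector of per-sample totals (optionally named).
#' @param internalStandard per-sample internal standard values, or NULL.
#' @param protein per-sample protein content or cell numbers, or NULL.
#' @return Normalised numeric vector, names preserved.
#' @examples
#' normalizeAbundance(c(a = 100), internalStandard = 2, protein = 5)  # 10
#' @export
normalizeAbundance <- function(values, internalStandard = NULL,
                               protein = NULL) {
  out <- as.numeric(values)
  names(out) <- names(values)
  checkDenom <- function(d, what) {
    d <- rep(as.numeric(d), length.out = length(out))
    bad <- which(d <= 0)
    if (length(bad)) {
      nm <- if (!is.null(names(out))) names(out)[bad[1]] else bad[1]
      stop(what, " is non-positive for sample ", nm)
    }
    d
  }
  if (!is.null(internalStandard))
    out <- out / checkDenom(internalStandard, "internal standard")
  if (!is.null(protein))
    out <- out / checkDenom(protein, "protein content")
  out
}

#' Correct a long-format isotopologue table
#'
#' Applies [correctMid()] to every compound/sample combination of a long
#' isotopologue table (the format written by [simTracingSamples()]) and
#' returns corrected MIDs together with labelling metrics.
#'
#' @param table data.frame with columns `compound`, `formula`, `sample`,
#'   `isotopologue` (0-based index) and `intensity`.
#' @param ... passed on to [correctMid()] (`abundances`, `mode`, `purity`).
#' @return data.frame with one row per compound/sample/isotopologue carrying
#'   the corrected fraction `mid`, plus per-record `total`,
#'   `labelledFraction` and `fractionalEnrichment`.
#' @export
correctTracingTable <- function(table, ...) {
  need <- c("compound", "formula", "sample", "isotopologue", "intensity")
  miss <- setdiff(need, colnames(table))
  if (length(miss))
    stop("table is missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(table$compound, table$sample, drop = TRUE)
  parts <- lapply(split(table, key), function(d) {
    d <- d[order(d$isotopologue), , drop = FALSE]
    res <- correctMid(d$intensity, d$formula[1], ...)
    met <- enrichmentMetrics(res$mid)
    data.frame(compound = d$compound[1], formula = d$formula[1],
               sample = d$sample[1], isotopologue = d$isotopologue,
               mid = res$mid, total = res$total,
               labelledFraction = met$labelledFraction,
               fractionalEnrichment = met$fractionalEnrichment,
               row.names = NULL)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
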