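#' Per-comparison differential statistics for an omics matrix
#'
#' For every non-reference group (and every format) computes, per feature,
#' the log2 fold change (difference of group means on the log2 scale), a
#' two-sided Welch t-test p-value on log2-transformed abundances, and a
#' Benjamini-Hochberg q-value across features within each comparison.
#' Non-positive abundances are treated as missing on the log scale;
#' features with fewer than two finite values in either compared group are
#' dropped from that comparison (no imputation) and reported with NA
#' statistics.
#'
#' An optional permutation mode replaces the t-distribution p-value with a
#' label-permutation p-value: group labels are shuffled within each
#' comparison and the null t statistics of all features are pooled.
#'
#' @param mat an [OmicsMatrix-class].
#' @param comparisons character vector of non-reference groups to compare
#'   against the reference (default: all of them).
#' @param method `"welch"` (default) or `"permutation"`.
#' @param nPerm number of label permutations (permutation mode, >= 250
#'   recommended).
#' @param seed seed for the permutation mode.
#' @return A tidy data.frame with columns `feature`, `group`, `format`,
#'   `log2fc`, `t`, `df`, `p`, `q`, `sign`, `nGroup`, `nRef`. `q >= p`
#'   within every comparison and `sign = sign(log2fc)`.
#' @examples
#' sim <- simProteome(nFeatures = 100, repsPerGroup = 3, seed = 1)
#' res <- differentialTable(sim$matrix)
#' head(res)
#' @export
differentialTable <- function(mat, comparisons = NULL,
                              method = c("welch", "permutation"),
                              nPerm = 250, seed = 1) {
  stopifnot(is(mat, "OmicsMatrix"))
  method <- match.arg(method)
  ref <- referenceGroup(mat)
  grp <- sampleGroups(mat)
  fmt <- sampleFormats(mat)
  if (is.null(comparisons)) comparisons <- setdiff(unique(grp), ref)
  unknown <- setdiff(comparisons, grp)
  if (length(unknown))
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  la <- log2(abundances(mat))
  la[!is.finite(la)] <- NA
  out <- list()
  for (f in unique(fmt)) {
    refIdx <- which(grp == ref & fmt == f)
    for (g in comparisons) {
      gIdx <- which(grp == g & fmt == f)
      if (length(gIdx) < 2 || length(refIdx) < 2)
        stop("fewer than 2 replicates for ", g, " vs ", ref,
             " in format ", f)
      st <- rowWelch(la[, gIdx, drop = FALSE], la[, refIdx, drop = FALSE])
      if (method == "permutation") {
        st$p <- permutationP(la[, c(gIdx, refIdx), drop = FALSE],
                             length(gIdx), st$t, nPerm,
                             seed + match(f, unique(fmt)) * 1000L +
                               match(g, comparisons))
      }
      q <- rep(NA_real_, length(st$p))
      ok <- !is.na(st$p)
      q[ok] <- p.adjust(st$p[ok], method = "BH")
      out[[length(out) + 1L]] <- data.frame(
        feature = rownames(la), group = g, format = f,
        log2fc = st$lfc, t = st$t, df = st$df, p = st$p, q = q,
        sign = sign(st$lfc), nGroup = st$n1, nRef = st$n2,
        row.names = NULL)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# vectorised Welch two-sample t on rows; returns NA where a group has < 2
# finite values; zero-variance identical groups give t = 0, p = 1
rowWelch <- function(a, b) {
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- apply(a, 1, var, na.rm = TRUE)
  v2 <- apply(b, 1, var, na.rm = TRUE)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  t <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # degenerate: both groups constant
  zeroVar <- !is.na(se2) & se2 == 0
  t[zeroVar & lfc == 0] <- 0
  t[zeroVar & lfc != 0] <- sign(lfc[zeroVar & lfc != 0]) * Inf
  df[zeroVar] <- n1[zeroVar] + n2[zeroVar] - 2
  p <- 2 * pt(-abs(t), df)
  p[zeroVar & lfc == 0] <- 1
  p[zeroVar & lfc != 0] <- 0
  drop <- n1 < 2 | n2 < 2
  lfc[drop] <- t[drop] <- df[drop] <- p[drop] <- NA
  list(lfc = lfc, t = t, df = df, p = p, n1 = n1, n2 = n2)
}

# pooled label-permutation p-values: null |t| from all features combined
permutationP <- function(x, n1, tObs, nPerm, seed) {
  withr::with_seed(seed, {
    n <- ncol(x)
    nullT <- unlist(lapply(seq_len(nPerm), function(i) {
      idx <- sample.int(n)
      st <- rowWelch(x[, idx[seq_len(n1)], drop = FALSE],
                     x[, idx[-seq_len(n1)], drop = FALSE])
      st$t[is.finite(st$t)]
    }))
    nullAbs <- sort(abs(nullT))
    N <- length(nullAbs)
    p <- (N - findInterval(abs(tObs) - 1e-12, nullAbs) + 1) / (N + 1)
    p[!is.finite(tObs)] <- 1 / (N + 1)
    p[is.na(tObs)] <- NA
    pmin(p, 1)
  })
}

#' Dunnett many-to-one comparisons with Monte Carlo adjustment
#'
#' Compares each non-reference group to the reference with the classical
#' Dunnett t statistics (pooled equal-variance model) and adjusts for the
#' family of comparisons using the null distribution of the maximum
#' absolute statistic, estimated by seeded Monte Carlo. The adjusted
#' p-value for comparison i is `P(max_j |T_j| >= |t_i|)` under the joint
#' null; it is floored at the unadjusted two-sided p-value so that the
#' family-wise p never undercuts the marginal one.
#'
#' With a single non-reference group the procedure reduces to a plain
#' two-sided pooled t-test and the result is flagged
#' (`method = "t-test"`).
#'
#' @param values numeric vector of observations for one feature.
#' @param groups group label per observation.
#' @param reference reference group label (default: first encountered).
#' @param nDraws Monte Carlo draws (>= 1e5 recommended).
#' @param seed seed for the Monte Carlo null.
#' @param null optional precomputed null from [dunnettNull()] for the same
#'   design, to share across many features.
#' @return data.frame with one row per non-reference group: `group`,
#'   `estimate` (mean difference), `t`, `pUnadjusted`, `pAdjusted`,
#'   `method`.
#' @examples
#' x <- c(rnorm(4), rnorm(4, 2), rnorm(4))
#' g <- rep(c("WT", "A", "B"), each = 4)
#' dunnettTest(x, g, reference = "WT", nDraws = 2e4, seed = 1)
#' @export
dunnettTest <- function(values, groups, reference = NULL, nDraws = 1e5,
                        seed = 1, null = NULL) {
  groups <- as.character(groups)
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) stop("unknown reference group: ", reference)
  lev <- c(reference, setdiff(unique(groups), reference))
  ns <- vapply(lev, function(g) sum(groups == g), integer(1))
  if (any(ns < 2)) stop("each group needs at least 2 observations")
  k <- length(lev) - 1L
  means <- vapply(lev, function(g) mean(values[groups == g]), numeric(1))
  df <- sum(ns) - length(lev)
  s2 <- sum(vapply(lev, function(g) {
    v <- values[groups == g]; sum((v - mean(v))^2)
  }, numeric(1))) / df
  sedv <- sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  t <- (means[-1] - means[1]) / sedv
  pUn <- 2 * pt(-abs(t), df)
  if (k == 1L) {
    return(data.frame(group = lev[-1], estimate = means[-1] - means[1],
                      t = unname(t), pUnadjusted = unname(pUn),
                      pAdjusted = unname(pUn), method = "t-test",
                      row.names = NULL))
  }
  if (is.null(null)) null <- dunnettNull(ns, nDraws = nDraws, seed = seed)
  N <- length(null)
  pAdj <- (N - findInterval(abs(t) - 1e-12, null)) / N
  pAdj <- pmax(pAdj, pUn)
  data.frame(group = lev[-1], estimate = unname(means[-1] - means[1]),
             t = unname(t), pUnadjusted = unname(pUn),
             pAdjusted = unname(pAdj), method = "dunnett-mc",
             row.names = NULL)
}

#' Monte Carlo null distribution of the Dunnett max-|t| statistic
#'
#' Simulates the joint null of the many-to-one comparison statistics for a
#' given design (group sizes, reference first) under the pooled-variance
#' model: group means are drawn as independent normals with variance
#' `1/n_g` and the pooled variance estimate as a scaled chi-square with
#' the design's error degrees of freedom. The sorted vector of
#' `max_j |T_j|` draws can be reused across all features sharing the
#' design.
#'
#' @param groupSizes integer vector of group sizes, reference group first.
#' @param nDraws number of Monte Carlo draws.
#' @param seed integer seed.
#' @return Sorted numeric vector of `nDraws` max-|t| null draws.
#' @export
dunnettNull <- function(groupSizes, nDraws = 1e5, seed = 1) {
  ns <- as.numeric(groupSizes)
  k <- length(ns) - 1L
  if (k < 1L) stop("need at least one non-reference group")
  df <- sum(ns) - length(ns)
  withr::with_seed(seed, {
    z0 <- rnorm(nDraws, 0, sqrt(1 / ns[1]))
    s <- sqrt(stats::rchisq(nDraws, df) / df)
    mx <- rep(0, nDraws)
    for (j in seq_len(k)) {
      zj <- rnorm(nDraws, 0, sqrt(1 / ns[j + 1L]))
      tj <- abs(zj - z0) / (s * sqrt(1 / ns[j + 1L] + 1 / ns[1]))
      mx <- pmax(mx, tj)
    }
    sort(mx)
  })
}

#' Select features consistently modulated across comparisons
#'
#' Implements the cross-condition consistency rule used to define
#' resistance panels: a feature is retained if it passes both the fold
#' change threshold (`|log2fc| >= log2(fcThreshold)`) and the significance
#' threshold (`p < pThreshold`, or `q` if `useQ`) in at least `kOfN` of the
#' comparisons present in `res`, and (if `requireSign`) all qualifying
#' comparisons agree in sign.
#'
#' @param res comparison table from [differentialTable()] (or any
#'   data.frame with `feature`, `log2fc` and `p`/`q` columns); filter it
#'   first (e.g. by `format`) to control which comparisons count.
#' @param fcThreshold linear fold-change threshold, must be > 1.
#' @param pThreshold significance threshold on p (or q).
#' @param kOfN minimum number of qualifying comparisons (default: all
#'   comparisons present per feature).
#' @param requireSign require one consistent sign across qualifying
#'   comparisons (default TRUE).
#' @param useQ use BH q-values instead of raw p-values.
#' @return data.frame with `feature`, `nQualify` and `direction` (+1/-1)
#'   for retained features, ordered by feature id.
#' @examples
#' sim <- simProteome(nFeatures = 200, repsPerGroup = 4, seed = 1)
#' res <- differentialTable(sim$matrix)
#' sel <- selectConsistent(res, fcThreshold = 1.5, useQ = TRUE)
#' nrow(sel)
#' @export
selectConsistent <- function(res, fcThreshold = 1.5, pThreshold = 0.05,
                             kOfN = NULL, requireSign = TRUE,
                             useQ = FALSE) {
  if (fcThreshold <= 1) stop("invalid threshold: fcThreshold must be > 1")
  if (nrow(res) == 0)
    return(data.frame(feature = character(), nQualify = integer(),
                      direction = integer()))
  pv <- if (useQ) res$q else res$p
  lfcCut <- log2(fcThreshold)
  ok <- !is.na(res$log2fc) & !is.na(pv) &
    abs(res$log2fc) >= lfcCut & pv < pThreshold
  nComp <- table(res$feature)
  if (is.null(kOfN)) kOfN <- max(nComp)
  if (kOfN > max(nComp))
    stop("kOfN (", kOfN, ") exceeds the number of comparisons (",
         max(nComp), ")")
  qual <- res[ok, , drop = FALSE]
  if (nrow(qual) == 0)
    return(data.frame(feature = character(), nQualify = integer(),
                      direction = integer()))
  counts <- tapply(qual$sign, qual$feature, length)
  signMin <- tapply(qual$sign, qual$feature, min)
  signMax <- tapply(qual$sign, qual$feature, max)
  keep <- counts >= kOfN
  if (requireSign) keep <- keep & (signMin == signMax)
  feats <- names(counts)[keep]
  out <- data.frame(feature = feats,
                    nQualify = as.integer(counts[keep]),
                    direction = as.integer(signMax[keep]))
  out[order(out$feature), , drop = FALSE]
}

#' Intersect per-format selections into a signature panel
#'
#' Takes the per-format outputs of [selectConsistent()] and intersects
#' them: the panel keeps only the features selected in every format, and
#' (if `requireSign`) with the same direction in all formats. When the
#' underlying comparison table is supplied the panel is annotated with the
#' supporting per-comparison log2 fold changes and ordered by decreasing
#' mean absolute log2 fold change.
#'
#' @param selections named list (one element per format) of
#'   [selectConsistent()] outputs.
#' @param res optional comparison table from [differentialTable()] for
#'   annotation and ordering.
#' @param requireSign require direction agreement across formats.
#' @return data.frame with `feature`, `direction` and, when `res` is given,
#'   one `log2fc_<group>_<format>` column per comparison plus
#'   `meanAbsLog2fc`.
#' @export
intersectContexts <- function(selections, res = NULL, requireSign = TRUE) {
  if (length(selections) < 2)
    stop("need selections from at least 2 formats")
  if (is.null(names(selections)) || any(!nzchar(names(selections))))
    stop("alignment error: 'selections' must be named by format")
  feats <- Reduce(intersect, lapply(selections, `[[`, "feature"))
  dirs <- vapply(feats, function(f) {
    d <- vapply(selections, function(s)
      s$direction[match(f, s$feature)], integer(1))
    if (length(unique(d)) == 1L) d[1] else NA_integer_
  }, integer(1))
  if (requireSign) feats <- feats[!is.na(dirs)]
  panel <- data.frame(feature = feats,
                      direction = dirs[feats], row.names = NULL)
  if (!is.null(res) && nrow(panel)) {
    keyed <- res[res$feature %in% feats, , drop = FALSE]
    wide <- tapply(keyed$log2fc,
                   list(keyed$feature,
                        paste0("log2fc_", keyed$group, "_", keyed$format)),
                   mean)
    wide <- wide[panel$feature, , drop = FALSE]
    panel <- cbind(panel, as.data.frame(wide))
    panel$meanAbsLog2fc <- rowMeans(abs(wide), na.rm = TRUE)
    panel <- panel[order(-panel$meanAbsLog2fc), , drop = FALSE]
    rownames(panel) <- NULL
  }
  panel
}

#' Score a selection against a planted truth table
#'
#' @param selected character vector of selected feature ids (or a
#'   data.frame with a `feature` column).
#' @param truth truth table with `feature` and `isSignature` columns, as
#'   produced by [simProteome()].
#' @return List with `sensitivity` (= recovered fraction of planted
#'   signature features) and `observedFdr` (= fraction of the selection
#'   that is not signature; 0 for an empty selection).
#' @examples
#' sim <- simProteome(nFeatures = 100, seed = 1)
#' sig <- sim$truth$feature[sim$truth$isSignature]
#' scoreSelection(sig, sim$truth)
#' @export
scoreSelection <- function(selected, truth) {
  if (is.data.frame(selected)) selected <- selected$feature
  selected <- as.character(selected)
  unknown <- setdiff(selected, truth$feature)
  if (length(unknown))
    stop("unknown feature id(s): ", paste(head(unknown, 3), collapse = ", "))
  sig <- truth$feature[truth$isSignature]
  tp <- length(intersect(selected, sig))
  list(sensitivity = if (length(sig)) tp / length(sig) else NA_real_,
       observedFdr = (length(selected) - tp) / max(1L, length(selected)))
}
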