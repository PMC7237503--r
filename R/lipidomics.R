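lipidClasses <- c("Cer", "CL", "DG", "LysoPC", "PC", "PE", "PG", "PI",
                  "PS", "SM", "TG", "BMP")

#' Parse lipid shorthand names
#'
#' Parses species-level lipid shorthand of the form `"<CLASS> <C>:<DB>"`
#' (e.g. `"PC 34:2"`) or the chain form
#' `"<CLASS> <c1>:<d1>/<c2>:<d2>[/...]"` (e.g. `"Cer d18:1/16:0"`), in
#' which chain carbons and double bonds are summed. The sphingoid-base
#' prefix `"d"` is tolerated. Supported classes: Cer, CL, DG, LysoPC, PC,
#' PE, PG, PI, PS, SM, TG, BMP. Ether/oxidised notations such as
#' `"PC O-34:2"` are rejected.
#'
#' @param name character vector of lipid names.
#' @return data.frame with columns `name`, `class`, `carbons`,
#'   `doubleBonds`.
#' @examples
#' parseLipidName(c("PC 34:2", "Cer d18:1/16:0"))
#' @export
parseLipidName <- function(name) {
  name <- as.character(name)
  one <- function(nm) {
    parts <- strsplit(trimws(nm), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("cannot parse lipid name '", nm, "'")
    cls <- parts[1]
    if (!cls %in% lipidClasses)
      stop("unknown lipid class '", cls, "' in '", nm, "'")
    chains <- strsplit(parts[2], "/", fixed = TRUE)[[1]]
    cPat <- "^d?([0-9]+):([0-9]+)$"
    bad <- chains[!grepl(cPat, chains)]
    if (length(bad))
      stop("malformed chain token '", bad[1], "' in '", nm, "'")
    cc <- as.integer(sub(cPat, "\\1", chains))
    dd <- as.integer(sub(cPat, "\\2", chains))
    if (sum(cc) <= 0)
      stop("lipid '", nm, "' must have a positive carbon count")
    c(sum(cc), sum(dd))
  }
  parsed <- vapply(name, one, numeric(2))
  data.frame(name = name, class = vapply(
               strsplit(trimws(name), "\\s+"), `[[`, character(1), 1),
             carbons = as.integer(parsed[1, ]),
             doubleBonds = as.integer(parsed[2, ]), row.names = NULL)
}

#' Format a lipid shorthand name
#'
#' Inverse of [parseLipidName()] for the species-level form; with `chains`
#' given, emits the chain form (first chain gets the sphingoid `"d"`
#' prefix when `sphingoid = TRUE`).
#'
#' @param class lipid class label.
#' @param carbons,doubleBonds species totals (species form).
#' @param chains optional list of `c(carbons, doubleBonds)` per chain.
#' @param sphingoid prefix the first chain with `"d"`.
#' @return character(1) lipid name.
#' @examples
#' formatLipidName("PC", 34, 2)
#' formatLipidName("Cer", chains = list(c(18, 1), c(16, 0)),
#'                 sphingoid = TRUE)
#' @export
formatLipidName <- function(class, carbons = NULL, doubleBonds = NULL,
                            chains = NULL, sphingoid = FALSE) {
  if (!class %in% lipidClasses)
    stop("unknown lipid class '", class, "'")
  if (is.null(chains)) {
    sprintf("%s %d:%d", class, as.integer(carbons),
            as.integer(doubleBonds))
  } else {
    toks <- vapply(chains, function(ch)
      sprintf("%d:%d", as.integer(ch[1]), as.integer(ch[2])), character(1))
    if (sphingoid) toks[1] <- paste0("d", toks[1])
    paste(class, paste(toks, collapse = "/"))
  }
}

#' Classify lipid saturation
#'
#' Binary saturation classes based on the total double-bond count of the
#' species: `"high_unsat"` for more than two double bonds,
#' `"low_unsat"` for saturated, mono- or bi-unsaturated species (two or
#' fewer). The classification partitions any parsed lipidome.
#'
#' @param x a [parseLipidName()] data.frame, or a numeric vector of
#'   double-bond counts.
#' @return character vector of `"high_unsat"` / `"low_unsat"`.
#' @examples
#' classifySaturation(c(0, 2, 3))
#' @export
classifySaturation <- function(x) {
  db <- if (is.data.frame(x)) x$doubleBonds else x
  if (any(db < 0, na.rm = TRUE)) stop("double-bond counts must be >= 0")
  ifelse(db > 2, "high_unsat", "low_unsat")
}

#' Fatty-acid class totals
#'
#' Sums absolute fatty-acid concentrations into the standard saturation
#' classes: SFA (no double bonds), MUFA (exactly one) and PUFA (two or
#' more), in the input units (typically nmol per mg protein).
#'
#' @param profile named numeric vector of concentrations with names of the
#'   form `"<carbons>:<doubleBonds>"` (e.g. `"16:1"`), or a data.frame
#'   with columns `fa` and `concentration`.
#' @return Named numeric vector with `SFA`, `MUFA` and `PUFA` totals.
#' @examples
#' faClassTotals(c("16:1" = 2, "18:1" = 3, "20:4" = 5, "22:6" = 1,
#'                 "16:0" = 4))
#' @export
faClassTotals <- function(profile) {
  if (is.data.frame(profile)) {
    conc <- profile$concentration
    fa <- profile$fa
  } else {
    conc <- as.numeric(profile)
    fa <- names(profile)
  }
  if (length(conc) == 0)
    return(c(SFA = 0, MUFA = 0, PUFA = 0))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  pat <- "^([0-9]+):([0-9]+)$"
  if (any(!grepl(pat, fa)))
    stop("fatty acids must be identified as '<carbons>:<doubleBonds>'")
  db <- as.integer(sub(pat, "\\2", fa))
  c(SFA = sum(conc[db == 0]), MUFA = sum(conc[db == 1]),
    PUFA = sum(conc[db >= 2]))
}

#' Filtered lipid heatmap matrix with saturation annotations
#'
#' Applies the differential-selection semantics of [selectConsistent()] to
#' a lipidomics matrix (retain species passing `|FC| >= fcThreshold` and
#' `p < pThreshold` in at least `minGroups` comparisons) and returns the
#' heatmap values for the retained species: either the per-comparison
#' natural-log fold changes (`mode = "logFC"`; set `logBase = 2` for log2)
#' or per-species z-scores across samples (`mode = "zscore"`). Rows are
#' annotated with lipid class and saturation class and sorted by class,
#' then double-bond count.
#'
#' @param mat an [OmicsMatrix-class] whose row names are lipid shorthand
#'   names.
#' @param species optional pre-parsed [parseLipidName()] table aligned
#'   with `mat` rows (parsed from row names when NULL).
#' @param mode `"logFC"` or `"zscore"`.
#' @param fcThreshold linear fold-change threshold (> 1).
#' @param pThreshold significance threshold.
#' @param minGroups minimum number of qualifying comparisons.
#' @param requireSign require sign agreement across qualifying
#'   comparisons (default FALSE: saturation shifts may go both ways).
#' @param logBase base of the reported fold changes in logFC mode.
#' @return List with `values` (numeric matrix, retained species x
#'   comparisons or samples) and `annotation` (data.frame with `name`,
#'   `class`, `carbons`, `doubleBonds`, `saturationClass`).
#' @examples
#' sim <- simLipidome(nPerClass = 5, koEffect = 2, seed = 1)
#' hm <- lipidDiffMatrix(sim$matrix, sim$species, fcThreshold = 1.2)
#' head(hm$annotation)
#' @export
lipidDiffMatrix <- function(mat, species = NULL,
                            mode = c("logFC", "zscore"),
                            fcThreshold = 1.5, pThreshold = 0.05,
                            minGroups = 1, requireSign = FALSE,
                            logBase = exp(1)) {
  mode <- match.arg(mode)
  if (is.null(species)) species <- parseLipidName(rownames(mat))
  if (nrow(species) != nrow(mat) ||
      !all(species$name == rownames(mat)))
    stop("alignment error: species table does not match matrix rows")
  res <- differentialTable(mat)
  sel <- selectConsistent(res, fcThreshold = fcThreshold,
                          pThreshold = pThreshold, kOfN = minGroups,
                          requireSign = requireSign)
  keep <- species$name %in% sel$feature
  ann <- species[keep, , drop = FALSE]
  ann$saturationClass <- classifySaturation(ann)
  ord <- order(ann$class, ann$doubleBonds)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) == 0)
    return(list(values = matrix(numeric(), 0, 0), annotation = ann))
  if (mode == "logFC") {
    sub <- res[res$feature %in% ann$name, , drop = FALSE]
    vals <- tapply(sub$log2fc,
                   list(sub$feature, paste(sub$group, sub$format, sep = "_")),
                   mean) * log(2) / log(logBase)
    vals <- vals[ann$name, , drop = FALSE]
  } else {
    a <- log2(abundances(mat)[ann$name, , drop = FALSE])
    vals <- t(scale(t(a)))
  }
  list(values = vals, annotation = ann)
}
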