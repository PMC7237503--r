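#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats approx coef dbinom density dist dnorm kmeans lm mad median
#'   model.matrix p.adjust pchisq pnorm pt qnorm quantile rbinom rexp rnorm
#'   runif runmed rt sd setNames t.test var wilcox.test
#' @importFrom utils head read.delim write.table
NULL

#' OmicsMatrix: feature-by-sample abundance matrix with experimental design
#'
#' An `OmicsMatrix` extends
#' [SummarizedExperiment::SummarizedExperiment] and holds a non-negative
#' feature-by-sample abundance matrix (assay `"abundance"`) together with the
#' experimental design: for every sample a biological `group` (e.g. wild type
#' and resistant derivatives), a culture `format` (e.g. `"2D"`, `"3D"`) and a
#' `replicate` index. The reference group, against which all differential
#' comparisons are made, is stored in the `reference` slot.
#'
#' @slot reference character(1), the reference (control) group; must be one of
#'   the levels of `colData(x)$group`.
#'
#' @seealso [OmicsMatrix()] for construction, [differentialTable()] for
#'   group-vs-reference statistics.
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  slots = c(reference = "character")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "format", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData is missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an assay named 'abundance' is required")
  else {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (any(a < 0, na.rm = TRUE))
      msg <- c(msg, "abundances must be non-negative")
  }
  if (length(object@reference) != 1L)
    msg <- c(msg, "'reference' must be a single group label")
  else if ("group" %in% colnames(cd) &&
           !object@reference %in% cd$group)
    msg <- c(msg, sprintf("reference group '%s' absent from design",
                          object@reference))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature ids are not allowed")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param abundance numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids, column names sample ids.
#' @param group character/factor, biological group per sample.
#' @param format character/factor, culture or assay format per sample.
#'   Defaults to a single format `"2D"` for designs without a format axis.
#' @param replicate integer replicate index per sample.
#' @param reference character(1), reference group label (default: first level
#'   of `group`).
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rlnorm(40), 10, 4,
#'             dimnames = list(paste0("P", 1:10), paste0("s", 1:4)))
#' om <- OmicsMatrix(m, group = rep(c("WT", "RES"), each = 2),
#'                   replicate = rep(1:2, 2))
#' referenceGroup(om)
#' @export
OmicsMatrix <- function(abundance, group, format = "2D", replicate = NULL,
                        reference = NULL) {
  abundance <- as.matrix(abundance)
  n <- ncol(abundance)
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sample", seq_len(n))
  group <- as.character(rep(group, length.out = n))
  format <- as.character(rep(format, length.out = n))
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_len(n), paste(group, format),
                            FUN = seq_along)
  }
  if (is.null(reference)) reference <- group[1L]
  cd <- S4Vectors::DataFrame(group = group, format = format,
                             replicate = as.integer(replicate),
                             row.names = colnames(abundance))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance), colData = cd)
  new("OmicsMatrix", se, reference = reference)
}

#' @describeIn OmicsMatrix abundance matrix accessor.
#' @param x,object an `OmicsMatrix`.
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn OmicsMatrix sample group labels.
#' @export
sampleGroups <- function(x) SummarizedExperiment::colData(x)$group

#' @describeIn OmicsMatrix sample format labels.
#' @export
sampleFormats <- function(x) SummarizedExperiment::colData(x)$format

#' @describeIn OmicsMatrix reference group label.
#' @export
referenceGroup <- function(x) x@reference

#' @describeIn OmicsMatrix feature identifiers.
#' @export
featureIds <- function(x) rownames(x)

setMethod("show", "OmicsMatrix", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("OmicsMatrix: %d features x %d samples\n",
              nrow(object), ncol(object)))
  cat("  groups:  ", paste(unique(cd$group), collapse = ", "),
      sprintf(" (reference: %s)\n", object@reference))
  cat("  formats: ", paste(unique(cd$format), collapse = ", "), "\n")
})

#' RamanMap: gridded hyperspectral Raman map
#'
#' Holds a shared wavenumber axis, one spectrum per pixel (columns of the
#' `spectra` matrix) and the pixel grid coordinates in micrometres. A
#' processing `log` records, in order, the transformations that produced the
#' object, so that the provenance of any derived quantity is explicit.
#'
#' @slot wavenumber strictly increasing numeric axis in reciprocal
#'   centimetres.
#' @slot spectra numeric matrix, `length(wavenumber)` rows, one column per
#'   pixel; column names are pixel ids.
#' @slot coords data.frame with columns `x` and `y` (micrometres), one row
#'   per pixel, row names matching `colnames(spectra)`.
#' @slot log character vector of applied processing steps.
#' @seealso [simRamanMap()], [preprocessMap()], [bandRatios()]
#' @export
setClass("RamanMap",
  slots = c(wavenumber = "numeric", spectra = "matrix",
            coords = "data.frame", log = "character")
)

setValidity("RamanMap", function(object) {
  msg <- character()
  if (length(object@wavenumber) != nrow(object@spectra))
    msg <- c(msg, "axis length must equal the number of spectral rows")
  if (is.unsorted(object@wavenumber, strictly = TRUE))
    msg <- c(msg, "wavenumber axis must be strictly increasing")
  if (nrow(object@coords) != ncol(object@spectra))
    msg <- c(msg, "one coordinate row per pixel is required")
  if (!all(c("x", "y") %in% colnames(object@coords)))
    msg <- c(msg, "coords must have columns 'x' and 'y'")
  if (length(msg)) msg else TRUE
})

#' Construct a RamanMap
#'
#' @param wavenumber numeric axis (reciprocal centimetres), strictly
#'   increasing.
#' @param spectra matrix of intensities, rows = axis points, columns =
#'   pixels.
#' @param coords data.frame with `x`, `y` pixel positions in micrometres.
#' @param log character vector of processing steps already applied.
#' @return A [RamanMap-class] object.
#' @export
RamanMap <- function(wavenumber, spectra, coords, log = character()) {
  spectra <- as.matrix(spectra)
  if (is.null(colnames(spectra)))
    colnames(spectra) <- paste0("px", seq_len(ncol(spectra)))
  if (nrow(coords) != ncol(spectra))
    stop("one coordinate row per pixel is required")
  rownames(coords) <- colnames(spectra)
  new("RamanMap", wavenumber = as.numeric(wavenumber), spectra = spectra,
      coords = coords, log = log)
}

#' @describeIn RamanMap wavenumber axis accessor.
#' @param x,object a `RamanMap`.
#' @export
wavenumbers <- function(x) x@wavenumber

#' @describeIn RamanMap spectral matrix accessor (axis points x pixels).
#' @export
spectraMatrix <- function(x) x@spectra

#' @describeIn RamanMap pixel coordinate accessor.
#' @export
pixelCoords <- function(x) x@coords

#' @describeIn RamanMap processing log accessor.
#' @export
processingLog <- function(x) x@log

setMethod("show", "RamanMap", function(object) {
  cat(sprintf("RamanMap: %d pixels, axis %g-%g cm^-1 (%d points)\n",
              ncol(object@spectra), min(object@wavenumber),
              max(object@wavenumber), length(object@wavenumber)))
  if (length(object@log))
    cat("  processing:", paste(object@log, collapse = " -> "), "\n")
})

# subset pixels, keeping axis
subsetPixels <- function(map, keep, step = NULL) {
  out <- RamanMap(map@wavenumber, map@spectra[, keep, drop = FALSE],
                  map@coords[keep, , drop = FALSE],
                  log = c(map@log, step))
  out
}
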