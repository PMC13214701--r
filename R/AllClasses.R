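#' @import methods
NULL

#' Tissue classes recognised by the pipeline
#'
#' The three histology-confirmed tissue states in their canonical order:
#' normal white matter, damaged white matter, tumor. The order is load-bearing:
#' it fixes the deterministic tie-break at prediction time and the column order
#' of every score matrix. The scan-level binary task collapses
#' \code{Tumor} to positive and the two white-matter states to negative.
#'
#' @return Character vector \code{c("Normal", "DamagedMatter", "Tumor")}.
#' @examples
#' tissueClasses()
#' @export
tissueClasses <- function() c("Normal", "DamagedMatter", "Tumor")

#' Display colours for rendered segmentation maps (Green/Yellow/Red).
#' @return Named character vector of hex colours, one per tissue class.
#' @export
tissueColors <- function() {
  c(Normal = "#00B050", DamagedMatter = "#E6C800", Tumor = "#D01818")
}

## ---------------------------------------------------------------------------
## BScan
## ---------------------------------------------------------------------------

#' BScan: a 2-D OCT cross-section in linear intensity
#'
#' Rows are depth pixels (index increasing away from the probe), columns are
#' adjacent A-scans. Intensity is always held in linear units internally;
#' \code{isDb} only records the on-disk scale the raster was read from.
#' The raster must be at least 41 rows deep (room for the depth 20--40 feature
#' region plus the 10-pixel speckle window) and 20 columns wide (one feature
#' block).
#'
#' @slot intensity numeric matrix, finite and non-negative.
#' @slot axialPitch axial inter-pixel distance in mm (default 0.0075).
#' @slot scanId scan identifier.
#' @slot isDb whether the on-disk raster was stored in dB.
#' @slot noiseFloorDb SNR cutoff in dB used for masking (default 15).
#' @slot noiseReference linear-intensity noise reference; length 0 when it must
#'   be estimated from the raster itself.
#' @slot label optional per-A-scan ground-truth tissue class (length 0 or
#'   \code{ncol(intensity)}).
#' @export
setClass("BScan",
  slots = c(
    intensity      = "matrix",
    axialPitch     = "numeric",
    scanId         = "character",
    isDb           = "logical",
    noiseFloorDb   = "numeric",
    noiseReference = "numeric",
    label          = "character"
  ),
  prototype = list(
    axialPitch = 0.0075, scanId = "scan", isDb = FALSE,
    noiseFloorDb = 15, noiseReference = numeric(0), label = character(0)
  )
)

setValidity("BScan", function(object) {
  I <- object@intensity
  msg <- character(0)
  if (!is.numeric(I)) msg <- c(msg, "intensity must be a numeric matrix")
  else {
    if (any(!is.finite(I))) msg <- c(msg, "intensity must be finite")
    if (any(I < 0)) msg <- c(msg, "intensity must be non-negative (linear scale)")
    if (nrow(I) < 41) msg <- c(msg, "raster must be at least 41 depth pixels")
    if (ncol(I) < 20) msg <- c(msg, "raster must be at least 20 A-scans wide")
  }
  if (length(object@axialPitch) != 1 || !is.finite(object@axialPitch) ||
      object@axialPitch <= 0)
    msg <- c(msg, "axialPitch must be a single positive number")
  if (length(object@noiseFloorDb) != 1 || object@noiseFloorDb < 0)
    msg <- c(msg, "noiseFloorDb must be a single non-negative number")
  if (length(object@noiseReference) > 1 ||
      (length(object@noiseReference) == 1 && object@noiseReference <= 0))
    msg <- c(msg, "noiseReference, when given, must be a single positive number")
  if (length(object@label) > 0) {
    if (length(object@label) != ncol(I))
      msg <- c(msg, "label length must equal the number of A-scans")
    if (!all(object@label %in% tissueClasses()))
      msg <- c(msg, "labels must be one of the three tissue classes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BScan
#'
#' @param intensity numeric matrix of linear intensities (rows = depth).
#' @param axialPitch axial inter-pixel distance in mm.
#' @param scanId scan identifier.
#' @param isDb whether the source raster was stored in dB (informational).
#' @param noiseFloorDb SNR cutoff in dB.
#' @param noiseReference optional linear noise reference intensity.
#' @param label optional per-A-scan tissue class vector.
#' @return A \linkS4class{BScan}.
#' @examples
#' b <- BScan(matrix(1, 64, 32), scanId = "demo")
#' dim(intensity(b))
#' @export
BScan <- function(intensity, axialPitch = 0.0075, scanId = "scan",
                  isDb = FALSE, noiseFloorDb = 15,
                  noiseReference = numeric(0), label = character(0)) {
  new("BScan", intensity = intensity, axialPitch = axialPitch,
      scanId = scanId, isDb = isDb, noiseFloorDb = noiseFloorDb,
      noiseReference = noiseReference, label = label)
}

## ---------------------------------------------------------------------------
## ParametricMaps
## ---------------------------------------------------------------------------

#' ParametricMaps: paired OAC and RSC rasters with an SNR validity mask
#'
#' All three rasters share the source B-scan's shape. Cells failing the SNR
#' cutoff (or, for RSC, whose sliding window lacks full valid support) carry
#' \code{NaN}, never a silent zero. On the valid mask, OAC (mm^-1) and RSC
#' (dimensionless) are non-negative.
#'
#' @slot oac attenuation-coefficient raster in mm^-1.
#' @slot rsc refined speckle-contrast raster (dimensionless).
#' @slot validMask logical raster; TRUE where the SNR cutoff is met.
#' @slot scanId source scan identifier.
#' @slot axialPitch axial pitch of the source scan, mm.
#' @export
setClass("ParametricMaps",
  slots = c(oac = "matrix", rsc = "matrix", validMask = "matrix",
            scanId = "character", axialPitch = "numeric")
)

setValidity("ParametricMaps", function(object) {
  msg <- character(0)
  d <- dim(object@oac)
  if (!identical(d, dim(object@rsc)) || !identical(d, dim(object@validMask)))
    msg <- c(msg, "oac, rsc and validMask must have identical shapes")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  ok <- object@validMask & is.finite(object@oac)
  if (any(object@oac[ok] < 0)) msg <- c(msg, "OAC negative on valid mask")
  okr <- object@validMask & is.finite(object@rsc)
  if (any(object@rsc[okr] < 0)) msg <- c(msg, "RSC negative on valid mask")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TissueSVM
## ---------------------------------------------------------------------------

#' TissueSVM: a standardized linear one-vs-rest tissue classifier
#'
#' Holds the feature scaler fitted on the training blocks (per-feature mean and
#' standard deviation) and one linear decision function per tissue class
#' against the rest, expressed in standardized feature space as a weight
#' vector plus intercept. The manifest records training scan ids, the
#' regularization constant and the seed, making retraining reproducible.
#'
#' @slot classes tissue classes present, in canonical order.
#' @slot center,scale per-feature scaler statistics (length 2: OAC, RSC).
#' @slot weights classes x 2 matrix of standardized-space weights.
#' @slot intercepts per-class intercepts.
#' @slot cost SVM regularization constant C.
#' @slot manifest list: training scan ids, block count, seed.
#' @export
setClass("TissueSVM",
  slots = c(classes = "character", center = "numeric", scale = "numeric",
            weights = "matrix", intercepts = "numeric", cost = "numeric",
            manifest = "list")
)

setValidity("TissueSVM", function(object) {
  msg <- character(0)
  if (length(object@center) != 2 || length(object@scale) != 2)
    msg <- c(msg, "scaler must have exactly 2 features (OAC, RSC)")
  if (any(object@scale <= 0)) msg <- c(msg, "scaler SDs must be positive")
  if (nrow(object@weights) != length(object@classes) ||
      ncol(object@weights) != 2)
    msg <- c(msg, "weights must be classes x 2")
  if (length(object@intercepts) != length(object@classes))
    msg <- c(msg, "one intercept per class required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SegmentationMap
## ---------------------------------------------------------------------------

#' SegmentationMap: per-block tissue labels for one scan
#'
#' One label per 20-A-scan block, the argmax of the per-class decision scores;
#' blocks with too little valid signal carry \code{NA}. Rendered as
#' green/yellow/red column stripes over the structural image.
#'
#' @slot scanId source scan identifier.
#' @slot labels factor of tissue classes (NA = invalid block).
#' @slot scores blocks x classes decision-score matrix.
#' @slot blockWidth block width in A-scans.
#' @slot modelId identifier of the model that produced the map.
#' @export
setClass("SegmentationMap",
  slots = c(scanId = "character", labels = "factor", scores = "matrix",
            blockWidth = "integer", modelId = "character")
)

setValidity("SegmentationMap", function(object) {
  msg <- character(0)
  if (!all(levels(object@labels) == tissueClasses()))
    msg <- c(msg, "labels must use the canonical tissue-class levels")
  if (nrow(object@scores) != length(object@labels))
    msg <- c(msg, "one score row per block required")
  ok <- !is.na(object@labels) & rowSums(is.finite(object@scores)) == ncol(object@scores)
  if (any(ok)) {
    am <- max.col(object@scores[ok, , drop = FALSE], ties.method = "first")
    if (!all(colnames(object@scores)[am] == as.character(object@labels[ok])))
      msg <- c(msg, "label must be the argmax of the decision scores")
  }
  if (object@blockWidth < 1L) msg <- c(msg, "blockWidth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentationMap
#'
#' @param scanId scan identifier.
#' @param labels character/factor of per-block classes (NA allowed).
#' @param scores optional blocks x classes score matrix; defaults to a one-hot
#'   encoding of the labels (used for synthetic maps without a model).
#' @param blockWidth block width in A-scans.
#' @param modelId provenance string.
#' @return A \linkS4class{SegmentationMap}.
#' @export
SegmentationMap <- function(scanId, labels, scores = NULL,
                            blockWidth = 20L, modelId = "synthetic") {
  labels <- factor(as.character(labels), levels = tissueClasses())
  if (is.null(scores)) {
    scores <- matrix(0, length(labels), 3,
                     dimnames = list(NULL, tissueClasses()))
    idx <- cbind(seq_along(labels), as.integer(labels))
    scores[idx[!is.na(labels), , drop = FALSE]] <- 1
  }
  new("SegmentationMap", scanId = scanId, labels = labels, scores = scores,
      blockWidth = as.integer(blockWidth), modelId = modelId)
}

## ---------------------------------------------------------------------------
## AssessmentSet
## ---------------------------------------------------------------------------

#' AssessmentSet: a complete scans x readers forced-choice call matrix
#'
#' Every reader calls every scan either \code{"WM"} or \code{"Tumor"}; no
#' missing cells and no third category (forced choice). Ground truth is one
#' binary label per scan.
#'
#' @slot scanIds scan identifiers (rows).
#' @slot readerIds reader identifiers (columns).
#' @slot truth per-scan ground truth, "WM" or "Tumor".
#' @slot calls scans x readers character matrix of calls.
#' @export
setClass("AssessmentSet",
  slots = c(scanIds = "character", readerIds = "character",
            truth = "character", calls = "matrix")
)

setValidity("AssessmentSet", function(object) {
  msg <- character(0)
  n <- length(object@scanIds); r <- length(object@readerIds)
  if (nrow(object@calls) != n || ncol(object@calls) != r)
    msg <- c(msg, "calls must be scans x readers")
  if (length(object@truth) != n)
    msg <- c(msg, "one truth value per scan required")
  if (!all(object@truth %in% c("WM", "Tumor")))
    msg <- c(msg, "truth must be WM or Tumor")
  if (anyNA(object@calls) || !all(object@calls %in% c("WM", "Tumor")))
    msg <- c(msg, "forced choice: every call must be WM or Tumor")
  if (anyDuplicated(object@scanIds)) msg <- c(msg, "duplicate scan ids")
  if (anyDuplicated(object@readerIds)) msg <- c(msg, "duplicate reader ids")
  if (length(msg)) msg else TRUE
})

#' Construct an AssessmentSet
#'
#' @param calls scans x readers character matrix of "WM"/"Tumor" calls.
#' @param truth per-scan ground truth ("WM"/"Tumor").
#' @param scanIds,readerIds identifiers; default to dimnames or serial ids.
#' @return An \linkS4class{AssessmentSet}.
#' @examples
#' a <- AssessmentSet(matrix("Tumor", 2, 3), truth = c("Tumor", "WM"))
#' confusionCounts(a)
#' @export
AssessmentSet <- function(calls, truth, scanIds = NULL, readerIds = NULL) {
  calls <- as.matrix(calls)
  if (is.null(scanIds))
    scanIds <- rownames(calls) %||% sprintf("scan%03d", seq_len(nrow(calls)))
  if (is.null(readerIds))
    readerIds <- colnames(calls) %||% sprintf("reader%d", seq_len(ncol(calls)))
  dimnames(calls) <- list(scanIds, readerIds)
  new("AssessmentSet", scanIds = scanIds, readerIds = readerIds,
      truth = truth, calls = calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
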