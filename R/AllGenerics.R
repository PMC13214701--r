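#' @rdname BScan-class
#' @param object,x a pipeline object
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname BScan-class
#' @export
setGeneric("axialPitch", function(x) standardGeneric("axialPitch"))
#' @rdname BScan-class
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))
#' @rdname BScan-class
#' @export
setGeneric("scanLabel", function(x) standardGeneric("scanLabel"))
#' @rdname ParametricMaps-class
#' @param x a pipeline object
#' @export
setGeneric("oacMap", function(x) standardGeneric("oacMap"))
#' @rdname ParametricMaps-class
#' @export
setGeneric("rscMap", function(x) standardGeneric("rscMap"))
#' @rdname ParametricMaps-class
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname SegmentationMap-class
#' @param x a pipeline object
#' @export
setGeneric("blockLabels", function(x) standardGeneric("blockLabels"))
#' @rdname SegmentationMap-class
#' @export
setGeneric("blockScores", function(x) standardGeneric("blockScores"))
#' @rdname AssessmentSet-class
#' @param x a pipeline object
#' @export
setGeneric("readerCalls", function(x) standardGeneric("readerCalls"))
#' @rdname AssessmentSet-class
#' @export
setGeneric("scanTruth", function(x) standardGeneric("scanTruth"))

setMethod("intensity", "BScan", function(x) x@intensity)
setMethod("axialPitch", "BScan", function(x) x@axialPitch)
setMethod("axialPitch", "ParametricMaps", function(x) x@axialPitch)
setMethod("scanId", "BScan", function(x) x@scanId)
setMethod("scanId", "ParametricMaps", function(x) x@scanId)
setMethod("scanId", "SegmentationMap", function(x) x@scanId)
setMethod("scanLabel", "BScan", function(x) x@label)
setMethod("oacMap", "ParametricMaps", function(x) x@oac)
setMethod("rscMap", "ParametricMaps", function(x) x@rsc)
setMethod("validMask", "ParametricMaps", function(x) x@validMask)
setMethod("blockLabels", "SegmentationMap", function(x) x@labels)
setMethod("blockScores", "SegmentationMap", function(x) x@scores)
setMethod("readerCalls", "AssessmentSet", function(x) x@calls)
setMethod("scanTruth", "AssessmentSet", function(x) x@truth)

setMethod("dim", "BScan", function(x) dim(x@intensity))
setMethod("dim", "ParametricMaps", function(x) dim(x@oac))

setMethod("show", "BScan", function(object) {
  cat(sprintf("BScan '%s': %d depth px x %d A-scans, pitch %.4g mm%s\n",
              object@scanId, nrow(object@intensity), ncol(object@intensity),
              object@axialPitch,
              if (length(object@label)) ", labelled" else ""))
})

setMethod("show", "ParametricMaps", function(object) {
  cat(sprintf("ParametricMaps '%s': %d x %d, %.1f%% valid\n",
              object@scanId, nrow(object@oac), ncol(object@oac),
              100 * mean(object@validMask)))
})

setMethod("show", "SegmentationMap", function(object) {
  tab <- table(object@labels, useNA = "ifany")
  cat(sprintf("SegmentationMap '%s' (model %s): %d blocks of %d A-scans\n",
              object@scanId, object@modelId, length(object@labels),
              object@blockWidth))
  print(tab)
})

setMethod("show", "TissueSVM", function(object) {
  cat(sprintf("TissueSVM: linear OvR over (OAC, RSC), C = %g, classes: %s\n",
              object@cost, paste(object@classes, collapse = ", ")))
})

setMethod("show", "AssessmentSet", function(object) {
  cat(sprintf("AssessmentSet: %d scans x %d readers (%d Tumor / %d WM truth)\n",
              length(object@scanIds), length(object@readerIds),
              sum(object@truth == "Tumor"), sum(object@truth == "WM")))
})
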