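#' Read a JSON metadata sidecar
#'
#' One JSON object per scan with at least \code{axial_pitch_mm} and
#' \code{intensity_scale} ("linear" or "dB"); optional \code{scan_id},
#' \code{noise_floor_db} (default 15), \code{noise_reference} (linear) and a
#' per-A-scan \code{label} array.
#'
#' @param path path to the JSON sidecar.
#' @return named list of metadata fields.
#' @export
readSidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar file not found: ", path)
  meta <- jsonlite::fromJSON(path)
  if (is.null(meta$axial_pitch_mm) || !is.numeric(meta$axial_pitch_mm) ||
      meta$axial_pitch_mm <= 0)
    stop("sidecar must give a positive axial_pitch_mm")
  if (is.null(meta$intensity_scale) ||
      !meta$intensity_scale %in% c("linear", "dB"))
    stop("sidecar intensity_scale must be 'linear' or 'dB'")
  meta$noise_floor_db <- meta$noise_floor_db %||% 15
  meta
}

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = , tiff = {
      info <- tiff::readTIFF(path, payload = FALSE)
      ## 8/16-bit samples are integers wanted as stored; 32-bit samples are
      ## float and must not go through the as.is integer path
      if (identical(info$bits.per.sample, 32L))
        tiff::readTIFF(path)
      else tiff::readTIFF(path, as.is = TRUE)
    },
    png = {
      p <- png::readPNG(path, info = TRUE)
      depth <- attr(p, "info")$bit.depth %||% 8L
      p * (2^depth - 1)
    },
    stop("unsupported raster format: ", ext))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] > 1L) stop("multi-channel raster not supported")
    x <- x[, , 1L]
  }
  storage.mode(x) <- "double"
  attributes(x) <- list(dim = dim(x))   # drop reader metadata attributes
  x
}

#' Read an OCT B-scan from a raster file plus metadata sidecar
#'
#' Accepts single-channel 16-bit or float TIFF (canonical) and PNG rasters.
#' The sidecar is mandatory: without the axial pitch the attenuation
#' coefficient has no units. If the sidecar declares the on-disk scale as dB,
#' pixel values v are converted to linear intensity \code{10^(v/10)} before
#' anything else touches them; all downstream computation sees linear units.
#'
#' @param path raster file (.tif/.tiff/.png).
#' @param sidecar JSON sidecar path (see \code{\link{readSidecar}}).
#' @return A \linkS4class{BScan} in linear intensity.
#' @export
readBScan <- function(path, sidecar) {
  if (missing(sidecar) || is.null(sidecar))
    stop("a metadata sidecar is required (axial pitch defines OAC units)")
  meta <- readSidecar(sidecar)
  x <- .readRaster(path)
  if (!is.null(meta$scale_factor)) x <- x * meta$scale_factor
  isDb <- meta$intensity_scale == "dB"
  if (isDb) x <- dbToLinear(x)
  BScan(x,
        axialPitch = meta$axial_pitch_mm,
        scanId = meta$scan_id %||% tools::file_path_sans_ext(basename(path)),
        isDb = isDb,
        noiseFloorDb = meta$noise_floor_db,
        noiseReference = if (is.null(meta$noise_reference)) numeric(0)
                         else as.numeric(meta$noise_reference),
        label = if (is.null(meta$label)) character(0)
                else as.character(meta$label))
}

#' Write a B-scan as TIFF plus JSON sidecar
#'
#' \code{format = "float"} (default) stores 32-bit float samples normalised
#' to [0, 1] (TIFF float storage is only defined on that range), with the
#' normalisation recorded as \code{scale_factor} in the sidecar so reading
#' restores physical units; the round trip is exact to single precision.
#' \code{format = "16bit"} requires integer values in [0, 65535] and
#' round-trips bit-exactly.
#'
#' @param scan a \linkS4class{BScan}.
#' @param path output TIFF path.
#' @param sidecar output JSON sidecar path; default replaces the raster
#'   extension with \code{.json}.
#' @param format "float" or "16bit".
#' @return invisibly, the raster path.
#' @export
writeBScan <- function(scan, path, sidecar = NULL, format = c("float", "16bit")) {
  format <- match.arg(format)
  if (is.null(sidecar))
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  I <- scan@intensity
  scaleFactor <- 1
  if (format == "16bit") {
    if (any(I != round(I)) || any(I > 65535))
      stop("16bit format requires integer intensities in [0, 65535]")
    tiff::writeTIFF(I / 65535, path, bits.per.sample = 16L)
  } else {
    scaleFactor <- max(I, 1e-300)
    tiff::writeTIFF(I / scaleFactor, path, bits.per.sample = 32L)
  }
  meta <- list(scan_id = scan@scanId,
               axial_pitch_mm = scan@axialPitch,
               intensity_scale = "linear",
               noise_floor_db = scan@noiseFloorDb)
  if (scaleFactor != 1) meta$scale_factor <- scaleFactor
  if (length(scan@noiseReference)) meta$noise_reference <- scan@noiseReference
  if (length(scan@label)) meta$label <- scan@label
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a blockwise feature table as CSV
#'
#' Columns \code{scan_id, block_index, mean_oac, mean_rsc, label} (plus any
#' extra columns present). Feature values are serialised with 12 significant
#' digits and round-trip losslessly at that precision.
#'
#' @param blocks non-empty data.frame from \code{\link{extractBlocks}}.
#' @param path CSV path.
#' @return invisibly, the path (write) or the parsed data.frame (read).
#' @export
writeFeatureTable <- function(blocks, path) {
  if (is.null(blocks) || nrow(blocks) == 0)
    stop("refusing to write an empty feature table")
  out <- blocks
  for (col in c("mean_oac", "mean_rsc", "valid_frac"))
    if (col %in% names(out)) out[[col]] <- sprintf("%.12g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("mean_oac", "mean_rsc", "valid_frac"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  df
}

#' Read a forced-choice assessment table
#'
#' Expects CSV columns \code{scan_id, reader_id, call, truth} with calls and
#' truth in \{WM, Tumor\}. The forced-choice design is enforced: every reader
#' must have rated every scan exactly once, any missing cell, duplicate, or
#' third category ("Uncertain" etc.) is a hard error, and truth must be
#' consistent within a scan.
#'
#' @param path CSV path.
#' @return An \linkS4class{AssessmentSet}.
#' @export
readAssessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "reader_id", "call", "truth")
  if (!all(need %in% names(df)))
    stop("assessment CSV must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(c(df$call, df$truth)), c("WM", "Tumor"))
  if (length(bad))
    stop("forced choice violated: unexpected category ", paste(bad, collapse = ", "))
  scans <- unique(df$scan_id); readers <- unique(df$reader_id)
  if (nrow(df) != length(scans) * length(readers) ||
      anyDuplicated(df[c("scan_id", "reader_id")]))
    stop("assessment matrix incomplete: every reader must rate every scan once")
  tr <- tapply(df$truth, df$scan_id, function(v) {
    u <- unique(v)
    if (length(u) != 1) stop("inconsistent truth for a scan")
    u
  })
  calls <- matrix(NA_character_, length(scans), length(readers),
                  dimnames = list(scans, readers))
  calls[cbind(match(df$scan_id, scans), match(df$reader_id, readers))] <- df$call
  AssessmentSet(calls, truth = as.character(tr[scans]),
                scanIds = scans, readerIds = readers)
}

#' @rdname readAssessments
#' @param assessments an \linkS4class{AssessmentSet} to serialise.
#' @export
writeAssessments <- function(assessments, path) {
  a <- assessments
  df <- expand.grid(scan_id = a@scanIds, reader_id = a@readerIds,
                    stringsAsFactors = FALSE)
  df$call <- a@calls[cbind(match(df$scan_id, a@scanIds),
                           match(df$reader_id, a@readerIds))]
  df$truth <- a@truth[match(df$scan_id, a@scanIds)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
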