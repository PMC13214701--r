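#' Depth-resolved optical attenuation coefficient (OAC)
#'
#' Estimates the per-pixel attenuation coefficient of each A-scan from the
#' ratio of local intensity to its depth tail sum,
#' \deqn{\mu_s(j) = \frac{I(j)}{2\Delta \sum_{i=j}^{N-1} I(i)},}
#' where \eqn{\Delta} is the axial inter-pixel distance in mm and the sum runs
#' to the bottom pixel of the scan. The estimator assumes the signal has
#' decayed to (near) zero by the bottom of the raster; the truncated tail
#' induces a known depth-dependent upward bias of relative size
#' \eqn{e^{-2\mu\Delta(N-j)}} which is characterised, not corrected.
#'
#' Because intensity appears in both numerator and denominator, the OAC raster
#' is invariant under global intensity scaling. Columns whose tail sum is zero
#' (e.g. an all-zero A-scan) yield \code{NaN}, the sentinel for undefined
#' cells.
#'
#' @param scan a \linkS4class{BScan} in linear intensity, or a numeric matrix
#'   (rows = depth) combined with \code{pitch}.
#' @param pitch axial pitch in mm, only used for matrix input.
#' @return numeric matrix of attenuation coefficients in mm^-1, same shape as
#'   the input raster.
#' @examples
#' b <- BScan(matrix(2, 64, 32), axialPitch = 0.0075)
#' oac <- computeOAC(b)
#' oac[1, 1]  # 1 / (2 * 0.0075 * 64) for a uniform A-scan
#' @export
computeOAC <- function(scan, pitch = NULL) {
  if (is(scan, "BScan")) {
    I <- scan@intensity
    pitch <- scan@axialPitch
  } else {
    I <- scan
    if (is.null(pitch)) stop("pitch required for matrix input")
    if (any(!is.finite(I)) || any(I < 0))
      stop("intensity must be finite and non-negative (linear-scale contract)")
  }
  ## reversed cumulative sum per column = truncated tail sum
  tail <- apply(I, 2L, function(col) rev(cumsum(rev(col))))
  oac <- I / (2 * pitch * tail)
  oac[tail == 0] <- NaN
  oac
}

#' Refined speckle contrast (RSC) of an OAC raster
#'
#' Local dispersion-over-mean of the attenuation coefficient in a centered
#' sliding window (default 10 px depth x 20 px width). Computing contrast on
#' the OAC field rather than raw intensity compensates for depth-dependent
#' signal decay, so the statistic reflects microstructural heterogeneity
#' rather than attenuation itself. The default statistic is the standard
#' speckle-contrast form sd/mean (population standard deviation);
#' \code{type = "variance"} gives variance/mean instead.
#'
#' Cells whose window extends past the raster border, or whose window contains
#' any masked (\code{NaN}) OAC value, are \code{NaN}: no partial-window
#' statistics are invented. RSC is scale-invariant in the sd/mean form and
#' invariant under any permutation of values inside a window.
#'
#' @param oac numeric matrix from \code{\link{computeOAC}} (masked cells NaN).
#' @param window integer pair (depth, width); default \code{c(10, 20)}.
#' @param type \code{"std"} (sd/mean, default) or \code{"variance"}
#'   (variance/mean).
#' @return numeric matrix of speckle-contrast values, same shape as
#'   \code{oac}.
#' @export
computeRSC <- function(oac, window = c(10L, 20L),
                       type = c("std", "variance")) {
  type <- match.arg(type)
  h <- as.integer(window[1]); w <- as.integer(window[2])
  if (h < 1L || w < 1L) stop("window dimensions must be positive")
  if (h > nrow(oac) || w > ncol(oac)) stop("window larger than raster")
  bad <- !is.finite(oac)
  z <- oac
  z[bad] <- 0
  n <- h * w
  s1 <- .boxSum(z, h, w)
  s2 <- .boxSum(z * z, h, w)
  nbad <- .boxSum(bad + 0, h, w)
  mu <- s1 / n
  v <- pmax(s2 / n - mu * mu, 0)
  rsc <- if (type == "std") sqrt(v) / mu else v / mu
  rsc[!is.finite(rsc)] <- NaN
  rsc[is.na(nbad) | nbad > 0] <- NaN
  rsc
}

#' Signal-to-noise mask for a B-scan
#'
#' TRUE where the pixel intensity is at least \code{noiseFloorDb} decibels
#' above the noise reference, i.e. \code{10*log10(I / I_noise) >= cutoff}
#' (default cutoff 15 dB). The noise reference is taken from the scan's
#' metadata when present; otherwise it is estimated as the median intensity of
#' the bottom 5\% of rows, where an OCT B-scan is normally noise-dominated.
#'
#' With \code{smooth = NULL} (default) the criterion is evaluated per pixel —
#' the literal reading of the cutoff. On speckled data a per-pixel mask is
#' salt-and-pepper: fully developed speckle sends ~1--2\% of pixels below any
#' threshold even at high mean SNR. Supplying \code{smooth = c(h, w)}
#' evaluates the criterion on a clamped-window box average of the intensity
#' (speckle-reduced) and forces each column's mask to a depth prefix (valid
#' above the first failing depth, invalid below), which is the physically
#' intended behaviour: the noise floor cuts off the signal-starved deep
#' region, not isolated speckle dropouts.
#'
#' @param scan a \linkS4class{BScan} in linear intensity.
#' @param noiseFloorDb SNR cutoff in dB; defaults to the scan's metadata
#'   value.
#' @param noiseReference optional linear-intensity noise reference overriding
#'   the scan metadata and the bottom-rows estimate.
#' @param smooth optional (depth, width) box-average window; see Details.
#' @return logical matrix, TRUE = pixel passes the SNR cutoff.
#' @export
snrMask <- function(scan, noiseFloorDb = NULL, noiseReference = NULL,
                    smooth = NULL) {
  stopifnot(is(scan, "BScan"))
  I <- scan@intensity
  if (is.null(noiseFloorDb)) noiseFloorDb <- scan@noiseFloorDb
  if (is.null(noiseReference)) {
    noiseReference <- if (length(scan@noiseReference) == 1) {
      scan@noiseReference
    } else {
      k <- max(1L, floor(0.05 * nrow(I)))
      stats::median(I[(nrow(I) - k + 1L):nrow(I), ])
    }
  }
  if (!is.finite(noiseReference) || noiseReference <= 0)
    stop("noise reference must be positive")
  if (is.null(smooth))
    return(10 * log10(I / noiseReference) >= noiseFloorDb)
  Is <- .boxMeanClamped(I, smooth[1], smooth[2])
  ok <- 10 * log10(Is / noiseReference) >= noiseFloorDb
  ## force a per-column prefix: everything below the first failure is invalid
  apply(ok, 2L, function(v) {
    f <- which(!v)
    if (length(f)) v[f[1]:length(v)] <- FALSE
    v
  })
}

## Centered box mean with windows clamped at the raster borders (partial
## windows allowed), separable two-pass implementation.
.boxMeanClamped <- function(m, h, w) {
  pass <- function(x, k) {
    n <- nrow(x)
    C <- rbind(0, apply(x, 2L, cumsum))
    lo <- pmax(seq_len(n) - k %/% 2L, 1L)
    hi <- pmin(lo + k - 1L, n)
    (C[hi + 1L, , drop = FALSE] - C[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  t(pass(t(pass(m, h)), w))
}

#' Compute OAC + RSC parametric maps with SNR masking
#'
#' Runs the full parametric-mapping stage: attenuation coefficients per pixel,
#' the SNR validity mask at the configured noise floor, and speckle contrast
#' over the masked OAC field. OAC is computed from the complete raster (the
#' tail sum uses all pixels); the mask is applied to the output maps, and
#' masked cells are excluded from every RSC window (windows touching them are
#' themselves masked). The mask is evaluated on the speckle-reduced smoothed
#' intensity and per column is a depth prefix (see \code{\link{snrMask}}),
#' so masking removes the signal-starved deep region rather than isolated
#' speckle dropouts.
#'
#' @param scan a \linkS4class{BScan} in linear intensity.
#' @param window RSC sliding window (depth, width), default \code{c(10, 20)}.
#' @param rscType RSC statistic, \code{"std"} or \code{"variance"}.
#' @param noiseFloorDb,noiseReference see \code{\link{snrMask}}.
#' @param snrSmooth smoothing window for the mask; \code{NULL} for the raw
#'   per-pixel criterion.
#' @return A \linkS4class{ParametricMaps} object.
#' @examples
#' set.seed(1)
#' b <- simulateBScan(layoutHomogeneous(40, "Normal"), seed = 1)
#' m <- computeParametricMaps(b)
#' mean(oacMap(m)[validMask(m)], na.rm = TRUE)
#' @export
computeParametricMaps <- function(scan, window = c(10L, 20L),
                                  rscType = c("std", "variance"),
                                  noiseFloorDb = NULL, noiseReference = NULL,
                                  snrSmooth = window) {
  rscType <- match.arg(rscType)
  mask <- snrMask(scan, noiseFloorDb, noiseReference, smooth = snrSmooth)
  oac <- computeOAC(scan)
  mask <- mask & is.finite(oac)
  oacMasked <- oac
  oacMasked[!mask] <- NaN
  rsc <- computeRSC(oacMasked, window = window, type = rscType)
  new("ParametricMaps", oac = oacMasked, rsc = rsc, validMask = mask,
      scanId = scan@scanId, axialPitch = scan@axialPitch)
}

#' Per-block valid-signal depth extent
#'
#' For each block of \code{blockWidth} columns, the deepest SNR-valid pixel
#' (averaged over the block's columns) as a fraction of the scan depth.
#' This is the depth-evidence input of the contextual filter: strongly
#' attenuating tissue loses signal early and has a shallow extent.
#'
#' @param maps a \linkS4class{ParametricMaps}.
#' @param blockWidth block width in A-scans (default 20).
#' @return numeric vector, one fraction in [0, 1] per complete block.
#' @export
blockDepthExtent <- function(maps, blockWidth = 20L) {
  m <- maps@validMask
  nb <- ncol(m) %/% blockWidth
  if (nb < 1L) stop("raster narrower than one block")
  vapply(seq_len(nb), function(b) {
    cols <- ((b - 1L) * blockWidth + 1L):(b * blockWidth)
    depth <- apply(m[, cols, drop = FALSE], 2L, function(v) {
      w <- which(v)
      if (length(w)) max(w) else 0L
    })
    mean(depth) / nrow(m)
  }, numeric(1))
}
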