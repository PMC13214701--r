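#' Extract blockwise (mean OAC, mean RSC) feature vectors
#'
#' Partitions each scan left-to-right into non-overlapping blocks of
#' \code{blockWidth} adjacent A-scans (trailing remainder columns are
#' dropped) and averages OAC and RSC over the valid cells inside the depth
#' region of interest. The default ROI is depth pixels 20--40, taken as the
#' half-open 0-based interval [20, 40), i.e. 20 rows. A block is flagged
#' invalid when fewer than \code{minValidFrac} of its ROI cells pass the SNR
#' mask or when no finite RSC cells remain; invalid blocks are reported, never
#' silently imputed.
#'
#' @param maps a \linkS4class{ParametricMaps} or a list of them.
#' @param blockWidth block width in A-scans (default 20).
#' @param depthRoi half-open 0-based depth interval, default \code{c(20, 40)}.
#' @param minValidFrac minimum fraction of unmasked ROI cells for a block to
#'   count as valid (default 0.5).
#' @param labels optional per-A-scan ground-truth classes: a character vector
#'   (single scan) or list of vectors aligned with \code{maps}. Block labels
#'   are the majority class over the block's columns (ties broken by canonical
#'   class order).
#' @return data.frame with one row per block: \code{scan_id},
#'   \code{block_index} (0-based), \code{a_start}, \code{a_end} (half-open,
#'   0-based), \code{mean_oac}, \code{mean_rsc}, \code{valid_frac},
#'   \code{valid}, \code{label}.
#' @examples
#' b <- simulateBScan(layoutHomogeneous(60, "Tumor"), seed = 2)
#' m <- computeParametricMaps(b)
#' extractBlocks(m, labels = scanLabel(b))
#' @export
extractBlocks <- function(maps, blockWidth = 20L, depthRoi = c(20L, 40L),
                          minValidFrac = 0.5, labels = NULL) {
  if (is(maps, "ParametricMaps")) {
    maps <- list(maps)
    if (!is.null(labels) && !is.list(labels)) labels <- list(labels)
  }
  blockWidth <- as.integer(blockWidth)
  if (blockWidth < 1L) stop("blockWidth must be >= 1")
  out <- lapply(seq_along(maps), function(i) {
    .extractBlocksOne(maps[[i]], blockWidth, depthRoi, minValidFrac,
                      if (is.null(labels)) NULL else labels[[i]])
  })
  do.call(rbind, out)
}

.extractBlocksOne <- function(m, blockWidth, depthRoi, minValidFrac, label) {
  nr <- nrow(m@oac); nc <- ncol(m@oac)
  if (depthRoi[1] < 0 || depthRoi[2] > nr || depthRoi[1] >= depthRoi[2])
    stop("depth ROI outside raster")
  rows <- (depthRoi[1] + 1L):depthRoi[2]        # 0-based half-open -> 1-based
  nb <- nc %/% blockWidth
  if (nb < 1L) stop("raster narrower than one block")
  if (!is.null(label) && length(label) != nc)
    stop("labels must have one entry per A-scan")
  res <- lapply(seq_len(nb), function(b) {
    cols <- ((b - 1L) * blockWidth + 1L):(b * blockWidth)
    oacROI <- m@oac[rows, cols]
    rscROI <- m@rsc[rows, cols]
    vfrac <- mean(m@validMask[rows, cols])
    meanOac <- if (any(is.finite(oacROI))) mean(oacROI[is.finite(oacROI)]) else NaN
    meanRsc <- if (any(is.finite(rscROI))) mean(rscROI[is.finite(rscROI)]) else NaN
    lab <- NA_character_
    if (!is.null(label)) {
      tab <- table(factor(label[cols], levels = tissueClasses()))
      lab <- names(tab)[which.max(tab)]
    }
    data.frame(scan_id = m@scanId, block_index = b - 1L,
               a_start = (b - 1L) * blockWidth, a_end = b * blockWidth,
               mean_oac = meanOac, mean_rsc = meanRsc,
               valid_frac = vfrac,
               valid = vfrac >= minValidFrac && is.finite(meanOac) &&
                       is.finite(meanRsc),
               label = lab, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
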