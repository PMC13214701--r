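#' Optical tissue model for the synthetic B-scan generator
#'
#' Per-class attenuation coefficients and texture heterogeneity for the three
#' tissue states. The defaults make the classes separable but overlapping in
#' the (OAC, RSC) feature plane. They are simulator constants calibrated to
#' qualitative separability, not measured tissue properties: tumor attenuates
#' strongest and is most heterogeneous, damaged white matter sits in between.
#'
#' @param muS per-class attenuation coefficient, mm^-1.
#' @param sigmaTex per-class lognormal spatial-texture SD modulating local
#'   reflectivity (dimensionless).
#' @param i0 surface reflectivity (linear intensity at depth 0).
#' @param noiseLevel additive noise-floor intensity (linear, relative to
#'   \code{i0}); also the noise reference recorded in generated sidecars.
#' @return validated list of class \code{"TissueModel"}.
#' @export
tissueModel <- function(muS = c(Normal = 1.0, DamagedMatter = 2.0, Tumor = 3.5),
                        sigmaTex = c(Normal = 0.10, DamagedMatter = 0.30,
                                     Tumor = 0.55),
                        i0 = 1, noiseLevel = 1e-4) {
  stopifnot(all(muS > 0), all(sigmaTex >= 0), i0 > 0, noiseLevel >= 0,
            setequal(names(muS), tissueClasses()),
            setequal(names(sigmaTex), tissueClasses()))
  if (anyDuplicated(paste(muS[tissueClasses()], sigmaTex[tissueClasses()])))
    stop("class parameter pairs must be distinct")
  structure(list(muS = muS, sigmaTex = sigmaTex, i0 = i0,
                 noiseLevel = noiseLevel), class = "TissueModel")
}

#' Tissue layouts: per-A-scan ground-truth class sequences
#'
#' \code{layoutHomogeneous} fills the whole width with one class.
#' \code{layoutInfiltration} places a contiguous tumor segment (with optional
#' damaged-matter margins, as at an infiltration front) on a background.
#' \code{layoutScattered} places isolated, non-adjacent single tumor blocks on
#' a background — the tissue pattern whose segmentation produces the
#' scattered false-positive-like maps. Each layout carries its pattern family
#' and scan-level truth as attributes (scattered singleton scans count as WM
#' at scan level: they model algorithmic noise, not a resectable tumor).
#'
#' @param width number of A-scans.
#' @param class tissue class for homogeneous layouts.
#' @param start 0-based A-scan index where the tumor segment starts.
#' @param length tumor segment length in A-scans.
#' @param background background class (default "Normal").
#' @param marginWidth damaged-matter margin on each side of the tumor
#'   segment, in A-scans (default 20, one block; 0 disables).
#' @param blockIndices 0-based indices of the singleton tumor blocks
#'   (non-adjacent).
#' @param blockWidth width of one block in A-scans.
#' @return character vector of per-A-scan classes with attributes
#'   \code{pattern} and \code{scan_truth}.
#' @export
layoutHomogeneous <- function(width, class = "Normal") {
  stopifnot(class %in% tissueClasses())
  structure(rep(class, width), pattern = "homogeneous",
            scan_truth = if (class == "Tumor") "Tumor" else "WM")
}

#' @rdname layoutHomogeneous
#' @export
layoutInfiltration <- function(width, start, length,
                               background = "Normal", marginWidth = 20L) {
  stopifnot(start >= 0, length >= 1, start + length <= width)
  lay <- rep(background, width)
  if (marginWidth > 0) {
    lo <- max(0L, start - marginWidth)
    hi <- min(width, start + length + marginWidth)
    lay[seq(lo + 1L, hi)] <- "DamagedMatter"
  }
  lay[seq(start + 1L, start + length)] <- "Tumor"
  structure(lay, pattern = "infiltration", scan_truth = "Tumor")
}

#' @rdname layoutHomogeneous
#' @export
layoutScattered <- function(width, blockIndices, blockWidth = 20L,
                            background = "Normal") {
  nb <- width %/% blockWidth
  stopifnot(all(blockIndices >= 0), all(blockIndices < nb))
  if (any(diff(sort(blockIndices)) < 2))
    stop("scattered singleton blocks must be non-adjacent")
  lay <- rep(background, width)
  for (b in blockIndices)
    lay[(b * blockWidth + 1L):((b + 1L) * blockWidth)] <- "Tumor"
  structure(lay, pattern = "scattered_fp", scan_truth = "WM")
}

## One-dimensional Gaussian smoothing along rows with replicated edges and a
## kernel normalised to preserve unit variance of white noise.
.smoothRows <- function(x, sd = 3, half = 9L) {
  k <- stats::dnorm(-half:half, sd = sd)
  k <- k / sqrt(sum(k^2))
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (d in -half:half) {
    idx <- pmin(pmax(seq_len(n) + d, 1L), n)
    out <- out + k[d + half + 1L] * x[idx, , drop = FALSE]
  }
  out
}

## 2-D lognormal texture field (depth x width), correlation length ~3 px in
## both axes, unit mean per class. The field must vary axially as well as
## laterally: a purely per-column reflectivity multiplier cancels exactly in
## the OAC ratio and would leave speckle contrast blind to tissue texture.
.textureField <- function(layout, sigmaTex, depth) {
  w <- length(layout)
  g <- matrix(stats::rnorm(depth * w), depth, w)
  gs <- t(.smoothRows(t(.smoothRows(g)), sd = 3))
  sig <- matrix(sigmaTex[layout], depth, w, byrow = TRUE)
  exp(sig * gs - sig^2 / 2)
}

#' Simulate one OCT B-scan with known ground truth
#'
#' Per pixel, the mean intensity follows Beer-Lambert decay
#' \code{i0 * T(row, col) * exp(-2 * muS(class) * pitch * row)} where
#' \code{T} is a smoothed 2-D lognormal texture field (correlation length 3
#' px in both axes) modulating local reflectivity; the realised intensity is
#' the mean multiplied by a unit-mean exponential deviate (fully developed
#' speckle, intensity coefficient of variation 1) plus an additive
#' exponential noise floor. Everything is seed-deterministic. No axial PSF or
#' confocal roll-off is modelled: the generator exercises the pipeline's
#' statistics, not wave optics.
#'
#' @param layout per-A-scan class vector from the layout constructors.
#' @param tissue a \code{\link{tissueModel}}.
#' @param depth number of depth pixels (default 256).
#' @param pitch axial pitch in mm (default 0.0075).
#' @param seed RNG seed (NULL = use the current stream).
#' @param speckle,texture,noise switch the three stochastic components off for
#'   noiseless phantoms.
#' @param scanId scan identifier.
#' @return A \linkS4class{BScan} with the layout recorded in its label slot
#'   and the noise level as its noise reference.
#' @examples
#' b <- simulateBScan(layoutHomogeneous(100, "Tumor"), seed = 42)
#' b
#' @export
simulateBScan <- function(layout, tissue = tissueModel(), depth = 256L,
                          pitch = 0.0075, seed = NULL, speckle = TRUE,
                          texture = TRUE, noise = TRUE, scanId = "sim") {
  layout <- as.character(layout)
  w <- length(layout)
  .withSeed(seed, {
    Tf <- if (texture) .textureField(layout, tissue$sigmaTex, depth)
          else matrix(1, depth, w)
    mu <- tissue$muS[layout]
    rows0 <- seq_len(depth) - 1L
    meanI <- tissue$i0 *
             exp(outer(-2 * pitch * rows0, mu)) * Tf
    I <- if (speckle) meanI * matrix(stats::rexp(depth * w), depth, w)
         else meanI
    if (noise && tissue$noiseLevel > 0)
      I <- I + tissue$noiseLevel * matrix(stats::rexp(depth * w), depth, w)
    BScan(I, axialPitch = pitch, scanId = scanId,
          noiseReference = if (noise && tissue$noiseLevel > 0)
            tissue$noiseLevel else numeric(0),
          label = layout)
  })
}

## deterministic largest-remainder allocation of n into weighted bins
.allocate <- function(n, weights) {
  if (abs(sum(weights) - 1) > 1e-9 && sum(weights) != n)
    stop("mix must sum to 1 (fractions) or to the scan count")
  w <- weights / sum(weights)
  raw <- n * w
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  stats::setNames(as.integer(cnt), names(weights))
}

#' Simulate a reproducible cohort of B-scans
#'
#' Draws \code{n} scans with a deterministic pattern/class allocation
#' (largest-remainder, so the requested mix is hit exactly), simulates each
#' with a per-scan seed derived from \code{seed}, and optionally writes the
#' dataset directory (float TIFF + JSON sidecar per scan plus a
#' \code{manifest.csv}). Re-running with the same seed reproduces the
#' manifest byte-identically.
#'
#' @param n number of scans.
#' @param classMix named fractions (or counts summing to the homogeneous scan
#'   count) over the tissue classes for homogeneous scans; default an even
#'   WM/tumor-style split \code{c(Normal = 0.5, Tumor = 0.5)}.
#' @param patternMix named fractions over
#'   \code{c(homogeneous, infiltration, scattered_fp)}; default all
#'   homogeneous.
#' @param width A-scans per scan (default 400).
#' @param depth depth pixels (default 256).
#' @param tissue a \code{\link{tissueModel}}.
#' @param seed cohort seed (required for reproducibility).
#' @param dir optional output directory for the oct-io dataset layout.
#' @return list with \code{scans} (list of \linkS4class{BScan}) and
#'   \code{manifest} (data.frame: scan_id, pattern, scan_truth, width,
#'   and file paths when written).
#' @export
simulateCohort <- function(n, classMix = c(Normal = 0.5, Tumor = 0.5),
                           patternMix = c(homogeneous = 1),
                           width = 400L, depth = 256L,
                           tissue = tissueModel(), seed = 1L, dir = NULL) {
  patterns <- c("homogeneous", "infiltration", "scattered_fp")
  pm <- stats::setNames(rep(0, 3), patterns)
  pm[names(patternMix)] <- patternMix
  pcnt <- .allocate(n, pm)
  cm <- stats::setNames(rep(0, 3), tissueClasses())
  cm[names(classMix)] <- classMix
  ccnt <- .allocate(pcnt["homogeneous"], cm)
  blockWidth <- 20L
  nb <- width %/% blockWidth
  layouts <- .withSeed(seed, {
    c(
      unlist(lapply(tissueClasses(), function(cl)
        replicate(ccnt[cl], layoutHomogeneous(width, cl),
                  simplify = FALSE)), recursive = FALSE),
      replicate(pcnt["infiltration"], {
        lenMax <- min(8L * blockWidth, width)
        lenMin <- min(3L * blockWidth, lenMax)
        len <- if (lenMin == lenMax) lenMin else sample(seq(lenMin, lenMax), 1)
        start <- sample.int(width - len + 1L, 1) - 1L
        layoutInfiltration(width, start, len)
      }, simplify = FALSE),
      replicate(pcnt["scattered_fp"], {
        k <- sample(1:2, 1)
        repeat {
          idx <- sort(sample.int(nb, k) - 1L)
          if (k == 1 || all(diff(idx) >= 2)) break
        }
        layoutScattered(width, idx, blockWidth)
      }, simplify = FALSE)
    )
  })
  ids <- sprintf("scan%03d", seq_along(layouts))
  scans <- lapply(seq_along(layouts), function(i)
    simulateBScan(layouts[[i]], tissue = tissue, depth = depth,
                  seed = (seed * 1009L + i) %% .Machine$integer.max,
                  scanId = ids[i]))
  manifest <- data.frame(
    scan_id = ids,
    pattern = vapply(layouts, attr, character(1), "pattern"),
    scan_truth = vapply(layouts, attr, character(1), "scan_truth"),
    width = width, depth = depth, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$file <- file.path(dir, paste0(ids, ".tif"))
    manifest$sidecar <- file.path(dir, paste0(ids, ".json"))
    for (i in seq_along(scans))
      writeBScan(scans[[i]], manifest$file[i], manifest$sidecar[i])
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(scans = scans, manifest = manifest)
}

#' Simulate a forced-choice reader panel
#'
#' Each reader calls each scan by their scan-level sensitivity (probability of
#' calling a tumor scan Tumor) and specificity (probability of calling a WM
#' scan WM); a call is always made (forced choice).
#' \code{correlation = "unanimous"} draws one call vector per scan using the
#' first reader's rates and gives it to every reader — a panel whose
#' disagreement is entirely scan-driven, the regime where scan-level
#' bootstrap variance follows the single-observer binomial form.
#'
#' @param truth per-scan ground truth ("WM"/"Tumor").
#' @param readers data.frame with columns \code{reader_id},
#'   \code{sensitivity}, \code{specificity} (rates in [0, 1]).
#' @param seed RNG seed.
#' @param correlation \code{"independent"} (default) or \code{"unanimous"}.
#' @return An \linkS4class{AssessmentSet}.
#' @examples
#' rd <- data.frame(reader_id = paste0("r", 1:5),
#'                  sensitivity = 0.74, specificity = 0.85)
#' simulateReaderPanel(rep(c("Tumor", "WM"), c(42, 44)), rd, seed = 3)
#' @export
simulateReaderPanel <- function(truth, readers, seed = NULL,
                                correlation = c("independent", "unanimous")) {
  correlation <- match.arg(correlation)
  stopifnot(nrow(readers) >= 1,
            all(readers$sensitivity >= 0 & readers$sensitivity <= 1),
            all(readers$specificity >= 0 & readers$specificity <= 1))
  n <- length(truth); r <- nrow(readers)
  .withSeed(seed, {
    drawOne <- function(sens, spec) {
      pTumor <- ifelse(truth == "Tumor", sens, 1 - spec)
      ifelse(stats::runif(n) < pTumor, "Tumor", "WM")
    }
    calls <- if (correlation == "unanimous") {
      matrix(drawOne(readers$sensitivity[1], readers$specificity[1]), n, r)
    } else {
      vapply(seq_len(r), function(j)
        drawOne(readers$sensitivity[j], readers$specificity[j]),
        character(n))
    }
    AssessmentSet(matrix(calls, n, r), truth = truth,
                  readerIds = as.character(readers$reader_id))
  })
}

#' Synthetic segmentation maps of the false-positive archetypes
#'
#' Builds tumor-free scans' segmentation maps carrying algorithmic false
#' positives in the two spatial families seen in human-in-the-loop review:
#' \emph{scattered} — one or two isolated single Red blocks, each flanked by
#' Green (the non-anatomical noise pattern a reader overrides) — and
#' \emph{clustered} — one contiguous Red run of 5--8 blocks with
#' damaged-matter margins (the morphologically plausible pattern that fools
#' the reader). Positions and run lengths are randomised per map.
#'
#' @param nScattered,nClustered number of maps per family.
#' @param nBlocks blocks per map (default 20, a 400-A-scan scan).
#' @param seed RNG seed.
#' @return list with \code{segmaps} (list of \linkS4class{SegmentationMap}),
#'   \code{truth} (all "WM") and \code{family}.
#' @export
simulateFalsePositiveMaps <- function(nScattered = 9L, nClustered = 4L,
                                      nBlocks = 20L, seed = NULL) {
  .withSeed(seed, {
    scattered <- replicate(nScattered, {
      k <- sample(1:2, 1)
      repeat {
        ## interior positions so every singleton has Green on both sides
        idx <- sort(sample(2:(nBlocks - 1L), k))
        if (k == 1 || all(diff(idx) >= 2)) break
      }
      lab <- rep("Normal", nBlocks)
      lab[idx] <- "Tumor"
      lab
    }, simplify = FALSE)
    clustered <- replicate(nClustered, {
      len <- sample(5:8, 1)
      start <- sample.int(nBlocks - len - 1L, 1) + 1L   # keep room for margins
      lab <- rep("Normal", nBlocks)
      lab[max(1L, start - 1L):min(nBlocks, start + len)] <- "DamagedMatter"
      lab[start:(start + len - 1L)] <- "Tumor"
      lab
    }, simplify = FALSE)
    labs <- c(scattered, clustered)
    fam <- rep(c("scattered", "clustered"), c(nScattered, nClustered))
    segmaps <- lapply(seq_along(labs), function(i)
      SegmentationMap(sprintf("fp%02d", i), labs[[i]]))
    list(segmaps = segmaps, truth = rep("WM", length(labs)), family = fam)
  })
}

#' Synthetic archetype cohort of segmentation maps
#'
#' The scan-level outcome taxonomy in one cohort: true-tumor maps (dense Red
#' runs with damaged-matter margins), clean all-Green WM maps, and the two
#' false-positive families of \code{\link{simulateFalsePositiveMaps}}. Used
#' to measure what the contextual filter changes relative to the naive
#' any-Red machine rule.
#'
#' @param nTumor,nClean,nScattered,nClustered scans per family.
#' @param nBlocks blocks per map.
#' @param seed RNG seed.
#' @return list with \code{segmaps}, \code{truth} and \code{family}.
#' @export
simulateArchetypeCohort <- function(nTumor = 20L, nClean = 31L,
                                    nScattered = 9L, nClustered = 4L,
                                    nBlocks = 20L, seed = NULL) {
  .withSeed(seed, {
    tumor <- replicate(nTumor, {
      len <- sample(8:14, 1)
      start <- sample.int(nBlocks - len + 1L, 1)
      lab <- rep("Normal", nBlocks)
      lab[max(1L, start - 1L):min(nBlocks, start + len)] <- "DamagedMatter"
      lab[start:(start + len - 1L)] <- "Tumor"
      lab
    }, simplify = FALSE)
    clean <- replicate(nClean, rep("Normal", nBlocks), simplify = FALSE)
    fp <- simulateFalsePositiveMaps(nScattered, nClustered, nBlocks)
    labs <- c(tumor, clean)
    segmaps <- c(
      lapply(seq_along(labs), function(i)
        SegmentationMap(sprintf("arch%02d", i), labs[[i]])),
      fp$segmaps)
    list(segmaps = segmaps,
         truth = c(rep("Tumor", nTumor), rep("WM", nClean), fp$truth),
         family = c(rep("tumor", nTumor), rep("clean", nClean), fp$family))
  })
}
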