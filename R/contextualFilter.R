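#' Configuration of the contextual override filter
#'
#' The filter is a deterministic model of the contextual reasoning a trained
#' reader applies to a segmentation map before making the scan-level call:
#' rare, scattered red stripes surrounded by green are algorithmic noise;
#' dense contiguous red clusters — especially ones adjoining damaged-matter
#' yellow, as at an infiltration margin — are real; and positive evidence
#' confined to a shallow sliver of the depth range is weaker than evidence
#' spanning the B-scan vertically. All quantifications are engineering
#' defaults (the underlying heuristics are qualitative) and every one is
#' exposed here.
#'
#' @param minRun minimum contiguous Red-block run length treated as real;
#'   shorter runs flanked by Green on both sides are suppressed (default 2).
#' @param densityLow,densityHigh Red-block fraction mapped to the base
#'   probability: <= low gives 0.1, >= high gives 0.9, linear in between
#'   (defaults 0.10, 0.30).
#' @param neighborWeight multiplier (>= 1) applied when surviving Red blocks
#'   adjoin Yellow blocks (default 1.5).
#' @param depthFraction minimum fraction of the scan depth that positive
#'   evidence must span to avoid attenuation (default 0.5).
#' @param decisionThreshold probability cutoff; the call is Tumor only when
#'   the probability strictly exceeds it (default 0.5).
#' @return validated configuration list of class \code{"FilterConfig"}.
#' @examples
#' cfg <- filterConfig()
#' cfg$minRun
#' @export
filterConfig <- function(minRun = 2L, densityLow = 0.10, densityHigh = 0.30,
                         neighborWeight = 1.5, depthFraction = 0.5,
                         decisionThreshold = 0.5) {
  stopifnot(minRun >= 1, densityLow < densityHigh,
            densityLow >= 0, densityHigh <= 1,
            neighborWeight >= 1, depthFraction > 0, depthFraction <= 1,
            decisionThreshold >= 0, decisionThreshold <= 1)
  structure(list(minRun = as.integer(minRun), densityLow = densityLow,
                 densityHigh = densityHigh, neighborWeight = neighborWeight,
                 depthFraction = depthFraction,
                 decisionThreshold = decisionThreshold),
            class = "FilterConfig")
}

#' Scan-level tumor probability from a segmentation map
#'
#' Converts per-block tissue labels into a continuous tumor probability and a
#' binary call by four deterministic rules applied in order:
#' \enumerate{
#'   \item \emph{scattered-noise suppression}: Red runs shorter than
#'     \code{minRun} whose both flanks are Green (the map boundary counts as
#'     Green) are removed from the evidence;
#'   \item \emph{density}: the surviving Red fraction is mapped through the
#'     density thresholds to a base probability (0.1 below, 0.9 above, linear
#'     between);
#'   \item \emph{margin context}: if any surviving Red block adjoins a Yellow
#'     block the probability is multiplied by \code{neighborWeight};
#'   \item \emph{depth extent}: if the deepest valid-signal extent among
#'     surviving Red blocks falls short of \code{depthFraction} of the scan
#'     depth, the probability is multiplied by \code{extent/depthFraction}.
#' }
#' The result is clipped to [0, 1]; the call is Tumor only when the
#' probability strictly exceeds the decision threshold (a probability of
#' exactly 0.5 at the default threshold is called WM). The function is pure:
#' identical inputs give identical verdicts and evidence traces.
#'
#' @param segmap a \linkS4class{SegmentationMap} (labels complete; NA blocks
#'   are treated as uninformative, neither Red nor Green).
#' @param depthExtent per-block valid-signal depth extent in [0, 1] (see
#'   \code{\link{blockDepthExtent}}); default 1 (full depth) for every block.
#' @param config a \code{\link{filterConfig}}.
#' @return list of class \code{"ScanVerdict"}: \code{scan_id},
#'   \code{tumor_probability}, \code{call}, and an \code{evidence} trace
#'   (runs with suppression flags, raw and effective red fraction, yellow
#'   adjacency, depth extent, fired rules).
#' @examples
#' m <- SegmentationMap("s1", rep(c("Normal", "Tumor"), c(14, 6)))
#' scoreScan(m)$call
#' @export
scoreScan <- function(segmap, depthExtent = NULL, config = filterConfig()) {
  lab <- as.character(blockLabels(segmap))
  n <- length(lab)
  if (n == 0) stop("empty segmentation map")
  if (is.null(depthExtent)) depthExtent <- rep(1, n)
  if (length(depthExtent) != n)
    stop("one depth extent per block required")
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  isRed <- !is.na(r$values) & r$values == "Tumor"
  ## a flank beyond the map boundary counts as Green
  flank <- function(i) if (i < 1 || i > length(r$values)) "Normal"
                       else r$values[i]
  suppressed <- logical(length(r$values))
  for (i in which(isRed)) {
    if (r$lengths[i] < config$minRun &&
        identical(flank(i - 1L), "Normal") &&
        identical(flank(i + 1L), "Normal"))
      suppressed[i] <- TRUE
  }
  surviving <- rep(FALSE, n)
  for (i in which(isRed & !suppressed))
    surviving[starts[i]:ends[i]] <- TRUE

  rawFrac <- sum(lab == "Tumor", na.rm = TRUE) / n
  frac <- sum(surviving) / n
  base <- if (frac <= config$densityLow) 0.1
          else if (frac >= config$densityHigh) 0.9
          else 0.1 + (frac - config$densityLow) /
                     (config$densityHigh - config$densityLow) * 0.8
  p <- base
  fired <- character(0)
  if (any(suppressed)) fired <- c(fired, "scattered_suppression")

  yellowAdj <- FALSE
  if (any(surviving)) {
    idx <- which(surviving)
    nb <- unique(c(idx - 1L, idx + 1L))
    nb <- nb[nb >= 1L & nb <= n]
    yellowAdj <- any(lab[nb] == "DamagedMatter", na.rm = TRUE)
    if (yellowAdj) {
      p <- p * config$neighborWeight
      fired <- c(fired, "yellow_adjacency")
    }
    extent <- max(depthExtent[surviving])
    if (extent < config$depthFraction) {
      p <- p * extent / config$depthFraction
      fired <- c(fired, "shallow_attenuation")
    }
  } else extent <- NA_real_

  p <- min(max(p, 0), 1)
  structure(list(
    scan_id = scanId(segmap),
    tumor_probability = p,
    call = if (p > config$decisionThreshold) "Tumor" else "WM",
    evidence = list(
      runs = data.frame(value = r$values, start = starts - 1L,
                        length = r$lengths,
                        suppressed = suppressed, stringsAsFactors = FALSE),
      red_fraction_raw = rawFrac,
      red_fraction_effective = frac,
      base_probability = base,
      yellow_adjacent = yellowAdj,
      depth_extent = extent,
      fired = fired
    )
  ), class = "ScanVerdict")
}

#' Filter a cohort of segmentation maps and tally overrides
#'
#' Applies \code{\link{scoreScan}} to every map and compares each call with
#' the naive machine rule "any Red block implies Tumor". A scan where the
#' naive rule says Tumor but the filter says WM is an \emph{override}. When
#' ground truth is supplied, the override ledger additionally splits the
#' algorithmic false positives (truth WM, naive Tumor) into overridden vs
#' confirmed — the human-in-the-loop outcome taxonomy.
#'
#' @param segmaps list of \linkS4class{SegmentationMap}.
#' @param config a \code{\link{filterConfig}}.
#' @param depthExtents optional list of per-block depth extents aligned with
#'   \code{segmaps}.
#' @param truth optional per-scan ground truth ("WM"/"Tumor").
#' @return data.frame with one row per scan (\code{scan_id, probability,
#'   call, naive_call, overridden, fired_rules}, plus \code{truth} when
#'   given), with an attribute \code{"overrides"} summarising the ledger:
#'   counts of overridden and confirmed scans and, given truth, the same
#'   restricted to algorithmic false positives plus the override rate.
#' @export
batchVerdicts <- function(segmaps, config = filterConfig(),
                          depthExtents = NULL, truth = NULL) {
  verdicts <- lapply(seq_along(segmaps), function(i) {
    scoreScan(segmaps[[i]],
              depthExtent = if (is.null(depthExtents)) NULL
                            else depthExtents[[i]],
              config = config)
  })
  naive <- vapply(segmaps, function(m) {
    if (any(blockLabels(m) == "Tumor", na.rm = TRUE)) "Tumor" else "WM"
  }, character(1))
  df <- data.frame(
    scan_id = vapply(verdicts, `[[`, character(1), "scan_id"),
    probability = vapply(verdicts, `[[`, numeric(1), "tumor_probability"),
    call = vapply(verdicts, `[[`, character(1), "call"),
    naive_call = naive,
    stringsAsFactors = FALSE)
  df$overridden <- df$naive_call == "Tumor" & df$call == "WM"
  df$fired_rules <- vapply(verdicts, function(v)
    paste(v$evidence$fired, collapse = ";"), character(1))
  ledger <- list(n_overridden = sum(df$overridden),
                 n_disagreements = sum(df$call != df$naive_call))
  if (!is.null(truth)) {
    df$truth <- truth
    fp <- truth == "WM" & df$naive_call == "Tumor"
    ledger$n_false_positive <- sum(fp)
    ledger$n_fp_overridden <- sum(fp & df$overridden)
    ledger$n_fp_confirmed <- sum(fp & !df$overridden)
    ledger$override_rate <- if (sum(fp)) sum(fp & df$overridden) / sum(fp)
                            else NA_real_
  }
  attr(df, "overrides") <- ledger
  df
}

#' @export
print.ScanVerdict <- function(x, ...) {
  cat(sprintf("ScanVerdict '%s': P(tumor) = %.3f -> %s [%s]\n",
              x$scan_id, x$tumor_probability, x$call,
              if (length(x$evidence$fired))
                paste(x$evidence$fired, collapse = ", ") else "no rules fired"))
  invisible(x)
}

#' Write scan verdicts as CSV
#' @param verdicts data.frame from \code{\link{batchVerdicts}}.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeVerdicts <- function(verdicts, path) {
  utils::write.csv(verdicts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
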