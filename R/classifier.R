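## Feature scaler: per-feature mean and population standard deviation
## (ddof = 0, the standardization convention of StandardScaler-style
## preprocessing; also makes the scaler exactly invariant to duplicating the
## training set).
.fitScaler <- function(x) {
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))
  zero <- which(scl == 0 | !is.finite(scl))
  if (length(zero))
    stop("degenerate zero-variance feature: ",
         paste(colnames(x)[zero], collapse = ", "))
  list(center = ctr, scale = scl)
}

.applyScaler <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

.featureMatrix <- function(blocks) {
  x <- as.matrix(blocks[, c("mean_oac", "mean_rsc")])
  colnames(x) <- c("mean_oac", "mean_rsc")
  x
}

#' Train the standardized linear one-vs-rest tissue SVM
#'
#' Fits the two-feature (mean OAC, mean RSC) classifier used to segment
#' B-scans: features are standardized to zero mean and unit variance on the
#' training blocks, then one linear-kernel support vector machine is fitted
#' per tissue class against the rest (a true one-vs-rest scheme). Training is
#' deterministic given the same blocks and configuration. Blocks flagged
#' invalid are excluded.
#'
#' @param blocks labelled feature blocks from \code{\link{extractBlocks}}
#'   (columns \code{mean_oac, mean_rsc, label}, optionally \code{valid}).
#' @param cost SVM regularization constant C (default 1).
#' @param seed recorded in the manifest for provenance (the fit itself is
#'   deterministic).
#' @param ... further solver arguments passed to \code{\link[e1071]{svm}}
#'   (e.g. \code{tolerance}).
#' @return A \linkS4class{TissueSVM}.
#' @examples
#' blocks <- data.frame(mean_oac = c(rnorm(20, 1), rnorm(20, 4)),
#'                      mean_rsc = c(rnorm(20, 0.1), rnorm(20, 0.6)),
#'                      label = rep(c("Normal", "Tumor"), each = 20))
#' trainTissueSVM(blocks)
#' @export
trainTissueSVM <- function(blocks, cost = 1, seed = NULL, ...) {
  if ("valid" %in% names(blocks)) blocks <- blocks[blocks$valid, , drop = FALSE]
  lab <- as.character(blocks$label)
  if (anyNA(lab)) stop("all training blocks must be labelled")
  classes <- intersect(tissueClasses(), unique(lab))
  if (length(classes) < 2) stop("at least two tissue classes required")
  if (any(table(lab) < 2)) stop("at least two blocks per class required")
  x <- .featureMatrix(blocks)
  sc <- .fitScaler(x)
  xs <- .applyScaler(x, sc$center, sc$scale)
  W <- matrix(0, length(classes), 2,
              dimnames = list(classes, colnames(x)))
  b <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    y <- factor(ifelse(lab == cl, cl, ".rest"), levels = c(cl, ".rest"))
    fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE,
                      ...)
    ## decision value = x %*% w - rho; libsvm orients the sign to whichever
    ## label it saw first in the data (fit$labels), so flip when that is not
    ## the target class
    w <- drop(t(fit$SV) %*% fit$coefs)
    rho <- fit$rho
    if (fit$labels[1] != 1L) { w <- -w; rho <- -rho }
    W[cl, ] <- w
    b[cl] <- -rho
  }
  new("TissueSVM", classes = classes, center = sc$center, scale = sc$scale,
      weights = W, intercepts = b, cost = cost,
      manifest = list(scan_ids = sort(unique(as.character(blocks$scan_id))),
                      n_blocks = nrow(blocks), cost = cost,
                      seed = if (is.null(seed)) NA_integer_ else seed))
}

#' Per-class one-vs-rest decision scores
#'
#' @param model a \linkS4class{TissueSVM}.
#' @param blocks feature blocks (or a 2-column feature matrix).
#' @return numeric matrix, one row per block, one column per class; positive
#'   score = the class side of that class's margin.
#' @export
decisionScores <- function(model, blocks) {
  x <- if (is.matrix(blocks)) blocks else .featureMatrix(blocks)
  if (ncol(x) != 2) stop("feature dimensionality mismatch: expected 2 features")
  xs <- .applyScaler(x, model@center, model@scale)
  xs %*% t(model@weights) +
    matrix(model@intercepts, nrow(x), length(model@classes), byrow = TRUE)
}

## argmax with deterministic tie-break by canonical class order
.predictFromScores <- function(scores) {
  cls <- colnames(scores)
  factor(cls[max.col(scores, ties.method = "first")], levels = tissueClasses())
}

#' Grouped leave-one-out cross-validation
#'
#' For each held-out group (a scan by default, so that blocks from one scan
#' never appear on both sides of a fold), the feature scaler and the
#' one-vs-rest SVMs are refitted from scratch on the remaining groups only;
#' the held-out blocks are then scored by that fold's model. Scaling is
#' strictly fold-contained: no statistic of the held-out data leaks into the
#' fit. \code{grouping = "per_block"} gives classical LOOCV with one fold per
#' block.
#'
#' @param blocks labelled feature blocks.
#' @param grouping \code{"per_scan"} (default) or \code{"per_block"}.
#' @param cost SVM regularization constant.
#' @return data.frame aligned with the (valid) input blocks: original columns
#'   plus \code{fold}, \code{predicted} and one \code{score_<class>} column
#'   per class. Attribute \code{"folds"} gives the fold count.
#' @export
loocvPredict <- function(blocks, grouping = c("per_scan", "per_block"),
                         cost = 1) {
  grouping <- match.arg(grouping)
  if ("valid" %in% names(blocks)) blocks <- blocks[blocks$valid, , drop = FALSE]
  lab <- as.character(blocks$label)
  classes <- intersect(tissueClasses(), unique(lab))
  grp <- if (grouping == "per_scan") as.character(blocks$scan_id)
         else as.character(seq_len(nrow(blocks)))
  groups <- unique(grp)
  if (length(groups) < 3) stop("at least 3 groups required for LOOCV")
  scores <- matrix(NA_real_, nrow(blocks), length(classes),
                   dimnames = list(NULL, classes))
  fold <- match(grp, groups)
  for (g in groups) {
    hold <- grp == g
    trainLab <- lab[!hold]
    if (!setequal(unique(trainLab), classes))
      stop("fold holding out group '", g,
           "' loses a class from the training remainder")
    m <- trainTissueSVM(blocks[!hold, , drop = FALSE], cost = cost)
    scores[hold, ] <- decisionScores(m, blocks[hold, , drop = FALSE])
  }
  out <- blocks
  out$fold <- fold
  out$predicted <- .predictFromScores(scores)
  for (cl in classes) out[[paste0("score_", cl)]] <- scores[, cl]
  attr(out, "folds") <- length(groups)
  out
}

#' Binary ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (ties grouped),
#' accumulating true/false positive rates, and integrates by the trapezoidal
#' rule — equivalent to concordant-pair counting with half credit for tied
#' scores.
#'
#' @param scores numeric decision scores (larger = more positive).
#' @param positive logical vector, TRUE for the positive class.
#' @return list with \code{fpr}, \code{tpr}, \code{thresholds} and \code{auc}.
#' @export
rocCurve <- function(scores, positive) {
  positive <- as.logical(positive)
  P <- sum(positive); N <- sum(!positive)
  if (P == 0 || N == 0)
    stop("ROC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- positive[o]
  last <- which(!duplicated(s, fromLast = TRUE))   # last index of each tie group
  tpr <- c(0, cumsum(y)[last] / P)
  fpr <- c(0, cumsum(!y)[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' One-vs-rest ROC/AUC for the multi-class LOOCV output
#'
#' One ROC curve per tissue class using that class's own decision score
#' against all other classes, plus the binary tumor-vs-rest curve (the
#' clinically decisive task) built from the Tumor score.
#'
#' @param scores blocks x classes decision-score matrix (e.g. the
#'   \code{score_*} columns of \code{\link{loocvPredict}}).
#' @param labels true classes aligned with the score rows.
#' @return list with per-class elements (each a \code{\link{rocCurve}}
#'   result), \code{auc} (named vector) and \code{tumor_vs_rest}.
#' @export
multiclassROC <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("AUC undefined for single-class labels")
  cls <- colnames(scores)
  curves <- lapply(cls, function(cl) rocCurve(scores[, cl], labels == cl))
  names(curves) <- cls
  tumor <- rocCurve(scores[, "Tumor"], labels == "Tumor")
  list(curves = curves,
       auc = vapply(curves, `[[`, numeric(1), "auc"),
       tumor_vs_rest = tumor)
}

#' Segment a scan with a trained model
#'
#' Extracts feature blocks from the parametric maps and assigns each block the
#' argmax tissue class of its decision scores. Invalid blocks (insufficient
#' valid signal in the ROI) get an \code{NA} label and \code{NA} scores.
#'
#' @param maps a \linkS4class{ParametricMaps}.
#' @param model a \linkS4class{TissueSVM}.
#' @param blockWidth,depthRoi,minValidFrac see \code{\link{extractBlocks}}.
#' @return A \linkS4class{SegmentationMap}.
#' @export
segmentScan <- function(maps, model, blockWidth = 20L,
                        depthRoi = c(20L, 40L), minValidFrac = 0.5) {
  blocks <- extractBlocks(maps, blockWidth = blockWidth, depthRoi = depthRoi,
                          minValidFrac = minValidFrac)
  scores <- matrix(NA_real_, nrow(blocks), length(model@classes),
                   dimnames = list(NULL, model@classes))
  if (any(blocks$valid))
    scores[blocks$valid, ] <-
      decisionScores(model, blocks[blocks$valid, , drop = FALSE])
  labels <- factor(rep(NA_character_, nrow(blocks)), levels = tissueClasses())
  labels[blocks$valid] <-
    .predictFromScores(scores[blocks$valid, , drop = FALSE])
  new("SegmentationMap", scanId = maps@scanId, labels = labels,
      scores = scores, blockWidth = as.integer(blockWidth),
      modelId = sprintf("tissueSVM-C%g-n%d", model@cost,
                        model@manifest$n_blocks))
}

#' Render a segmentation map over its structural scan
#'
#' Produces an RGB image of the B-scan in log-scaled grayscale with each
#' block's 20-column stripe tinted green (Normal), yellow (DamagedMatter) or
#' red (Tumor); invalid blocks get a neutral gray stripe. A class-colour
#' legend strip can be appended at the right edge; it is suppressed by
#' default so the map itself fills the frame.
#'
#' @param segmap a \linkS4class{SegmentationMap}.
#' @param scan the source \linkS4class{BScan}.
#' @param path optional PNG output path.
#' @param alpha tint strength in [0, 1].
#' @param colorbar append a legend strip (default FALSE).
#' @param dynamicRangeDb display dynamic range for the grayscale background.
#' @return invisibly, the H x W x 3 RGB array.
#' @export
renderSegmentation <- function(segmap, scan, path = NULL, alpha = 0.45,
                               colorbar = FALSE, dynamicRangeDb = 40) {
  I <- scan@intensity
  d <- 10 * log10(pmax(I, .Machine$double.xmin) / max(I, .Machine$double.xmin))
  g <- pmin(pmax((d + dynamicRangeDb) / dynamicRangeDb, 0), 1)
  rgb <- array(rep(g, 3), dim = c(nrow(I), ncol(I), 3))
  cols <- grDevices::col2rgb(tissueColors()) / 255
  w <- segmap@blockWidth
  for (b in seq_along(segmap@labels)) {
    colRange <- ((b - 1L) * w + 1L):min(b * w, ncol(I))
    lab <- as.character(segmap@labels[b])
    tint <- if (is.na(lab)) c(0.5, 0.5, 0.5) else cols[, lab]
    for (ch in 1:3)
      rgb[, colRange, ch] <- (1 - alpha) * rgb[, colRange, ch] +
                             alpha * tint[ch]
  }
  if (colorbar) {
    bar <- array(0, dim = c(nrow(I), 8L, 3L))
    seg <- split(seq_len(nrow(I)),
                 cut(seq_len(nrow(I)), 3L, labels = FALSE))
    for (k in 1:3) for (ch in 1:3) bar[seg[[k]], , ch] <- cols[ch, k]
    rgb2 <- array(0, dim = dim(rgb) + c(0L, 8L, 0L))
    rgb2[, seq_len(ncol(I)), ] <- rgb
    rgb2[, ncol(I) + 1:8, ] <- bar
    rgb <- rgb2
  }
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}

#' Serialise / restore a trained model as a JSON manifest
#'
#' The manifest is human-readable and diffable: scaler statistics, per-class
#' weights and intercepts, the regularization constant and the training
#' provenance, at full double precision.
#'
#' @param model a \linkS4class{TissueSVM}.
#' @param path JSON path.
#' @return invisibly the path (write); a \linkS4class{TissueSVM} (read).
#' @export
writeModel <- function(model, path) {
  jsonlite::write_json(list(
    classes = model@classes,
    scaler = list(center = model@center, scale = model@scale),
    weights = apply(model@weights, 1L, identity, simplify = FALSE),
    intercepts = as.list(model@intercepts),
    cost = model@cost,
    manifest = model@manifest
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  W <- do.call(rbind, j$weights[j$classes])
  colnames(W) <- c("mean_oac", "mean_rsc")
  new("TissueSVM", classes = j$classes,
      center = stats::setNames(unlist(j$scaler$center), colnames(W)),
      scale = stats::setNames(unlist(j$scaler$scale), colnames(W)),
      weights = W,
      intercepts = stats::setNames(unlist(j$intercepts)[j$classes], j$classes),
      cost = j$cost, manifest = as.list(j$manifest))
}
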