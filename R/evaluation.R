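#' Pooled assessment-level confusion counts
#'
#' Every (scan, reader) assessment is counted once against the scan's ground
#' truth: tp = tumor scans called Tumor, tn = WM scans called WM, fp = WM
#' scans called Tumor, fn = tumor scans called WM, pooled over readers.
#'
#' @param assessments an \linkS4class{AssessmentSet}.
#' @return named integer vector \code{c(tp, tn, fp, fn)}.
#' @export
confusionCounts <- function(assessments) {
  truth <- matrix(assessments@truth, nrow(assessments@calls),
                  ncol(assessments@calls))
  calls <- assessments@calls
  c(tp = sum(truth == "Tumor" & calls == "Tumor"),
    tn = sum(truth == "WM" & calls == "WM"),
    fp = sum(truth == "WM" & calls == "Tumor"),
    fn = sum(truth == "Tumor" & calls == "WM"))
}

#' Sensitivity, specificity and global accuracy from confusion counts
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), accuracy =
#' (tp+tn)/total. Metrics with a zero denominator are flagged undefined
#' (\code{NA}), never reported as 0. Point estimates are returned both as
#' proportions (full precision) and as whole-percent values rounded half-up,
#' the convention of clinical performance tables.
#'
#' @param counts named vector/list with \code{tp, tn, fp, fn}, or an
#'   \linkS4class{AssessmentSet} (counted first).
#' @return data.frame with columns \code{metric}, \code{proportion},
#'   \code{percent}.
#' @examples
#' diagnosticMetrics(c(tp = 205, tn = 198, fp = 22, fn = 5))  # 98 / 90 / 94
#' @export
diagnosticMetrics <- function(counts) {
  if (is(counts, "AssessmentSet")) counts <- confusionCounts(counts)
  counts <- as.list(counts)
  with(counts, {
    sens <- if ((tp + fn) > 0) tp / (tp + fn) else NA_real_
    spec <- if ((tn + fp) > 0) tn / (tn + fp) else NA_real_
    tot <- tp + tn + fp + fn
    acc <- if (tot > 0) (tp + tn) / tot else NA_real_
    data.frame(metric = c("sensitivity", "specificity", "accuracy"),
               proportion = c(sens, spec, acc),
               percent = .percentHalfUp(c(sens, spec, acc)))
  })
}

#' Inter-rater consistency of a forced-choice reader panel
#'
#' \code{pairwise_agreement} (default) is the mean over scans of the fraction
#' of concordant reader pairs — the simplest reading of "degree of agreement
#' among the readers". \code{fleiss_kappa} is Fleiss' chance-corrected
#' multi-rater kappa over the two categories. Both are deterministic and
#' invariant under relabelling of readers and scans.
#'
#' @param assessments an \linkS4class{AssessmentSet} with at least 2 readers.
#' @param method \code{"pairwise_agreement"} or \code{"fleiss_kappa"}.
#' @return a single number: agreement in [0, 1], or kappa in [-1, 1].
#' @examples
#' a <- AssessmentSet(matrix("WM", 4, 5), truth = rep("WM", 4))
#' readerConsistency(a)   # unanimous panel -> 1
#' @export
readerConsistency <- function(assessments,
                              method = c("pairwise_agreement",
                                         "fleiss_kappa")) {
  method <- match.arg(method)
  calls <- assessments@calls
  r <- ncol(calls)
  if (r < 2) stop("consistency requires at least 2 readers")
  k <- rowSums(calls == "Tumor")      # Tumor calls per scan
  if (method == "pairwise_agreement") {
    conc <- choose(k, 2) + choose(r - k, 2)
    return(mean(conc / choose(r, 2)))
  }
  ## Fleiss' kappa, two categories
  n <- nrow(calls)
  nij <- cbind(Tumor = k, WM = r - k)
  Pi <- (rowSums(nij^2) - r) / (r * (r - 1))
  pj <- colSums(nij) / (n * r)
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  if (Pe == 1) return(1)  # degenerate: every call identical in one category
  (Pbar - Pe) / (1 - Pe)
}

## Named fast-path statistics for the bootstrap: functions of
## (calls matrix, truth vector) returning one number.
.panelStatistic <- function(statistic) {
  if (is.function(statistic)) return(statistic)
  switch(statistic,
    accuracy = function(calls, truth) mean(calls == truth),
    sensitivity = function(calls, truth) {
      pos <- truth == "Tumor"
      if (!any(pos)) return(NA_real_)
      mean(calls[pos, , drop = FALSE] == "Tumor")
    },
    specificity = function(calls, truth) {
      neg <- truth == "WM"
      if (!any(neg)) return(NA_real_)
      mean(calls[neg, , drop = FALSE] == "WM")
    },
    consistency = function(calls, truth) {
      r <- ncol(calls)
      k <- rowSums(calls == "Tumor")
      mean((choose(k, 2) + choose(r - k, 2)) / choose(r, 2))
    },
    stop("unknown statistic: ", statistic))
}

#' Scan-level percentile bootstrap confidence interval
#'
#' Resamples scans with replacement (keeping each resampled scan's complete
#' reader-call vector and truth, and maintaining the original scan count),
#' recomputes the statistic per iteration, and takes the empirical 2.5th and
#' 97.5th percentiles of the \code{B} replicates. Deterministic given
#' \code{seed}. \code{unit = "assessment"} resamples individual
#' (scan, reader) prediction pairs instead.
#'
#' Iterations where the statistic is undefined (e.g. a resample with no tumor
#' scans) are dropped from the percentiles; if more than half the iterations
#' are undefined the run errors with a diagnostic rather than returning a
#' misleading interval.
#'
#' @param assessments an \linkS4class{AssessmentSet}.
#' @param statistic \code{"accuracy"}, \code{"sensitivity"},
#'   \code{"specificity"}, \code{"consistency"}, or a
#'   \code{function(calls, truth)} returning one number.
#' @param B number of bootstrap iterations (default 10000).
#' @param seed RNG seed (mandatory for reproducible intervals).
#' @param unit \code{"scan"} (default) or \code{"assessment"}.
#' @param probs percentile pair, default \code{c(0.025, 0.975)}.
#' @return list: \code{estimate} (plug-in point estimate), \code{ci}
#'   (length-2 vector), \code{B}, \code{seed}, \code{n_undefined},
#'   \code{replicates} (the bootstrap distribution).
#' @examples
#' a <- AssessmentSet(matrix(rep(c("Tumor", "WM"), c(40, 46)), 86, 3),
#'                    truth = rep(c("Tumor", "WM"), c(40, 46)))
#' bootstrapCI(a, "accuracy", B = 200, seed = 7)$ci
#' @export
bootstrapCI <- function(assessments, statistic, B = 10000L, seed,
                        unit = c("scan", "assessment"),
                        probs = c(0.025, 0.975)) {
  unit <- match.arg(unit)
  stat <- .panelStatistic(statistic)
  calls <- assessments@calls
  truth <- assessments@truth
  n <- nrow(calls)
  estimate <- stat(calls, truth)
  reps <- .withSeed(seed, {
    vapply(seq_len(B), function(i) {
      if (unit == "scan") {
        idx <- sample.int(n, n, replace = TRUE)
        stat(calls[idx, , drop = FALSE], truth[idx])
      } else {
        flat <- as.vector(calls)
        tflat <- rep(truth, ncol(calls))
        idx <- sample.int(length(flat), length(flat), replace = TRUE)
        stat(matrix(flat[idx], ncol = 1L), tflat[idx])
      }
    }, numeric(1))
  })
  nUndef <- sum(is.na(reps))
  if (nUndef > B / 2)
    stop(sprintf(paste0("statistic undefined in %d of %d bootstrap ",
                        "iterations; the panel is too degenerate to ",
                        "bootstrap (e.g. too few positive scans)"),
                 nUndef, B))
  ci <- unname(stats::quantile(reps, probs, na.rm = TRUE))
  list(estimate = estimate, ci = ci, B = B, seed = seed,
       n_undefined = nUndef, replicates = reps)
}

#' Compare diagnostic reports across imaging modalities
#'
#' Tabulates point estimates and confidence intervals per metric for each
#' modality and flags, for every modality pair, whether the intervals
#' overlap — the significance criterion used in multi-reader comparisons of
#' this design. No additional hypothesis tests are invented.
#'
#' @param reports named list of data.frames, each with columns \code{metric},
#'   \code{estimate}, \code{lower}, \code{upper}.
#' @return list with \code{estimates} (long table) and \code{pairs} (one row
#'   per modality pair x metric with the difference and the overlap flag).
#' @examples
#' r <- list(
#'   A = data.frame(metric = "sensitivity", estimate = 98, lower = 92, upper = 100),
#'   B = data.frame(metric = "sensitivity", estimate = 86, lower = 74, upper = 95))
#' compareModalities(r)$pairs
#' @export
compareModalities <- function(reports) {
  if (length(reports) < 2) stop("at least two reports required")
  if (is.null(names(reports)))
    names(reports) <- paste0("modality", seq_along(reports))
  est <- do.call(rbind, lapply(names(reports), function(nm) {
    cbind(modality = nm, reports[[nm]], stringsAsFactors = FALSE)
  }))
  metrics <- unique(est$metric)
  cmb <- utils::combn(names(reports), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    do.call(rbind, lapply(metrics, function(m) {
      ra <- est[est$modality == a & est$metric == m, ]
      rb <- est[est$modality == b & est$metric == m, ]
      if (!nrow(ra) || !nrow(rb)) return(NULL)
      data.frame(metric = m, modality_a = a, modality_b = b,
                 difference = ra$estimate - rb$estimate,
                 ci_overlap = !(ra$upper < rb$lower || rb$upper < ra$lower),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(estimates = est, pairs = pairs)
}
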