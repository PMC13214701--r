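# Independent brute-force oracles used to verify the package's statistics.
# These deliberately use naive enumeration, never the code paths they check.

# AUC by exhaustive concordant-pair counting, half credit for tied scores.
oracleAUC <- function(scores, positive) {
  p <- scores[positive]
  n <- scores[!positive]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# Confusion counts and metrics by looping over every (scan, reader) cell.
oracleMetrics <- function(calls, truth) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(calls))) for (j in seq_len(ncol(calls))) {
    if (truth[i] == "Tumor") {
      if (calls[i, j] == "Tumor") tp <- tp + 1 else fn <- fn + 1
    } else {
      if (calls[i, j] == "WM") tn <- tn + 1 else fp <- fp + 1
    }
  }
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + tn + fp + fn))
}

# Mean pairwise agreement by looping over every reader pair on every scan.
oracleAgreement <- function(calls) {
  r <- ncol(calls)
  agree <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    conc <- 0; tot <- 0
    for (a in seq_len(r - 1)) for (b in (a + 1):r) {
      tot <- tot + 1
      if (calls[i, a] == calls[i, b]) conc <- conc + 1
    }
    agree[i] <- conc / tot
  }
  mean(agree)
}

# Random forced-choice panel.
randomPanel <- function(nScan, nReader, seed) {
  set.seed(seed)
  truth <- sample(c("WM", "Tumor"), nScan, replace = TRUE)
  if (length(unique(truth)) == 1) truth[1] <- setdiff(c("WM", "Tumor"), truth[1])
  calls <- matrix(sample(c("WM", "Tumor"), nScan * nReader, replace = TRUE),
                  nScan, nReader)
  AssessmentSet(calls, truth = truth)
}

# Constant-valued ParametricMaps for feature-extraction contracts.
constantMaps <- function(nr, nc, oac = 2, rsc = 0.3, scanId = "const") {
  new("ParametricMaps",
      oac = matrix(oac, nr, nc), rsc = matrix(rsc, nr, nc),
      validMask = matrix(TRUE, nr, nc), scanId = scanId, axialPitch = 0.0075)
}

# Noiseless exponential-decay phantom.
expPhantom <- function(mu, depth, width = 20, pitch = 0.0075, i0 = 1) {
  I <- i0 * matrix(exp(-2 * mu * pitch * (seq_len(depth) - 1)), depth, width)
  BScan(I, axialPitch = pitch, scanId = sprintf("phantom-mu%g", mu))
}

# Shared small training cohort for classifier tests (built once per run).
trainingBlocks <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- simulateCohort(9, classMix = c(Normal = 3, DamagedMatter = 3,
                                            Tumor = 3),
                            width = 200L, seed = 402L)
      cache <<- do.call(rbind, lapply(coh$scans, function(s)
        extractBlocks(computeParametricMaps(s), labels = scanLabel(s))))
    }
    cache
  }
})
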