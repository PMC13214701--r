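test_that("noiseless homogeneous scans reproduce the OAC closed form exactly", {
  s <- simulateBScan(layoutHomogeneous(60, "Normal"), seed = 1,
                     speckle = FALSE, texture = FALSE, noise = FALSE)
  oac <- computeOAC(s)
  D <- axialPitch(s); N <- nrow(intensity(s)); j <- 0:(N - 1)
  expected <- (1 - exp(-2 * 1 * D)) / (2 * D * (1 - exp(-2 * 1 * D * (N - j))))
  for (c in c(1, 30, 60))
    expect_lt(max(abs(oac[, c] / expected - 1)), 1e-9)
})

test_that("fully developed speckle has unit intensity coefficient of variation", {
  s <- simulateBScan(layoutHomogeneous(200, "Normal"), seed = 2,
                     texture = FALSE, noise = FALSE)
  I <- intensity(s)
  ## decay-compensate each row, then window CV should be ~1 (exponential law)
  D <- axialPitch(s)
  flat <- I / exp(-2 * 1 * D * (seq_len(nrow(I)) - 1))
  cvs <- c()
  for (r in seq(1, nrow(I) - 9, by = 10)) for (cc in seq(1, 181, by = 20)) {
    w <- flat[r:(r + 9), cc:(cc + 19)]
    cvs <- c(cvs, sd(w) / mean(w))
  }
  expect_lt(abs(mean(cvs) - 1), 0.1)
})

test_that("tumor exceeds normal in ROI-mean OAC and RSC across seed replicates", {
  reps <- 60
  deltaOac <- deltaRsc <- numeric(reps)
  for (i in seq_len(reps)) {
    bT <- extractBlocks(computeParametricMaps(
      simulateBScan(layoutHomogeneous(100, "Tumor"), seed = 2000 + i)))
    bN <- extractBlocks(computeParametricMaps(
      simulateBScan(layoutHomogeneous(100, "Normal"), seed = 6000 + i)))
    deltaOac[i] <- mean(bT$mean_oac) - mean(bN$mean_oac)
    deltaRsc[i] <- mean(bT$mean_rsc) - mean(bN$mean_rsc)
  }
  expect_gte(mean(deltaOac > 0), 0.99)
  expect_gte(mean(deltaRsc > 0), 0.95)
})

test_that("with speckle the ROI-mean OAC estimator stays within 5% of its target", {
  D <- 0.0075
  mus <- c(Normal = 1, DamagedMatter = 2, Tumor = 3.5)
  for (cl in names(mus)) {
    est <- vapply(1:200, function(i) {
      s <- simulateBScan(layoutHomogeneous(100, cl), seed = 3000 + i)
      mean(extractBlocks(computeParametricMaps(s))$mean_oac)
    }, numeric(1))
    target <- (1 - exp(-2 * mus[cl] * D)) / (2 * D)
    expect_lt(abs(mean(est) / target - 1), 0.05)
  }
})

test_that("widening the tumor-normal attenuation gap never hurts tumor AUC", {
  aucAt <- function(tumorMu, seedBase) {
    tm <- tissueModel(muS = c(Normal = 1, DamagedMatter = 2,
                              Tumor = tumorMu))
    coh <- simulateCohort(9, classMix = c(Normal = 3, DamagedMatter = 3,
                                          Tumor = 3),
                          width = 200L, tissue = tm, seed = seedBase)
    blocks <- do.call(rbind, lapply(coh$scans, function(s)
      extractBlocks(computeParametricMaps(s), labels = scanLabel(s))))
    cv <- loocvPredict(blocks)
    rocCurve(cv$score_Tumor, cv$label == "Tumor")$auc
  }
  aucs1 <- vapply(1:3, function(s) aucAt(2.25, 800 + s), numeric(1))
  aucs2 <- vapply(1:3, function(s) aucAt(3.5, 800 + s), numeric(1))
  expect_gte(mean(aucs2), mean(aucs1) - 0.02)
})

test_that("cohorts are seed-deterministic down to the written manifest", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  c1 <- simulateCohort(6, classMix = c(Normal = 0.5, Tumor = 0.5),
                       patternMix = c(homogeneous = 0.5, infiltration = 0.25,
                                      scattered_fp = 0.25),
                       width = 100L, seed = 5L, dir = dir1)
  c2 <- simulateCohort(6, classMix = c(Normal = 0.5, Tumor = 0.5),
                       patternMix = c(homogeneous = 0.5, infiltration = 0.25,
                                      scattered_fp = 0.25),
                       width = 100L, seed = 5L, dir = dir2)
  expect_identical(c1$manifest[names(c1$manifest) != "file" &
                               names(c1$manifest) != "sidecar"],
                   c2$manifest[names(c2$manifest) != "file" &
                               names(c2$manifest) != "sidecar"])
  m1 <- readLines(file.path(dir1, "manifest.csv"))
  m2 <- readLines(file.path(dir2, "manifest.csv"))
  expect_identical(gsub(dir1, "", m1, fixed = TRUE),
                   gsub(dir2, "", m2, fixed = TRUE))
  for (i in 1:6)
    expect_identical(intensity(c1$scans[[i]]), intensity(c2$scans[[i]]))
  ## the written dataset reads back through the oct-io layer
  b <- readBScan(c1$manifest$file[1], c1$manifest$sidecar[1])
  expect_lt(max(abs(intensity(b) - intensity(c1$scans[[1]]))) /
            max(intensity(c1$scans[[1]])), 1e-7)
  expect_identical(scanLabel(b), scanLabel(c1$scans[[1]]))
})

test_that("cohort mixes are honoured exactly", {
  c86 <- simulateCohort(86, classMix = c(Normal = 44, Tumor = 42),
                        width = 40L, seed = 3L)
  expect_equal(sum(c86$manifest$scan_truth == "WM"), 44L)
  expect_equal(sum(c86$manifest$scan_truth == "Tumor"), 42L)
  c23 <- simulateCohort(23, classMix = c(Normal = 8, DamagedMatter = 7,
                                         Tumor = 8), seed = 4L)
  blocks <- extractBlocks(lapply(c23$scans, computeParametricMaps))
  expect_equal(nrow(blocks), 460L)
})

test_that("reader panels realise the configured operating points", {
  truth <- rep(c("Tumor", "WM"), c(42, 44))
  perfect <- data.frame(reader_id = paste0("r", 1:5), sensitivity = 1,
                        specificity = 1)
  expect_equal(confusionCounts(simulateReaderPanel(truth, perfect, seed = 1)),
               c(tp = 210L, tn = 220L, fp = 0L, fn = 0L))
  alwaysT <- data.frame(reader_id = "r1", sensitivity = 1, specificity = 0)
  m <- diagnosticMetrics(confusionCounts(
    simulateReaderPanel(truth, alwaysT, seed = 2)))
  expect_equal(m$proportion[1:2], c(1, 0))
  ## structural-arm operating point concentrates over seeds
  rd <- data.frame(reader_id = paste0("r", 1:5), sensitivity = 0.74,
                   specificity = 0.85)
  props <- t(vapply(1:30, function(s)
    diagnosticMetrics(confusionCounts(
      simulateReaderPanel(truth, rd, seed = s)))$proportion,
    numeric(3)))
  expect_lt(abs(mean(props[, 1]) - 0.74), 0.02)
  expect_lt(abs(mean(props[, 2]) - 0.85), 0.02)
})

test_that("layout constructors enforce their geometric invariants", {
  inf <- layoutInfiltration(400, 100, 60)
  expect_equal(attr(inf, "scan_truth"), "Tumor")
  expect_equal(sum(inf == "Tumor"), 60)
  r <- rle(inf == "Tumor")
  expect_equal(sum(r$values), 1L)                   # one contiguous segment
  expect_error(layoutScattered(400, c(3, 4)), "non-adjacent")
  sc <- layoutScattered(400, c(3, 7))
  expect_equal(attr(sc, "scan_truth"), "WM")
  expect_error(tissueModel(muS = c(Normal = -1, DamagedMatter = 2,
                                   Tumor = 3.5)))
})
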