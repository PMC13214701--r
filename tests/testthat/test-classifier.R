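## two well-separated 2-D Gaussian clouds (4 pooled SDs apart)
gaussCloudBlocks <- function(n = 100, gap = 4, seed = 17) {
  set.seed(seed)
  data.frame(
    scan_id = rep(sprintf("s%02d", 1:10), length.out = 2 * n),
    mean_oac = c(rnorm(n, 0), rnorm(n, gap)),
    mean_rsc = c(rnorm(n, 0), rnorm(n, gap)),
    label = rep(c("Normal", "Tumor"), each = n),
    stringsAsFactors = FALSE)
}

test_that("training standardizes features and separates distant clouds", {
  blocks <- gaussCloudBlocks()
  m <- trainTissueSVM(blocks)
  ## scaler applied to its own training data: mean 0, variance 1
  x <- as.matrix(blocks[, c("mean_oac", "mean_rsc")])
  xs <- sweep(sweep(x, 2, m@center), 2, m@scale, "/")
  expect_equal(unname(colMeans(xs)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(colMeans(xs^2)), c(1, 1), tolerance = 1e-9)
  ## training accuracy on 4-SD-separated clouds
  pred <- colnames(decisionScores(m, blocks))[
    max.col(decisionScores(m, blocks), ties.method = "first")]
  expect_gte(mean(pred == blocks$label), 0.99)
})

test_that("training rejects degenerate inputs with informative errors", {
  blocks <- gaussCloudBlocks()
  one <- blocks[blocks$label == "Normal", ]
  expect_error(trainTissueSVM(one), "two tissue classes")
  flat <- blocks; flat$mean_rsc <- 1
  expect_error(trainTissueSVM(flat), "mean_rsc")
  tiny <- blocks[c(1, 101), ]
  expect_error(trainTissueSVM(tiny), "two blocks per class")
})

test_that("training is deterministic and survives a JSON round-trip", {
  blocks <- trainingBlocks()
  m1 <- trainTissueSVM(blocks, seed = 5L)
  m2 <- trainTissueSVM(blocks, seed = 5L)
  expect_identical(m1@weights, m2@weights)
  expect_identical(m1@manifest, m2@manifest)
  dir <- withr::local_tempdir()
  writeModel(m1, file.path(dir, "model.json"))
  m3 <- readModel(file.path(dir, "model.json"))
  expect_equal(decisionScores(m3, blocks), decisionScores(m1, blocks),
               tolerance = 1e-12)
})

test_that("duplicating every training point leaves the hard-margin boundary unchanged", {
  ## in the regime where no dual coefficient touches the cost bound the SVM
  ## solution depends only on the support set, so duplication is a no-op
  blocks <- gaussCloudBlocks(n = 60, gap = 6)
  m1 <- trainTissueSVM(blocks, cost = 100, tolerance = 1e-9)
  m2 <- trainTissueSVM(rbind(blocks, blocks), cost = 100, tolerance = 1e-9)
  expect_equal(m1@weights, m2@weights, tolerance = 1e-6)
  expect_equal(m1@intercepts, m2@intercepts, tolerance = 1e-6)
})

test_that("grouped LOOCV refits scaler and model strictly inside each fold", {
  blocks <- trainingBlocks()
  cv <- loocvPredict(blocks)
  expect_equal(attr(cv, "folds"), 9L)
  expect_equal(nrow(cv), nrow(blocks))
  ## audit one fold by recomputation: held-out scores must equal those of a
  ## model fitted on the remainder only
  g <- unique(blocks$scan_id)[1]
  hold <- blocks$scan_id == g
  mRest <- trainTissueSVM(blocks[!hold, ])
  sc <- decisionScores(mRest, blocks[hold, ])
  for (cl in mRest@classes)
    expect_equal(cv[[paste0("score_", cl)]][hold], unname(sc[, cl]))
  ## determinism
  cv2 <- loocvPredict(blocks)
  expect_identical(cv$predicted, cv2$predicted)
})

test_that("LOOCV grouping semantics: fold counts, separability, degeneracy", {
  blocks <- gaussCloudBlocks(n = 30, gap = 8, seed = 23)
  blocks$scan_id <- rep(c("a", "b", "c"), each = 20)
  ## 3 groups, perfectly separable -> all out-of-fold predictions correct
  cv <- loocvPredict(blocks)
  expect_equal(attr(cv, "folds"), 3L)
  expect_equal(mean(cv$predicted == cv$label), 1.0)
  ## per-block grouping: one fold per block
  cvb <- loocvPredict(blocks, grouping = "per_block")
  expect_equal(attr(cvb, "folds"), nrow(blocks))
  ## a fold whose remainder loses a class is refused
  blocks2 <- blocks
  blocks2$scan_id[blocks2$label == "Tumor"] <- "onlyTumor"
  blocks2$scan_id[blocks2$label == "Normal"] <-
    rep(c("n1", "n2"), length.out = 30)
  expect_error(loocvPredict(blocks2), "loses a class")
})

test_that("label-permuted LOOCV collapses to the majority-class rate", {
  set.seed(41)
  blocks <- gaussCloudBlocks(n = 40, gap = 4, seed = 29)
  blocks$label <- sample(blocks$label)
  cv <- loocvPredict(blocks, grouping = "per_block")
  acc <- mean(cv$predicted == cv$label)
  maj <- max(table(blocks$label)) / nrow(blocks)
  expect_lt(abs(acc - maj), 4 * sqrt(maj * (1 - maj) / nrow(blocks)) + 0.1)
})

test_that("ROC sweep equals the exhaustive pair-count oracle, ties included", {
  ## frozen case computed with the pair-count oracle: scores
  ## (0.1-, 0.4+, 0.35-, 0.8+) have all four positive-negative pairs
  ## concordant, hence AUC 1
  expect_equal(rocCurve(c(0.1, 0.4, 0.35, 0.8),
                        c(FALSE, TRUE, FALSE, TRUE))$auc, 1.0)
  ## one discordant pair out of four -> 0.75
  expect_equal(rocCurve(c(0.5, 0.4, 0.35, 0.8),
                        c(FALSE, TRUE, FALSE, TRUE))$auc, 0.75)
  ## tied scores earn half credit
  expect_equal(rocCurve(c(1, 1), c(TRUE, FALSE))$auc, 0.5)
  ## random instances, n <= 50, against the oracle
  set.seed(6)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    s <- round(rnorm(n), sample(0:2, 1))   # coarse rounding induces ties
    y <- runif(n) < 0.5
    if (all(y) || !any(y)) y[1:2] <- c(TRUE, FALSE)
    expect_equal(rocCurve(s, y)$auc, oracleAUC(s, y), tolerance = 1e-12)
  }
  expect_error(rocCurve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- rnorm(80); y <- runif(80) < 0.4
  ours <- rocCurve(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("null scores give chance-level AUC", {
  set.seed(8)
  s <- rnorm(2000); y <- runif(2000) < 0.5
  expect_lt(abs(rocCurve(s, y)$auc - 0.5), 0.05)
})

test_that("segmentation labels blocks by score argmax with NA for invalid blocks", {
  blocks <- trainingBlocks()
  model <- trainTissueSVM(blocks)
  ## homogeneous Normal scan -> all Green
  sN <- simulateBScan(layoutHomogeneous(400, "Normal"), seed = 91)
  segN <- segmentScan(computeParametricMaps(sN), model)
  expect_equal(length(blockLabels(segN)), 20L)     # 400 / 20
  expect_true(all(blockLabels(segN) == "Normal"))
  ## 5-block tumor insert -> those blocks Red
  sT <- simulateBScan(layoutInfiltration(400, 200, 100, marginWidth = 0),
                      seed = 92)
  segT <- segmentScan(computeParametricMaps(sT), model)
  expect_true(all(blockLabels(segT)[11:15] == "Tumor"))
  expect_true(all(blockLabels(segT)[c(1:10, 16:20)] != "Tumor"))
  ## labels are the argmax of the stored scores
  sc <- blockScores(segT)
  expect_equal(as.character(blockLabels(segT)),
               colnames(sc)[max.col(sc, ties.method = "first")])
  ## feature dimensionality mismatch
  expect_error(decisionScores(model, matrix(1, 3, 3)), "dimensionality")
})

test_that("rendered maps tint stripes by class and gray out missing blocks", {
  dir <- withr::local_tempdir()
  scan <- simulateBScan(layoutHomogeneous(60, "Normal"), seed = 55)
  segRed <- SegmentationMap("r", rep("Tumor", 3))
  img <- renderSegmentation(segRed, scan, path = file.path(dir, "red.png"))
  expect_true(file.exists(file.path(dir, "red.png")))
  expect_true(all(img[, , 1] > img[, , 2]))        # red channel dominates
  segAlt <- SegmentationMap("a", c("Normal", "Tumor", "Normal"))
  imgA <- renderSegmentation(segAlt, scan)
  expect_true(all(imgA[, 21:40, 1] > imgA[, 21:40, 2]))   # red stripe
  expect_true(all(imgA[, 1:20, 2] > imgA[, 1:20, 1]))     # green stripe
  segNA <- SegmentationMap("n", c("Normal", NA, "Normal"))
  imgN <- renderSegmentation(segNA, scan, alpha = 1)
  expect_true(all(imgN[, 21:40, 1] == 0.5))               # neutral gray
  ## colorbar strip widens the image
  imgC <- renderSegmentation(segAlt, scan, colorbar = TRUE)
  expect_equal(dim(imgC)[2], 60 + 8)
})
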