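perfectPanel <- function(nTumor = 42, nWM = 44, nReaders = 5) {
  truth <- rep(c("Tumor", "WM"), c(nTumor, nWM))
  AssessmentSet(matrix(truth, length(truth), nReaders), truth = truth)
}

test_that("confusion counts pool assessments against scan truth", {
  cc <- confusionCounts(perfectPanel())
  expect_equal(cc, c(tp = 210L, tn = 220L, fp = 0L, fn = 0L))
  a1 <- AssessmentSet(matrix("WM", 1, 1), truth = "Tumor")
  expect_equal(confusionCounts(a1), c(tp = 0L, tn = 0L, fp = 0L, fn = 1L))
})

test_that("metrics follow the standard definitions with half-up percent rounding", {
  m <- diagnosticMetrics(c(tp = 1, tn = 1, fp = 0, fn = 0))
  expect_equal(m$percent, c(100, 100, 100))
  ## half-up: 74.5 rounds to 75, not 74
  expect_equal(diagnosticMetrics(c(tp = 149, tn = 0, fp = 0, fn = 51))$percent[1],
               75)
  ## zero denominators are flagged undefined, never reported as 0
  und <- diagnosticMetrics(c(tp = 0, tn = 3, fp = 1, fn = 0))
  expect_true(is.na(und$proportion[1]))
  expect_false(is.na(und$proportion[2]))
})

test_that("metrics and consistency agree with brute-force oracles on random panels", {
  for (i in 1:100) {
    a <- randomPanel(nScan = sample(2:10, 1), nReader = sample(2:5, 1),
                     seed = 1000 + i)
    m <- diagnosticMetrics(confusionCounts(a))
    o <- oracleMetrics(readerCalls(a), scanTruth(a))
    expect_equal(m$proportion, unname(o[c("sensitivity", "specificity",
                                          "accuracy")]))
    expect_equal(readerConsistency(a), oracleAgreement(readerCalls(a)))
  }
})

test_that("consistency handles unanimity, known splits, and the null", {
  u <- perfectPanel(4, 4)
  expect_equal(readerConsistency(u), 1.0)
  expect_equal(readerConsistency(u, "fleiss_kappa"), 1.0)
  ## 5 readers split 3-2 on every scan: (C(3,2)+C(2,2))/C(5,2) = 0.4
  calls <- matrix(rep(c("Tumor", "Tumor", "Tumor", "WM", "WM"), 6), 6, 5,
                  byrow = TRUE)
  a32 <- AssessmentSet(calls, truth = rep("Tumor", 6))
  expect_equal(readerConsistency(a32), 0.4)
  ## frozen hand-computed Fleiss' kappa values
  k0 <- AssessmentSet(rbind(c("Tumor", "Tumor", "WM"),
                            c("WM", "WM", "WM"),
                            c("Tumor", "WM", "WM")), truth = rep("WM", 3))
  expect_equal(readerConsistency(k0, "fleiss_kappa"), 0.0)
  k1 <- AssessmentSet(rbind(c("Tumor", "Tumor", "WM"),
                            c("WM", "WM", "WM"),
                            c("Tumor", "Tumor", "WM")), truth = rep("WM", 3))
  expect_equal(readerConsistency(k1, "fleiss_kappa"), 0.1)
  ## two coin-flip readers: agreement ~0.5, kappa ~0
  rd <- data.frame(reader_id = c("a", "b"), sensitivity = 0.5,
                   specificity = 0.5)
  null <- simulateReaderPanel(rep(c("Tumor", "WM"), 5000), rd, seed = 77)
  expect_lt(abs(readerConsistency(null) - 0.5), 0.03)
  expect_lt(abs(readerConsistency(null, "fleiss_kappa")), 0.03)
  ## one reader is an error
  expect_error(readerConsistency(AssessmentSet(matrix("WM", 3, 1),
                                               truth = rep("WM", 3))),
               "2 readers")
})

test_that("consistency is invariant under reader and scan permutations", {
  a <- randomPanel(12, 5, seed = 321)
  calls <- readerCalls(a)
  perm <- AssessmentSet(calls[sample(12), sample(5)],
                        truth = scanTruth(a)[1:12])  # truth irrelevant here
  for (m in c("pairwise_agreement", "fleiss_kappa"))
    expect_equal(readerConsistency(perm, m),
                 readerConsistency(AssessmentSet(calls, scanTruth(a)), m))
})

test_that("bootstrap CIs are percentile-based, seeded, and degenerate correctly", {
  p <- perfectPanel(10, 10, 3)
  b <- bootstrapCI(p, "accuracy", B = 200, seed = 5)
  expect_equal(b$ci, c(1, 1))                     # every resample is perfect
  ## bit-exact seed reproducibility
  a <- randomPanel(40, 5, seed = 9)
  b1 <- bootstrapCI(a, "accuracy", B = 500, seed = 42)
  b2 <- bootstrapCI(a, "accuracy", B = 500, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$ci, b2$ci)
  ## the interval contains the plug-in estimate
  expect_true(b1$ci[1] <= b1$estimate && b1$estimate <= b1$ci[2])
  ## an undefined statistic in most iterations errors with a diagnostic
  allWM <- AssessmentSet(matrix("WM", 8, 3), truth = rep("WM", 8))
  expect_error(bootstrapCI(allWM, "sensitivity", B = 100, seed = 1),
               "undefined")
})

test_that("bootstrap CI contains the point estimate across random panels", {
  contained <- vapply(1:30, function(i) {
    a <- randomPanel(60, 5, seed = 5000 + i)
    b <- bootstrapCI(a, "accuracy", B = 400, seed = i)
    b$ci[1] <= b$estimate && b$estimate <= b$ci[2]
  }, logical(1))
  expect_gte(mean(contained), 29 / 30)
})

test_that("CI width shrinks like 1/sqrt(n) when the panel doubles", {
  rd <- data.frame(reader_id = paste0("r", 1:5), sensitivity = 0.8,
                   specificity = 0.8)
  width <- function(n, seed) {
    truth <- rep(c("Tumor", "WM"), each = n / 2)
    a <- simulateReaderPanel(truth, rd, seed = seed,
                             correlation = "unanimous")
    b <- bootstrapCI(a, "accuracy", B = 1500, seed = seed + 1)
    b$ci[2] - b$ci[1]
  }
  ratios <- vapply(1:5, function(s) width(86, s) / width(172, 100 + s),
                   numeric(1))
  expect_lt(abs(mean(ratios) - sqrt(2)), 0.25)
})

test_that("assessment-pair bootstrap mode resamples individual predictions", {
  a <- randomPanel(30, 4, seed = 61)
  b <- bootstrapCI(a, "accuracy", B = 300, seed = 3, unit = "assessment")
  expect_true(b$ci[1] <= b$estimate && b$estimate <= b$ci[2])
  expect_equal(b$B, 300)
})

test_that("modality comparison reports CI overlap as printed", {
  r <- list(
    seg = data.frame(metric = "sensitivity", estimate = 98, lower = 92,
                     upper = 100),
    vlm = data.frame(metric = "sensitivity", estimate = 86, lower = 74,
                     upper = 95))
  cmp <- compareModalities(r)
  expect_true(cmp$pairs$ci_overlap)                 # [92,100] vs [74,95] touch
  expect_equal(cmp$pairs$difference, 12)
  ## identical reports: zero differences, all overlapping
  same <- compareModalities(list(a = r$seg, b = r$seg))
  expect_equal(same$pairs$difference, 0)
  expect_true(all(same$pairs$ci_overlap))
  ## disjoint intervals do not overlap
  dj <- compareModalities(list(
    a = data.frame(metric = "accuracy", estimate = 5, lower = 0, upper = 10),
    b = data.frame(metric = "accuracy", estimate = 25, lower = 20,
                   upper = 30)))
  expect_false(dj$pairs$ci_overlap)
})
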