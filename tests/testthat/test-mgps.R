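test_that("position-weighted similarity follows the scoring rules", {
  # gap terms score 0, the center comparison is fixed at 1
  expect_identical(mgpsSimilarity("-Y-", "-Y-", c(1, 7, 1)), 7)
  # BLOSUM62 A/A = 4 checked independently against the Biostrings table
  expect_identical(rawB62("A", "A"), 4)
  expect_identical(mgpsSimilarity("AYA", "AYA", c(1, 7, 1)), 15)
  # raw negative sums clip to zero
  expect_identical(rawB62("W", "D") < 0, TRUE)
  expect_identical(mgpsSimilarity("WYW", "DYD", c(10, 0, 10)), 0)
  expect_error(mgpsSimilarity("AYA", "AAYAA", c(1, 1, 1)), "equal length")
})

test_that("model score is the mean clipped similarity over references", {
  m <- mgpsModelFromWeights("PTP1B", c(1, 7, 1), "-Y-")
  expect_identical(mgpsScore(m, "-Y-"), 7)
  # zeros stay in the average
  m2 <- mgpsModelFromWeights("PTP1B", c(10, 0, 10), c("AYA", "DYD"))
  sAA <- 2 * 10 * rawB62("A", "A")          # vs "AYA": 80
  expect_identical(mgpsScore(m2, "AYA"), sAA / 2)
  # permutation invariance of the reference set
  m2r <- mgpsModelFromWeights("PTP1B", c(10, 0, 10), c("DYD", "AYA"))
  expect_identical(mgpsScore(m2r, "AYA"), mgpsScore(m2, "AYA"))
  # excluding the only reference is an error
  expect_error(mgpsScore(m, "-Y-", exclude = "-Y-"), "reference")
})

test_that("vectorized scoring matches the brute-force oracle", {
  set.seed(41)
  aas <- c("A", "C", "D", "E", "K", "R", "W", "Y", "-")
  for (rep in 1:5) {
    refs <- replicate(4, paste0(
      paste(sample(aas, 2, TRUE), collapse = ""), "Y",
      paste(sample(aas, 2, TRUE), collapse = "")))
    w <- round(runif(5, 0, 4))
    m <- mgpsModelFromWeights("PTP1B", w, refs)
    queries <- replicate(3, paste0(
      paste(sample(aas, 2, TRUE), collapse = ""), "Y",
      paste(sample(aas, 2, TRUE), collapse = "")))
    expect_equal(mgpsScore(m, queries),
                 vapply(queries, bruteMgpsScore, numeric(1), refs, w),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("hill climbing yields a non-decreasing AUC trace", {
  ts <- generateSynthetic("PTP1B", nPos = 20, nNeg = 80, seed = 8)
  fit <- trainMgpsWeights(ts)
  expect_false(is.unsorted(fit$trace$auc))
  # tuning never hurts the jackknife objective
  expect_gte(fit$auc, fit$trace$auc[1])
  expect_identical(fit$auc, fit$trace$auc[nrow(fit$trace)])
  # non-center weights respect the >= 0 constraint
  expect_true(all(fit$weights[-11] >= 0))
})

test_that("a single informative position earns the dominant weight", {
  # positives carry D at offset -2; everything else is uniform noise
  set.seed(12)
  flank <- function() paste(sample(c("A", "G", "S", "T", "L"), 5, TRUE),
                            collapse = "")
  pos <- replicate(25, paste0(substr(flank(), 1, 3), "D",
                              substr(flank(), 5, 5), "Y", flank()))
  neg <- replicate(150, paste0(flank(), "Y", flank()))
  fit <- trainMgpsWeights(toySet(pos, neg))  # 11-mers, planted offset -2
  flankW <- fit$weights[-c(4, 6)]  # exclude planted position and center
  expect_gt(fit$weights[4], max(flankW))
})

test_that("degenerate training sets terminate with initial weights", {
  # identical positives and negatives: every jackknife score ties
  ts <- toySet(rep("AAYAA", 3), rep("AAYAA", 5))
  expect_warning(fit <- trainMgpsWeights(ts), "tied")
  expect_identical(fit$weights, c(1, 1, 7, 1, 1))
})

test_that("all-zero flank weights collapse scores to a constant", {
  ts <- generateSynthetic("PTP1B", nPos = 10, nNeg = 40, seed = 3)
  w <- rep(0, 21); w[11] <- 7
  m <- mgpsModelFromWeights("PTP1B", w, positives(ts))
  sc <- mgpsScore(m, siteWindows(ts)$peptide)
  expect_identical(length(unique(sc)), 1L)
  # a constant scorer has AUC exactly 0.5 under the midrank convention
  expect_identical(computeAuc(sc, siteWindows(ts)$label), 0.5)
})

test_that("length selection returns the argmax of the scan", {
  ts <- generateSynthetic("PTP1B", nPos = 15, nNeg = 60, seed = 23)
  one <- selectMgpsLength(ts, lengths = 13L)
  expect_identical(halfWidth(one$model), 6L)
  res <- selectMgpsLength(ts, lengths = c(9L, 13L, 17L))
  expect_identical(2L * halfWidth(res$model) + 1L,
                   res$scan$length[which.max(res$scan$auc)])
  expect_true(all(res$model@auc >= res$scan$auc - 1e-12))
  expect_error(selectMgpsLength(ts, lengths = integer(0)), "lengths")
})

test_that("trained models carry usable specificity thresholds", {
  ts <- generateSynthetic("SHP-1", nPos = 20, nNeg = 100, seed = 6)
  m <- trainMgps(ts)
  expect_named(m@thresholds, c("0.90", "0.85", "0.80"))
  # model file round-trip preserves scoring exactly
  f <- tempfile(fileext = ".json")
  saveModel(m, f)
  m2 <- loadModel(f)
  q <- siteWindows(ts)$peptide[1:5]
  expect_equal(mgpsScore(m2, q), mgpsScore(m, q), tolerance = 1e-12)
})
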