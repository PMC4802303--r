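test_that("AUC equals the pairwise probability with ties at one half", {
  expect_identical(
    computeAuc(c(1, 2, 3, 4), c("negative", "negative", "positive",
                                "positive")), 1)
  expect_identical(
    computeAuc(c(1, 2, 3, 4), c("positive", "positive", "negative",
                                "negative")), 0)
  # tie-rich case frozen from the pairwise oracle: {2,3} vs {1,2}
  expect_identical(
    computeAuc(c(1, 2, 2, 3), c("negative", "positive", "negative",
                                "positive")), 0.875)
  expect_error(computeAuc(1:3, rep("positive", 3)), "both classes")
})

test_that("AUC agrees with the O(n^2) oracle and with pROC", {
  set.seed(101)
  for (rep in 1:6) {
    n <- sample(20:200, 1)
    labels <- sample(rep(c("positive", "negative"), c(n %/% 3,
                                                      n - n %/% 3)))
    scores <- round(rnorm(n) + (labels == "positive"), 1)  # many ties
    a <- computeAuc(scores, labels)
    expect_equal(a, bruteAuc(scores, labels), tolerance = 1e-12)
    p <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, levels = c("negative",
                                                        "positive"),
      direction = "<", quiet = TRUE)))
    expect_equal(a, p, tolerance = 1e-12)
    # complement symmetry
    expect_equal(computeAuc(-scores, labels), 1 - a, tolerance = 1e-12)
  }
})

test_that("ROC points integrate to the same area", {
  set.seed(5)
  labels <- rep(c("positive", "negative"), c(30, 70))
  scores <- rnorm(100) + (labels == "positive")
  roc <- rocPointsTable(scores, labels)
  # trapezoid over the empirical curve
  area <- sum(diff(roc$FPR) * (head(roc$TPR, -1) + tail(roc$TPR, -1)) / 2)
  expect_equal(area, computeAuc(scores, labels), tolerance = 1e-12)
  expect_identical(roc$FPR[1], 0)
  expect_identical(roc$TPR[nrow(roc)], 1)
})

test_that("jackknife scores each sample without itself", {
  # separable toy problem: leave-one-out scoring stays perfect
  ts <- toySet(rep("AAAAYAAAA", 4), rep("WWWWYWWWW", 8))
  fitFun <- function(tr) knnModel(tr, k = 3)
  scoreFun <- function(m, pep) knnScore(m, pep)
  rep1 <- jackknifeEval(ts, fitFun, scoreFun)
  expect_identical(auc(rep1), 1)
  # constant scorer gives AUC 0.5 under midranks
  rep2 <- jackknifeEval(ts, function(tr) NULL, function(m, pep) 0)
  expect_identical(auc(rep2), 0.5)
})

test_that("jackknife matches a hand-unrolled leave-one-out", {
  ts <- generateSynthetic("PTP1B", nPos = 3, nNeg = 3, seed = 71)
  w <- siteWindows(ts)
  fitFun <- function(tr) tr
  scoreFun <- function(m, pep) {
    # mean raw BLOSUM similarity to the fold's positives
    refs <- positives(m)
    if (!length(refs)) return(0)
    mean(vapply(refs, function(r) {
      sum(vapply(seq_len(nchar(pep)), function(i) {
        rawB62(substr(pep, i, i), substr(r, i, i))
      }, numeric(1)))
    }, numeric(1)))
  }
  rep1 <- jackknifeEval(ts, fitFun, scoreFun)
  manual <- vapply(seq_len(6), function(i) {
    scoreFun(SiteTrainingSet("PTP1B", 10, w[-i, , drop = FALSE]),
             w$peptide[i])
  }, numeric(1))
  expect_equal(sampleScores(rep1)$score, manual, tolerance = 1e-12)
  # permutation invariance: shuffling sample order preserves per-sample
  # scores
  perm <- sample(6)
  ts2 <- SiteTrainingSet("PTP1B", 10, w[perm, , drop = FALSE])
  rep2 <- jackknifeEval(ts2, fitFun, scoreFun)
  expect_equal(sampleScores(rep2)$score, manual[perm], tolerance = 1e-12)
})

test_that("repeated k-fold is seeded, stratified and reduces to LOO", {
  ts <- generateSynthetic("PTP1B", nPos = 8, nNeg = 16, seed = 3)
  fitFun <- function(tr) knnModel(tr, k = 3)
  scoreFun <- function(m, pep) knnScore(m, pep)
  a <- repeatedKfold(ts, fitFun, scoreFun, k = 4, repeats = 3, seed = 11)
  b <- repeatedKfold(ts, fitFun, scoreFun, k = 4, repeats = 3, seed = 11)
  expect_identical(a$aucs, b$aucs)
  expect_identical(a$meanAuc, mean(a$aucs))
  # stratification balances both classes across folds
  folds <- a$reports[[1]]@meta$folds
  labels <- siteWindows(ts)$label
  for (f in 1:4) {
    expect_identical(sum(folds == f & labels == "positive"), 2L)
    expect_identical(sum(folds == f & labels == "negative"), 4L)
  }
  # k = n with one repeat is the jackknife
  loo <- repeatedKfold(ts, fitFun, scoreFun, k = 24L, repeats = 1,
                       seed = 1)
  jk <- jackknifeEval(ts, fitFun, scoreFun)
  expect_equal(loo$reports[[1]]@scores$score, sampleScores(jk)$score,
               tolerance = 1e-12)
})

test_that("operating points realize the smallest specificity >= level", {
  # perfect separation: everything is 1 at the 0.90 level
  labels <- rep(c("positive", "negative"), c(5, 5))
  op <- operatingPoint(c(rep(2, 5), rep(1, 5)), labels, 0.90)
  expect_identical(unname(op[c("SPE", "SEN", "MCC")]), c(1, 1, 1))
  # MCC identities: all four cells equal gives 0
  op2 <- operatingPoint(c(1, 1, 2, 2, 1, 1, 2, 2),
                        rep(c("positive", "negative"), each = 4), 0)
  expect_identical(unname(op2["MCC"]), 0)
  # realized SPE never undershoots the level
  set.seed(9)
  sc <- rnorm(60)
  lb <- sample(rep(c("positive", "negative"), c(20, 40)))
  for (lv in c(0.9, 0.85, 0.8)) {
    expect_gte(operatingPoint(sc, lb, lv)[["SPE"]], lv)
  }
})

test_that("coarse scorers leave duplicate levels unavailable", {
  # six-valued kNN-style scores on an imbalanced toy multiset
  scores <- c(rep(1, 3), rep(0.8, 2), rep(0.6, 4), rep(0.4, 3),
              rep(0.2, 18), rep(0, 30))
  labels <- c(rep("positive", 8), rep("negative", 52))
  ops <- operatingPoints(scores, labels, c(0.90, 0.85, 0.80))
  expect_true(any(!ops$available))
  expect_true(all(is.na(ops$SEN[!ops$available])))
  # realized SPE at available levels meets its level
  avail <- ops[ops$available, ]
  expect_true(all(avail$SPE >= avail$level))
})

test_that("complementarity is the Pearson correlation with flagging", {
  x <- rnorm(50)
  expect_equal(complementarity(x, x), 1, tolerance = 1e-12)
  expect_equal(complementarity(x, -x), -1, tolerance = 1e-12)
  set.seed(33)
  lowCors <- replicate(10, complementarity(rnorm(1000), rnorm(1000)))
  expect_lt(max(abs(lowCors)), 0.15)
  expect_warning(complementarity(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("the linear ensemble combines component scores sensibly", {
  set.seed(44)
  labels <- rep(c("positive", "negative"), c(30, 90))
  perfect <- (labels == "positive") * 2 + rnorm(120, sd = 0.1)
  random <- rnorm(120)
  # identical components add nothing
  same <- cbind(a = perfect, b = perfect)
  repSame <- ensembleJackknife(same, labels)
  expect_equal(auc(repSame), computeAuc(perfect, labels),
               tolerance = 0.02)
  # a random partner costs at most a little
  mix <- cbind(good = perfect, noise = random)
  repMix <- ensembleJackknife(mix, labels)
  expect_gte(auc(repMix), computeAuc(perfect, labels) - 0.05)
  # orientation: positives score higher on average
  m <- trainEnsemble(mix, labels)
  sc <- ensembleScore(m, mix)
  expect_gt(mean(sc[labels == "positive"]),
            mean(sc[labels == "negative"]))
  expect_error(trainEnsemble(matrix(perfect, ncol = 1), labels), ">= 2")
  expect_warning(trainEnsemble(cbind(perfect, 0 * random), labels),
                 "constant")
})
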