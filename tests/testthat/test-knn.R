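test_that("the vote is the positive fraction of the top-k pool", {
  # query identical to the positives: all 5 nearest are positive
  pos <- rep("AAAAYAAAA", 5)
  neg <- rep("WWWWYWWWW", 10)
  ts <- toySet(pos, neg)
  expect_identical(knnScore(ts, "AAAAYAAAA", k = 5), 1)
  expect_identical(knnScore(ts, "WWWWYWWWW", k = 5), 0)
  expect_error(knnScore(ts, "AAAAYAAAA", k = 99), "training-set size")
})

test_that("k = 5 emits exactly the six scores 0, 0.2, ..., 1", {
  ts <- generateSynthetic("PTP1B", nPos = 30, nNeg = 120, seed = 19)
  sc <- knnScore(ts, siteWindows(ts)$peptide, k = 5, posWeight = 2)
  expect_true(all(sc %in% ((0:5) / 5)))
  sc7 <- knnScore(ts, siteWindows(ts)$peptide, k = 7, posWeight = 2)
  expect_true(all(sc7 %in% ((0:7) / 7)))  # k+1 values in general
})

test_that("ties rank positives before negatives, then pool order", {
  # one positive and one negative exactly equidistant from the query
  ts <- toySet("AAYAA", "AAYAA")
  expect_identical(knnScore(ts, "AAYAA", k = 1, posWeight = 1), 1)
  # ...but a higher-scoring negative wins outright
  ts2 <- toySet("CCYCC", "AAYAA")
  expect_identical(knnScore(ts2, "AAYAA", k = 1, posWeight = 1), 0)
})

test_that("increasing the positive weight never lowers a score", {
  ts <- generateSynthetic("SHP-1", nPos = 20, nNeg = 80, seed = 29)
  q <- siteWindows(ts)$peptide[seq(1, 100, 7)]
  prev <- knnScore(ts, q, k = 5, posWeight = 1)
  for (w in c(2, 4, 7)) {
    cur <- knnScore(ts, q, k = 5, posWeight = w)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("ranking matches the exhaustive oracle on small pools", {
  set.seed(59)
  aas <- c("A", "D", "E", "K", "W")
  mkWin <- function() {
    w <- paste0(paste(sample(aas, 3, TRUE), collapse = ""), "Y",
                paste(sample(aas, 3, TRUE), collapse = ""))
    # occasional terminal pads, kept contiguous
    if (runif(1) < 0.3) substr(w, 1, sample(2, 1)) <- "--"
    if (runif(1) < 0.3) substr(w, 7, 7) <- "-"
    w
  }
  for (rep in 1:4) {
    pool <- replicate(8, mkWin())
    labels <- sample(rep(c("positive", "negative"), c(3, 5)))
    ts <- SiteTrainingSet("PTP1B", 3, data.frame(
      peptide = pool, label = labels,
      protein_id = sprintf("Q%02d", 1:8), position = 4L))
    q <- mkWin()
    for (w in c(1, 2.9)) {
      expect_identical(knnScore(ts, q, k = 3, posWeight = w),
                       bruteKnnScore(q, pool, labels, w, 3))
    }
  }
})

test_that("grid tuning returns the jackknife-AUC argmax", {
  ts <- generateSynthetic("PTP1B", nPos = 15, nNeg = 60, seed = 37)
  one <- tuneKnn(ts, lengths = 11L, weights = 3)
  expect_identical(one$model@posWeight, 3)
  expect_identical(one$model@halfWidth, 5L)
  res <- tuneKnn(ts, lengths = c(9L, 15L), weights = c(1, 3, 5))
  best <- res$scan[which.max(res$scan$auc), ]
  expect_identical(2L * res$model@halfWidth + 1L, as.integer(best$length))
  expect_identical(res$model@posWeight, best$posWeight)
  expect_equal(res$model@auc, best$auc, tolerance = 1e-12)
})

test_that("published kNN presets load as models", {
  for (e in c("PTP1B", "SHP-1", "SHP-2")) {
    p <- knnPreset(e)
    expect_identical(p$k, 5L)
  }
  expect_identical(knnPreset("PTP1B")$length, 23L)
  expect_identical(knnPreset("PTP1B")$posWeight, 2.9)
  expect_identical(knnPreset("SHP-1")[c("length", "posWeight")],
                   list(length = 25L, posWeight = 5))
  expect_identical(knnPreset("SHP-2")[c("length", "posWeight")],
                   list(length = 39L, posWeight = 6))
  ts <- generateSynthetic("PTP1B", nPos = 10, nNeg = 40, seed = 3)
  p <- knnPreset("PTP1B")
  m <- knnModel(ts, n = (p$length - 1L) %/% 2L, k = p$k,
                posWeight = p$posWeight)
  expect_s4_class(m, "KnnModel")
  expect_identical(2L * m@halfWidth + 1L, 23L)
})
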