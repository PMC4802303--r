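test_that("pair counting and normalization follow the encoding rules", {
  # "AYA", k = 0: pairs AY and YA, each 1 of 2
  v <- cksaapEncode("AYA", kMax = 1L)
  expect_identical(unname(v[1, "k0_AY"]), 0.5)
  expect_identical(unname(v[1, "k0_YA"]), 0.5)
  expect_identical(sum(v[1, startsWith(colnames(v), "k0_")]), 1)
  # "AAAAA", k = 2: the only two 2-spaced pairs are both AxxA
  v2 <- cksaapEncode("AAAAA", kMax = 2L)
  expect_identical(unname(v2[1, "k2_AA"]), 1)
  # hand-enumerated: positions (1,4) and (2,5)
  expect_identical(sum(v2[1, startsWith(colnames(v2), "k2_")] > 0), 1L)
  expect_error(cksaapEncode("AYA", kMax = 4L), "too short")
})

test_that("every 21-mer yields 2205 features with unit k-slices", {
  set.seed(77)
  peps <- c(
    replicate(5, paste(sample(c("A", "C", "D", "Y", "-"), 21, TRUE),
                       collapse = "")),
    paste0(strrep("-", 10), "Y", strrep("-", 10)),  # heavy padding
    strrep("-", 21))                                # all pads
  X <- cksaapEncode(peps)
  expect_identical(ncol(X), 2205L)
  for (k in 0:4) {
    slice <- X[, startsWith(colnames(X), sprintf("k%d_", k)), drop = FALSE]
    expect_equal(unname(rowSums(slice)), rep(1, nrow(X)),
                 tolerance = 1e-12)
  }
})

test_that("the feature index map is a stable bijection", {
  nm <- cksaapFeatureNames()
  expect_identical(length(nm), 2205L)
  expect_false(any(duplicated(nm)))
  # frozen layout: k-major, then first symbol, then second symbol
  expect_identical(nm[1], "k0_AA")
  expect_identical(nm[441], "k0_--")
  expect_identical(nm[442], "k1_AA")
  expect_identical(nm[2205], "k4_--")
})

test_that("nonstandard residues lose mass without shifting other pairs", {
  a <- cksaapEncode("AXAYAXA", kMax = 1L)  # X is inert
  expect_lt(sum(a[1, startsWith(colnames(a), "k0_")]), 1)
  expect_identical(unname(a[1, "k0_AY"]), 1 / 6)
})

test_that("a separable toy problem is learned perfectly", {
  pos <- paste0("AAAA", strrep("A", 4), "Y", strrep("A", 8))
  neg <- paste0("CCCC", strrep("C", 4), "Y", strrep("C", 8))
  ts <- toySet(rep(substr(pos, 1, 17), 8), rep(substr(neg, 1, 17), 8))
  m <- trainCksaap(ts, gammas = 2^-5, costs = 1, repeats = 1, folds = 2)
  sc <- cksaapScore(m, siteWindows(ts)$peptide)
  expect_identical(computeAuc(sc, siteWindows(ts)$label), 1)
  # all training positives rank above all training negatives
  expect_gt(min(sc[siteWindows(ts)$label == "positive"]),
            max(sc[siteWindows(ts)$label == "negative"]))
})

test_that("scores are deterministic, batch-invariant and serializable", {
  ts <- generateSynthetic("PTP1B", nPos = 15, nNeg = 60, seed = 13)
  m1 <- trainCksaap(ts, gammas = 2^-7, costs = 2^-3, repeats = 2)
  m2 <- trainCksaap(ts, gammas = 2^-7, costs = 2^-3, repeats = 2)
  q <- siteWindows(ts)$peptide[c(1, 20, 40)]
  expect_identical(cksaapScore(m1, q), cksaapScore(m2, q))
  # singleton batch equals the same peptide inside a larger batch
  expect_equal(cksaapScore(m1, q[2]), cksaapScore(m1, q)[2],
               tolerance = 1e-12)
  f <- tempfile(fileext = ".json")
  saveModel(m1, f)
  expect_equal(cksaapScore(loadModel(f), q), cksaapScore(m1, q),
               tolerance = 1e-9)
})

test_that("single-class and non-finite inputs are rejected", {
  X <- matrix(rnorm(20), 10)
  expect_error(dephossite:::.svmFitRaw(X, rep("positive", 10), 0.1, 1),
               "both classes")
  X[1] <- NaN
  expect_error(dephossite:::.svmFitRaw(
    X, rep(c("positive", "negative"), 5), 0.1, 1), "non-finite")
})

test_that("published parameter presets are exposed", {
  p <- cksaapPreset("PTP1B")
  expect_identical(p$length, 45L)
  expect_identical(p$gamma, 2^-7)
  expect_identical(p$cost, 2^-3)
  expect_identical(cksaapPreset("SHP-2")$length, 57L)
})
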