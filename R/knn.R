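## Raw BLOSUM62 similarity (sum over positions, '-' scores 0, no center
## override, no clipping): nTrain x nQuery matrix.
.rawSimMatrix <- function(Qmat, Tmat) {
  A <- .pairSubMatrix(Qmat, Tmat, center = FALSE)
  matrix(rowSums(A), nrow = nrow(Tmat), ncol = nrow(Qmat))
}

## Fraction of positives among the top-k pool members for each query
## column of the similarity matrix S (nPool x nQuery). Positive-sample
## similarities are multiplied by posWeight before ranking; ties rank
## positives before negatives, then by pool input order. selfIdx[q], when
## given, removes that pool member from query q's ranking (leave-one-out).
.knnVote <- function(S, poolLabels, posWeight, k, selfIdx = NULL) {
  isPos <- poolLabels == "positive"
  W <- S
  W[isPos, ] <- W[isPos, , drop = FALSE] * posWeight
  labelRank <- ifelse(isPos, 0L, 1L)
  nQ <- ncol(W)
  out <- numeric(nQ)
  for (q in seq_len(nQ)) {
    sc <- W[, q]
    if (!is.null(selfIdx) && !is.na(selfIdx[q])) sc[selfIdx[q]] <- -Inf
    ord <- order(-sc, labelRank, seq_along(sc))[seq_len(k)]
    out[q] <- sum(isPos[ord]) / k
  }
  out
}

#' Score windows with the BLOSUM62 k-nearest-neighbour predictor
#'
#' Each query is compared with every training window by raw BLOSUM62
#' similarity (positions summed, `-` scoring 0); positive-sample
#' similarities are multiplied by the class weight, the pool is ranked
#' from high to low, and the score is the fraction of positives among the
#' top k — so a k = 5 model emits exactly the six values 0, 0.2, ..., 1.
#'
#' @param train a [SiteTrainingSet-class] or [KnnModel-class].
#' @param peptides character vector of query windows.
#' @param k neighbourhood size (default 5).
#' @param posWeight multiplier for positive-sample similarities
#'   (default 1).
#' @return numeric scores in `{0, 1/k, ..., 1}`.
#' @export
knnScore <- function(train, peptides, k = 5L, posWeight = 1) {
  if (is(train, "KnnModel")) {
    pool <- train@trainWindows
    k <- train@k
    posWeight <- train@posWeight
    n <- train@halfWidth
  } else {
    pool <- siteWindows(train)
    n <- halfWidth(train)
  }
  if (k > nrow(pool)) stop("k exceeds the training-set size")
  peptides <- rewindowPeptides(peptides, n)
  S <- .rawSimMatrix(peptideMatrix(peptides), peptideMatrix(pool$peptide))
  .knnVote(S, pool$label, posWeight, k)
}

## Leave-one-out kNN scores of every training sample.
.knnJackknifeScores <- function(peptides, labels, posWeight, k) {
  S <- .rawSimMatrix(peptideMatrix(peptides), peptideMatrix(peptides))
  .knnVote(S, labels, posWeight, k, selfIdx = seq_along(peptides))
}

#' Build a kNN model at a fixed configuration
#'
#' Stores the training pool and configuration; the jackknife AUC and the
#' specificity thresholds are computed from leave-one-out scores.
#'
#' @param train a [SiteTrainingSet-class].
#' @param n half-width for the model windows (default: the set's own).
#' @param k neighbourhood size (default 5).
#' @param posWeight positive-sample similarity multiplier in `[1, 7]`.
#' @param specificityLevels specificity levels for stored thresholds.
#' @return a [KnnModel-class].
#' @export
knnModel <- function(train, n = NULL, k = 5L, posWeight = 1,
                     specificityLevels = c(0.90, 0.85, 0.80)) {
  if (is.null(n)) n <- halfWidth(train)
  w <- siteWindows(train)
  pool <- data.frame(peptide = rewindowPeptides(w$peptide, n),
                     label = w$label, stringsAsFactors = FALSE)
  sc <- .knnJackknifeScores(pool$peptide, pool$label, posWeight, k)
  new("KnnModel", enzyme = enzyme(train), halfWidth = as.integer(n),
      k = as.integer(k), posWeight = posWeight, trainWindows = pool,
      auc = computeAuc(sc, pool$label),
      thresholds = thresholdsAtSpecificity(sc, pool$label,
                                           specificityLevels))
}

#' Tune the kNN configuration by jackknife AUC
#'
#' Scans the (window length, positive weight) grid — the published
#' protocol uses lengths 9 to 51 step 2 and weights 1 to 7 step 0.1 —
#' scoring each cell by leave-one-out AUC, and returns the argmax
#' configuration as a fitted model.
#'
#' @param train a [SiteTrainingSet-class].
#' @param lengths odd candidate window lengths.
#' @param weights candidate positive-sample weights.
#' @param k neighbourhood size (default 5).
#' @param specificityLevels specificity levels for stored thresholds.
#' @return list with `model` (a [KnnModel-class]) and `scan`
#'   (data.frame `length`, `posWeight`, `auc`).
#' @export
tuneKnn <- function(train, lengths = seq(9L, 51L, 2L),
                    weights = seq(1, 7, 0.1), k = 5L,
                    specificityLevels = c(0.90, 0.85, 0.80)) {
  stopifnot(all(lengths %% 2L == 1L))
  w <- siteWindows(train)
  scan <- expand.grid(length = lengths, posWeight = weights,
                      KEEP.OUT.ATTRS = FALSE)
  scan$auc <- NA_real_
  for (len in lengths) {
    pep <- rewindowPeptides(w$peptide, (len - 1L) %/% 2L)
    S <- .rawSimMatrix(peptideMatrix(pep), peptideMatrix(pep))
    rows <- which(scan$length == len)
    for (i in rows) {
      sc <- .knnVote(S, w$label, scan$posWeight[i], k,
                     selfIdx = seq_along(pep))
      scan$auc[i] <- computeAuc(sc, w$label)
    }
  }
  best <- which.max(scan$auc)
  model <- knnModel(train, (scan$length[best] - 1L) %/% 2L, k,
                    scan$posWeight[best], specificityLevels)
  list(model = model, scan = scan)
}

#' Published tuned parameter presets for the kNN predictor
#'
#' @param enzyme phosphatase name.
#' @return list with `length`, `posWeight`, `k`.
#' @export
knnPreset <- function(enzyme = ENZYMES) {
  enzyme <- match.arg(enzyme)
  switch(enzyme,
    "PTP1B" = list(length = 23L, posWeight = 2.9, k = 5L),
    "SHP-1" = list(length = 25L, posWeight = 5, k = 5L),
    "SHP-2" = list(length = 39L, posWeight = 6, k = 5L))
}
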