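#' Area under the ROC curve
#'
#' Midrank Mann-Whitney statistic: the probability that a random positive
#' outscores a random negative, ties counting one half. Equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric predictor scores (higher = more positive-like).
#' @param labels `"positive"`/`"negative"` labels (or a logical vector,
#'   `TRUE` = positive).
#' @return AUC in `[0, 1]`.
#' @export
computeAuc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L) {
    stop("AUC requires samples from both classes")
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Empirical ROC curve points
#'
#' Thresholds are enumerated at the observed score values (prediction
#' rule: `score >= t` is called positive), plus the trivial all-negative
#' threshold, giving (FPR, TPR) pairs from (0, 0) to (1, 1).
#'
#' @inheritParams computeAuc
#' @return data.frame with columns `threshold`, `FPR`, `TPR`.
#' @export
rocPointsTable <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / sum(pos),
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / sum(!pos),
                numeric(1))
  data.frame(threshold = thr, FPR = fpr, TPR = tpr)
}

.confusion <- function(scores, labels, threshold) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  call <- scores >= threshold
  c(TP = sum(call & pos), FP = sum(call & !pos),
    TN = sum(!call & !pos), FN = sum(!call & pos))
}

.mcc <- function(cm) {
  cm <- as.numeric(cm)  # avoid integer overflow in the products
  names(cm) <- c("TP", "FP", "TN", "FN")
  TP <- cm["TP"]; FP <- cm["FP"]; TN <- cm["TN"]; FN <- cm["FN"]
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  if (den == 0) return(0)
  unname((TP * TN - FP * FN) / den)
}

#' Operating point at a fixed specificity level
#'
#' Chooses the threshold whose realized specificity is the smallest
#' attainable value at or above `level` (thresholds enumerated at the
#' observed scores plus the all-negative threshold) and reports the
#' realized specificity, sensitivity and Matthews correlation
#' coefficient there.
#'
#' @inheritParams computeAuc
#' @param level target specificity (e.g. 0.90).
#' @return named numeric `c(SPE, SEN, MCC, threshold)`.
#' @export
operatingPoint <- function(scores, labels, level) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  if (!any(pos) || all(pos)) stop("both classes required")
  thr <- c(sort(unique(scores), decreasing = FALSE), Inf)
  spe <- vapply(thr, function(t) {
    cm <- .confusion(scores, labels, t)
    unname(cm["TN"] / (cm["TN"] + cm["FP"]))
  }, numeric(1))
  ok <- which(spe >= level)
  i <- ok[which.min(spe[ok])]
  cm <- .confusion(scores, labels, thr[i])
  c(SPE = unname(spe[i]),
    SEN = unname(cm["TP"] / (cm["TP"] + cm["FN"])),
    MCC = .mcc(cm), threshold = thr[i])
}

#' Operating points at several specificity levels
#'
#' Applies [operatingPoint()] to each level (visited from strictest to
#' loosest). A level whose chosen threshold coincides with the threshold
#' already used for a stricter level is flagged unavailable — the score's
#' granularity cannot distinguish the two levels, as happens for the
#' six-valued kNN scorer.
#'
#' @inheritParams computeAuc
#' @param levels target specificity levels (default 0.90, 0.85, 0.80).
#' @return data.frame with `level`, `SPE`, `SEN`, `MCC`, `threshold`,
#'   `available`.
#' @export
operatingPoints <- function(scores, labels, levels = c(0.90, 0.85, 0.80)) {
  levels <- sort(levels, decreasing = TRUE)
  used <- numeric(0)
  rows <- lapply(levels, function(lv) {
    op <- operatingPoint(scores, labels, lv)
    avail <- !op["threshold"] %in% used
    used <<- c(used, op["threshold"])
    data.frame(level = lv, SPE = op[["SPE"]], SEN = op[["SEN"]],
               MCC = op[["MCC"]], threshold = op[["threshold"]],
               available = avail)
  })
  out <- do.call(rbind, rows)
  out[!out$available, c("SPE", "SEN", "MCC")] <- NA_real_
  out
}

#' Score thresholds realizing given specificity levels
#'
#' @inheritParams operatingPoints
#' @return named numeric vector of thresholds (names = levels).
#' @export
thresholdsAtSpecificity <- function(scores, labels,
                                    levels = c(0.90, 0.85, 0.80)) {
  th <- vapply(levels, function(lv) {
    operatingPoint(scores, labels, lv)[["threshold"]]
  }, numeric(1))
  names(th) <- format(levels, nsmall = 2)
  th
}

.makeEvalReport <- function(protocol, ids, labels, scores, meta = list(),
                            levels = c(0.90, 0.85, 0.80)) {
  new("EvalReport", protocol = protocol,
      scores = data.frame(id = ids, label = labels, score = scores,
                          stringsAsFactors = FALSE),
      rocPoints = rocPointsTable(scores, labels),
      auc = computeAuc(scores, labels),
      operatingPoints = operatingPoints(scores, labels, levels),
      meta = meta)
}

.subsetTrainingSet <- function(train, keep) {
  SiteTrainingSet(enzyme(train), halfWidth(train),
                  siteWindows(train)[keep, , drop = FALSE])
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each sample is scored by a model fitted on all other samples. The
#' protocol is deterministic: the number of folds is the training-set
#' size and no randomness is involved.
#'
#' @param train a [SiteTrainingSet-class].
#' @param fitFun function(train) returning a fitted model.
#' @param scoreFun function(model, peptides) returning numeric scores.
#' @param levels specificity levels for the report's operating points.
#' @return an [EvalReport-class].
#' @export
jackknifeEval <- function(train, fitFun, scoreFun,
                          levels = c(0.90, 0.85, 0.80)) {
  w <- siteWindows(train)
  n <- nrow(w)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    model <- tryCatch(fitFun(.subsetTrainingSet(train, setdiff(seq_len(n),
                                                               i))),
                      error = function(e) {
                        stop(sprintf("training failed on fold %d: %s", i,
                                     conditionMessage(e)))
                      })
    scores[i] <- scoreFun(model, w$peptide[i])
  }
  .makeEvalReport("jackknife", paste(w$protein_id, w$position), w$label,
                  scores, meta = list(n = n), levels = levels)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds, balancing both classes
#' across folds; a fixed seed reproduces the partition exactly.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed for the draw.
#' @return integer fold ids in `1..k`.
#' @export
stratifiedFolds <- function(labels, k, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- length(labels)
  if (k == n) return(sample.int(n))  # definitional limit: leave-one-out
  folds <- integer(n)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    # random fold order per class keeps overall fold sizes balanced when
    # a class has fewer members than there are folds
    folds[idx] <- sample(rep_len(sample.int(k), length(idx)))
  }
  folds
}

#' Repeated stratified k-fold cross validation
#'
#' For each repeat the data are randomly partitioned into `k` stratified
#' folds; each fold is scored by a model fitted on the others, and the
#' repeat's AUC is computed from the pooled out-of-fold scores. Identical
#' seeds reproduce the partitions exactly. With `repeats = 1` and
#' `k = n` this reduces to the jackknife.
#'
#' @inheritParams jackknifeEval
#' @param k number of folds (default 5).
#' @param repeats number of repetitions (default 30).
#' @param seed RNG seed; repeat `r` draws folds with `seed + r - 1`.
#' @return list with `reports` (one [EvalReport-class] per repeat),
#'   `aucs`, `meanAuc`, `sdAuc`.
#' @export
repeatedKfold <- function(train, fitFun, scoreFun, k = 5L, repeats = 30L,
                          seed = 1L, levels = c(0.90, 0.85, 0.80)) {
  w <- siteWindows(train)
  n <- nrow(w)
  if (min(table(w$label)) < 2L) stop("need >= 2 samples per class")
  reports <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- stratifiedFolds(w$label, k, seed = seed + r - 1L)
    scores <- numeric(n)
    for (f in seq_len(k)) {
      hold <- folds == f
      model <- fitFun(.subsetTrainingSet(train, which(!hold)))
      scores[hold] <- scoreFun(model, w$peptide[hold])
    }
    reports[[r]] <- .makeEvalReport(
      "kfold", paste(w$protein_id, w$position), w$label, scores,
      meta = list(k = k, seed = seed + r - 1L, folds = folds),
      levels = levels)
  }
  aucs <- vapply(reports, auc, numeric(1))
  list(reports = reports, aucs = aucs, meanAuc = mean(aucs),
       sdAuc = stats::sd(aucs))
}

#' Complementarity of two predictors
#'
#' Pearson correlation of their cross-validated score vectors over the
#' same samples; the closer |r| is to 1 the weaker the complementarity.
#'
#' @param scoresA,scoresB equal-length numeric score vectors.
#' @return Pearson correlation in `[-1, 1]`, or `NA` (with a warning)
#'   when either vector has zero variance.
#' @export
complementarity <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB)) {
    stop("score vectors must have equal length")
  }
  if (stats::sd(scoresA) == 0 || stats::sd(scoresB) == 0) {
    warning("zero-variance score vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(scoresA, scoresB, method = "pearson")
}

#' Combine predictors with a linear-kernel SVM
#'
#' Fits a linear support-vector classifier on the matrix of component
#' score vectors (one column per predictor, cross-validated scores to
#' avoid leakage); the ensemble score of a sample is the signed distance
#' to the separating hyperplane, oriented so positives score higher.
#'
#' @param scoreMatrix numeric matrix, one column per component predictor.
#' @param labels class labels.
#' @param cost soft-margin cost of the combiner (default 1).
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(scoreMatrix, labels, cost = 1) {
  scoreMatrix <- as.matrix(scoreMatrix)
  if (ncol(scoreMatrix) < 2L) stop("ensemble needs >= 2 score columns")
  sds <- apply(scoreMatrix, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant score column(s): ",
            paste(which(sds == 0), collapse = ", "))
  }
  # standardize the component columns: the predictors emit scores on
  # unrelated scales (mean similarities vs decision values)
  ctr <- colMeans(scoreMatrix)
  scl <- ifelse(sds > 0, sds, 1)
  Z <- sweep(sweep(scoreMatrix, 2L, ctr), 2L, scl, "/")
  # inverse-class-frequency weights: with ~1:14 imbalance an unweighted
  # soft margin collapses to the trivial all-negative solution (w = 0)
  pos <- labels == "positive"
  cw <- c(positive = length(labels) / (2 * sum(pos)),
          negative = length(labels) / (2 * sum(!pos)))
  fit <- .svmFitRaw(Z, labels, gamma = 1, cost = cost, kernel = "linear",
                    classWeights = cw)
  wvec <- drop(crossprod(fit$SV, fit$coefs))
  new("EnsembleModel",
      methods = colnames(scoreMatrix) %||% paste0("m", seq_len(ncol(
        scoreMatrix))),
      weights = wvec, center = unname(ctr), scale = unname(scl),
      bias = -fit$rho, cost = cost, auc = numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score samples with an ensemble model
#'
#' @param model an [EnsembleModel-class].
#' @param scoreMatrix matrix of component scores (columns in model order).
#' @return numeric ensemble scores.
#' @export
ensembleScore <- function(model, scoreMatrix) {
  Z <- sweep(sweep(as.matrix(scoreMatrix), 2L, model@center), 2L,
             model@scale, "/")
  drop(Z %*% model@weights) + model@bias
}

#' Nested-jackknife evaluation of an ensemble
#'
#' Outer leave-one-out over the combiner: each sample's ensemble score
#' comes from a linear SVM fitted on all other samples' component
#' scores, so the combiner never sees the sample it scores. A
#' `naive = TRUE` mode refits once on all samples instead.
#'
#' @inheritParams trainEnsemble
#' @param naive if `TRUE`, skip the outer loop (single refit).
#' @param levels specificity levels for the report.
#' @return an [EvalReport-class].
#' @export
ensembleJackknife <- function(scoreMatrix, labels, cost = 1, naive = FALSE,
                              levels = c(0.90, 0.85, 0.80)) {
  scoreMatrix <- as.matrix(scoreMatrix)
  n <- nrow(scoreMatrix)
  if (naive) {
    model <- trainEnsemble(scoreMatrix, labels, cost)
    scores <- ensembleScore(model, scoreMatrix)
  } else {
    scores <- numeric(n)
    for (i in seq_len(n)) {
      model <- trainEnsemble(scoreMatrix[-i, , drop = FALSE], labels[-i],
                             cost)
      scores[i] <- ensembleScore(model, scoreMatrix[i, , drop = FALSE])
    }
  }
  .makeEvalReport(if (naive) "jackknife-naive" else "jackknife",
                  seq_len(n), labels, scores,
                  meta = list(cost = cost, naive = naive), levels = levels)
}
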