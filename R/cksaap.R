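#' Feature names of the CKSAAP encoding
#'
#' The frozen index map: feature `(k, s1, s2)` sits at position
#' `k * 441 + (i1 - 1) * 21 + i2` (1-based), where `i1`, `i2` index the
#' 21-symbol alphabet `ALPHABET21` (20 residues then `-`).
#'
#' @param kMax maximum pair spacing (default 4).
#' @return character vector of `441 * (kMax + 1)` names like `"k2_AC"`.
#' @export
cksaapFeatureNames <- function(kMax = 4L) {
  unlist(lapply(0:kMax, function(k) {
    outer(ALPHABET21, ALPHABET21,
          function(a, b) sprintf("k%d_%s%s", k, a, b))
  }))
}

#' CKSAAP encoding of peptide windows
#'
#' For each spacing `k = 0..kMax`, counts ordered symbol pairs at
#' positions `(p, p + k + 1)` and divides by the number of such pairs,
#' `L - k - 1` (= `2n - k` for a `2n + 1`-mer). The terminal-gap symbol
#' `-` is a first-class 21st symbol; nonstandard letters fall into an
#' inert bucket whose frequency mass is simply lost. Each k-slice of the
#' resulting vector sums to 1 (up to lost nonstandard mass), giving
#' `441 * (kMax + 1)` features — 2205 for the default `kMax = 4`.
#'
#' @param peptides character vector of equal-length windows.
#' @param kMax maximum spacing; window length must exceed `kMax + 1`.
#' @return numeric matrix, one row per peptide, with
#'   [cksaapFeatureNames()] as column names.
#' @export
cksaapEncode <- function(peptides, kMax = 4L) {
  M <- peptideMatrix(peptides)
  L <- ncol(M)
  if (L <= kMax + 1L) {
    stop(sprintf("window length %d too short for k up to %d", L, kMax))
  }
  nFeat <- 441L * (kMax + 1L)
  out <- matrix(0, nrow(M), nFeat, dimnames = list(NULL,
                cksaapFeatureNames(kMax)))
  for (k in 0:kMax) {
    i1 <- seq_len(L - k - 1L)
    A <- M[, i1, drop = FALSE]
    B <- M[, i1 + k + 1L, drop = FALSE]
    valid <- A <= 21L & B <= 21L
    idx <- k * 441L + (A - 1L) * 21L + B
    idx[!valid] <- NA_integer_
    for (r in seq_len(nrow(M))) {
      v <- idx[r, ]
      v <- v[!is.na(v)]
      if (length(v)) {
        tab <- tabulate(v, nbins = nFeat)
        out[r, ] <- out[r, ] + tab / (L - k - 1L)
      }
    }
  }
  out
}

#' Export a CKSAAP feature matrix
#'
#' @param peptides character vector of windows.
#' @param path output file.
#' @param sparse if `TRUE`, write a triplet format (`row`, `feature`,
#'   `value`); otherwise a dense TSV with feature-name header.
#' @param kMax maximum spacing.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(peptides, path, sparse = FALSE, kMax = 4L) {
  X <- cksaapEncode(peptides, kMax)
  if (sparse) {
    nz <- which(X != 0, arr.ind = TRUE)
    df <- data.frame(row = nz[, 1L], feature = colnames(X)[nz[, 2L]],
                     value = X[nz])
    df <- df[order(df$row, df$feature), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(X), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

.rbfKernel <- function(X, SV, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * tcrossprod(X, SV)
  exp(-gamma * pmax(d2, 0))
}

## Fit a binary SVM and return an explicit decision function,
## sign-oriented so the positive class scores higher.
.svmFitRaw <- function(X, labels, gamma, cost, kernel = "radial",
                       classWeights = NULL) {
  if (length(unique(labels)) < 2L) {
    stop("SVM training requires samples from both classes")
  }
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- factor(labels, levels = SITE_LABELS)
  m <- if (is.null(classWeights)) {
    e1071::svm(x = X, y = y, kernel = kernel, gamma = gamma,
               cost = cost, scale = FALSE)
  } else {
    e1071::svm(x = X, y = y, kernel = kernel, gamma = gamma,
               cost = cost, scale = FALSE, class.weights = classWeights)
  }
  SV <- as.matrix(m$SV)
  coefs <- as.numeric(m$coefs)
  rho <- as.numeric(m$rho)
  K <- if (kernel == "radial") .rbfKernel(X, SV, gamma) else
    tcrossprod(X, SV)
  dec <- drop(K %*% coefs) - rho
  # orient so the positive class scores higher; rank-based (AUC < 0.5)
  # is robust when decision values are nearly one-sided
  if (computeAuc(dec, labels) < 0.5) {
    coefs <- -coefs
    rho <- -rho
  }
  list(SV = SV, coefs = coefs, rho = rho, gamma = gamma, kernel = kernel)
}

.svmDecision <- function(fit, X) {
  K <- if (fit$kernel == "radial") .rbfKernel(X, fit$SV, fit$gamma) else
    tcrossprod(X, fit$SV)
  drop(K %*% fit$coefs) - fit$rho
}

## Mean AUC of repeated stratified k-fold CV on an encoded matrix.
.cvAucMatrix <- function(X, labels, gamma, cost, k = 5L, repeats = 30L,
                        seed = 1L, returnScores = FALSE) {
  n <- length(labels)
  aucs <- numeric(repeats)
  oof <- NULL
  for (r in seq_len(repeats)) {
    folds <- stratifiedFolds(labels, k, seed = seed + r - 1L)
    scores <- numeric(n)
    for (f in seq_len(k)) {
      hold <- folds == f
      fit <- .svmFitRaw(X[!hold, , drop = FALSE], labels[!hold],
                        gamma, cost)
      scores[hold] <- .svmDecision(fit, X[hold, , drop = FALSE])
    }
    aucs[r] <- computeAuc(scores, labels)
    if (r == 1L) oof <- scores
  }
  if (returnScores) list(meanAuc = mean(aucs), aucs = aucs, scores = oof)
  else mean(aucs)
}

#' Train a CKSAAP support-vector model
#'
#' Encodes the training windows with [cksaapEncode()] and grid-searches
#' the RBF kernel parameters (and optionally the peptide length) for the
#' combination maximizing mean AUC over repeated stratified k-fold cross
#' validation. The published protocol scans gamma and C over `2^-10` to
#' `2^10` with 30 repeats of 5-fold CV; reduced grids can be passed for
#' faster runs.
#'
#' @param train a [SiteTrainingSet-class].
#' @param lengths candidate window lengths (default: the set's own).
#' @param gammas,costs RBF parameter grids (powers of two by convention).
#' @param folds,repeats cross-validation shape (default 5-fold, 30x).
#' @param seed RNG seed for the fold draws.
#' @param kMax maximum CKSAAP spacing.
#' @param specificityLevels specificity levels for stored thresholds.
#' @return a [CksaapModel-class].
#' @export
trainCksaap <- function(train, lengths = NULL, gammas = 2^(-10:10),
                        costs = 2^(-10:10), folds = 5L, repeats = 30L,
                        seed = 1L, kMax = 4L,
                        specificityLevels = c(0.90, 0.85, 0.80)) {
  if (is.null(lengths)) lengths <- 2L * halfWidth(train) + 1L
  stopifnot(all(lengths %% 2L == 1L))
  w <- siteWindows(train)
  labels <- w$label
  scan <- expand.grid(length = lengths, gamma = gammas, cost = costs,
                      KEEP.OUT.ATTRS = FALSE)
  scan$auc <- NA_real_
  best <- NULL
  for (len in lengths) {
    X <- cksaapEncode(rewindowPeptides(w$peptide, (len - 1L) %/% 2L), kMax)
    rows <- which(scan$length == len)
    for (i in rows) {
      res <- .cvAucMatrix(X, labels, scan$gamma[i], scan$cost[i],
                          k = folds, repeats = repeats, seed = seed,
                          returnScores = TRUE)
      scan$auc[i] <- res$meanAuc
      if (is.null(best) || res$meanAuc > best$auc) {
        best <- list(auc = res$meanAuc, len = len, gamma = scan$gamma[i],
                     cost = scan$cost[i], scores = res$scores)
      }
    }
  }
  n <- (best$len - 1L) %/% 2L
  X <- cksaapEncode(rewindowPeptides(w$peptide, n), kMax)
  fit <- .svmFitRaw(X, labels, best$gamma, best$cost)
  new("CksaapModel", enzyme = enzyme(train), halfWidth = as.integer(n),
      kMax = as.integer(kMax), gamma = best$gamma, cost = best$cost,
      SV = fit$SV, coefs = fit$coefs, rho = fit$rho, cvAuc = best$auc,
      scanReport = scan,
      thresholds = thresholdsAtSpecificity(best$scores, labels,
                                           specificityLevels))
}

#' Score windows with a CKSAAP SVM model
#'
#' Windows are re-windowed to the model length if needed, encoded, and
#' mapped through the stored decision function (signed distance to the
#' separating hyperplane; higher means more dephosphorylation-site-like).
#'
#' @param model a [CksaapModel-class].
#' @param peptides character vector of windows.
#' @return numeric decision scores.
#' @export
cksaapScore <- function(model, peptides) {
  L <- 2L * model@halfWidth + 1L
  if (length(peptides) == 0L) return(numeric(0))
  if (nchar(peptides[1L]) != L) {
    peptides <- rewindowPeptides(peptides, model@halfWidth)
  }
  if (any(nchar(peptides) != L)) {
    stop("windows could not be re-windowed to the model length")
  }
  X <- cksaapEncode(peptides, model@kMax)
  .svmDecision(list(SV = model@SV, coefs = model@coefs, rho = model@rho,
                    gamma = model@gamma, kernel = "radial"), X)
}

#' Published tuned parameter presets for the CKSAAP predictor
#'
#' @param enzyme phosphatase name.
#' @return list with `length`, `gamma`, `cost`.
#' @export
cksaapPreset <- function(enzyme = ENZYMES) {
  enzyme <- match.arg(enzyme)
  switch(enzyme,
    "PTP1B" = list(length = 45L, gamma = 2^-7, cost = 2^-3),
    "SHP-1" = list(length = 47L, gamma = 2^-9, cost = 2^-2),
    "SHP-2" = list(length = 57L, gamma = 2^-10, cost = 2^-2))
}
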