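## Pairwise position-wise substitution contributions between query and
## reference windows. Rows are (query, reference) pairs in query-major
## order; the center column is hard-set to 1 (the tyrosine-tyrosine
## comparison at the site itself), and '-' or nonstandard symbols score 0
## through the extended substitution table.
.pairSubMatrix <- function(Q, R, center = TRUE) {
  sub <- substitutionMatrix()
  nq <- nrow(Q)
  nr <- nrow(R)
  L <- ncol(Q)
  out <- matrix(0, nq * nr, L)
  qi <- rep(seq_len(nq), each = nr)
  ri <- rep(seq_len(nr), times = nq)
  for (l in seq_len(L)) {
    out[, l] <- sub[(R[ri, l] - 1L) * 22L + Q[qi, l]]
  }
  if (center) out[, (L + 1L) %/% 2L] <- 1
  out
}

#' Position-weighted similarity of two peptide windows
#'
#' `s = sum_i w_i * sub(a_i, b_i)` with the center term contributing
#' `w_center * 1` regardless of the residues, `-` scoring 0 against
#' everything, and the result clipped at 0 (`max(s, 0)`).
#'
#' @param query,reference peptide windows of equal odd length.
#' @param weights numeric position weights of the same length.
#' @return non-negative similarity score.
#' @examples
#' mgpsSimilarity("-Y-", "-Y-", c(1, 7, 1))  # 7
#' @export
mgpsSimilarity <- function(query, reference, weights) {
  if (nchar(query) != nchar(reference)) {
    stop("query and reference windows must have equal length")
  }
  if (length(weights) != nchar(query)) {
    stop("need one weight per window position")
  }
  A <- .pairSubMatrix(peptideMatrix(query), peptideMatrix(reference))
  max(drop(A %*% weights), 0)
}

## Clipped-similarity matrix: nRef x nQuery, entry [r, q] = max(s_rq, 0).
.clippedSimMatrix <- function(Qmat, Rmat, w) {
  A <- .pairSubMatrix(Qmat, Rmat)
  matrix(pmax(drop(A %*% w), 0), nrow = nrow(Rmat), ncol = nrow(Qmat))
}

#' Score windows with an MGPS model
#'
#' The score of a query is the mean of its zero-clipped position-weighted
#' similarities to all positive reference windows. When `exclude` is
#' given, one matching reference is removed first (leave-one-out scoring
#' of a training positive).
#'
#' @param model an [MgpsModel-class].
#' @param peptides character vector of query windows (model length).
#' @param exclude optional single reference peptide to omit.
#' @param averageNonzero if `TRUE`, average only over references with a
#'   positive clipped similarity (the stricter nearest-neighbour reading);
#'   default `FALSE` averages over all references, zeros included.
#' @return numeric scores, one per query.
#' @export
mgpsScore <- function(model, peptides, exclude = NULL,
                      averageNonzero = FALSE) {
  refs <- model@refPositives
  if (!is.null(exclude)) {
    hit <- match(exclude, refs)
    if (!is.na(hit)) refs <- refs[-hit]
  }
  if (length(refs) == 0L) {
    stop("MGPS model has no effective reference positives")
  }
  L <- 2L * model@halfWidth + 1L
  if (any(nchar(peptides) != L)) {
    stop(sprintf("query windows must have the model length %d", L))
  }
  S <- .clippedSimMatrix(peptideMatrix(peptides), peptideMatrix(refs),
                         model@weights)
  if (averageNonzero) {
    apply(S, 2L, function(col) {
      nz <- col[col > 0]
      if (length(nz)) mean(nz) else 0
    })
  } else {
    colMeans(S)
  }
}

## Precomputed pair-contribution matrices for fast jackknife AUC during
## weight training: only the weight vector changes between evaluations.
.mgpsPrecompute <- function(posPep, negPep) {
  P <- peptideMatrix(posPep)
  N <- peptideMatrix(negPep)
  list(Apos = .pairSubMatrix(P, P), Aneg = .pairSubMatrix(N, P),
       npos = nrow(P), nneg = nrow(N))
}

## Jackknife scores under weights w: each positive is scored against the
## other positives (self excluded); negatives against all positives.
.mgpsJackknifeScores <- function(pre, w) {
  Spos <- matrix(pmax(drop(pre$Apos %*% w), 0), pre$npos, pre$npos)
  posScores <- (colSums(Spos) - diag(Spos)) / (pre$npos - 1L)
  Sneg <- matrix(pmax(drop(pre$Aneg %*% w), 0), pre$npos, pre$nneg)
  negScores <- colMeans(Sneg)
  list(pos = posScores, neg = negScores)
}

.mgpsJackknifeAuc <- function(pre, w) {
  sc <- .mgpsJackknifeScores(pre, w)
  computeAuc(c(sc$pos, sc$neg),
             rep(c("positive", "negative"), c(pre$npos, pre$nneg)))
}

#' Train MGPS position weights by AUC hill climbing
#'
#' Initializes the center weight to 7 (the BLOSUM62 tyrosine self-score)
#' and all other weights to 1, then sweeps positions left to right, trying
#' `w_i + 1` and `w_i - 1` (the decrement only where the result stays
#' `>= 0`, except at the unconstrained center) and accepting the candidate
#' with the highest jackknife AUC only on strict improvement (ties keep
#' the incumbent; among tied candidates the increment is preferred). Full
#' sweeps repeat until one passes with no accepted move.
#'
#' @param train a [SiteTrainingSet-class] (>= 2 positives).
#' @param n half-width to train at; windows are re-windowed if needed.
#'   Defaults to the training set's own width.
#' @param maxSweeps safety cap on full sweeps (default 50).
#' @return list with `weights`, `trace` (accepted moves with their AUC;
#'   first row records the initial state), and `auc`.
#' @export
trainMgpsWeights <- function(train, n = NULL, maxSweeps = 50L) {
  if (is.null(n)) n <- halfWidth(train)
  posPep <- rewindowPeptides(positives(train), n)
  negPep <- rewindowPeptides(negatives(train), n)
  if (length(posPep) < 2L) stop("need >= 2 positive windows to train")
  L <- 2L * n + 1L
  ctr <- n + 1L
  pre <- .mgpsPrecompute(posPep, negPep)

  w <- rep(1, L)
  w[ctr] <- 7
  sc0 <- .mgpsJackknifeScores(pre, w)
  if (length(unique(round(c(sc0$pos, sc0$neg), 12))) == 1L) {
    warning("all jackknife scores tied at initialization; ",
            "returning initial weights")
    tr <- data.frame(position = 0L, weight = NA_real_, auc = 0.5)
    return(list(weights = w, trace = tr, auc = 0.5))
  }
  a <- computeAuc(c(sc0$pos, sc0$neg),
                  rep(c("positive", "negative"), c(pre$npos, pre$nneg)))
  trace <- data.frame(position = 0L, weight = NA_real_, auc = a)

  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    for (i in seq_len(L)) {
      w1 <- w; w1[i] <- w[i] + 1
      a1 <- .mgpsJackknifeAuc(pre, w1)
      if (i == ctr || w[i] - 1 >= 0) {
        w2 <- w; w2[i] <- w[i] - 1
        a2 <- .mgpsJackknifeAuc(pre, w2)
      } else {
        a2 <- -1
      }
      if (max(a1, a2) > a) {
        if (a1 >= a2) {  # prefer the increment on ties
          w <- w1; a <- a1
        } else {
          w <- w2; a <- a2
        }
        improved <- TRUE
        trace <- rbind(trace, data.frame(position = i, weight = w[i],
                                         auc = a))
      }
    }
    if (!improved) break
  }
  list(weights = w, trace = trace, auc = a)
}

#' Train an MGPS model
#'
#' Runs [trainMgpsWeights()] at the requested half-width and packages the
#' result with the positive reference windows, the training trace, the
#' jackknife AUC and the score thresholds at the configured specificity
#' levels (taken from the training jackknife score distribution).
#'
#' @inheritParams trainMgpsWeights
#' @param specificityLevels specificity levels for stored thresholds.
#' @return an [MgpsModel-class].
#' @export
trainMgps <- function(train, n = NULL, maxSweeps = 50L,
                      specificityLevels = c(0.90, 0.85, 0.80)) {
  if (is.null(n)) n <- halfWidth(train)
  fit <- trainMgpsWeights(train, n, maxSweeps)
  refs <- rewindowPeptides(positives(train), n)
  model <- new("MgpsModel", enzyme = enzyme(train), halfWidth = as.integer(n),
               weights = fit$weights, refPositives = refs,
               trace = fit$trace, auc = fit$auc, thresholds = numeric(0))
  sc <- .mgpsJackknifeScores(.mgpsPrecompute(
    refs, rewindowPeptides(negatives(train), n)), fit$weights)
  labels <- rep(c("positive", "negative"),
                c(length(sc$pos), length(sc$neg)))
  model@thresholds <- thresholdsAtSpecificity(c(sc$pos, sc$neg), labels,
                                              specificityLevels)
  model
}

#' Build an MGPS model from fixed weights
#'
#' Wraps an externally supplied weight vector (for example a published
#' tuned parameter row) with a reference-positive set for scoring without
#' retraining.
#'
#' @param enzyme phosphatase name.
#' @param weights numeric position weights (odd length).
#' @param refPositives character vector of reference positive windows of
#'   the same length.
#' @return an [MgpsModel-class].
#' @export
mgpsModelFromWeights <- function(enzyme, weights, refPositives) {
  L <- length(weights)
  stopifnot(L %% 2L == 1L)
  new("MgpsModel", enzyme = enzyme, halfWidth = as.integer((L - 1L) / 2L),
      weights = as.numeric(weights),
      refPositives = rewindowPeptides(refPositives, (L - 1L) %/% 2L),
      trace = data.frame(position = integer(0), weight = numeric(0),
                         auc = numeric(0)),
      auc = numeric(0), thresholds = numeric(0))
}

#' Select the MGPS peptide length
#'
#' Trains position weights at each candidate length (windows re-windowed
#' symmetrically) and returns the model for the length with maximal
#' post-training jackknife AUC (ties resolved toward the shorter length).
#'
#' @inheritParams trainMgps
#' @param lengths odd candidate window lengths (default 9 to 61 step 2).
#' @return list with `model` (an [MgpsModel-class]) and `scan`
#'   (data.frame `length`, `auc`).
#' @export
selectMgpsLength <- function(train, lengths = seq(9L, 61L, 2L),
                             maxSweeps = 50L,
                             specificityLevels = c(0.90, 0.85, 0.80)) {
  if (length(lengths) == 0L) stop("no candidate lengths supplied")
  stopifnot(all(lengths %% 2L == 1L))
  fits <- lapply(lengths, function(len) {
    trainMgpsWeights(train, (len - 1L) %/% 2L, maxSweeps)
  })
  aucs <- vapply(fits, `[[`, numeric(1), "auc")
  best <- which.max(aucs)
  model <- trainMgps(train, (lengths[best] - 1L) %/% 2L, maxSweeps,
                     specificityLevels)
  list(model = model, scan = data.frame(length = lengths, auc = aucs))
}
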