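#' Score peptide windows with any trained model
#'
#' @param model a trained predictor ([MgpsModel-class],
#'   [CksaapModel-class] or [KnnModel-class]).
#' @param peptides character vector of peptide windows; re-windowed to
#'   the model's length when necessary.
#' @param ... passed to the class-specific scorer.
#' @return numeric scores, higher = more dephosphorylation-site-like.
#' @export
setGeneric("scoreWindows",
           function(model, peptides, ...) standardGeneric("scoreWindows"))

#' @rdname scoreWindows
#' @export
setMethod("scoreWindows", "MgpsModel", function(model, peptides, ...) {
  mgpsScore(model, rewindowPeptides(peptides, model@halfWidth), ...)
})

#' @rdname scoreWindows
#' @export
setMethod("scoreWindows", "CksaapModel", function(model, peptides, ...) {
  cksaapScore(model, peptides)
})

#' @rdname scoreWindows
#' @export
setMethod("scoreWindows", "KnnModel", function(model, peptides, ...) {
  knnScore(model, peptides)
})

#' Scan proteins for candidate dephosphorylation sites
#'
#' Windows every tyrosine of every input sequence at each model's
#' peptide length, scores it, and emits one row per (site, model) with
#' the score and a call at each stored specificity level. Calls are
#' nested: a site flagged at 90% specificity is also flagged at 85% and
#' 80%.
#'
#' @param models a single model or named list of trained models.
#' @param sequences named character vector of protein sequences, or a
#'   FASTA path.
#' @return data.frame `protein_id`, `position`, `peptide`, `method`,
#'   `score`, plus one logical `call_<level>` column per stored level.
#' @export
predictSites <- function(models, sequences) {
  if (!is.list(models)) models <- list(model = models)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, function(m) class(m)[1L], character(1))
  }
  if (length(sequences) == 1L && file.exists(sequences[1L])) {
    sequences <- .readFastaNamed(sequences)
  }
  rows <- list()
  for (id in names(sequences)) {
    ypos <- which(strsplit(toupper(sequences[[id]]), "",
                           fixed = TRUE)[[1L]] == "Y")
    if (!length(ypos)) {
      message("no tyrosine residues in ", id)
      next
    }
    for (mName in names(models)) {
      m <- models[[mName]]
      pep <- vapply(ypos, function(p) {
        extractWindow(sequences[[id]], p, m@halfWidth)
      }, character(1))
      sc <- scoreWindows(m, pep)
      df <- data.frame(protein_id = id, position = ypos, peptide = pep,
                       method = mName, score = sc,
                       stringsAsFactors = FALSE)
      for (lv in names(m@thresholds)) {
        df[[paste0("call_", trimws(lv))]] <- sc >= m@thresholds[[lv]]
      }
      rows[[length(rows) + 1L]] <- df
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      peptide = character(0), method = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Evaluate a predictor under a cross-validation protocol
#'
#' Runs the jackknife or repeated stratified k-fold protocol for one of
#' the three predictors. Hyperparameters are fixed globally (supplied or
#' defaults) and per-fold scoring refits the model parts that depend on
#' the training samples: the MGPS reference set drops the held-out
#' positive, the kNN pool drops the held-out sample, and the SVM is
#' refitted per fold.
#'
#' @param train a [SiteTrainingSet-class].
#' @param method `"mgps"`, `"cksaap"` or `"knn"`.
#' @param protocol `"jackknife"` or `"kfold"`.
#' @param k,repeats,seed k-fold shape (default 5-fold, 30 repeats).
#' @param mgpsWeights optional fixed MGPS weight vector (otherwise
#'   trained on the full set by hill climbing).
#' @param gamma,cost CKSAAP SVM parameters (default the sensible middle
#'   of the scanned grid, `2^-7` and `2^-3`).
#' @param knnK,posWeight kNN configuration.
#' @param levels specificity levels for the report.
#' @return an [EvalReport-class] for the jackknife, or the
#'   [repeatedKfold()] list for the k-fold protocol.
#' @export
evaluatePredictor <- function(train, method = c("mgps", "cksaap", "knn"),
                              protocol = c("jackknife", "kfold"), k = 5L,
                              repeats = 30L, seed = 1L,
                              mgpsWeights = NULL, gamma = 2^-7,
                              cost = 2^-3, knnK = 5L, posWeight = 1,
                              levels = c(0.90, 0.85, 0.80)) {
  method <- match.arg(method)
  protocol <- match.arg(protocol)
  w <- siteWindows(train)

  if (method == "mgps") {
    wt <- mgpsWeights %||% trainMgpsWeights(train)$weights
    if (protocol == "jackknife") {
      pre <- .mgpsPrecompute(positives(train), negatives(train))
      sc <- .mgpsJackknifeScores(pre, wt)
      ord <- c(which(w$label == "positive"), which(w$label == "negative"))
      scores <- numeric(nrow(w))
      scores[ord] <- c(sc$pos, sc$neg)
      return(.makeEvalReport("jackknife", paste(w$protein_id, w$position),
                             w$label, scores, meta = list(method = method),
                             levels = levels))
    }
    fitFun <- function(tr) mgpsModelFromWeights(enzyme(tr), wt,
                                                positives(tr))
    scoreFun <- function(m, pep) mgpsScore(m, pep)
  } else if (method == "knn") {
    if (protocol == "jackknife") {
      sc <- .knnJackknifeScores(w$peptide, w$label, posWeight, knnK)
      return(.makeEvalReport("jackknife", paste(w$protein_id, w$position),
                             w$label, sc, meta = list(method = method),
                             levels = levels))
    }
    fitFun <- function(tr) knnModel(tr, k = knnK, posWeight = posWeight)
    scoreFun <- function(m, pep) knnScore(m, pep)
  } else {
    fitFun <- function(tr) {
      X <- cksaapEncode(siteWindows(tr)$peptide)
      fit <- .svmFitRaw(X, siteWindows(tr)$label, gamma, cost)
      structure(fit, class = "cksaapFit")
    }
    scoreFun <- function(m, pep) .svmDecision(m, cksaapEncode(pep))
    if (protocol == "jackknife") {
      return(jackknifeEval(train, fitFun, scoreFun, levels))
    }
  }
  if (protocol == "jackknife") {
    jackknifeEval(train, fitFun, scoreFun, levels)
  } else {
    repeatedKfold(train, fitFun, scoreFun, k = k, repeats = repeats,
                  seed = seed, levels = levels)
  }
}
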