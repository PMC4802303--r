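ENZYMES <- c("PTP1B", "SHP-1", "SHP-2")
SITE_LABELS <- c("positive", "negative")

.checkWindowStrings <- function(peptide, width = NULL, strictCenter = TRUE) {
  if (length(peptide) == 0L) return(TRUE)
  lens <- nchar(peptide)
  if (length(unique(lens)) != 1L) {
    return("all peptide windows must have identical length")
  }
  L <- lens[1L]
  if (L %% 2L != 1L) return("window length must be odd (2n+1)")
  if (!is.null(width) && L != width) {
    return(sprintf("window length %d does not match 2n+1 = %d", L, width))
  }
  if (strictCenter) {
    ctr <- substr(peptide, (L + 1L) %/% 2L, (L + 1L) %/% 2L)
    if (any(ctr != "Y")) {
      bad <- which(ctr != "Y")[1L]
      return(sprintf("window %d has non-Y center '%s'", bad, ctr[bad]))
    }
  }
  # '-' only as a contiguous prefix and/or suffix
  core <- gsub("^-*", "", gsub("-*$", "", peptide))
  if (any(grepl("-", core, fixed = TRUE))) {
    return("'-' may only appear as a contiguous prefix and/or suffix")
  }
  TRUE
}

#' @name SiteTrainingSet-class
#' @title Training set of labelled tyrosine-centered peptide windows
#'
#' @description Holds the positive (experimentally dephosphorylated) and
#' negative (other tyrosine) windows of one phosphatase, all of width
#' `2n + 1` with the candidate tyrosine at the center and terminal
#' shortfalls padded with `-`.
#'
#' @slot enzyme character, one of `"PTP1B"`, `"SHP-1"`, `"SHP-2"`.
#' @slot halfWidth integer `n`; windows have `2n + 1` residues.
#' @slot windows data.frame with columns `peptide`, `label`
#'   (`"positive"`/`"negative"`), `protein_id`, `position` (1-based).
#' @exportClass SiteTrainingSet
setClass("SiteTrainingSet",
         representation(enzyme = "character",
                        halfWidth = "integer",
                        windows = "data.frame"))

setValidity("SiteTrainingSet", function(object) {
  w <- object@windows
  need <- c("peptide", "label", "protein_id", "position")
  if (!all(need %in% names(w))) {
    return(paste("windows must have columns", paste(need, collapse = ", ")))
  }
  if (length(object@enzyme) != 1L || !object@enzyme %in% ENZYMES) {
    return(paste("enzyme must be one of", paste(ENZYMES, collapse = ", ")))
  }
  if (length(object@halfWidth) != 1L || object@halfWidth < 1L) {
    return("halfWidth must be a positive integer")
  }
  if (!all(w$label %in% SITE_LABELS)) {
    return("labels must be 'positive' or 'negative'")
  }
  .checkWindowStrings(w$peptide, width = 2L * object@halfWidth + 1L)
})

#' Construct a SiteTrainingSet
#'
#' @param enzyme phosphatase name.
#' @param halfWidth window half-width `n`.
#' @param windows data.frame with columns `peptide`, `label`, `protein_id`,
#'   `position`.
#' @return a [SiteTrainingSet-class] object.
#' @export
SiteTrainingSet <- function(enzyme, halfWidth, windows) {
  windows$peptide <- as.character(windows$peptide)
  windows$label <- as.character(windows$label)
  windows$protein_id <- as.character(windows$protein_id)
  windows$position <- as.integer(windows$position)
  rownames(windows) <- NULL
  new("SiteTrainingSet", enzyme = enzyme,
      halfWidth = as.integer(halfWidth), windows = windows)
}

#' @describeIn SiteTrainingSet-class phosphatase name.
#' @param x,object a `SiteTrainingSet`.
#' @export
setGeneric("enzyme", function(x) standardGeneric("enzyme"))
#' @export
setMethod("enzyme", "SiteTrainingSet", function(x) x@enzyme)

#' @describeIn SiteTrainingSet-class window half-width `n`.
#' @export
setGeneric("halfWidth", function(x) standardGeneric("halfWidth"))
#' @export
setMethod("halfWidth", "SiteTrainingSet", function(x) x@halfWidth)

#' @describeIn SiteTrainingSet-class full windows table.
#' @export
siteWindows <- function(x) x@windows

#' @describeIn SiteTrainingSet-class positive peptide windows.
#' @export
positives <- function(x) x@windows$peptide[x@windows$label == "positive"]

#' @describeIn SiteTrainingSet-class negative peptide windows.
#' @export
negatives <- function(x) x@windows$peptide[x@windows$label == "negative"]

setMethod("show", "SiteTrainingSet", function(object) {
  cat(sprintf("SiteTrainingSet (%s): %d positives, %d negatives, window %d\n",
              object@enzyme, length(positives(object)),
              length(negatives(object)), 2L * object@halfWidth + 1L))
})

#' @name MgpsModel-class
#' @title Position-weighted BLOSUM similarity scorer
#'
#' @description A query window is scored by its mean zero-clipped
#' position-weighted BLOSUM62 similarity to all positive training windows;
#' the per-position weights are trained by AUC-driven hill climbing.
#'
#' @slot enzyme phosphatase name.
#' @slot halfWidth window half-width `n`.
#' @slot weights numeric vector of `2n + 1` position weights; all
#'   non-center weights are `>= 0`, the center weight is unconstrained.
#' @slot refPositives character vector of positive reference windows.
#' @slot trace data.frame of accepted hill-climb moves
#'   (`position`, `weight`, `auc`); AUC is non-decreasing.
#' @slot auc jackknife AUC of the trained model on its training set.
#' @slot thresholds named numeric score thresholds at the configured
#'   specificity levels (taken from training jackknife scores).
#' @exportClass MgpsModel
setClass("MgpsModel",
         representation(enzyme = "character", halfWidth = "integer",
                        weights = "numeric", refPositives = "character",
                        trace = "data.frame", auc = "numeric",
                        thresholds = "numeric"))

setValidity("MgpsModel", function(object) {
  L <- 2L * object@halfWidth + 1L
  if (length(object@weights) != L) {
    return(sprintf("need %d position weights, got %d", L,
                   length(object@weights)))
  }
  ctr <- object@halfWidth + 1L
  if (any(object@weights[-ctr] < 0)) {
    return("non-center position weights must be >= 0")
  }
  if (nrow(object@trace) > 0L && is.unsorted(object@trace$auc)) {
    return("training trace AUC must be non-decreasing")
  }
  .checkWindowStrings(object@refPositives, width = L, strictCenter = FALSE)
})

setMethod("show", "MgpsModel", function(object) {
  cat(sprintf(
    "MgpsModel (%s): window %d, %d reference positives, jackknife AUC %.3f\n",
    object@enzyme, 2L * object@halfWidth + 1L,
    length(object@refPositives),
    if (length(object@auc)) object@auc else NA_real_))
})

#' @describeIn MgpsModel-class trained position weights.
#' @param x an `MgpsModel`.
#' @export
positionWeights <- function(x) x@weights

#' @describeIn MgpsModel-class hill-climb trace of accepted moves.
#' @export
trainingTrace <- function(x) x@trace

#' @export
setMethod("halfWidth", "MgpsModel", function(x) x@halfWidth)
#' @export
setMethod("enzyme", "MgpsModel", function(x) x@enzyme)

#' @name CksaapModel-class
#' @title RBF-kernel SVM on the CKSAAP encoding
#'
#' @description Support-vector classifier over the 2205-dimensional
#' composition of k-spaced amino-acid pairs (k = 0..4, 21-symbol alphabet).
#' The decision function is stored explicitly (support vectors, dual
#' coefficients, offset) so that models serialize to JSON and scoring does
#' not depend on the solver object.
#'
#' @slot enzyme phosphatase name.
#' @slot halfWidth window half-width of the encoded peptides.
#' @slot kMax maximum pair spacing (default 4).
#' @slot gamma,cost tuned RBF kernel parameters.
#' @slot SV support-vector feature matrix.
#' @slot coefs dual coefficients (sign-oriented so positives score higher).
#' @slot rho decision-function offset.
#' @slot cvAuc cross-validated AUC at the selected parameters.
#' @slot scanReport grid-search report (length, gamma, cost, mean AUC).
#' @slot thresholds named numeric score thresholds at specificity levels.
#' @exportClass CksaapModel
setClass("CksaapModel",
         representation(enzyme = "character", halfWidth = "integer",
                        kMax = "integer", gamma = "numeric", cost = "numeric",
                        SV = "matrix", coefs = "numeric", rho = "numeric",
                        cvAuc = "numeric", scanReport = "data.frame",
                        thresholds = "numeric"))

setValidity("CksaapModel", function(object) {
  if (nrow(object@SV) != length(object@coefs)) {
    return("one dual coefficient per support vector required")
  }
  if (object@gamma <= 0 || object@cost <= 0) {
    return("gamma and cost must be positive")
  }
  TRUE
})

setMethod("show", "CksaapModel", function(object) {
  cat(sprintf(
    "CksaapModel (%s): window %d, gamma 2^%g, C 2^%g, %d SVs, CV AUC %.3f\n",
    object@enzyme, 2L * object@halfWidth + 1L, log2(object@gamma),
    log2(object@cost), nrow(object@SV),
    if (length(object@cvAuc)) object@cvAuc else NA_real_))
})

#' @export
setMethod("halfWidth", "CksaapModel", function(x) x@halfWidth)
#' @export
setMethod("enzyme", "CksaapModel", function(x) x@enzyme)

#' @name KnnModel-class
#' @title BLOSUM62 k-nearest-neighbour baseline
#'
#' @description Scores a query window by the fraction of positives among its
#' top-k training neighbours under raw BLOSUM62 similarity, with
#' positive-sample similarities multiplied by a class weight.
#'
#' @slot enzyme phosphatase name.
#' @slot halfWidth window half-width.
#' @slot k neighbourhood size (default 5).
#' @slot posWeight multiplier applied to positive-sample similarities.
#' @slot trainWindows data.frame (`peptide`, `label`) of the ranked pool.
#' @slot auc jackknife AUC at the tuned configuration.
#' @slot thresholds named numeric score thresholds at specificity levels.
#' @exportClass KnnModel
setClass("KnnModel",
         representation(enzyme = "character", halfWidth = "integer",
                        k = "integer", posWeight = "numeric",
                        trainWindows = "data.frame", auc = "numeric",
                        thresholds = "numeric"))

setValidity("KnnModel", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (object@posWeight < 1) return("positive weight must be >= 1")
  if (object@k > nrow(object@trainWindows)) {
    return("k exceeds the training-set size")
  }
  TRUE
})

setMethod("show", "KnnModel", function(object) {
  cat(sprintf("KnnModel (%s): window %d, k = %d, positive weight %.1f\n",
              object@enzyme, 2L * object@halfWidth + 1L, object@k,
              object@posWeight))
})

#' @export
setMethod("halfWidth", "KnnModel", function(x) x@halfWidth)
#' @export
setMethod("enzyme", "KnnModel", function(x) x@enzyme)

#' @name EnsembleModel-class
#' @title Linear combination of predictor scores
#'
#' @description A linear-kernel support-vector classifier fitted on the
#' component predictors' cross-validated score vectors; the ensemble score
#' is the signed distance to the separating hyperplane.
#'
#' @slot methods character names of the component predictors (>= 2).
#' @slot weights linear combination weights, one per component (applied
#'   to standardized component scores).
#' @slot center,scale per-component standardization parameters learned
#'   from the combiner's training scores.
#' @slot bias intercept of the decision function.
#' @slot cost soft-margin cost used for the combiner.
#' @slot auc nested-jackknife AUC of the ensemble, when evaluated.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
         representation(methods = "character", weights = "numeric",
                        center = "numeric", scale = "numeric",
                        bias = "numeric", cost = "numeric",
                        auc = "numeric"))

setValidity("EnsembleModel", function(object) {
  if (length(object@methods) < 2L) return("ensemble needs >= 2 components")
  if (length(object@weights) != length(object@methods)) {
    return("one weight per component required")
  }
  TRUE
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %s; weights %s\n",
              paste(object@methods, collapse = " + "),
              paste(signif(object@weights, 3), collapse = ", ")))
})

#' @name EvalReport-class
#' @title Evaluation report for one protocol run
#'
#' @slot protocol `"jackknife"` or `"kfold"`.
#' @slot scores data.frame with per-sample `id`, `label`, `score` (and
#'   `fold`/`repeat` for k-fold).
#' @slot rocPoints data.frame of (FPR, TPR) pairs of the empirical ROC.
#' @slot auc area under the ROC curve (midrank Mann-Whitney).
#' @slot operatingPoints data.frame with one row per specificity level:
#'   `level`, `SPE`, `SEN`, `MCC`, `available`.
#' @slot meta list: seed, k, repeats, per-repeat AUCs, etc.
#' @exportClass EvalReport
setClass("EvalReport",
         representation(protocol = "character", scores = "data.frame",
                        rocPoints = "data.frame", auc = "numeric",
                        operatingPoints = "data.frame", meta = "list"))

setValidity("EvalReport", function(object) {
  if (length(object@auc) && (object@auc < 0 || object@auc > 1)) {
    return("AUC must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (%s): %d samples, AUC %.3f\n", object@protocol,
              nrow(object@scores), object@auc))
})

#' @describeIn EvalReport-class area under the ROC curve.
#' @param x an `EvalReport`.
#' @export
auc <- function(x) x@auc

#' @describeIn EvalReport-class per-sample score table.
#' @export
sampleScores <- function(x) x@scores

#' @describeIn EvalReport-class operating points at the fixed specificity
#'   levels.
#' @export
operatingPointTable <- function(x) x@operatingPoints

#' @describeIn EvalReport-class ROC curve points (FPR, TPR).
#' @export
rocCurve <- function(x) x@rocPoints
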