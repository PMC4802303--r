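.pkgVersion <- function() as.character(utils::packageVersion("dephossite"))

#' Save a model to JSON
#'
#' All four model classes serialize to a self-contained JSON file
#' (class tag, tool version, enzyme, window, parameters, reference
#' peptides or support vectors, training trace, specificity thresholds),
#' so published weight vectors can be loaded for scoring without
#' retraining and SVM models round-trip exactly.
#'
#' @param model an [MgpsModel-class], [CksaapModel-class],
#'   [KnnModel-class] or [EnsembleModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  obj <- list(tool = "dephossite", version = .pkgVersion(),
              class = class(model)[1L])
  slots <- switch(class(model)[1L],
    MgpsModel = list(enzyme = model@enzyme, halfWidth = model@halfWidth,
                     weights = model@weights,
                     refPositives = model@refPositives,
                     trace = model@trace, auc = model@auc,
                     thresholds = as.list(model@thresholds)),
    CksaapModel = list(enzyme = model@enzyme, halfWidth = model@halfWidth,
                       kMax = model@kMax, gamma = model@gamma,
                       cost = model@cost, SV = model@SV,
                       coefs = model@coefs, rho = model@rho,
                       cvAuc = model@cvAuc,
                       thresholds = as.list(model@thresholds)),
    KnnModel = list(enzyme = model@enzyme, halfWidth = model@halfWidth,
                    k = model@k, posWeight = model@posWeight,
                    trainWindows = model@trainWindows, auc = model@auc,
                    thresholds = as.list(model@thresholds)),
    EnsembleModel = list(methods = model@methods, weights = model@weights,
                         center = model@center, scale = model@scale,
                         bias = model@bias, cost = model@cost,
                         auc = model@auc),
    stop("unsupported model class: ", class(model)[1L]))
  jsonlite::write_json(c(obj, slots), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model from JSON
#'
#' @param path file written by [saveModel()].
#' @return the reconstructed model object.
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- function() {
    if (length(obj$thresholds)) unlist(obj$thresholds) else numeric(0)
  }
  switch(obj$class,
    MgpsModel = new("MgpsModel", enzyme = obj$enzyme,
                    halfWidth = as.integer(obj$halfWidth),
                    weights = as.numeric(obj$weights),
                    refPositives = as.character(obj$refPositives),
                    trace = as.data.frame(obj$trace),
                    auc = as.numeric(obj$auc %||% numeric(0)),
                    thresholds = thr()),
    CksaapModel = new("CksaapModel", enzyme = obj$enzyme,
                      halfWidth = as.integer(obj$halfWidth),
                      kMax = as.integer(obj$kMax),
                      gamma = obj$gamma, cost = obj$cost,
                      SV = as.matrix(obj$SV),
                      coefs = as.numeric(obj$coefs), rho = obj$rho,
                      cvAuc = as.numeric(obj$cvAuc %||% numeric(0)),
                      scanReport = data.frame(), thresholds = thr()),
    KnnModel = new("KnnModel", enzyme = obj$enzyme,
                   halfWidth = as.integer(obj$halfWidth),
                   k = as.integer(obj$k), posWeight = obj$posWeight,
                   trainWindows = as.data.frame(obj$trainWindows),
                   auc = as.numeric(obj$auc %||% numeric(0)),
                   thresholds = thr()),
    EnsembleModel = new("EnsembleModel", methods = obj$methods,
                        weights = as.numeric(obj$weights),
                        center = as.numeric(obj$center),
                        scale = as.numeric(obj$scale),
                        bias = obj$bias, cost = obj$cost,
                        auc = as.numeric(obj$auc %||% numeric(0))),
    stop("unrecognized model file: ", path))
}

#' Write an evaluation report
#'
#' Flat TSV of per-sample scores plus commented provenance/header lines
#' (tool version, protocol, AUC, operating points); the ROC points go to
#' a sibling `<path>.roc.csv`.
#'
#' @param report an [EvalReport-class].
#' @param path output TSV path.
#' @param seed seed recorded in the provenance header (optional).
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path, seed = NA) {
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(c(
    sprintf("# dephossite %s", .pkgVersion()),
    sprintf("# protocol=%s seed=%s", report@protocol, seed),
    sprintf("# auc=%.6f", report@auc),
    paste0("# operating_points: ",
           paste(apply(report@operatingPoints, 1L, function(r) {
             sprintf("level=%s SPE=%s SEN=%s MCC=%s", r[["level"]],
                     r[["SPE"]], r[["SEN"]], r[["MCC"]])
           }), collapse = "; "))), con)
  utils::write.table(report@scores, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  utils::write.table(report@rocPoints, paste0(path, ".roc.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
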