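#' Save a trained model
#'
#' Writes a single versioned JSON file embedding the scaler, the SVM dual
#' solution (support vectors, alpha*y coefficients, rho), the Platt
#' calibration parameters and the feature configuration. Numeric payloads
#' are stored as 17-significant-digit decimal strings so that a save/load
#' round trip reproduces predictions bit-exactly.
#'
#' @param model a `linc_model` from [train_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "linc_model"))
  num <- function(x) sprintf("%.17g", as.numeric(x))
  obj <- list(
    format = "lincsvm_model",
    version = model$version,
    feature_config = list(kmers = model$config$kmers,
                          use_conservation = model$config$use_conservation,
                          feature_order = model$config$feature_order),
    scaler = list(features = model$scaler$features,
                  min = num(model$scaler$min), max = num(model$scaler$max)),
    svm = list(C = num(model$svm$C), gamma = num(model$svm$gamma),
               rho = num(model$svm$rho), n_sv = nrow(model$svm$sv),
               coef = num(model$svm$coef), sv = num(as.numeric(model$svm$sv))),
    platt = list(A = num(model$platt$A), B = num(model$platt$B)),
    labels = model$labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a trained model
#'
#' Rejects files whose format or version tag is unknown.
#'
#' @param path path written by [save_model()].
#' @return A `linc_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse model file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!identical(obj$format, "lincsvm_model")) {
    stop("not a lincsvm model file: ", path, call. = FALSE)
  }
  if (!identical(as.integer(obj$version), 1L)) {
    stop("unsupported model file version '", obj$version,
         "' (this build reads version 1)", call. = FALSE)
  }
  required <- c("feature_config", "scaler", "svm", "platt", "labels")
  if (!all(required %in% names(obj))) {
    stop("truncated model file '", path, "': missing ",
         paste(setdiff(required, names(obj)), collapse = ", "), call. = FALSE)
  }
  cfg <- structure(list(
    kmers = as.character(obj$feature_config$kmers %||% character()),
    use_conservation = isTRUE(obj$feature_config$use_conservation),
    feature_order = as.character(obj$feature_config$feature_order)),
    class = "feature_config")
  n_sv <- as.integer(obj$svm$n_sv)
  d <- length(cfg$feature_order)
  sv <- matrix(as.numeric(obj$svm$sv), nrow = n_sv, ncol = d)
  colnames(sv) <- cfg$feature_order
  scaler <- structure(list(min = stats::setNames(as.numeric(obj$scaler$min),
                                                 obj$scaler$features),
                           max = stats::setNames(as.numeric(obj$scaler$max),
                                                 obj$scaler$features),
                           features = as.character(obj$scaler$features)),
                      class = "scaler_params")
  structure(list(format = "lincsvm_model", version = 1L, config = cfg,
                 scaler = scaler,
                 svm = list(sv = sv, coef = as.numeric(obj$svm$coef),
                            rho = as.numeric(obj$svm$rho),
                            gamma = as.numeric(obj$svm$gamma),
                            C = as.numeric(obj$svm$C)),
                 platt = list(A = as.numeric(obj$platt$A),
                              B = as.numeric(obj$platt$B)),
                 labels = obj$labels),
            class = "linc_model")
}
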