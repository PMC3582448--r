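#' Labeled feature dataset
#'
#' Binds a raw feature matrix to class labels for training and evaluation.
#' The positive class is `noncoding` (lincRNA), the negative class `coding`
#' (protein-coding transcript).
#'
#' @param features numeric matrix, one row per transcript, columns in the
#'   feature order of the [feature_config()] used to build them.
#' @param labels character vector in `{"noncoding", "coding"}`.
#' @param ids transcript ids; defaults to the matrix rownames.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(features, labels, ids = rownames(features)) {
  features <- as.matrix(features)
  if (is.null(ids)) stop("transcript ids required", call. = FALSE)
  if (length(labels) != nrow(features) || length(ids) != nrow(features)) {
    stop("features, labels and ids must have matching lengths", call. = FALSE)
  }
  if (!all(labels %in% c("noncoding", "coding"))) {
    stop("labels must be 'noncoding' or 'coding'", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate transcript ids", call. = FALSE)
  structure(list(features = features, labels = labels, ids = as.character(ids)),
            class = "labeled_dataset")
}

dataset_subset <- function(data, idx) {
  labeled_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
                  data$ids[idx])
}

#' SVM hyperparameters
#'
#' @param C positive regularization constant.
#' @param gamma positive RBF kernel width.
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(C, gamma) {
  if (!is.finite(C) || !is.finite(gamma) || C <= 0 || gamma <= 0) {
    stop("C and gamma must be finite and > 0", call. = FALSE)
  }
  structure(list(C = C, gamma = gamma), class = "svm_params")
}

#' Default (C, gamma) search grid
#'
#' The conventional LIBSVM grid: `C` over `2^-5, 2^-3, ..., 2^15` and `gamma`
#' over `2^-15, 2^-13, ..., 2^3`, ordered by C then gamma so grid-search ties
#' resolve to the smaller values.
#'
#' @return Data frame with columns `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  grid <- expand.grid(gamma = 2^seq(-15, 3, by = 2), C = 2^seq(-5, 15, by = 2))
  grid[order(grid$C, grid$gamma), c("C", "gamma")]
}

# solver tolerance is pinned; the dual solution contract (support vectors,
# alpha*y coefficients, rho) is what the rest of the package depends on
SVM_EPS <- 1e-3

svm_fit <- function(x_scaled, y, C, gamma) {
  n <- nrow(x_scaled)
  max_iter <- max(20000L, 100L * n)
  sol <- .smo_solve(x_scaled, as.integer(y), C, gamma, SVM_EPS, max_iter)
  sv_idx <- which(sol$alpha > 0)
  if (!length(sv_idx)) sv_idx <- seq_len(min(n, 1L))
  list(sv = x_scaled[sv_idx, , drop = FALSE],
       coef = sol$alpha[sv_idx] * y[sv_idx],
       rho = sol$rho, gamma = gamma, C = C)
}

svm_decision <- function(fit, x_scaled) {
  K <- .rbf_kernel(x_scaled, fit$sv, fit$gamma)
  as.numeric(K %*% fit$coef) - fit$rho
}

labels_to_y <- function(labels) ifelse(labels == "noncoding", 1L, -1L)

# deterministic stratified fold assignment; every instance lands in exactly
# one fold and both classes are spread as evenly as possible
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation accuracy
#'
#' The scaler is fitted within each training fold only, so no information
#' from a held-out fold leaks into its evaluation.
#'
#' @param data a [labeled_dataset()] with raw (unscaled) features.
#' @param params an [svm_params()].
#' @param folds number of folds (>= 2); the training protocol uses 10.
#' @param seed integer seed controlling fold assignment.
#' @return Numeric vector of per-fold held-out accuracies.
#' @export
cross_validate <- function(data, params, folds = 10L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"), folds >= 2L)
  counts <- table(data$labels)
  if (length(counts) < 2L) {
    stop("cross-validation needs both classes present", call. = FALSE)
  }
  if (min(counts) < folds) {
    stop("class '", names(counts)[which.min(counts)], "' has ", min(counts),
         " members, fewer than ", folds, " folds", call. = FALSE)
  }
  fold <- stratified_folds(data$labels, folds, seed)
  y <- labels_to_y(data$labels)
  vapply(seq_len(folds), function(f) {
    tr <- fold != f
    scaler <- fit_scaler(data$features[tr, , drop = FALSE])
    fit <- svm_fit(apply_scaler(data$features[tr, , drop = FALSE], scaler),
                   y[tr], params$C, params$gamma)
    d <- svm_decision(fit, apply_scaler(data$features[!tr, , drop = FALSE],
                                        scaler))
    mean(ifelse(d >= 0, 1L, -1L) == y[!tr])
  }, 0)
}

#' Hyperparameter grid search
#'
#' Scores every (C, gamma) pair by stratified k-fold cross-validated accuracy
#' on a seed-deterministic subsample of at most `subsample_n` instances
#' (mirroring the protocol of searching on 5,000 randomly selected training
#' instances), and returns the best pair; ties go to smaller C, then smaller
#' gamma.
#'
#' @param data a [labeled_dataset()].
#' @param grid data frame with columns `C` and `gamma`; defaults to
#'   [default_svm_grid()].
#' @param folds cross-validation folds used for scoring each pair.
#' @param subsample_n maximum number of instances used during the search.
#' @param seed integer seed (subsampling and fold assignment).
#' @return List with `params` (an [svm_params()]) and `cv_accuracy`.
#' @export
grid_search <- function(data, grid = default_svm_grid(), folds = 5L,
                        subsample_n = 5000L, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"), nrow(grid) >= 1L)
  if (length(unique(data$labels)) < 2L) {
    stop("grid search needs both classes present", call. = FALSE)
  }
  n <- nrow(data$features)
  sub <- data
  if (subsample_n < n) {
    idx <- with_seed(seed, sample(n, subsample_n))
    sub <- dataset_subset(data, idx)
    if (length(unique(sub$labels)) < 2L) {
      stop("a class is absent after subsampling; increase subsample_n",
           call. = FALSE)
    }
  }
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  best <- NULL
  best_acc <- -Inf
  for (r in seq_len(nrow(grid))) {
    acc <- mean(cross_validate(sub, svm_params(grid$C[r], grid$gamma[r]),
                               folds = folds, seed = seed))
    if (acc > best_acc) {
      best_acc <- acc
      best <- svm_params(grid$C[r], grid$gamma[r])
    }
  }
  list(params = best, cv_accuracy = best_acc)
}

#' Train the RBF-SVM classifier
#'
#' Fits the min-max scaler on the training data, trains the binary RBF-SVM
#' (positive class = noncoding), and fits a Platt sigmoid on out-of-fold
#' decision values from an internal stratified split so the non-coding score
#' behaves like a calibrated probability.
#'
#' @param data a [labeled_dataset()] with raw features.
#' @param params an [svm_params()].
#' @param cfg the [feature_config()] the features were built with; stored in
#'   the model and enforced at prediction time.
#' @param seed integer seed for the internal calibration split.
#' @param calibration_folds folds of the internal split (default 5).
#' @return An object of class `linc_model`.
#' @export
train_model <- function(data, params, cfg = feature_config(), seed = 1L,
                        calibration_folds = 5L) {
  stopifnot(inherits(data, "labeled_dataset"), inherits(params, "svm_params"))
  counts <- table(data$labels)
  if (length(counts) < 2L) {
    stop("training needs both classes present", call. = FALSE)
  }
  x <- data$features
  if (!identical(colnames(x), cfg$feature_order)) {
    stop("feature columns (", paste(colnames(x), collapse = ", "),
         ") do not match the configured order (",
         paste(cfg$feature_order, collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(unique(x)) < 2L) {
    stop("degenerate training data: all feature vectors identical",
         call. = FALSE)
  }
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  y <- labels_to_y(data$labels)

  k <- min(calibration_folds, min(counts))
  if (k >= 2L) {
    fold <- stratified_folds(data$labels, k, seed)
    deci <- numeric(nrow(xs))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit_f <- svm_fit(xs[tr, , drop = FALSE], y[tr], params$C, params$gamma)
      deci[!tr] <- svm_decision(fit_f, xs[!tr, , drop = FALSE])
    }
  } else {
    warning("too few instances per class for an out-of-fold calibration ",
            "split; fitting the sigmoid on in-sample decision values",
            call. = FALSE)
    fit_all <- svm_fit(xs, y, params$C, params$gamma)
    deci <- svm_decision(fit_all, xs)
  }
  platt <- platt_fit(deci, y)
  fit <- svm_fit(xs, y, params$C, params$gamma)
  structure(list(format = "lincsvm_model", version = 1L, config = cfg,
                 scaler = scaler, svm = fit, platt = platt,
                 labels = list(positive = "noncoding", negative = "coding")),
            class = "linc_model")
}

#' @export
print.linc_model <- function(x, ...) {
  cat(sprintf(paste0("<linc_model v%d> RBF-SVM: C=%g gamma=%g, %d support ",
                     "vectors, %d features\n"),
              x$version, x$svm$C, x$svm$gamma, nrow(x$svm$sv),
              length(x$config$feature_order)))
  invisible(x)
}

# Platt's sigmoid P(y=1 | d) = 1 / (1 + exp(A*d + B)) fitted by the robust
# Newton procedure of Lin, Lin & Weng (2007), as used for LIBSVM probability
# estimates.
platt_fit <- function(deci, y, maxiter = 100L, minstep = 1e-10,
                      sigma = 1e-12) {
  prior1 <- sum(y > 0)
  prior0 <- sum(y <= 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  fun <- function(A, B) {
    fApB <- deci * A + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  fval <- fun(A, B)
  for (it in seq_len(maxiter)) {
    fApB <- deci * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sigma + sum(deci * deci * d2)
    h22 <- sigma + sum(d2)
    h21 <- sum(deci * d2)
    d1 <- t - p
    g1 <- sum(deci * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    while (stepsize >= minstep) {
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      newf <- fun(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA
        B <- newB
        fval <- newf
        break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < minstep) break
  }
  list(A = A, B = B)
}

#' Non-coding score from a decision value
#'
#' @param model a `linc_model`.
#' @param d numeric decision value(s).
#' @return `1 / (1 + exp(A*d + B))`, oriented so larger = more non-coding.
#' @export
noncoding_score <- function(model, d) {
  fApB <- d * model$platt$A + model$platt$B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Predict labels and non-coding scores
#'
#' Applies the stored scaler to raw feature vectors, computes the RBF-SVM
#' decision value, and maps it through the Platt sigmoid to a non-coding
#' score in `[0, 1]`. A transcript is labeled `noncoding` exactly when its
#' score reaches the threshold.
#'
#' @param object a `linc_model`.
#' @param features raw (unscaled) feature matrix; column names must match
#'   the model's feature order.
#' @param threshold score threshold for the `noncoding` label (default 0.5,
#'   the calibrated-probability default).
#' @param ... unused.
#' @return Data frame with `transcript_id`, `label`, `noncoding_score` and
#'   `decision_value`.
#' @export
predict.linc_model <- function(object, features, threshold = 0.5, ...) {
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list("tx", names(features)))
  }
  if (!identical(colnames(features), object$config$feature_order)) {
    stop("feature order mismatch: model expects (",
         paste(object$config$feature_order, collapse = ", "),
         ") but input has (", paste(colnames(features), collapse = ", "), ")",
         call. = FALSE)
  }
  xs <- apply_scaler(features, object$scaler)
  d <- svm_decision(object$svm, xs)
  score <- noncoding_score(object, d)
  ids <- rownames(features)
  if (is.null(ids)) ids <- paste0("tx", seq_len(nrow(features)))
  data.frame(transcript_id = ids,
             label = ifelse(score >= threshold, "noncoding", "coding"),
             noncoding_score = score, decision_value = d,
             stringsAsFactors = FALSE)
}

#' @rdname predict.linc_model
#' @param model a `linc_model`.
#' @export
predict_transcripts <- function(model, features, threshold = 0.5) {
  predict(model, features, threshold = threshold)
}

#' Balance two single-class datasets
#'
#' Subsamples the larger class down to the size of the smaller (or to a
#' requested per-class `n`), seed-deterministically, and returns the merged,
#' shuffled training set plus the held-out remainder, mirroring the balanced
#' train/remainder split used to curate the gold-standard corpus.
#'
#' @param pos [labeled_dataset()] of the positive (noncoding) class.
#' @param neg [labeled_dataset()] of the negative (coding) class.
#' @param seed integer seed.
#' @param n optional per-class size; defaults to the smaller class size.
#' @return List with `train` (balanced) and `remainder` datasets (the
#'   remainder may be empty).
#' @export
balance_dataset <- function(pos, neg, seed = 1L, n = NULL) {
  stopifnot(inherits(pos, "labeled_dataset"), inherits(neg, "labeled_dataset"))
  if (is.null(n)) n <- min(length(pos$ids), length(neg$ids))
  n <- as.integer(n)
  if (n < 1L) stop("per-class size must be >= 1", call. = FALSE)
  if (n > length(pos$ids) || n > length(neg$ids)) {
    stop("requested per-class size ", n, " exceeds a class size (",
         length(pos$ids), " positives, ", length(neg$ids), " negatives)",
         call. = FALSE)
  }
  with_seed(seed, {
    pos_idx <- sample(length(pos$ids), n)
    neg_idx <- sample(length(neg$ids), n)
    train <- merge_datasets(dataset_subset(pos, pos_idx),
                            dataset_subset(neg, neg_idx))
    train <- dataset_subset(train, sample(length(train$ids)))
  })
  rest_pos <- setdiff(seq_along(pos$ids), pos_idx)
  rest_neg <- setdiff(seq_along(neg$ids), neg_idx)
  remainder <- merge_datasets(dataset_subset(pos, rest_pos),
                              dataset_subset(neg, rest_neg))
  list(train = train, remainder = remainder)
}

merge_datasets <- function(a, b) {
  labeled_dataset(rbind(a$features, b$features), c(a$labels, b$labels),
                  c(a$ids, b$ids))
}
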