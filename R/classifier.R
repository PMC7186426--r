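# Three-class workload classifier over DFHM features.
#
# Training uses libsvm (e1071) with an RBF kernel, one-vs-one multiclass,
# inverse-frequency class weights and a 5-fold stratified cross-validated
# grid search over (C, gamma).  Prediction never calls back into the fitted
# e1071 object: the support vectors, dual coefficients and rho offsets are
# extracted once at training time and the one-vs-one voting is evaluated by
# the package's own code, so a model saved as a JSON archive (numbers only,
# no executable code) predicts identically after reloading.

CLASSIFIER_VERSION <- "dfhm-svm-1"

#' Train the DFHM workload classifier
#'
#' @param features a \code{dfhm_features} object or a numeric matrix with
#'   feature names as column names
#' @param labels integer workload classes in \{1, 2, 3\} (1 = low,
#'   2 = moderate, 3 = high), aligned with the feature rows; at least two
#'   classes must be present
#' @param config list of training settings: \code{cost_grid},
#'   \code{gamma_grid}, \code{folds} (default 5-fold stratified CV)
#' @param seed integer seed for fold assignment
#' @return object of class \code{workload_classifier}
#' @export
train_workload_classifier <- function(features, labels,
                                      config = list(), seed = 1) {
  X <- if (inherits(features, "dfhm_features")) features$features else as.matrix(features)
  if (is.null(colnames(X))) stop_dfhm("features must carry feature names")
  labels <- as.integer(labels)
  if (length(labels) != nrow(X)) {
    stop_dfhm("labels (", length(labels), ") and features (", nrow(X),
              ") are misaligned")
  }
  if (!all(labels %in% 1:3)) stop_dfhm("labels must be in {1, 2, 3}")
  if (length(unique(labels)) < 2) {
    stop_dfhm("training needs at least two distinct classes")
  }
  kernel <- config$kernel %||% "radial"
  cost_grid <- config$cost_grid %||% 2^(0:4)
  gamma_grid <- if (kernel == "linear") 0 else
    config$gamma_grid %||% (c(0.25, 1, 4) / ncol(X))
  folds <- config$folds %||% 5L

  y <- factor(labels, levels = sort(unique(labels)))
  tab <- table(y)
  wts <- stats::setNames(as.numeric(sum(tab) / (length(tab) * tab)), names(tab))

  fold_id <- with_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) next
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = kernel,
                      cost = grid$cost[g], gamma = max(grid$gamma[g], 1e-12),
                      class.weights = wts, scale = FALSE)
      hits <- hits + sum(stats::predict(m, X[!tr, , drop = FALSE]) == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  best <- which.max(acc)   # ties: first grid entry (smallest cost, gamma)
  fit <- e1071::svm(X, y, kernel = kernel, cost = grid$cost[best],
                    gamma = max(grid$gamma[best], 1e-12),
                    class.weights = wts, scale = FALSE)
  clf <- structure(list(
    version = CLASSIFIER_VERSION,
    feature_names = colnames(X),
    classes = as.integer(levels(y)),
    label_order = as.integer(levels(y))[fit$labels],  # libsvm internal order
    kernel = kernel,
    gamma = fit$gamma,
    rho = as.numeric(fit$rho),
    coefs = unname(as.matrix(fit$coefs)),
    SV = unname(as.matrix(fit$SV)),
    nSV = as.integer(fit$nSV),
    training_config = list(kernel = kernel, cost = grid$cost[best],
                           gamma = grid$gamma[best], folds = folds,
                           cost_grid = cost_grid, gamma_grid = gamma_grid,
                           class_weights = as.list(wts)),
    cv_accuracy = max(acc),
    seed = seed), class = "workload_classifier")
  clf
}

#' @export
print.workload_classifier <- function(x, ...) {
  cat("<workload_classifier> ", x$kernel %||% "radial", " SVM, classes {",
      paste(x$classes, collapse = ", "), "}, ",
      nrow(x$SV), " support vectors, ", length(x$feature_names),
      " features\n  C = ", x$training_config$cost, ", gamma = ",
      signif(x$gamma, 3), ", CV accuracy = ", round(x$cv_accuracy, 3),
      "\n", sep = "")
  invisible(x)
}

# One-vs-one decision values + majority vote (libsvm layout).
svm_vote <- function(clf, X) {
  k <- length(clf$label_order)
  if (nrow(X) == 0) return(integer(0))
  if (identical(clf$kernel %||% "radial", "linear")) {
    K <- tcrossprod(X, clf$SV)
  } else {
    d2 <- outer(rowSums(X^2), rowSums(clf$SV^2), `+`) -
      2 * tcrossprod(X, clf$SV)
    K <- exp(-clf$gamma * pmax(d2, 0))          # n x nSV_total
  }
  start <- c(0, cumsum(clf$nSV))
  votes <- matrix(0L, nrow(X), k)
  p <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- p + 1
      si <- (start[i] + 1):start[i + 1]
      sj <- (start[j] + 1):start[j + 1]
      dec <- K[, si, drop = FALSE] %*% clf$coefs[si, j - 1] +
        K[, sj, drop = FALSE] %*% clf$coefs[sj, i] - clf$rho[p]
      win <- ifelse(dec > 0, i, j)
      votes[cbind(seq_len(nrow(X)), win)] <- votes[cbind(seq_len(nrow(X)), win)] + 1L
    }
  }
  clf$label_order[max.col(votes, ties.method = "first")]
}

#' Predict workload classes for DFHM features
#'
#' @param object a \code{workload_classifier}
#' @param newdata a \code{dfhm_features} object or numeric matrix whose
#'   column names must match the training feature names exactly (same order;
#'   no silent reordering)
#' @param ... unused
#' @return a \code{classification_series} when \code{newdata} carries
#'   segment times, otherwise an integer vector of classes in \{1, 2, 3\}
#' @export
predict.workload_classifier <- function(object, newdata, ...) {
  times <- NULL
  if (inherits(newdata, "dfhm_features")) {
    times <- newdata$times
    X <- newdata$features
  } else {
    X <- as.matrix(newdata)
  }
  if (!identical(colnames(X), object$feature_names)) {
    stop_dfhm("feature names/order do not match the classifier contract")
  }
  cls <- svm_vote(object, X)
  if (is.null(times)) cls else classification_series(times, cls)
}

#' Save / load a workload classifier as a JSON archive
#'
#' The archive is self-describing (version tag, feature names, training
#' configuration) and purely numeric -- no serialized code.  Loading a file
#' with a different version tag is an explicit error.
#'
#' @param clf a \code{workload_classifier}
#' @param path file path
#' @return \code{load_workload_classifier} returns the classifier;
#'   \code{save_workload_classifier} returns \code{path} invisibly.
#' @export
save_workload_classifier <- function(clf, path) {
  payload <- unclass(clf)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_workload_classifier
#' @export
load_workload_classifier <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_dfhm("unreadable model file: ",
                                                conditionMessage(e)))
  if (!identical(obj$version, CLASSIFIER_VERSION)) {
    stop_dfhm("model version mismatch: file has '", obj$version %||% "none",
              "', package expects '", CLASSIFIER_VERSION, "'")
  }
  obj$coefs <- as.matrix(obj$coefs)
  obj$SV <- as.matrix(obj$SV)
  obj$classes <- as.integer(obj$classes)
  obj$label_order <- as.integer(obj$label_order)
  obj$nSV <- as.integer(obj$nSV)
  structure(obj, class = "workload_classifier")
}
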