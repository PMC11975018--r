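#' @useDynLib mlbpsp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Stratified fold assignment: within each class, participants are shuffled
# and dealt round-robin into folds.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    fold[idx] <- (sample(seq_along(idx)) %% n_folds) + 1L
  }
  fold
}

classifier_report <- function(task, truth, predicted, folds, seed) {
  classes <- sort(unique(c(truth, predicted)))
  confusion <- table(truth = factor(truth, classes),
                     predicted = factor(predicted, classes))
  accuracy <- mean(truth == predicted)
  misalloc <- vapply(classes, function(c) {
    n_pred <- sum(predicted == c)
    if (n_pred == 0) NA_real_ else sum(predicted == c & truth != c) / n_pred
  }, numeric(1))
  structure(list(task = task, accuracy = accuracy,
                 misclassification = 1 - accuracy,
                 confusion = confusion,
                 misallocation = stats::setNames(misalloc, paste0("predicted_", classes)),
                 folds = folds, seed = seed, n = length(truth)),
            class = "mlbpsp_classifier_report")
}

#' Random-forest phenotype classification from baseline scores
#'
#' Classifies participants into the phenotypes from baseline summary scores
#' (BDI-II total, GDS, PAOFI total, IADL total) with a random forest under
#' stratified 10-fold cross-validation; out-of-fold predictions are pooled
#' into one report.
#'
#' @param scores data.frame or matrix of baseline predictor columns
#'   (complete cases required).
#' @param labels integer phenotype labels (same order as \code{scores}).
#' @param seed integer seed (controls folds, bootstraps and splits).
#' @param n_folds folds (default 10; reduced with a warning when the
#'   smallest class has fewer members).
#' @param n_trees trees per forest (default 500).
#' @param mtry candidate features per split (default \code{floor(sqrt(p))}).
#' @return object of class \code{mlbpsp_classifier_report}.
#' @export
rf_crossval_phenotypes <- function(scores, labels, seed = 1L,
                                   n_folds = 10L, n_trees = 500L, mtry = NULL) {
  X <- as.matrix(scores)
  if (anyNA(X)) stop("predictor columns must be complete")
  y <- as.integer(labels)
  K <- max(y)
  min_class <- min(table(y))
  if (min_class < n_folds) {
    n_folds <- max(2L, as.integer(min_class))
    warning("smallest class has ", min_class,
            " members; folds reduced to ", n_folds)
  }
  set.seed(child_seed(seed, "rf_cv"))
  folds <- stratified_folds(y, n_folds)
  pred <- integer(length(y))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    pred[test] <- .rf_fit_predict(X[!test, , drop = FALSE], y[!test],
                                  X[test, , drop = FALSE], K,
                                  n_trees = as.integer(n_trees),
                                  mtry = if (is.null(mtry)) 0L else as.integer(mtry))
  }
  classifier_report("4-class", y, pred, folds, seed)
}

#' Binary healthy-vs-other logistic classification
#'
#' Collapses the labels to phenotype 1 vs all others and classifies from the
#' baseline scores with logistic regression under stratified 10-fold
#' cross-validation at a 0.5 probability threshold. Reports overall accuracy
#' and the two misallocation rates: the fraction of predicted-P1
#' participants who truly belong to P2-4 and vice versa.
#'
#' @inheritParams rf_crossval_phenotypes
#' @param threshold probability-of-P1 cutoff for predicting the healthy
#'   phenotype (default 0.5); at 1.0 nobody is predicted P1 and the
#'   predicted-P1 misallocation rate is reported as \code{NA}.
#' @return object of class \code{mlbpsp_classifier_report} with
#'   \code{misallocation} entries \code{predicted_P1} and
#'   \code{predicted_other}.
#' @export
binary_healthy_classifier <- function(scores, labels, seed = 1L,
                                      n_folds = 10L, threshold = 0.5) {
  X <- as.data.frame(scores)
  if (anyNA(X)) stop("predictor columns must be complete")
  y <- as.integer(as.integer(labels) == 1L)  # 1 = healthy phenotype (P1)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  set.seed(child_seed(seed, "binary_cv"))
  folds <- stratified_folds(y, n_folds)
  prob <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    d <- cbind(.y = y, X)
    fit <- suppressWarnings(stats::glm(.y ~ ., data = d[!test, , drop = FALSE],
                                       family = stats::binomial()))
    prob[test] <- stats::predict(fit, newdata = d[test, , drop = FALSE],
                                 type = "response")
  }
  # 1 = predicted P1; at threshold >= 1 nobody is predicted healthy (fitted
  # probabilities can saturate at 1 under separation)
  pred <- if (threshold >= 1) rep(0L, length(prob)) else as.integer(prob >= threshold)
  rep_ <- classifier_report("binary", y, pred, folds, seed)
  rep_$misallocation <- c(
    predicted_P1 = if (sum(pred == 1)) sum(pred == 1 & y == 0) / sum(pred == 1) else NA_real_,
    predicted_other = if (sum(pred == 0)) sum(pred == 0 & y == 1) / sum(pred == 0) else NA_real_)
  rep_
}
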