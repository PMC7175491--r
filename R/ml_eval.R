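#' Build a classifier feature matrix from a site set
#'
#' Samples x member-probe betas, with any missing entries imputed by the
#' probe mean (classifiers require complete data).
#'
#' @param betas beta matrix (probes x samples).
#' @param set a [site_set()] (or character vector of probe ids).
#' @param labels per-sample class labels, `disease` / `normal`.
#' @return list with `x` (samples x probes numeric matrix) and `y` (factor
#'   with levels `disease`, `normal`).
#' @export
feature_matrix <- function(betas, set, labels) {
  assert_beta_matrix(betas)
  ids <- if (inherits(set, "site_set")) set$probe_ids else as.character(set)
  ids <- intersect(ids, rownames(betas))
  if (!length(ids)) stop("no member probes present in the beta matrix", call. = FALSE)
  stopifnot(length(labels) == ncol(betas))
  if (!all(labels %in% c("disease", "normal"))) {
    stop("labels must be 'disease' or 'normal'", call. = FALSE)
  }
  x <- t(betas[ids, , drop = FALSE])
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  list(x = x, y = factor(labels, levels = c("disease", "normal")))
}

default_learner_params <- function(learner) {
  switch(learner,
         random_forest = list(ntree = 5000),
         neural_net = list(size = 2, decay = 1e-4, maxit = 400))
}

fit_predict <- function(learner, params, x_train, y_train, x_test) {
  if (learner == "random_forest") {
    fit <- randomForest::randomForest(x_train, y_train, ntree = params$ntree)
    as.character(stats::predict(fit, x_test))
  } else {
    df <- data.frame(.y = y_train, x_train, check.names = FALSE)
    fit <- nnet::nnet(.y ~ ., data = df, size = params$size,
                      decay = params$decay, maxit = params$maxit,
                      trace = FALSE)
    as.character(stats::predict(fit, data.frame(x_test, check.names = FALSE),
                                type = "class"))
  }
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                   cl, length(idx), k), call. = FALSE)
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Evaluate a binary classifier on a methylation feature matrix
#'
#' Trains the chosen learner (random forest, default 5000 trees; or a
#' single-hidden-layer neural network, 2 hidden units, weight decay 1e-4,
#' max 400 iterations) and tabulates one confusion matrix with disease as
#' the positive class.  Under the default stratified k-fold scheme the
#' confusion pools out-of-fold predictions; `oob` uses the random forest's
#' out-of-bag votes; `resubstitution` predicts the training data.
#'
#' @param features list `x`, `y` from [feature_matrix()].
#' @param learner `"random_forest"` or `"neural_net"`.
#' @param scheme `"cv_k_fold"` (default), `"oob"`, or `"resubstitution"`.
#' @param params learner hyperparameters; missing entries take the defaults
#'   above.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (fold assignment and learner randomness).
#' @return list (`classifier_eval`): `confusion` (TP/FN/FP/TN),
#'   `sensitivity`, `specificity`, `learner`, `scheme`, `params`, `seed`.
#' @export
evaluate_classifier <- function(features,
                                learner = c("random_forest", "neural_net"),
                                scheme = c("cv_k_fold", "oob", "resubstitution"),
                                params = list(), folds = 5, seed = 1) {
  learner <- match.arg(learner)
  scheme <- match.arg(scheme)
  stopifnot(is.list(features), all(c("x", "y") %in% names(features)))
  x <- features$x
  y <- features$y
  if (nlevels(droplevels(y)) != 2) stop("both classes must be present", call. = FALSE)
  params <- utils::modifyList(default_learner_params(learner), params)
  if (scheme == "oob" && learner != "random_forest") {
    stop("the oob scheme is only defined for random_forest", call. = FALSE)
  }

  pred <- with_seed(seed, {
    if (scheme == "resubstitution") {
      fit_predict(learner, params, x, y, x)
    } else if (scheme == "oob") {
      fit <- randomForest::randomForest(x, y, ntree = params$ntree)
      as.character(fit$predicted)
    } else {
      fold <- stratified_folds(y, folds)
      out <- character(length(y))
      for (k in seq_len(folds)) {
        test <- fold == k
        out[test] <- fit_predict(learner, params,
                                 x[!test, , drop = FALSE], droplevels(y[!test]),
                                 x[test, , drop = FALSE])
      }
      out
    }
  })

  confusion <- c(
    TP = sum(pred == "disease" & y == "disease"),
    FN = sum(pred != "disease" & y == "disease"),
    FP = sum(pred == "disease" & y == "normal"),
    TN = sum(pred != "disease" & y == "normal")
  )
  metrics <- sens_spec_at(confusion = confusion)
  structure(list(confusion = confusion,
                 sensitivity = metrics$sensitivity,
                 specificity = metrics$specificity,
                 learner = learner, scheme = scheme,
                 params = params, folds = folds, seed = seed),
            class = "classifier_eval")
}

#' Compare classifiers trained on two site sets
#'
#' Evaluates the same learner under the same scheme and seed (hence the same
#' fold assignment) on the feature matrices of two site sets, e.g. the
#' hyper-DMS and hypo-DMS sets, and reports the paired metrics and their
#' differences (A minus B).
#'
#' @param betas beta matrix.
#' @param labels per-sample `disease` / `normal` labels.
#' @param set_a,set_b two [site_set()]s.
#' @param learner,scheme,params,folds,seed as in [evaluate_classifier()].
#' @return list with `eval_a`, `eval_b`, `sensitivity_diff`,
#'   `specificity_diff`.
#' @export
compare_site_set_models <- function(betas, labels, set_a, set_b,
                                    learner = "random_forest",
                                    scheme = "cv_k_fold",
                                    params = list(), folds = 5, seed = 1) {
  fa <- feature_matrix(betas, set_a, labels)
  fb <- feature_matrix(betas, set_b, labels)
  ea <- evaluate_classifier(fa, learner, scheme, params, folds, seed)
  eb <- evaluate_classifier(fb, learner, scheme, params, folds, seed)
  list(eval_a = ea, eval_b = eb,
       sensitivity_diff = ea$sensitivity - eb$sensitivity,
       specificity_diff = ea$specificity - eb$specificity)
}
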