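as_feature_matrix <- function(x, call = rlang::caller_env()) {
  if (is.data.frame(x)) {
    assert_binary_table(x, call = call)
    return(response_matrix(x))
  }
  if (!is.matrix(x)) {
    abort("Features must be a binarized response table or a numeric matrix.",
          class = "eyestrat_validation_error", call = call)
  }
  x
}

# Weighted linear discriminant with ridge-regularized pooled covariance.
# Binary item features make the pooled covariance singular, hence the
# ridge lambda = ridge * trace/p. Returns the linear scoring coefficients;
# class plausibilities are softmax posteriors of the discriminant scores.
fit_wlda <- function(x, y_idx, n_classes, w, ridge = 1e-3) {
  w <- w / sum(w)
  cw <- as.vector(rowsum(w, y_idx, reorder = TRUE))          # class weights
  mu <- rowsum(x * w, y_idx, reorder = TRUE) / cw             # K x p means
  xc <- x - mu[y_idx, , drop = FALSE]
  S <- crossprod(xc * sqrt(w))                                # pooled cov
  lambda <- ridge * sum(diag(S)) / ncol(x)
  diag(S) <- diag(S) + max(lambda, 1e-12)
  A <- t(solve(S, t(mu)))                                     # K x p
  const <- -0.5 * rowSums(A * mu) + log(pmax(cw, 1e-300))
  list(A = A, const = const)
}

wlda_posterior <- function(learner, x) {
  scores <- x %*% t(learner$A)
  scores <- sweep(scores, 2, learner$const, "+")
  scores <- scores - apply(scores, 1, max)
  e <- exp(scores)
  e / rowSums(e)
}

#' Train an AdaBoost.M2 ensemble of discriminant weak learners
#'
#' Multi-class boosting over (example, incorrect-label) pairs. A weight
#' distribution \eqn{D_t(i, y)} is kept over every example and every label
#' other than its true one; at each round a weighted linear discriminant is
#' fitted (ridge-regularized pooled covariance, since binary item features
#' are collinear) yielding class plausibilities \eqn{h_t(x, y) \in [0,1]}
#' (softmax posteriors). The round's pseudo-loss is
#' \deqn{\epsilon_t = \tfrac12 \sum_{i, y \ne y_i} D_t(i,y)
#'   \left(1 - h_t(x_i, y_i) + h_t(x_i, y)\right),}
#' \eqn{\beta_t = \epsilon_t / (1 - \epsilon_t)} (bounded below), and the
#' weights update as \eqn{D_{t+1}(i,y) \propto D_t(i,y)\,
#' \beta_t^{\frac12 (1 + h_t(x_i,y_i) - h_t(x_i,y))}}. Boosting stops early
#' when \eqn{\epsilon_t \ge 1/2} (no weak learner) or \eqn{\epsilon_t = 0}
#' (perfect learner). The final score of class \eqn{y} is
#' \eqn{\sum_t \ln(1/\beta_t) h_t(x, y)}.
#'
#' @param x Training features: a binarized response table or a numeric
#'   matrix (rows = subjects).
#' @param y Training labels (e.g. rank-ordered subgroup labels), one per
#'   row; at least 2 per class.
#' @param rounds Maximum number of weak learners (default 20).
#' @param ridge Ridge coefficient for the discriminant covariance
#'   (default 1e-3, scaled by trace/dimension).
#' @return An object of class `adaboost_m2` holding the weak learners,
#'   their weights `ln(1/beta)`, the class labels and the feature names.
#'   With a single training class a degenerate constant predictor is
#'   returned with a warning.
#' @seealso [predict.adaboost_m2()], [permutation_test()]
#' @export
adaboost_m2 <- function(x, y, rounds = 20, ridge = 1e-3) {
  xm <- as_feature_matrix(x)
  if (nrow(xm) == 0) {
    abort("Empty feature matrix.", class = "eyestrat_parameter_error")
  }
  if (length(y) != nrow(xm)) {
    abort("`y` must have one label per feature row.",
          class = "eyestrat_validation_error")
  }
  classes <- sort(unique(y))
  if (length(classes) < 2) {
    warn("Single-class training labels: returning a constant predictor.")
    return(structure(
      list(learners = list(), alphas = numeric(0), classes = classes,
           features = colnames(xm), degenerate = TRUE, rounds = 0L),
      class = "adaboost_m2"
    ))
  }
  small <- names(which(table(y) < 2))
  if (length(small) > 0) {
    abort(sprintf("Every class needs >= 2 training rows (violated by: %s).",
                  paste(small, collapse = ", ")),
          class = "eyestrat_parameter_error")
  }
  y_idx <- match(y, classes)
  n <- nrow(xm)
  K <- length(classes)
  D <- matrix(1 / (n * (K - 1)), nrow = n, ncol = K)
  D[cbind(seq_len(n), y_idx)] <- 0
  ii <- cbind(seq_len(n), y_idx)
  beta_floor <- 1e-10

  learners <- list()
  alphas <- numeric(0)
  for (t in seq_len(rounds)) {
    w <- rowSums(D)
    learner <- fit_wlda(xm, y_idx, K, w, ridge = ridge)
    h <- wlda_posterior(learner, xm)
    h_true <- h[ii]
    eps <- 0.5 * sum(D * (1 - h_true + h))
    if (eps >= 0.5) break
    beta <- max(eps / (1 - eps), beta_floor)
    learners[[length(learners) + 1]] <- learner
    alphas <- c(alphas, log(1 / beta))
    if (eps <= 0) break
    D <- D * beta^(0.5 * (1 + h_true - h))
    D[ii] <- 0
    D <- D / sum(D)
  }
  if (length(learners) == 0) {
    # no weak learner beat chance on round 1: fall back to the unboosted fit
    learner <- fit_wlda(xm, y_idx, K, rep(1 / n, n), ridge = ridge)
    learners <- list(learner)
    alphas <- 1
  }
  structure(
    list(learners = learners, alphas = alphas, classes = classes,
         features = colnames(xm), degenerate = FALSE,
         rounds = length(learners)),
    class = "adaboost_m2"
  )
}

#' @export
print.adaboost_m2 <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("<adaboost_m2: degenerate constant predictor ('%s')>\n",
                x$classes))
  } else {
    cat(sprintf("<adaboost_m2: %d weak learners, %d classes>\n",
                x$rounds, length(x$classes)))
  }
  invisible(x)
}

#' Predict subgroup labels with a boosted ensemble
#'
#' Class scores are the learner-weighted sums of plausibilities; the
#' predicted label is the argmax, with ties broken toward the lowest class
#' index. Predictions are row-wise, so they are invariant to the row order
#' of the test set.
#'
#' @param object An [adaboost_m2] model.
#' @param newdata Features: binarized response table or matrix with the
#'   training items.
#' @param ... Unused.
#' @return Vector of predicted labels (same type as the training labels).
#' @export
predict.adaboost_m2 <- function(object, newdata, ...) {
  xm <- as_feature_matrix(newdata)
  if (isTRUE(object$degenerate)) {
    return(rep(object$classes, nrow(xm)))
  }
  if (!is.null(object$features) && !is.null(colnames(xm))) {
    if (!identical(colnames(xm), object$features)) {
      abort("Test items do not match the training items.",
            class = "eyestrat_validation_error")
    }
  }
  scores <- matrix(0, nrow = nrow(xm), ncol = length(object$classes))
  for (t in seq_along(object$learners)) {
    scores <- scores + object$alphas[t] *
      wlda_posterior(object$learners[[t]], xm)
  }
  object$classes[max.col(scores, ties.method = "first")]
}

#' Evaluate predicted against true subgroup labels
#'
#' Computes overall accuracy, the confusion matrix (rows = actual,
#' columns = predicted), and accuracies after merging labels into coarser
#' groups — e.g. collapsing rank-ordered subgroups into "impaired"
#' (subgroups 1–2) versus "intact" (3–5). A correct fine-grained
#' prediction stays correct after merging, so every coarse accuracy is at
#' least the multi-class accuracy.
#'
#' @param truth,predicted Aligned label vectors.
#' @param merges Optional named list of merge specifications; each is a
#'   list of label groups (e.g. `list(impaired = c(1, 2), intact = 3:5)`).
#' @param classes Declared class set (default: union of labels in
#'   `truth`/`predicted` and merge groups); labels outside it are an error.
#' @return A list of class `classification_eval`: `accuracy`, `confusion`
#'   (count matrix), `merged` (tibble `merge`, `accuracy`), `n`.
#' @export
evaluate_predictions <- function(truth, predicted, merges = NULL,
                                 classes = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must be aligned.",
          class = "eyestrat_validation_error")
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(truth, predicted, unlist(merges))))
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad) > 0) {
    abort(sprintf("Label(s) outside the declared class set: %s.",
                  paste(bad, collapse = ", ")),
          class = "eyestrat_validation_error")
  }
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  confusion <- table(actual = tf, predicted = pf)
  accuracy <- mean(truth == predicted)
  merged <- NULL
  if (!is.null(merges)) {
    if (is.null(names(merges))) {
      names(merges) <- paste0("merge_", seq_along(merges))
    }
    merged <- purrr::imap_dfr(merges, function(groups, name) {
      map <- rep(NA_integer_, length(classes))
      for (g in seq_along(groups)) {
        map[match(groups[[g]], classes)] <- g
      }
      if (any(is.na(map))) {
        abort(sprintf("Merge '%s' does not cover every class.", name),
              class = "eyestrat_validation_error")
      }
      tibble::tibble(merge = name,
                     accuracy = mean(map[as.integer(tf)] == map[as.integer(pf)]))
    })
  }
  structure(
    list(accuracy = accuracy, confusion = confusion, merged = merged,
         n = length(truth)),
    class = "classification_eval"
  )
}

#' @export
print.classification_eval <- function(x, ...) {
  cat(sprintf("<classification: accuracy %.3f on %d subjects>\n",
              x$accuracy, x$n))
  print(x$confusion)
  if (!is.null(x$merged)) print(x$merged)
  invisible(x)
}

#' Label-permutation test of cross-cohort classification
#'
#' Fits the boosted ensemble on the training cohort and measures accuracy
#' on the independent test cohort; then refits `n_perm` times with the
#' training labels randomly permuted, recording the null test accuracy
#' each time. The p-value is the add-one estimator
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}, which can
#' never be exactly zero from finite permutations; the raw proportion
#' \eqn{\#\{null \ge observed\}/n_{perm}} is also reported. The seed fully
#' determines the permutation stream.
#'
#' @param train_x,train_y Training features and labels.
#' @param test_x,test_y Test features and labels (homologous rank-ordered
#'   subgroup labels from the independent cohort's own stratification).
#' @param rounds Boosting rounds (default 20).
#' @param n_perm Number of label permutations (default 10000; reduce for
#'   quick checks).
#' @param seed Integer seed for the permutation stream.
#' @param merges Optional merge specifications passed to
#'   [evaluate_predictions()] for the observed fit.
#' @return An object of class `permutation_result`: observed accuracy,
#'   `null` accuracy vector, `p_value` (add-one), `p_raw`, the observed
#'   [evaluate_predictions()] result, `n_perm` and `seed`.
#' @export
permutation_test <- function(train_x, train_y, test_x, test_y, rounds = 20,
                             n_perm = 10000, seed = 1, merges = NULL) {
  if (n_perm < 1) {
    abort("`n_perm` must be >= 1.", class = "eyestrat_parameter_error")
  }
  xm_train <- as_feature_matrix(train_x)
  xm_test <- as_feature_matrix(test_x)
  model <- adaboost_m2(xm_train, train_y, rounds = rounds)
  evaluation <- evaluate_predictions(test_y, predict(model, xm_test),
                                     merges = merges)
  observed <- evaluation$accuracy
  null_acc <- numeric(n_perm)
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      yb <- sample(train_y)
      mb <- adaboost_m2(xm_train, yb, rounds = rounds)
      null_acc[b] <- mean(predict(mb, xm_test) == test_y)
    }
  })
  exceed <- sum(null_acc >= observed)
  structure(
    list(observed = observed, null = null_acc,
         p_value = (1 + exceed) / (1 + n_perm), p_raw = exceed / n_perm,
         n_perm = n_perm, seed = seed, evaluation = evaluation,
         rounds = rounds),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation test: observed accuracy %.3f, p = %.4g (%d permutations, null range %.3f-%.3f)>\n",
    x$observed, x$p_value, x$n_perm, min(x$null), max(x$null)))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), null_accuracy = x$null)
}

#' @rdname permutation_test
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    observed_accuracy = x$observed, p_value = x$p_value, p_raw = x$p_raw,
    n_perm = x$n_perm, null_min = min(x$null), null_max = max(x$null),
    rounds = x$rounds
  )
}
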