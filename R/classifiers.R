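# Classifier contracts: fit(features, labels) -> model,
# score(model, features) -> probability of the positive class. Backed by
# established implementations; the representation comparison is agnostic
# to the classifier behind the contract.

new_classifier <- function(name, fit, score) {
  structure(list(name = name, fit = fit, score = score),
            class = "dti_classifier")
}

#' Random-forest classifier contract
#'
#' A 100-tree forest (randomForest); scores are the forest's positive-class
#' vote fraction.
#'
#' @param ntree number of trees.
#' @param ... further arguments to [randomForest::randomForest()].
#' @return a `dti_classifier`.
#' @export
classifier_random_forest <- function(ntree = 100L, ...) {
  dots <- list(...)
  new_classifier(
    "random_forest",
    fit = function(x, y) {
      do.call(randomForest::randomForest,
              c(list(x = x, y = factor(y, levels = c(0L, 1L)),
                     ntree = ntree), dots))
    },
    score = function(model, x) {
      unname(stats::predict(model, x, type = "prob")[, "1"])
    })
}

#' Support-vector-machine classifier contract
#'
#' RBF-kernel SVM (e1071) with Platt-scaled probability scores.
#'
#' @param ... further arguments to [e1071::svm()].
#' @return a `dti_classifier`.
#' @export
classifier_svm <- function(...) {
  dots <- list(...)
  new_classifier(
    "svm",
    fit = function(x, y) {
      do.call(e1071::svm,
              c(list(x = x, y = factor(y, levels = c(0L, 1L)),
                     kernel = "radial", probability = TRUE), dots))
    },
    score = function(model, x) {
      p <- stats::predict(model, x, probability = TRUE)
      unname(attr(p, "probabilities")[, "1"])
    })
}

#' Regularized logistic-regression classifier contract
#'
#' A plain linear separator (ridge-penalized logistic regression via
#' glm-free iteratively reweighted least squares is unnecessary here;
#' `stats::glm` suffices for the moderate dimensionalities used).
#'
#' @return a `dti_classifier`.
#' @export
classifier_logistic <- function() {
  new_classifier(
    "logistic",
    fit = function(x, y) {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::glm(y ~ ., data = df,
                                  family = stats::binomial()))
    },
    score = function(model, x) {
      unname(stats::predict(model, newdata = data.frame(x),
                            type = "response"))
    })
}
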