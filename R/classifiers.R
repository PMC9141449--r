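# Thin uniform wrapper over the seven standard classifiers used throughout
# the evaluation protocols. All models consume a numeric matrix and binary
# 0/1 labels and emit class probabilities plus hard predictions.

SUPPORTED_MODELS <- c("svm", "dt", "rf", "lda", "lr", "nb", "knn")

#' Fit one of the supported classifiers
#'
#' Hyperparameters follow widely used defaults: RBF SVM with C = 1 and
#' gamma = 1/d, k = 5 for KNN, 100 trees for the random forest.
#'
#' @param model One of `r paste(SUPPORTED_MODELS, collapse = ", ")`.
#' @param x Numeric matrix, instances x features.
#' @param y Binary labels (0/1).
#' @param seed Seed for the stochastic learners (random forest).
#' @return A `physio_classifier` to pass to [predict_classifier()].
#' @export
fit_classifier <- function(model, x, y, seed = 1) {
  model <- match.arg(model, SUPPORTED_MODELS)
  x <- as.matrix(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  yf <- factor(y, levels = c(0, 1))
  fit <- switch(model,
    svm = e1071::svm(x, yf, kernel = "radial", cost = 1, probability = TRUE),
    dt = {
      df <- data.frame(x, .y = yf)
      rpart::rpart(.y ~ ., df, method = "class",
                   control = rpart::rpart.control(minsplit = 4, cp = 0.001))
    },
    rf = with_seed(seed, randomForest::randomForest(x, yf, ntree = 100)),
    lda = MASS::lda(x, grouping = yf),
    lr = {
      df <- data.frame(x, .y = yf)
      suppressWarnings(stats::glm(.y ~ ., df, family = stats::binomial()))
    },
    nb = e1071::naiveBayes(x, yf),
    knn = list(train = x, y = yf, k = min(5, nrow(x))))
  structure(list(model = model, fit = fit), class = "physio_classifier")
}

#' Predict classes and probabilities
#'
#' @param object A `physio_classifier`.
#' @param x Numeric matrix of new instances.
#' @return List with `class` (0/1 vector) and `prob` (matrix n x 2, columns
#'   `p0`, `p1`, rows summing to 1).
#' @export
predict_classifier <- function(object, x) {
  x <- as.matrix(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  fit <- object$fit
  prob <- switch(object$model,
    svm = {
      pr <- attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      cbind(pr[, "0"], pr[, "1"])
    },
    dt = {
      pr <- stats::predict(fit, data.frame(x), type = "prob")
      cbind(pr[, "0"], pr[, "1"])
    },
    rf = {
      pr <- stats::predict(fit, x, type = "prob")
      cbind(pr[, "0"], pr[, "1"])
    },
    lda = {
      pr <- stats::predict(fit, x)$posterior
      cbind(pr[, "0"], pr[, "1"])
    },
    lr = {
      p1 <- stats::predict(fit, data.frame(x), type = "response")
      cbind(1 - p1, p1)
    },
    nb = {
      pr <- stats::predict(fit, x, type = "raw")
      cbind(pr[, "0"], pr[, "1"])
    },
    knn = {
      pr <- class::knn(fit$train, x, fit$y, k = fit$k, prob = TRUE)
      pwin <- attr(pr, "prob")
      p1 <- ifelse(pr == "1", pwin, 1 - pwin)
      cbind(1 - p1, p1)
    })
  colnames(prob) <- c("p0", "p1")
  list(class = as.integer(prob[, 2] > prob[, 1]), prob = prob)
}
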