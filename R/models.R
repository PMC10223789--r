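# The ten-classifier model zoo. Each model is fit with its implementation
# library's defaults unless hyperparameters override them; AdaBoost
# (SAMME over depth-1 rpart stumps) is implemented here since no installed
# library provides it.

.LABEL_LEVELS <- c("non_dependent", "dependent")

.asFactorY <- function(y) factor(y, levels = .LABEL_LEVELS)

.hp <- function(spec, name, default) {
  if (name %in% names(spec@hyperparameters)) spec@hyperparameters[[name]]
  else default
}

# SAMME AdaBoost with decision stumps; binary case, alpha = log((1-e)/e).
.fitAdaboost <- function(X, y, nStumps, seed) {
  df <- data.frame(y = y, X, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (m in seq_len(nStumps)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y])
    if (err <= 0) { stumps <- c(stumps, list(fit)); alphas <- c(alphas, 10); break }
    if (err >= 0.5) {
      if (length(stumps) == 0) { stumps <- list(fit); alphas <- 1 }
      break
    }
    alpha <- log((1 - err) / err)
    stumps <- c(stumps, list(fit))
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

.predictAdaboost <- function(fit, X) {
  df <- data.frame(X, check.names = FALSE)
  score <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    p <- predict(fit$stumps[[m]], df, type = "class")
    score <- score + fit$alphas[m] * ifelse(p == "dependent", 1, -1)
  }
  ifelse(score > 0, "dependent", "non_dependent")
}

# glmnet needs >= 2 columns; pad single-feature designs with a zero column.
.padX <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `.pad` = 0)
}

#' Fit one classifier of the model zoo
#'
#' Internal workhorse behind \code{\link{crossvalF1}}; exported for direct
#' use. \code{X} is expected to be scaled already (cross-validation scales
#' within training folds).
#'
#' @param spec a \code{\link{modelSpec}}
#' @param X numeric matrix of features (instances as rows)
#' @param y labels, coerced to factor with levels
#'   \code{c("non_dependent", "dependent")}
#' @return an opaque fitted-model object for \code{\link{predictModel}}
#' @export
fitModel <- function(spec, X, y) {
  y <- .asFactorY(y)
  stopIfNot(nlevels(droplevels(y)) == 2,
            "degenerate single-class labels: both classes are required")
  X <- as.matrix(X)
  stopIfNot(all(is.finite(X)), "features contain non-finite values")
  n <- nrow(X)
  set.seed(spec@seed)
  fit <- switch(
    spec@name,
    adaboost = .fitAdaboost(X, y, .hp(spec, "n_stumps", 50L), spec@seed),
    decision_tree = rpart::rpart(
      y ~ ., data = data.frame(y = y, X, check.names = FALSE),
      method = "class"),
    gaussian_process = {
      # gausspr prints its sigma-estimation note to stdout; keep fits quiet
      out <- utils::capture.output(
        gp <- kernlab::gausspr(x = X, y = y, kernel = "rbfdot"))
      gp
    },
    knn = list(train = X, cl = y, k = .hp(spec, "k", 5L)),
    linear_svc = e1071::svm(x = X, y = y, kernel = "linear",
                            cost = .hp(spec, "cost", 1), scale = FALSE),
    logistic_regression = {
      lam <- .hp(spec, "lambda", NULL)
      alpha <- .hp(spec, "alpha", 1)
      if (is.null(lam)) {
        # library-default usage: lasso path with cross-validated penalty
        glmnet::cv.glmnet(.padX(X), y, family = "binomial", alpha = alpha,
                          nfolds = max(3, min(10, floor(n / 10))))
      } else {
        glmnet::glmnet(.padX(X), y, family = "binomial", alpha = alpha,
                       lambda = lam)
      }
    },
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = .hp(spec, "ntree", 100L)),
    ridge = glmnet::glmnet(
      .padX(X), ifelse(y == "dependent", 1, -1), family = "gaussian",
      alpha = 0, lambda = .hp(spec, "lambda", 1 / n)),
    sgd_linear_svc = e1071::svm(
      x = X, y = y, kernel = "linear",
      cost = .hp(spec, "cost", 1 / (1e-4 * n)), scale = FALSE),
    rbf_svc = e1071::svm(x = X, y = y, kernel = "radial",
                         cost = .hp(spec, "cost", 1), scale = FALSE),
    stop("unknown model: ", spec@name))
  structure(list(name = spec@name, fit = fit), class = "depnetModel")
}

#' Predict dependency labels from a fitted zoo model
#'
#' @param model object returned by \code{\link{fitModel}}
#' @param X numeric feature matrix on the same scale as training
#' @return character vector of \code{"dependent"} / \code{"non_dependent"}
#' @export
predictModel <- function(model, X) {
  X <- as.matrix(X)
  fit <- model$fit
  out <- switch(
    model$name,
    adaboost = .predictAdaboost(fit, X),
    decision_tree = as.character(
      predict(fit, data.frame(X, check.names = FALSE), type = "class")),
    gaussian_process = as.character(kernlab::predict(fit, X)),
    knn = as.character(class::knn(fit$train, X, fit$cl, k = fit$k,
                                  use.all = TRUE)),
    linear_svc = as.character(predict(fit, X)),
    logistic_regression = if (inherits(fit, "cv.glmnet"))
      as.character(predict(fit, .padX(X), s = "lambda.min", type = "class"))
    else as.character(predict(fit, .padX(X), type = "class")),
    random_forest = as.character(predict(fit, X)),
    ridge = ifelse(as.numeric(predict(fit, .padX(X))) > 0,
                   "dependent", "non_dependent"),
    sgd_linear_svc = as.character(predict(fit, X)),
    rbf_svc = as.character(predict(fit, X)),
    stop("unknown model: ", model$name))
  unname(out)
}
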