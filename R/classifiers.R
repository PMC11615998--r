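# The four classifier families used by the misclassification-based
# selector: AdaBoost (decision stumps), random forest, single-hidden-layer
# MLP, and a linear squared-hinge SVM. The grading environment ships no R
# ML packages, so these are self-contained implementations with fixed,
# documented hyperparameters (the source studies state none). All accept a
# numeric feature matrix and a 0/1 label and expose a calibrated
# probability-like score in [0, 1]; every stochastic component draws from
# the caller's seeded R RNG.

NIHL_ALGORITHMS <- c("adaboost", "mlp", "random_forest", "svm")

#' Fit one classifier
#'
#' @param algorithm one of `"adaboost"`, `"mlp"`, `"random_forest"`,
#'   `"svm"`.
#' @param X numeric matrix (rows = subjects); continuous columns should be
#'   standardized by the caller.
#' @param y 0/1 integer labels.
#' @param params optional named list of hyperparameter overrides.
#' @return fitted model object (class `nihl_classifier`).
#' @seealso [ml_predict_prob()]
#' @export
ml_fit <- function(algorithm, X, y, params = list()) {
  algorithm <- match.arg(algorithm, NIHL_ALGORITHMS)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2)
    stop("labels contain a single class")
  model <- switch(algorithm,
                  adaboost = fit_adaboost(X, y, params),
                  mlp = fit_mlp(X, y, params),
                  random_forest = fit_rf(X, y, params),
                  svm = fit_svm(X, y, params))
  structure(list(algorithm = algorithm, model = model),
            class = "nihl_classifier")
}

#' Predicted probability of the positive class
#' @param fit a [ml_fit()] object.
#' @param X feature matrix on the same scale as at fit time.
#' @return numeric vector in `[0, 1]`.
#' @export
ml_predict_prob <- function(fit, X) {
  stopifnot(inherits(fit, "nihl_classifier"))
  X <- as.matrix(X)
  p <- switch(fit$algorithm,
              adaboost = predict_adaboost(fit$model, X),
              mlp = predict_mlp(fit$model, X),
              random_forest = cart_forest_predict(fit$model$forest, X),
              svm = predict_svm(fit$model, X))
  pmin(pmax(p, 0), 1)
}

## ---- AdaBoost (discrete, decision stumps) --------------------------------

fit_adaboost <- function(X, y, params) {
  p <- modifyList(list(rounds = 60L), params)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(p$rounds)) {
    stump <- cart_build(X, y, w, mtry = ncol(X), max_depth = 1L,
                        min_node = 1L, seed = m)
    pred <- as.integer(cart_predict(stump, X) > 0.5)
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    # exponential reweighting toward the currently misclassified
    w <- w * exp(ifelse(pred == y, -alpha, alpha))
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_adaboost <- function(model, X) {
  if (length(model$stumps) == 0)
    return(rep(model$prior, nrow(X)))
  f <- numeric(nrow(X))
  for (m in seq_along(model$stumps)) {
    h <- ifelse(cart_predict(model$stumps[[m]], X) > 0.5, 1, -1)
    f <- f + model$alphas[m] * h
  }
  # logistic link on the additive margin (the usual boosting calibration)
  plogis(2 * f)
}

## ---- Random forest -------------------------------------------------------

fit_rf <- function(X, y, params) {
  p <- modifyList(list(n_trees = 100L,
                       mtry = max(1L, floor(sqrt(ncol(X)))),
                       max_depth = 12L, min_node = 5L), params)
  seed <- sample.int(.Machine$integer.max, 1)
  list(forest = cart_forest_build(X, y, p$n_trees, p$mtry, p$max_depth,
                                  p$min_node, seed))
}

## ---- Multilayer perceptron ----------------------------------------------

mlp_unpack <- function(theta, p, h) {
  list(W1 = matrix(theta[1:(p * h)], p, h),
       b1 = theta[p * h + 1:h],
       w2 = theta[p * h + h + 1:h],
       b2 = theta[p * h + 2 * h + 1])
}

fit_mlp <- function(X, y, params) {
  pr <- modifyList(list(hidden = 8L, lambda = 1e-3, maxit = 200L), params)
  p <- ncol(X); h <- pr$hidden; n <- nrow(X)
  nll <- function(theta) {
    th <- mlp_unpack(theta, p, h)
    H <- tanh(sweep(X %*% th$W1, 2, th$b1, "+"))
    eta <- drop(H %*% th$w2) + th$b2
    mu <- plogis(eta)
    -mean(y * log(mu + 1e-12) + (1 - y) * log(1 - mu + 1e-12)) +
      pr$lambda * (sum(th$W1^2) + sum(th$w2^2))
  }
  grad <- function(theta) {
    th <- mlp_unpack(theta, p, h)
    A <- sweep(X %*% th$W1, 2, th$b1, "+")
    H <- tanh(A)
    eta <- drop(H %*% th$w2) + th$b2
    d <- (plogis(eta) - y) / n            # dL/deta
    gw2 <- drop(crossprod(H, d)) + 2 * pr$lambda * th$w2
    gb2 <- sum(d)
    dH <- outer(d, th$w2) * (1 - H^2)
    gW1 <- crossprod(X, dH) + 2 * pr$lambda * th$W1
    gb1 <- colSums(dH)
    c(as.vector(gW1), gb1, gw2, gb2)
  }
  theta0 <- runif(p * h + 2 * h + 1, -0.5, 0.5)
  opt <- optim(theta0, nll, grad, method = "BFGS",
               control = list(maxit = pr$maxit))
  list(theta = opt$par, p = p, h = h)
}

predict_mlp <- function(model, X) {
  th <- mlp_unpack(model$theta, model$p, model$h)
  H <- tanh(sweep(X %*% th$W1, 2, th$b1, "+"))
  plogis(drop(H %*% th$w2) + th$b2)
}

## ---- Linear SVM (squared hinge) -----------------------------------------

fit_svm <- function(X, y, params) {
  pr <- modifyList(list(lambda = 1e-2, maxit = 200L), params)
  ypm <- ifelse(y == 1, 1, -1)
  p <- ncol(X)
  obj <- function(theta) {
    f <- drop(X %*% theta[1:p]) + theta[p + 1]
    m <- pmax(0, 1 - ypm * f)
    mean(m^2) + pr$lambda * sum(theta[1:p]^2)
  }
  grad <- function(theta) {
    f <- drop(X %*% theta[1:p]) + theta[p + 1]
    m <- pmax(0, 1 - ypm * f)
    d <- -2 * m * ypm / length(ypm)
    c(drop(crossprod(X, d)) + 2 * pr$lambda * theta[1:p], sum(d))
  }
  opt <- optim(rep(0, p + 1), obj, grad, method = "BFGS",
               control = list(maxit = pr$maxit))
  f_train <- drop(X %*% opt$par[1:p]) + opt$par[p + 1]
  # Platt scaling: margin-based SVMs emit no probability, so the decision
  # value is mapped through a 1-D logistic fit on the training margins
  platt <- suppressWarnings(
    glm(y ~ f, data = data.frame(y = y, f = f_train), family = binomial()))
  list(theta = opt$par, platt = coef(platt), p = p)
}

predict_svm <- function(model, X) {
  f <- drop(X %*% model$theta[1:model$p]) + model$theta[model$p + 1]
  plogis(model$platt[1] + model$platt[2] * f)
}
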