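#' Classifier specification
#'
#' A lightweight description of one classifier configuration from the five
#' families used for outcome prediction. Families map to standard fitters
#' (SVM: e1071, RF: randomForest, ANN: nnet single hidden layer with ridge
#' decay) or to small ensembles built on rpart trees (AdaBoost.M1 with
#' decision stumps; EDT = bootstrap-bagged trees).
#'
#' @param family One of `"svm"`, `"rf"`, `"adaboost"`, `"edt"`, `"ann"`, or
#'   the diagnostic `"dummy"` (ignores the features and always predicts
#'   `class`, default `"improved"` — the degenerate reference against which
#'   fold-averaging conventions are checked).
#' @param ... Family hyperparameters: svm `kernel` ("linear", "rbf",
#'   "poly3") and `cost`; rf/edt `n_trees`, `min_leaf`; adaboost
#'   `learning_rate`, `n_learners`; ann `hidden`, `learning_rate`,
#'   `epochs` (default 1000), `ridge` (default 0.01).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("svm", "rf", "adaboost", "edt", "ann",
                                  "dummy"),
                       ...) {
  family <- match.arg(family)
  params <- list(...)
  defaults <- switch(family,
    dummy = list(class = "improved"),
    svm = list(kernel = "rbf", cost = 10),
    rf = list(n_trees = 50L, min_leaf = 1L),
    edt = list(n_trees = 50L, min_leaf = 1L),
    adaboost = list(learning_rate = 0.1, n_learners = 25L),
    ann = list(hidden = 10L, learning_rate = 0.01, epochs = 1000L,
               ridge = 0.01)
  )
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  structure(c(list(family = family), defaults), class = "model_spec")
}

#' Default hyperparameter grids per classifier family
#'
#' The search grids of the outcome-prediction experiment: SVM kernels linear
#' / RBF / polynomial degree 3 with cost 0.1-10000; RF and EDT minimum leaf
#' size 1, 5, 10 with 5-100 trees; AdaBoost learning rate 0.001-0.1 with
#' 15-30 weak learners; ANN 10-50 hidden nodes with learning rate 0.1-0.001,
#' 1000 epochs, ridge 0.01.
#'
#' @param family Classifier family.
#' @return List of `model_spec` objects covering the grid.
#' @export
model_grid <- function(family = c("svm", "rf", "adaboost", "edt", "ann")) {
  family <- match.arg(family)
  grid <- switch(family,
    svm = expand.grid(kernel = c("linear", "rbf", "poly3"),
                      cost = c(0.1, 1, 10, 100, 1000, 10000),
                      stringsAsFactors = FALSE),
    rf = expand.grid(min_leaf = c(1L, 5L, 10L),
                     n_trees = c(5L, 25L, 50L, 100L)),
    edt = expand.grid(min_leaf = c(1L, 5L, 10L),
                      n_trees = c(5L, 25L, 50L, 100L)),
    adaboost = expand.grid(learning_rate = c(0.001, 0.01, 0.1),
                           n_learners = c(15L, 20L, 25L, 30L)),
    ann = expand.grid(hidden = c(10L, 20L, 50L),
                      learning_rate = c(0.1, 0.01, 0.001))
  )
  purrr::pmap(grid, function(...) do.call(model_spec,
                                          c(list(family = family), list(...))))
}

# Internal: fit a model_spec on a feature matrix and factor labels
# (levels improved/unimproved). Returns an object for predict_model().
fit_model <- function(spec, x, y) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("improved", "unimproved"))
  if (spec$family == "dummy") {
    return(structure(list(constant = spec$class),
                     class = "mfc_constant_model"))
  }
  if (length(unique(y)) < 2) {
    # degenerate single-class training set: constant predictor
    return(structure(list(constant = as.character(y[1])),
                     class = "mfc_constant_model"))
  }
  fit <- switch(spec$family,
    svm = {
      kern <- switch(spec$kernel, linear = "linear", rbf = "radial",
                     poly3 = "polynomial")
      e1071::svm(x, y, kernel = kern, cost = spec$cost,
                 degree = 3, scale = FALSE)
    },
    rf = randomForest::randomForest(x, y, ntree = spec$n_trees,
                                    nodesize = spec$min_leaf),
    edt = fit_bagged_trees(x, y, n_trees = spec$n_trees,
                           min_leaf = spec$min_leaf),
    adaboost = fit_adaboost(x, y, n_learners = spec$n_learners,
                            learning_rate = spec$learning_rate),
    ann = {
      nnet::nnet(x, nnet::class.ind(y), size = spec$hidden,
                 decay = spec$ridge, maxit = spec$epochs,
                 softmax = TRUE, trace = FALSE)
    }
  )
  structure(list(spec = spec, fit = fit, levels = levels(y)),
            class = "mfc_model")
}

predict_model <- function(model, x) {
  x <- as.matrix(x)
  if (inherits(model, "mfc_constant_model")) {
    return(factor(rep(model$constant, nrow(x)),
                  levels = c("improved", "unimproved")))
  }
  spec <- model$spec
  pred <- switch(spec$family,
    svm = stats::predict(model$fit, x),
    rf = stats::predict(model$fit, x),
    edt = predict_bagged_trees(model$fit, x),
    adaboost = predict_adaboost(model$fit, x),
    ann = {
      p <- stats::predict(model$fit, x)
      factor(model$levels[max.col(p)], levels = model$levels)
    }
  )
  factor(as.character(pred), levels = c("improved", "unimproved"))
}

# --- rpart-based ensembles -------------------------------------------------

as_rpart_frame <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(df)))
  df
}

# Bootstrap-bagged decision trees; majority vote at prediction.
fit_bagged_trees <- function(x, y, n_trees = 50L, min_leaf = 1L) {
  df <- as_rpart_frame(x)
  df$.y <- y
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample(nrow(df), replace = TRUE)
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = rpart::rpart.control(minbucket = min_leaf,
                                                minsplit = 2, cp = 0,
                                                xval = 0))
  })
  list(trees = trees, levels = levels(y))
}

predict_bagged_trees <- function(fit, x) {
  df <- as_rpart_frame(x)
  votes <- sapply(fit$trees, function(tr) {
    as.character(stats::predict(tr, df, type = "class"))
  })
  votes <- matrix(votes, nrow = nrow(df))
  pred <- apply(votes, 1, function(v) names(which.max(table(v))))
  factor(pred, levels = fit$levels)
}

# AdaBoost.M1 with depth-1 rpart stumps and a shrinkage learning rate.
fit_adaboost <- function(x, y, n_learners = 25L, learning_rate = 0.1) {
  df <- as_rpart_frame(x)
  n <- nrow(df)
  yy <- ifelse(y == "improved", 1, -1)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (b in seq_len(n_learners)) {
    tr <- rpart::rpart(factor(yy) ~ ., data = df, weights = w,
                       method = "class",
                       control = rpart::rpart.control(maxdepth = 1,
                                                      minsplit = 2, cp = 0,
                                                      xval = 0))
    pred <- as.numeric(as.character(stats::predict(tr, df, type = "class")))
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    alpha <- learning_rate * 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    stumps[[b]] <- tr
    alphas[b] <- alpha
    if (err >= 0.5) break
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, x) {
  df <- as_rpart_frame(x)
  score <- rep(0, nrow(df))
  for (b in seq_along(fit$stumps)) {
    pred <- as.numeric(as.character(
      stats::predict(fit$stumps[[b]], df, type = "class")))
    score <- score + fit$alphas[b] * pred
  }
  factor(ifelse(score >= 0, "improved", "unimproved"),
         levels = c("improved", "unimproved"))
}
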