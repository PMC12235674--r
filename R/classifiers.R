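# Uniform fit/predict-proba contract over the five classifier families.
# The families themselves are delegated to established libraries (e1071,
# ranger, xgboost, glmnet, nnet); everything around them - grids, tuning,
# the cross-platform protocol - is this package's code.

CLASSIFIER_FAMILIES <- c("MLP", "XGB", "LR", "SVM", "RF")

#' Hyperparameter grid for a classifier family
#'
#' Grids cover model complexity, regularization strength and training
#' stability: LR tunes the inverse regularization strength C (ridge
#' multinomial logistic via glmnet, lambda = 1/(C n)); SVM tunes kernel and
#' RBF gamma; RF tunes tree count, depth, node size and feature subsampling;
#' MLP tunes the hidden-layer size and L2 decay (single hidden layer); XGB
#' tunes tree count, learning rate, depth, row/column subsampling and gamma.
#' `fast = TRUE` shrinks every grid to one sensible point for desk-scale
#' runs; enumeration order is fixed, and ties in CV score are broken by
#' first-in-grid order.
#'
#' @param family one of `"MLP"`, `"XGB"`, `"LR"`, `"SVM"`, `"RF"`.
#' @param fast use the reduced one-point grid?
#' @return list of named parameter lists (enumeration order = tie-break
#'   order).
#' @export
classifier_grid <- function(family, fast = FALSE) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  if (fast) {
    return(switch(family,
      LR  = list(list(C = 1)),
      SVM = list(list(kernel = "linear")),
      RF  = list(list(num.trees = 100, max.depth = 6, min.node.size = 5,
                      mtry_rule = "sqrt")),
      MLP = list(list(size = 30, decay = 1e-3)),
      XGB = list(list(nrounds = 100, eta = 0.3, max_depth = 3,
                      subsample = 1, colsample_bytree = 1, gamma = 0))))
  }
  grid_from_df <- function(df) lapply(seq_len(nrow(df)), function(i) {
    as.list(df[i, , drop = FALSE])
  })
  switch(family,
    LR = lapply(10^seq(-2, 1, length.out = 5), function(C) list(C = C)),
    SVM = c(list(list(kernel = "linear")),
            lapply(list("scale", 0.01, 0.1), function(g)
              list(kernel = "radial", gamma = g))),
    RF = grid_from_df(expand.grid(num.trees = c(100, 200, 300),
                                  max.depth = c(3, 4, 6),
                                  min.node.size = c(2, 5, 10),
                                  mtry_rule = c("sqrt", "log2"),
                                  stringsAsFactors = FALSE)),
    MLP = grid_from_df(expand.grid(size = c(30, 50, 100),
                                   decay = c(1e-4, 1e-3))),
    XGB = grid_from_df(expand.grid(nrounds = c(100, 200, 300),
                                   eta = c(0.05, 0.1, 0.3),
                                   max_depth = c(3, 4, 6),
                                   subsample = c(0.6, 0.8, 1.0),
                                   colsample_bytree = c(0.6, 0.8, 1.0),
                                   gamma = c(0, 0.1, 0.5))))
}

mtry_from_rule <- function(rule, p) {
  m <- switch(rule, sqrt = sqrt(p), log2 = log2(p),
              stop("unknown mtry rule: ", rule, call. = FALSE))
  max(1L, min(p, floor(m)))
}

#' Fit one classifier configuration
#'
#' @param family one of `"MLP"`, `"XGB"`, `"LR"`, `"SVM"`, `"RF"`.
#' @param params one parameter list from [classifier_grid()].
#' @param x samples x features numeric matrix.
#' @param y factor of training labels (its levels define the class order of
#'   the probability output; levels absent from the training data get
#'   probability 0).
#' @param seed integer seed controlling any stochastic fitting.
#' @return object of class `crossnorm_fit` supporting [predict_proba()] and
#'   [predict_label()].
#' @export
fit_classifier <- function(family, params, x, y, seed = 1L) {
  family <- match.arg(family, CLASSIFIER_FAMILIES)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  classes <- levels(y)
  y0 <- droplevels(y)
  set.seed(seed)
  model <- switch(family,
    SVM = {
      gamma <- params$gamma
      if (identical(gamma, "scale") || is.null(gamma))
        gamma <- 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-12))
      e1071::svm(x, y0, kernel = params$kernel %||% "linear",
                 gamma = gamma, probability = TRUE, scale = FALSE)
    },
    RF = {
      ranger::ranger(x = x, y = y0, probability = TRUE,
                     num.trees = params$num.trees %||% 100,
                     max.depth = params$max.depth %||% 0,
                     min.node.size = params$min.node.size %||% 5,
                     mtry = mtry_from_rule(params$mtry_rule %||% "sqrt", ncol(x)),
                     seed = seed, num.threads = 1L)
    },
    XGB = {
      k <- nlevels(y0)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y0) - 1L)
      xgboost::xgb.train(params = list(objective = "multi:softprob",
                                       num_class = k,
                                       eta = params$eta %||% 0.3,
                                       max_depth = params$max_depth %||% 3,
                                       subsample = params$subsample %||% 1,
                                       colsample_bytree = params$colsample_bytree %||% 1,
                                       gamma = params$gamma %||% 0,
                                       nthread = 1L),
                         data = dtrain,
                         nrounds = params$nrounds %||% 100,
                         verbose = 0)
    },
    LR = {
      # glmnet wants a descending lambda path; fit down to the target
      # lambda = 1/(C n) and predict at it
      lam <- 1 / ((params$C %||% 1) * nrow(x))
      suppressWarnings(
        glmnet::glmnet(x, y0, family = "multinomial", alpha = 0,
                       lambda = lam * c(64, 16, 4, 1), maxit = 5e5))
    },
    MLP = {
      utils::capture.output(fit <- nnet::nnet(
        x = x, y = nnet::class.ind(y0), softmax = TRUE,
        size = params$size %||% 30, decay = params$decay %||% 1e-3,
        maxit = 500, trace = FALSE, MaxNWts = 1e6))
      fit
    })
  structure(list(family = family, model = model, params = params,
                 classes = classes, trained_levels = levels(y0)),
            class = "crossnorm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class-probability predictions
#'
#' @param object a [fit_classifier()] result.
#' @param newx samples x features matrix with the training feature columns.
#' @param ... unused.
#' @return samples x classes probability matrix, columns in the full class
#'   order the model was constructed with (classes unseen in training get 0).
#' @export
predict_proba <- function(object, newx, ...) UseMethod("predict_proba")

#' @export
predict_proba.crossnorm_fit <- function(object, newx, ...) {
  lev <- object$trained_levels
  p <- switch(object$family,
    SVM = {
      pr <- stats::predict(object$model, newx, probability = TRUE)
      attr(pr, "probabilities")[, lev, drop = FALSE]
    },
    RF = {
      pr <- stats::predict(object$model, data = newx,
                           num.threads = 1L)$predictions
      pr[, lev, drop = FALSE]
    },
    XGB = {
      v <- stats::predict(object$model, xgboost::xgb.DMatrix(newx))
      m <- if (is.matrix(v)) v else matrix(v, ncol = length(lev), byrow = TRUE)
      colnames(m) <- lev
      m
    },
    LR = {
      s <- min(object$model$lambda)
      arr <- stats::predict(object$model, newx, type = "response", s = s)
      m <- arr[, , 1L, drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, dimnames(arr)[[2L]]))
      m[, lev, drop = FALSE]
    },
    MLP = {
      m <- stats::predict(object$model, newx)
      colnames(m) <- lev
      m
    })
  out <- matrix(0, nrow = nrow(newx), ncol = length(object$classes),
                dimnames = list(rownames(newx), object$classes))
  out[, lev] <- p
  out
}

#' Predicted class labels (argmax of probabilities; ties to the first class)
#'
#' @inheritParams predict_proba
#' @return factor of predicted labels with the full class order as levels.
#' @export
predict_label <- function(object, newx) {
  p <- predict_proba(object, newx)
  factor(colnames(p)[max.col(p, ties.method = "first")],
         levels = object$classes)
}
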