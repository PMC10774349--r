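# Classifier panel.
#
# Two panels are defined: the eight-member selection ensemble (each member
# must expose a per-feature importance) and the five held-out validation
# classifiers (each must expose a continuous score for ROC analysis).
# Members wrap the installed learners (ranger, xgboost, e1071, glmnet,
# rpart, nnet); the simple linear online learners (SGD hinge,
# passive-aggressive) plus ridge, bagging aggregation, AdaBoost (SAMME on
# stumps) and kNN scoring are written out directly, since no installed
# package exposes them under this contract.
#
# Every member is a list(fit, importance, score): fit(X, y01, seed) trains
# deterministically under the given seed; importance(model, p) returns a
# non-negative length-p vector; score(model, X) returns a continuous score
# increasing with the probability of the positive class. Hyperparameters
# are frozen here (see refs_ensemble_spec() / validation_classifier_spec()).

# ---- hand-written linear online learners ------------------------------

# SGD-trained linear SVM (Pegasos: hinge loss, L2 penalty lambda, step
# 1/(lambda * t)).
fit_sgd_hinge <- function(X, y01, seed, lambda = 1e-4, epochs = 10L) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  y <- ifelse(y01 == 1L, 1, -1)
  w <- numeric(p); b <- 0; t <- 0
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- 1 / (lambda * t)
      xi <- X[i, ]
      margin <- y[i] * (sum(w * xi) + b)
      w <- (1 - eta * lambda) * w
      if (margin < 1) {
        w <- w + eta * y[i] * xi
        b <- b + eta * y[i] * 0.01
      }
    }
  }
  list(w = w, b = b)
}

# Passive-aggressive classifier (PA-I, hinge with aggressiveness cap C).
fit_passive_aggressive <- function(X, y01, seed, C = 1, epochs = 5L) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  y <- ifelse(y01 == 1L, 1, -1)
  w <- numeric(p); b <- 0
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      xi <- X[i, ]
      loss <- max(0, 1 - y[i] * (sum(w * xi) + b))
      if (loss > 0) {
        tau <- min(C, loss / (sum(xi * xi) + 1))
        w <- w + tau * y[i] * xi
        b <- b + tau * y[i]
      }
    }
  }
  list(w = w, b = b)
}

# Ridge classifier: least-squares on +/-1 labels with L2 penalty, solved in
# whichever of primal/dual space is smaller.
fit_ridge_classifier <- function(X, y01, alpha = 1) {
  y <- ifelse(y01 == 1L, 1, -1)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  if (p <= n) {
    w <- solve(crossprod(Xc) + alpha * diag(p), crossprod(Xc, y))
  } else {
    w <- crossprod(Xc, solve(tcrossprod(Xc) + alpha * diag(n), y))
  }
  w <- drop(w)
  list(w = w, b = mean(y) - sum(w * xm))
}

linear_score <- function(model, X) drop(X %*% model$w) + model$b

# ---- ensemble members --------------------------------------------------

member_sgd <- list(
  fit = function(X, y01, seed) fit_sgd_hinge(X, y01, seed),
  importance = function(m, p) abs(m$w),
  score = function(m, X) linear_score(m, X)
)

member_passive_aggressive <- list(
  fit = function(X, y01, seed) fit_passive_aggressive(X, y01, seed),
  importance = function(m, p) abs(m$w),
  score = function(m, X) linear_score(m, X)
)

member_ridge <- list(
  fit = function(X, y01, seed) fit_ridge_classifier(X, y01),
  importance = function(m, p) abs(m$w),
  score = function(m, X) linear_score(m, X)
)

member_logistic <- list(
  fit = function(X, y01, seed) {
    # L2-regularised logistic regression; fixed small penalty for stability
    # under separation.
    fit <- glmnet::glmnet(X, factor(y01, levels = c(0, 1)),
      family = "binomial", alpha = 0,
      lambda = 1 / nrow(X), standardize = FALSE
    )
    beta <- as.numeric(fit$beta)
    list(w = beta, b = as.numeric(fit$a0))
  },
  importance = function(m, p) abs(m$w),
  score = function(m, X) linear_score(m, X)
)

member_svc_linear <- list(
  fit = function(X, y01, seed) {
    fit <- e1071::svm(X, factor(y01, levels = c(0, 1)),
      kernel = "linear", cost = 1, scale = FALSE
    )
    list(fit = fit, w = drop(crossprod(fit$coefs, fit$SV)))
  },
  importance = function(m, p) abs(m$w),
  score = function(m, X) {
    pred <- stats::predict(m$fit, X, decision.values = TRUE)
    dvm <- attr(pred, "decision.values")
    dv <- dvm[, 1L]
    # the decision value is positive for the class named first in the
    # "a/b" column label; orient so larger score means class "1"
    if (startsWith(colnames(dvm)[1L], "1/")) dv else -dv
  }
)

member_gradient_boosting <- list(
  fit = function(X, y01, seed) {
    dtrain <- xgboost::xgb.DMatrix(X, label = y01, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(
        objective = "binary:logistic", max_depth = 3, eta = 0.1,
        nthread = 1, subsample = 1, colsample_bytree = 1, seed = seed,
        tree_method = "hist"
      ),
      data = dtrain, nrounds = 50, verbose = 0
    )
    list(booster = booster, features = colnames(X))
  },
  importance = function(m, p) {
    imp <- numeric(p)
    tab <- tryCatch(
      xgboost::xgb.importance(model = m$booster),
      error = function(e) NULL
    )
    if (!is.null(tab) && nrow(tab) > 0L) {
      idx <- match(tab$Feature, m$features)
      imp[idx[!is.na(idx)]] <- tab$Gain[!is.na(idx)]
    }
    imp
  },
  score = function(m, X) {
    stats::predict(m$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  }
)

member_random_forest <- list(
  fit = function(X, y01, seed) {
    ranger::ranger(
      x = X, y = factor(y01, levels = c(0, 1)),
      num.trees = 100, importance = "impurity", probability = TRUE,
      seed = seed, num.threads = 1
    )
  },
  importance = function(m, p) pmax(m$variable.importance, 0),
  score = function(m, X) stats::predict(m, X, num.threads = 1)$predictions[, "1"]
)

# Bagging of decision trees: bootstrap-resampled trees that consider every
# feature at every split (mtry = p), i.e. bagged CART rather than a random
# forest; 10 base trees, averaged impurity importance.
member_bagging <- list(
  fit = function(X, y01, seed) {
    ranger::ranger(
      x = X, y = factor(y01, levels = c(0, 1)),
      num.trees = 10, mtry = ncol(X), replace = TRUE, sample.fraction = 1,
      importance = "impurity", probability = TRUE,
      seed = seed, num.threads = 1
    )
  },
  importance = function(m, p) pmax(m$variable.importance, 0),
  score = function(m, X) stats::predict(m, X, num.threads = 1)$predictions[, "1"]
)

#' The eight-member selection ensemble
#'
#' Returns the frozen specification of the ensemble used for feature
#' selection: a stochastic-gradient-descent linear classifier, a linear
#' support-vector classifier, gradient boosting, a random forest, logistic
#' regression, a passive-aggressive classifier, a ridge classifier and
#' bagging of decision trees. Per-feature importance is `|coefficient|`
#' for the five linear members, impurity importance for the forest,
#' split-gain importance for boosting, and the average of per-tree
#' normalized importances for bagging; each member's vector is
#' L1-normalized before averaging so no member dominates by scale.
#'
#' @return Named list of member definitions (`fit`/`importance`/`score`).
#' @export
refs_ensemble_spec <- function() {
  list(
    sgd = member_sgd,
    svc_linear = member_svc_linear,
    gradient_boosting = member_gradient_boosting,
    random_forest = member_random_forest,
    logistic_regression = member_logistic,
    passive_aggressive = member_passive_aggressive,
    ridge = member_ridge,
    bagging = member_bagging
  )
}

# ---- validation classifiers -------------------------------------------

# AdaBoost (discrete SAMME) on depth-1 decision stumps.
fit_adaboost <- function(X, y01, seed, n_estimators = 50L) {
  set.seed(seed)
  n <- nrow(X)
  df <- data.frame(.y = factor(y01, levels = c(0, 1)), X, check.names = FALSE)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_estimators)) {
    tr <- rpart::rpart(.y ~ ., data = df, weights = w,
      method = "class",
      control = rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2, xval = 0)
    )
    pred <- as.integer(as.character(stats::predict(tr, df, type = "class")))
    err <- sum(w * (pred != y01))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5 && m > 1L) break
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(alpha * ifelse(pred != y01, 1, -1))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- tr
    alphas <- c(alphas, alpha)
  }
  list(stumps = stumps, alphas = alphas)
}

score_adaboost <- function(model, X) {
  df <- as.data.frame(X, check.names = FALSE)
  s <- numeric(nrow(df))
  for (k in seq_along(model$stumps)) {
    pred <- as.integer(as.character(
      stats::predict(model$stumps[[k]], df, type = "class")
    ))
    s <- s + model$alphas[k] * ifelse(pred == 1L, 1, -1)
  }
  s
}

# k-nearest-neighbour score: fraction of the k nearest training samples
# (Euclidean) that are cases; ties in distance broken by training order.
fit_knn <- function(X, y01, k = 5L) {
  list(X = X, y = y01, k = min(k, nrow(X)))
}

score_knn <- function(model, X) {
  d2 <- outer(rowSums(X^2), rowSums(model$X^2), "+") - 2 * tcrossprod(X, model$X)
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(model$k)]
    mean(model$y[nn])
  })
}

validation_members <- function() {
  list(
    adaboost = list(
      fit = function(X, y01, seed) fit_adaboost(X, y01, seed),
      score = function(m, X) score_adaboost(m, X)
    ),
    extra_trees = list(
      fit = function(X, y01, seed) {
        ranger::ranger(
          x = X, y = factor(y01, levels = c(0, 1)),
          num.trees = 100, splitrule = "extratrees", num.random.splits = 1,
          replace = FALSE, sample.fraction = 1, probability = TRUE,
          seed = seed, num.threads = 1
        )
      },
      score = function(m, X) stats::predict(m, X, num.threads = 1)$predictions[, "1"]
    ),
    kneighbors = list(
      fit = function(X, y01, seed) fit_knn(X, y01),
      score = function(m, X) score_knn(m, X)
    ),
    mlp = list(
      fit = function(X, y01, seed) {
        set.seed(seed)
        # hidden width capped so the weight count stays near 2000: the
        # BFGS optimizer is quadratic in the number of weights, and the
        # panel must also run on wide pre-selection matrices
        size <- max(4L, min(32L, as.integer(2000 / (ncol(X) + 2L))))
        nnet::nnet(X, y01,
          size = size, decay = 1e-4, maxit = 200,
          MaxNWts = 100000, trace = FALSE, entropy = TRUE
        )
      },
      score = function(m, X) drop(stats::predict(m, X))
    ),
    lasso_cv = list(
      fit = function(X, y01, seed) {
        set.seed(seed)
        foldid <- sample(rep_len(1:5, nrow(X)))
        glmnet::cv.glmnet(X, y01,
          family = "gaussian", alpha = 1, foldid = foldid,
          standardize = FALSE
        )
      },
      score = function(m, X) drop(stats::predict(m, X, s = "lambda.min"))
    )
  )
}

#' The five held-out validation classifiers
#'
#' The panel evaluating a fixed signature, deliberately disjoint from the
#' selection ensemble: AdaBoost (SAMME on decision stumps), extremely
#' randomized trees, k-nearest neighbours (k = 5), a single-hidden-layer
#' multi-layer perceptron, and cross-validated lasso regression whose
#' continuous prediction is used directly as a ranking score (AUC only
#' needs a ranking, so no threshold is chosen).
#'
#' @return Named list of classifier definitions (`fit`/`score`).
#' @export
validation_classifier_spec <- function() validation_members()
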