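#' @importFrom e1071 svm
#' @importFrom nnet nnet class.ind
#' @importFrom xgboost xgboost
#' @importFrom pROC roc auc
NULL

MODEL_FAMILIES <- c("random_forest", "svm", "knn", "nn_1layer", "nn_2layer",
                    "xgboost")

#' Model specification
#'
#' @param family one of random_forest, svm, knn, nn_1layer, nn_2layer,
#'   xgboost.
#' @param grid data.frame hyperparameter grid (one row per configuration);
#'   defaults to [defaultGrid].
#' @param seed integer seed for all stochastic fitting.
#' @return a `modelSpec` list.
#' @export
modelSpec <- function(family, grid = NULL, seed = 1L) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(grid)) grid <- defaultGrid(family)
  if (!nrow(grid)) stop("hyperparameter grid must be non-empty")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "modelSpec")
}

#' Default hyperparameter grids
#'
#' Compact grids per family: forests over tree count and mtry fraction,
#' RBF-SVM over cost, kNN over neighbourhood size, single- and two-layer
#' networks over hidden width, boosting over depth and learning rate.
#'
#' @param family model family name.
#' @return data.frame grid.
#' @export
defaultGrid <- function(family) {
  switch(match.arg(family, MODEL_FAMILIES),
    random_forest = expand.grid(num_trees = c(250, 500),
                                mtry_frac = c(NA, 1 / 3)),
    svm = data.frame(cost = c(0.1, 1, 10)),
    knn = data.frame(k = c(3, 5, 7, 11)),
    nn_1layer = data.frame(size = c(8, 16, 32), decay = 0.01),
    nn_2layer = data.frame(size = c(8, 16, 32)),
    xgboost = expand.grid(max_depth = c(2, 4, 6), eta = c(0.05, 0.3),
                          nrounds = 150)
  )
}

# ---- two-hidden-layer multilayer perceptron (softmax output) ----------------

# tanh hidden units, softmax output, cross-entropy loss, Adam updates,
# early stopping on the training loss plateau
.mlpFit <- function(X, y, hidden = c(16, 16), epochs = 300, lr = 0.01,
                    patience = 30, seed = 1L) {
  set.seed(as.integer(seed))
  y <- droplevels(as.factor(y))
  Y <- class.ind(y)
  n <- nrow(X); p <- ncol(X); L <- ncol(Y)
  sizes <- c(p, hidden, L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                           sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z); E / rowSums(E)
  }
  best_loss <- Inf; stall <- 0; t <- 0
  for (ep in seq_len(epochs)) {
    # forward
    A <- list(X)
    for (l in seq_along(W)) {
      Z <- sweep(A[[l]] %*% W[[l]], 2, b[[l]], "+")
      A[[l + 1]] <- if (l < length(W)) tanh(Z) else softmax(Z)
    }
    P <- A[[length(A)]]
    loss <- -mean(log(pmax(rowSums(Y * P), 1e-12)))
    if (loss < best_loss - 1e-5) { best_loss <- loss; stall <- 0 } else {
      stall <- stall + 1
      if (stall >= patience) break
    }
    # backward
    delta <- (P - Y) / n
    for (l in rev(seq_along(W))) {
      gW <- crossprod(A[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (1 - A[[l]]^2)
      t <- t + 1
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      W[[l]] <- W[[l]] - lr * (mW[[l]] / (1 - beta1^t)) /
        (sqrt(vW[[l]] / (1 - beta2^t)) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / (1 - beta1^t)) /
        (sqrt(vb[[l]] / (1 - beta2^t)) + eps)
    }
  }
  list(W = W, b = b, levels = levels(y))
}

.mlpPredict <- function(fit, X) {
  A <- X
  W <- fit$W; b <- fit$b
  for (l in seq_along(W)) {
    Z <- sweep(A %*% W[[l]], 2, b[[l]], "+")
    A <- if (l < length(W)) tanh(Z) else {
      Z <- Z - apply(Z, 1, max); E <- exp(Z); E / rowSums(E)
    }
  }
  colnames(A) <- fit$levels
  A
}

# ---- kNN with full per-class vote fractions ---------------------------------

.knnVotes <- function(train, test, cl, k) {
  cl <- as.factor(cl)
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(test)), rowSums(train^2)) -
    2 * tcrossprod(test, train)
  votes <- matrix(0, nrow(test), nlevels(cl),
                  dimnames = list(rownames(test), levels(cl)))
  for (i in seq_len(nrow(test))) {
    nn <- order(d2[i, ])[seq_len(k)]
    tab <- table(cl[nn])
    votes[i, names(tab)] <- tab / k
  }
  votes
}

# ---- family fit / predict wrappers ------------------------------------------

.needsScaling <- function(family) family %in% c("svm", "knn", "nn_1layer",
                                                "nn_2layer")

.fitFamily <- function(family, X, y, params, seed) {
  y <- droplevels(as.factor(y))
  p <- ncol(X)
  switch(family,
    random_forest = {
      mtry <- if (is.na(params$mtry_frac)) floor(sqrt(p)) else
        max(1, floor(p * params$mtry_frac))
      dat <- data.frame(X, check.names = FALSE); dat$.y <- y
      ranger(dependent.variable.name = ".y", data = dat,
             num.trees = params$num_trees, mtry = min(mtry, p),
             probability = TRUE, importance = "impurity", seed = seed)
    },
    svm = svm(X, y, kernel = "radial", cost = params$cost,
              probability = TRUE),
    knn = list(train = X, cl = y, k = params$k),
    nn_1layer = {
      set.seed(seed)
      if (nlevels(y) == 2) {
        nnet(X, class.ind(y)[, 2], size = params$size, decay = params$decay,
             maxit = 300, entropy = TRUE, trace = FALSE, MaxNWts = 20000)
      } else {
        nnet(X, class.ind(y), size = params$size, decay = params$decay,
             maxit = 300, softmax = TRUE, trace = FALSE, MaxNWts = 20000)
      }
    },
    nn_2layer = .mlpFit(X, y, hidden = rep(params$size, 2), seed = seed),
    xgboost = xgboost(X, y, nrounds = params$nrounds,
                      max_depth = params$max_depth,
                      learning_rate = params$eta, verbosity = 0,
                      nthreads = 1, seed = seed))
}

.predictFamily <- function(family, fit, X, levels) {
  prob <- switch(family,
    random_forest = {
      pr <- predict(fit, data.frame(X, check.names = FALSE))$predictions
      pr[, levels, drop = FALSE]
    },
    svm = {
      pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
      pr[, levels, drop = FALSE]
    },
    knn = .knnVotes(fit$train, X, fit$cl, fit$k)[, levels, drop = FALSE],
    nn_1layer = {
      raw <- predict(fit, X)
      if (length(levels) == 2) {
        cbind(1 - raw[, 1], raw[, 1])
      } else raw[, levels, drop = FALSE]
    },
    nn_2layer = .mlpPredict(fit, X)[, levels, drop = FALSE],
    xgboost = {
      raw <- predict(fit, X)
      # binary: numeric vector of P(second level); multiclass: matrix
      if (is.null(dim(raw))) cbind(1 - raw, raw) else
        raw[, levels, drop = FALSE]
    })
  colnames(prob) <- levels
  rownames(prob) <- rownames(X)
  cls <- factor(levels[max.col(prob, ties.method = "first")],
                levels = levels)
  list(class = cls, prob = prob)
}

# log sample identifiers touched during tuning (leakage instrumentation)
.logAccess <- function(access_log, ids) {
  if (is.environment(access_log)) {
    access_log$ids <- union(access_log$ids, ids)
  }
  invisible(NULL)
}

#' Tune one model family by stratified cross-validation
#'
#' Grid search by stratified k-fold cross-validation on balanced accuracy,
#' followed by a refit of the best configuration on the full training
#' data. Feature scaling (center/sd from the training data) is applied for
#' the distance- and gradient-based families. Seed-deterministic. When an
#' `access_log` environment is supplied, every sample identifier the
#' tuning procedure touches is recorded in it, so that leakage onto a
#' held-out set can be audited.
#'
#' @param spec a [modelSpec].
#' @param X sample x feature training matrix (rownames = sample IDs).
#' @param y training labels.
#' @param folds CV folds, default 10.
#' @param access_log optional environment for access instrumentation.
#' @return a `tunedModel` list: family, fitted model, best_params,
#'   cv_score, class levels, scaling, feature names, seed.
#' @export
tuneModel <- function(spec, X, y, folds = 10, access_log = NULL) {
  stopifnot(inherits(spec, "modelSpec"))
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%04d", seq_len(nrow(X)))
  .logAccess(access_log, rownames(X))
  y <- droplevels(as.factor(y))
  levels <- levels(y)
  center <- scl <- NULL
  if (.needsScaling(spec$family)) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd); scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scl, "/")
  }
  set.seed(spec$seed)
  fold <- stratifiedFolds(y, folds)
  grid <- spec$grid
  cv <- numeric(nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    params <- grid[gidx, , drop = FALSE]
    accs <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- .fitFamily(spec$family, X[tr, , drop = FALSE], y[tr], params,
                        seed = spec$seed + f)
      pred <- .predictFamily(spec$family, fit, X[!tr, , drop = FALSE],
                             levels)
      accs[f] <- .balancedAccuracy(y[!tr], pred$class)
    }
    cv[gidx] <- mean(accs)
  }
  best <- which.max(cv)  # ties: first grid row
  fit <- .fitFamily(spec$family, X, y, grid[best, , drop = FALSE],
                    seed = spec$seed)
  structure(list(family = spec$family, fit = fit,
                 best_params = grid[best, , drop = FALSE],
                 cv_score = cv[best], cv_all = cv, levels = levels,
                 center = center, scale = scl,
                 feature_names = colnames(X), seed = spec$seed),
            class = "tunedModel")
}

#' Predict from a tuned model
#'
#' @param model a `tunedModel`.
#' @param X sample x feature matrix covering the model's features.
#' @return list with `class` (factor) and `prob` (matrix, one column per
#'   class).
#' @export
predictModel <- function(model, X) {
  stopifnot(inherits(model, "tunedModel"))
  X <- as.matrix(X)
  missing <- setdiff(model$feature_names, colnames(X))
  if (length(missing)) {
    stop("missing panel gene(s): ", paste(missing, collapse = ", "))
  }
  X <- X[, model$feature_names, drop = FALSE]
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  .predictFamily(model$family, model$fit, X, model$levels)
}

#' Classification metric suite
#'
#' Balanced accuracy (macro mean of per-class recall), F1, AUROC, Matthews
#' correlation coefficient, positive predictive value, sensitivity and
#' specificity, each on the [0, 1] scale. Binary metrics use the textbook
#' definitions with the second factor level (or `positive`) as the
#' positive class; multiclass metrics are macro one-vs-rest, with the
#' Gorodkin generalization for MCC and macro one-vs-rest AUROC. AUROC is
#' NA when probabilities are absent or y_true has a single class.
#'
#' @param y_true,y_pred aligned label vectors.
#' @param prob optional probability matrix (columns named by class).
#' @param positive positive class for binary problems.
#' @return an `EvalReport` list: `metrics` (named numeric), `confusion`,
#'   `prob`.
#' @export
computeMetrics <- function(y_true, y_pred, prob = NULL, positive = NULL) {
  y_true <- as.factor(y_true)
  lev <- levels(y_true)
  y_pred <- factor(as.character(y_pred), levels = lev)
  if (length(y_true) != length(y_pred)) stop("unaligned label vectors")
  cm <- table(true = y_true, pred = y_pred)
  L <- length(lev)
  recall <- vapply(lev, function(l) {
    d <- sum(cm[l, ]); if (d == 0) NA_real_ else cm[l, l] / d
  }, numeric(1))
  precision <- vapply(lev, function(l) {
    d <- sum(cm[, l]); if (d == 0) NA_real_ else cm[l, l] / d
  }, numeric(1))
  bal_acc <- mean(recall, na.rm = TRUE)
  if (L == 2) {
    pos <- if (is.null(positive)) lev[2] else match.arg(positive, lev)
    neg <- setdiff(lev, pos)
    tp <- cm[pos, pos]; tn <- cm[neg, neg]
    fp <- cm[neg, pos]; fn <- cm[pos, neg]
    sens <- recall[pos]; spec <- recall[neg]; ppv <- precision[pos]
    f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_ else
      2 * ppv * sens / (ppv + sens)
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    auroc <- NA_real_
    if (!is.null(prob) && length(unique(y_true)) == 2) {
      auroc <- as.numeric(auc(roc(response = y_true,
                                  predictor = prob[, pos],
                                  levels = c(neg, pos), direction = "<",
                                  quiet = TRUE)))
    }
  } else {
    sens <- mean(recall, na.rm = TRUE)
    spec <- mean(vapply(lev, function(l) {
      tn <- sum(cm[lev != l, lev != l]); fp <- sum(cm[lev != l, l])
      if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    }, numeric(1)), na.rm = TRUE)
    ppv <- mean(precision, na.rm = TRUE)
    f1 <- mean(2 * precision * recall / (precision + recall), na.rm = TRUE)
    # Gorodkin R_K from the confusion matrix
    s <- sum(cm); c_ok <- sum(diag(cm))
    t_k <- rowSums(cm); p_k <- colSums(cm)
    num <- c_ok * s - sum(p_k * t_k)
    den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
    mcc <- if (den == 0) 0 else num / den
    auroc <- NA_real_
    if (!is.null(prob)) {
      aucs <- vapply(lev, function(l) {
        if (length(unique(y_true == l)) < 2) return(NA_real_)
        as.numeric(auc(roc(response = factor(y_true == l,
                                             c(FALSE, TRUE)),
                           predictor = prob[, l],
                           levels = c("FALSE", "TRUE"), direction = "<",
                           quiet = TRUE)))
      }, numeric(1))
      auroc <- mean(aucs, na.rm = TRUE)
    }
  }
  metrics <- c(balanced_accuracy = unname(bal_acc), f1 = unname(f1),
               auroc = unname(auroc), mcc = unname(mcc),
               ppv = unname(ppv), sensitivity = unname(sens),
               specificity = unname(spec))
  structure(list(metrics = metrics, confusion = cm, prob = prob),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("EvalReport (x100):\n")
  print(round(x$metrics * 100, 2))
  invisible(x)
}

#' Nested model selection over classifier families
#'
#' Each family is tuned by cross-validation strictly on the training data
#' (instrumented so that no held-out sample is touched during tuning),
#' then evaluated once on the held-out test set; families are ranked by
#' holdout balanced accuracy, ties broken by MCC, then by the order the
#' specs were given.
#'
#' @param specs list of [modelSpec]s (one per family).
#' @param X_train,y_train training data.
#' @param X_test,y_test disjoint holdout data (non-empty).
#' @param folds inner CV folds, default 10.
#' @param access_log optional environment recording sample accesses during
#'   tuning.
#' @return list with `best` (tuned model), `best_family`, `reports`
#'   (EvalReport per family), `models` and the `ranking` data.frame.
#' @export
nestedSelect <- function(specs, X_train, y_train, X_test, y_test,
                         folds = 10, access_log = NULL) {
  if (!nrow(as.matrix(X_test))) stop("empty test set")
  models <- list(); reports <- list()
  for (sp in specs) {
    m <- tuneModel(sp, X_train, y_train, folds = folds,
                   access_log = access_log)
    pred <- predictModel(m, X_test)
    models[[sp$family]] <- m
    reports[[sp$family]] <- computeMetrics(y_test, pred$class, pred$prob)
  }
  bal <- vapply(reports, function(r) r$metrics["balanced_accuracy"],
                numeric(1))
  mcc <- vapply(reports, function(r) r$metrics["mcc"], numeric(1))
  ord <- order(-bal, -mcc, seq_along(bal))
  ranking <- data.frame(family = names(reports)[ord],
                        balanced_accuracy = bal[ord], mcc = mcc[ord],
                        row.names = NULL)
  best_family <- ranking$family[1]
  list(best = models[[best_family]], best_family = best_family,
       reports = reports, models = models, ranking = ranking)
}

#' Agreement ensemble with abstention
#'
#' Runs each member model on the input; a prediction is accepted only when
#' all members agree on the class (with the mean member probability as the
#' ensemble probability), otherwise the sample is rejected as ambiguous
#' (ABSTAIN). Reports coverage (accepted / n) and, when true labels are
#' given, accuracy over the accepted samples only.
#'
#' @param models list of >= 2 `tunedModel`s sharing a label set.
#' @param X sample x feature matrix.
#' @param y_true optional true labels.
#' @return list with `decisions` data.frame (prediction or "ABSTAIN",
#'   member predictions, probability), `coverage`, `accuracy_accepted`.
#' @export
ensembleVote <- function(models, X, y_true = NULL) {
  stopifnot(length(models) >= 2)
  levs <- lapply(models, function(m) m$levels)
  if (!all(vapply(levs, identical, logical(1), levs[[1]]))) {
    stop("ensemble members must share the same label set")
  }
  preds <- lapply(models, function(m) predictModel(m, X))
  n <- nrow(as.matrix(X))
  member <- vapply(preds, function(p) as.character(p$class), character(n))
  member <- matrix(member, nrow = n)
  agree <- apply(member, 1, function(r) length(unique(r)) == 1)
  prediction <- ifelse(agree, member[, 1], "ABSTAIN")
  prob <- rep(NA_real_, n)
  for (i in which(agree)) {
    prob[i] <- mean(vapply(preds, function(p) p$prob[i, member[i, 1]],
                           numeric(1)))
  }
  decisions <- data.frame(prediction = prediction, probability = prob,
                          stringsAsFactors = FALSE)
  for (j in seq_along(preds)) decisions[[paste0("member_", j)]] <- member[, j]
  coverage <- mean(agree)
  acc <- NA_real_
  if (!is.null(y_true) && any(agree)) {
    acc <- mean(prediction[agree] == as.character(y_true)[agree])
  }
  list(decisions = decisions, coverage = coverage, accuracy_accepted = acc)
}
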