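# Regression (W+, W-, v_before, v_after) and classification (turn side)
# model families, evaluated by 10-fold cross-validation (single 70/15/15
# split with validation-based early stopping for the neural network).

#' Model specification
#'
#' @param family one of `"multilinear"`, `"svr"`, `"boosted_trees"`, `"ann"`
#'   (regression) or `"lda"`, `"svm"`, `"boosted_trees"`, `"ann"`
#'   (classification).
#' @param trees number of boosting rounds for boosted trees.
#' @param tree_depth maximum tree depth.
#' @param learn_rate boosting learning rate.
#' @param hidden hidden-layer size of the neural network.
#' @param ann_split train/validation/test fractions for the single-split
#'   neural-network protocol.
#' @param ann_epoch_chunk,ann_max_chunks early-stopping schedule: the network
#'   is trained in chunks of `ann_epoch_chunk` epochs, keeping the weights
#'   with the best validation error, for at most `ann_max_chunks` chunks.
#' @param epsilon_frac SVR tube width as a fraction of SD(y).
#' @param cost SVM/SVR cost parameter.
#' @param seed seed controlling fold assignment and any stochastic fit.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("multilinear", "svr", "boosted_trees", "ann",
                                  "lda", "svm"),
                       trees = 40, tree_depth = 4, learn_rate = 0.1,
                       hidden = 40, ann_split = c(0.70, 0.15, 0.15),
                       ann_epoch_chunk = 100, ann_max_chunks = 8,
                       epsilon_frac = 0.1, cost = 1, seed = 1L) {
  family <- match.arg(family)
  if (abs(sum(ann_split) - 1) > 1e-8) abort("ann_split must sum to 1")
  structure(list(family = family, trees = trees, tree_depth = tree_depth,
                 learn_rate = learn_rate, hidden = hidden,
                 ann_split = ann_split, ann_epoch_chunk = ann_epoch_chunk,
                 ann_max_chunks = ann_max_chunks, epsilon_frac = epsilon_frac,
                 cost = cost, seed = as.integer(seed)),
            class = "model_spec")
}

fit_xgb <- function(X, y, objective, spec) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = objective, eta = spec$learn_rate,
                  max_depth = spec$tree_depth, nthread = 1),
    data = dtrain, nrounds = spec$trees, verbose = 0
  )
}

# Gaussian kernel width by the median heuristic: gamma = 1 / (2 * median
# pairwise distance^2), computed on at most 400 rows for speed.
median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 400) round(seq(1, n, length.out = 400)) else seq_len(n)
  d <- as.numeric(dist(X[idx, , drop = FALSE]))
  med <- median(d[d > 0])
  if (!is.finite(med) || med == 0) return(1 / ncol(X))
  1 / (2 * med^2)
}

#' Regression performance metrics
#'
#' `R^2 = 1 - SSE/SST` (can be negative out of sample), root-mean-square
#' error and mean absolute error.
#'
#' @param y_true,y_pred equal-length numeric vectors, n >= 2.
#' @return named numeric `c(r2 =, rmse =, mae =)`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("y_true and y_pred lengths differ")
  if (length(y_true) < 2) abort("need at least 2 observations")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) abort("R^2 undefined: y_true has zero variance")
  err <- y_true - y_pred
  c(r2 = 1 - sum(err^2) / sst,
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)))
}

# ---- family fits -----------------------------------------------------------

fit_predict_regress <- function(spec, X_tr, y_tr, X_te, X_val = NULL, y_val = NULL) {
  switch(spec$family,
    multilinear = {
      df <- as.data.frame(X_tr); df$.y <- y_tr
      fit <- lm(.y ~ ., data = df)
      list(pred = unname(predict(fit, as.data.frame(X_te))), fit = fit)
    },
    svr = {
      gamma <- median_heuristic_gamma(X_tr)
      fit <- e1071::svm(x = X_tr, y = y_tr, type = "eps-regression",
                        kernel = "radial", gamma = gamma,
                        epsilon = spec$epsilon_frac * sd(y_tr), cost = spec$cost,
                        scale = TRUE)
      list(pred = unname(predict(fit, X_te)), fit = fit,
           hyper = list(gamma = gamma, epsilon = spec$epsilon_frac * sd(y_tr)))
    },
    boosted_trees = {
      fit <- fit_xgb(X_tr, y_tr, "reg:squarederror", spec)
      list(pred = unname(predict(fit, xgboost::xgb.DMatrix(X_te, nthread = 1))), fit = fit)
    },
    ann = {
      fit <- fit_ann(spec, X_tr, y_tr, X_val, y_val, classify = FALSE)
      list(pred = predict_ann(fit, X_te), fit = fit)
    },
    abort(sprintf("family '%s' is not a regression family", spec$family))
  )
}

fit_predict_classify <- function(spec, X_tr, y_tr, X_te, X_val = NULL, y_val = NULL) {
  # y is a factor with levels c("left", "right"); scores are P(left)
  switch(spec$family,
    lda = {
      fit <- MASS::lda(x = X_tr, grouping = y_tr)
      pr <- predict(fit, X_te)
      list(class = as.character(pr$class), score = pr$posterior[, "left"], fit = fit)
    },
    svm = {
      gamma <- median_heuristic_gamma(X_tr)
      fit <- e1071::svm(x = X_tr, y = y_tr, type = "C-classification",
                        kernel = "radial", gamma = gamma, cost = spec$cost,
                        scale = TRUE, probability = TRUE)
      pr <- predict(fit, X_te, probability = TRUE)
      list(class = as.character(pr),
           score = attr(pr, "probabilities")[, "left"], fit = fit)
    },
    boosted_trees = {
      fit <- fit_xgb(X_tr, as.numeric(y_tr == "left"), "binary:logistic", spec)
      score <- unname(predict(fit, xgboost::xgb.DMatrix(X_te, nthread = 1)))
      list(class = ifelse(score >= 0.5, "left", "right"), score = score, fit = fit)
    },
    ann = {
      fit <- fit_ann(spec, X_tr, as.numeric(y_tr == "left"),
                     X_val, if (!is.null(y_val)) as.numeric(y_val == "left"),
                     classify = TRUE)
      score <- predict_ann(fit, X_te)
      list(class = ifelse(score >= 0.5, "left", "right"), score = score, fit = fit)
    },
    abort(sprintf("family '%s' is not a classification family", spec$family))
  )
}

# Single-hidden-layer network with chunked training and validation-based
# early stopping; inputs standardized, regression targets standardized too.
fit_ann <- function(spec, X_tr, y_tr, X_val = NULL, y_val = NULL, classify = FALSE) {
  ctr <- list(mean = colMeans(X_tr), sd = pmax(apply(X_tr, 2, sd), 1e-8))
  Xs <- scale(X_tr, ctr$mean, ctr$sd)
  if (classify) {
    ys <- y_tr; y_scale <- list(mean = 0, sd = 1)
  } else {
    y_scale <- list(mean = mean(y_tr), sd = max(sd(y_tr), 1e-8))
    ys <- (y_tr - y_scale$mean) / y_scale$sd
  }
  has_val <- !is.null(X_val) && length(y_val) > 0
  if (has_val) {
    Xvs <- scale(X_val, ctr$mean, ctr$sd)
    yvs <- if (classify) y_val else (y_val - y_scale$mean) / y_scale$sd
  }
  best <- NULL; best_err <- Inf; wts <- NULL
  for (chunk in seq_len(spec$ann_max_chunks)) {
    args <- list(x = Xs, y = ys, size = spec$hidden, decay = 1e-3,
                 maxit = spec$ann_epoch_chunk, trace = FALSE,
                 MaxNWts = 5000, linout = !classify, entropy = classify)
    if (!is.null(wts)) args$Wts <- wts
    net <- do.call(nnet::nnet, args)
    wts <- net$wts
    if (has_val) {
      err <- mean((as.numeric(predict(net, Xvs)) - yvs)^2)
      if (err < best_err - 1e-8) { best_err <- err; best <- net } else break
    } else {
      best <- net
    }
  }
  list(net = best, x_center = ctr, y_scale = y_scale, classify = classify)
}

predict_ann <- function(fit, X) {
  Xs <- scale(X, fit$x_center$mean, fit$x_center$sd)
  p <- as.numeric(predict(fit$net, Xs))
  if (fit$classify) p else p * fit$y_scale$sd + fit$y_scale$mean
}

# ---- cross-validation drivers ---------------------------------------------

feature_cols <- function(data) grep("^F[0-9]+$", names(data), value = TRUE)

#' Cross-validated regression of a turn response
#'
#' Fits the requested family on a seeded random `k`-fold partition and pools
#' the held-out predictions into a single metric set. The neural-network
#' family instead uses (by default) a single 70/15/15
#' train/validation/test split with validation-based early stopping,
#' reporting metrics on the test portion; set `ann_mode = "cv"` to force it
#' through the same k-fold scheme (with an internal validation split per
#' fold).
#'
#' @param data tibble with the response and the feature columns.
#' @param response name of the response column (e.g. `"v_before"`).
#' @param spec a [model_spec()].
#' @param features feature column names; defaults to `F1...F18`.
#' @param k number of folds.
#' @param ann_mode `"split"` or `"cv"` (neural network only).
#' @return object of class `cod_eval`.
#' @export
crossval_regress <- function(data, response, spec, features = feature_cols(data),
                             k = 10, ann_mode = c("split", "cv")) {
  ann_mode <- match.arg(ann_mode)
  if (!inherits(spec, "model_spec")) abort("`spec` must be a model_spec")
  if (nrow(data) < k) abort(sprintf("fewer rows (%d) than folds (%d)", nrow(data), k))
  X <- as.matrix(data[, features]); y <- data[[response]]
  n <- nrow(X)
  preds <- withr::with_seed(spec$seed, {
    if (spec$family == "ann" && ann_mode == "split") {
      parts <- split_indices(n, spec$ann_split)
      fit <- fit_predict_regress(spec, X[parts$train, , drop = FALSE], y[parts$train],
                                 X[parts$test, , drop = FALSE],
                                 X[parts$val, , drop = FALSE], y[parts$val])
      tibble(row = parts$test, fold = NA_integer_, y = y[parts$test], y_hat = fit$pred)
    } else {
      folds <- sample(rep(seq_len(k), length.out = n))
      dplyr::bind_rows(lapply(seq_len(k), function(f) {
        tr <- which(folds != f); te <- which(folds == f)
        if (spec$family == "ann") {
          nv <- max(2, round(0.18 * length(tr)))
          vi <- sample(tr, nv); tri <- setdiff(tr, vi)
          fit <- fit_predict_regress(spec, X[tri, , drop = FALSE], y[tri],
                                     X[te, , drop = FALSE],
                                     X[vi, , drop = FALSE], y[vi])
        } else {
          fit <- fit_predict_regress(spec, X[tr, , drop = FALSE], y[tr],
                                     X[te, , drop = FALSE])
        }
        tibble(row = te, fold = f, y = y[te], y_hat = fit$pred)
      }))
    }
  })
  m <- regression_metrics(preds$y, preds$y_hat)
  importance <- if (spec$family == "boosted_trees") {
    fit_all <- withr::with_seed(spec$seed,
      fit_predict_regress(spec, X, y, X[1, , drop = FALSE])$fit)
    bt_feature_importance(fit_all, features)
  }
  structure(list(task = "regression", response = response, family = spec$family,
                 metrics = tibble(r2 = m[["r2"]], rmse = m[["rmse"]], mae = m[["mae"]]),
                 predictions = preds, importance = importance,
                 spec = spec, n = n, k = k, seed = spec$seed),
            class = "cod_eval")
}

#' Cross-validated turn-side classification
#'
#' Same scheme as [crossval_regress()] for the binary pivot-side label.
#' The positive class is `left`: sensitivity is the recall of left turns,
#' specificity that of right turns. AUC is computed from the pooled held-out
#' scores.
#'
#' @inheritParams crossval_regress
#' @param response name of the side column (factor or character,
#'   `"left"`/`"right"`).
#' @return object of class `cod_eval`.
#' @export
crossval_classify <- function(data, response = "side", spec,
                              features = feature_cols(data), k = 10,
                              ann_mode = c("split", "cv")) {
  ann_mode <- match.arg(ann_mode)
  if (!inherits(spec, "model_spec")) abort("`spec` must be a model_spec")
  y <- factor(data[[response]], levels = c("left", "right"))
  if (any(is.na(y))) abort("side labels must be 'left' or 'right'")
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present")
  if (nrow(data) < k) abort(sprintf("fewer rows (%d) than folds (%d)", nrow(data), k))
  X <- as.matrix(data[, features])
  n <- nrow(X)
  preds <- withr::with_seed(spec$seed, {
    if (spec$family == "ann" && ann_mode == "split") {
      parts <- split_indices(n, spec$ann_split)
      fit <- fit_predict_classify(spec, X[parts$train, , drop = FALSE], y[parts$train],
                                  X[parts$test, , drop = FALSE],
                                  X[parts$val, , drop = FALSE], y[parts$val])
      tibble(row = parts$test, fold = NA_integer_, y = as.character(y[parts$test]),
             class = fit$class, score = fit$score)
    } else {
      folds <- sample(rep(seq_len(k), length.out = n))
      dplyr::bind_rows(lapply(seq_len(k), function(f) {
        tr <- which(folds != f); te <- which(folds == f)
        if (spec$family == "ann") {
          nv <- max(2, round(0.18 * length(tr)))
          vi <- sample(tr, nv); tri <- setdiff(tr, vi)
          fit <- fit_predict_classify(spec, X[tri, , drop = FALSE], y[tri],
                                      X[te, , drop = FALSE],
                                      X[vi, , drop = FALSE], y[vi])
        } else {
          fit <- fit_predict_classify(spec, X[tr, , drop = FALSE], y[tr],
                                      X[te, , drop = FALSE])
        }
        tibble(row = te, fold = f, y = as.character(y[te]),
               class = fit$class, score = fit$score)
      }))
    }
  })
  tp <- sum(preds$class == "left" & preds$y == "left")
  tn <- sum(preds$class == "right" & preds$y == "right")
  npos <- sum(preds$y == "left"); nneg <- sum(preds$y == "right")
  auc <- if (length(unique(preds$score)) > 1) {
    as.numeric(pROC::auc(pROC::roc(response = preds$y, predictor = preds$score,
                                   levels = c("right", "left"), direction = "<",
                                   quiet = TRUE)))
  } else 0.5
  metrics <- tibble(
    accuracy = 100 * mean(preds$class == preds$y),
    sensitivity = 100 * tp / npos,
    specificity = 100 * tn / nneg,
    auc = auc
  )
  importance <- if (spec$family == "boosted_trees") {
    fit_all <- withr::with_seed(spec$seed,
      fit_predict_classify(spec, X, y, X[1, , drop = FALSE])$fit)
    bt_feature_importance(fit_all, features)
  }
  structure(list(task = "classification", response = response, family = spec$family,
                 metrics = metrics, predictions = preds, importance = importance,
                 spec = spec, n = n, k = k, seed = spec$seed),
            class = "cod_eval")
}

split_indices <- function(n, fractions) {
  idx <- sample(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  list(train = idx[seq_len(n_tr)],
       val = idx[n_tr + seq_len(n_va)],
       test = idx[(n_tr + n_va + 1):n])
}

#' Split-gain feature importance of a boosted-trees model
#'
#' Gain-based importance from the fitted booster, expanded to the full
#' feature list (features never used get 0) and normalized to sum to 1.
#'
#' @param fit a fitted `xgb.Booster`.
#' @param features feature names in training order.
#' @return tibble `feature`, `importance`, sorted by the feature order.
#' @export
bt_feature_importance <- function(fit, features) {
  if (!inherits(fit, "xgb.Booster")) abort("`fit` must be a fitted xgb.Booster")
  imp <- xgboost::xgb.importance(model = fit, feature_names = features)
  out <- tibble(feature = features,
                importance = imp$Gain[match(features, imp$Feature)])
  out$importance[is.na(out$importance)] <- 0
  tot <- sum(out$importance)
  if (tot > 0) out$importance <- out$importance / tot
  out
}

# ---- methods ---------------------------------------------------------------

#' @export
print.cod_eval <- function(x, ...) {
  cat(sprintf("<cod_eval> %s of '%s' by %s (n = %d)\n",
              x$task, x$response, x$family, x$n))
  print(as.data.frame(x$metrics), row.names = FALSE)
  invisible(x)
}

#' Tidy a cross-validation evaluation
#'
#' @param x a `cod_eval`.
#' @param ... unused.
#' @return one-row tibble of metrics with `response` and `family` columns.
#' @export
tidy.cod_eval <- function(x, ...) {
  dplyr::bind_cols(tibble(response = x$response, family = x$family), x$metrics)
}

#' @rdname tidy.cod_eval
#' @return `glance()`: one-row tibble with task, sample size, folds and seed.
#' @export
glance.cod_eval <- function(x, ...) {
  tibble(task = x$task, response = x$response, family = x$family,
         n = x$n, k = x$k, seed = x$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
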