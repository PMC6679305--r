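make_regression_data <- function(n = 200, sigma = 0, seed = 1, p = 5) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    beta <- seq_len(p) / p
    y <- drop(X %*% beta) + rnorm(n, 0, sigma)
    d <- tibble::as_tibble(as.data.frame(X))
    names(d) <- paste0("F", seq_len(p))
    d$y <- y
    d
  })
}

test_that("regression metrics agree with direct sums", {
  y <- c(1, 2, 3, 4, 7)
  yhat <- c(1.1, 1.8, 3.3, 3.6, 6.5)
  m <- regression_metrics(y, yhat)
  sse <- sum((y - yhat)^2)
  expect_equal(m[["r2"]], 1 - sse / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(m[["rmse"]], sqrt(sse / 5), tolerance = 1e-12)
  expect_equal(m[["mae"]], mean(abs(y - yhat)), tolerance = 1e-12)

  perfect <- regression_metrics(y, y)
  expect_equal(unname(perfect), c(1, 0, 0))
  expect_equal(regression_metrics(y, rep(mean(y), 5))[["r2"]], 0)
  expect_error(regression_metrics(rep(2, 4), rnorm(4)), "zero variance")
  expect_error(regression_metrics(1:3, 1:4), "lengths differ")
})

test_that("a noiseless linear response is fit perfectly by the linear family", {
  d <- make_regression_data(n = 120, sigma = 0)
  ev <- crossval_regress(d, "y", model_spec("multilinear", seed = 1), k = 10)
  expect_equal(ev$metrics$r2, 1, tolerance = 1e-9)
  expect_lt(ev$metrics$mae, 1e-9)
  expect_lt(ev$metrics$rmse, 1e-9)
})

test_that("held-out R2 approaches the analytic signal fraction", {
  sigma <- 1
  d <- make_regression_data(n = 800, sigma = sigma, seed = 3)
  signal_var <- var(d$y) - sigma^2
  target <- signal_var / (signal_var + sigma^2)
  ev <- crossval_regress(d, "y", model_spec("multilinear", seed = 2), k = 10)
  expect_equal(ev$metrics$r2, target, tolerance = 0.08)
})

test_that("a useless feature set cannot beat the constant baseline contract", {
  withr::with_seed(11, {
    d <- tibble::tibble(F1 = rnorm(150), F2 = rnorm(150), y = rnorm(150))
  })
  ev <- crossval_regress(d, "y", model_spec("multilinear", seed = 4), k = 10)
  expect_lt(ev$metrics$r2, 0.15)  # held-out R2 of noise hovers at/below zero
})

test_that("SVR, boosted trees and the network learn a nonlinear response", {
  withr::with_seed(21, {
    n <- 300
    d <- tibble::tibble(F1 = runif(n, -2, 2), F2 = runif(n, -2, 2))
    d$y <- sin(2 * d$F1) + d$F2^2 + rnorm(n, 0, 0.05)
  })
  lin <- crossval_regress(d, "y", model_spec("multilinear", seed = 5), k = 5)
  for (fam in c("svr", "boosted_trees")) {
    ev <- crossval_regress(d, "y", model_spec(fam, seed = 5), k = 5)
    expect_gt(ev$metrics$r2, lin$metrics$r2)
    expect_gt(ev$metrics$r2, 0.8)
  }
  ann <- crossval_regress(d, "y", model_spec("ann", hidden = 10, seed = 5))
  expect_gt(ann$metrics$r2, lin$metrics$r2)
})

test_that("LDA accuracy approaches the closed-form Bayes rate", {
  delta <- 1.2  # class-mean separation per coordinate, identity covariance
  n <- 3000
  withr::with_seed(31, {
    side <- rep(c("left", "right"), each = n / 2)
    mu <- ifelse(side == "left", delta / 2, -delta / 2)
    d <- tibble::tibble(F1 = rnorm(n, mu), F2 = rnorm(n, -mu), side = side)
  })
  bayes <- pnorm(sqrt(2 * delta^2) / 2)  # Phi(half Mahalanobis distance)
  ev <- crossval_classify(d, "side", model_spec("lda", seed = 6), k = 10)
  expect_equal(ev$metrics$accuracy / 100, bayes, tolerance = 0.02)
  expect_gt(ev$metrics$auc, 0.8)
})

test_that("shuffled labels give chance-level accuracy and AUC", {
  d <- small_processed()$turns
  d$side <- withr::with_seed(41, sample(d$side))
  ev <- crossval_classify(d, "side", model_spec("lda", seed = 7), k = 10)
  expect_gt(ev$metrics$accuracy, 35); expect_lt(ev$metrics$accuracy, 65)
  expect_gt(ev$metrics$auc, 0.35); expect_lt(ev$metrics$auc, 0.65)
})

test_that("classification errors surface for degenerate inputs", {
  d <- small_processed()$turns
  one <- d[d$side == "left", ]
  expect_error(crossval_classify(one, "side", model_spec("lda", seed = 1)),
               "both classes")
  expect_error(crossval_regress(d[1:5, ], "w_plus", model_spec("multilinear"), k = 10),
               "fewer rows")
})

test_that("boosted-trees importance concentrates on the causal feature", {
  withr::with_seed(51, {
    n <- 400
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 18), n)))
    names(d) <- paste0("F", 1:18)
    d$y <- 3 * d$F12
  })
  ev <- crossval_regress(d, "y", model_spec("boosted_trees", seed = 8), k = 5)
  imp <- ev$importance
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_gt(imp$importance[imp$feature == "F12"], 0.9)
})

test_that("importance on a pure-noise response stays near-uniform", {
  max_imp <- vapply(1:3, function(s) {
    withr::with_seed(60 + s, {
      n <- 500
      d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 18), n)))
      names(d) <- paste0("F", 1:18)
      d$y <- rnorm(n)
    })
    ev <- crossval_regress(d, "y", model_spec("boosted_trees", seed = s), k = 5)
    max(ev$importance$importance)
  }, numeric(1))
  expect_lt(max(max_imp), 3 / 18)
  expect_error(bt_feature_importance(lm(y ~ x, data.frame(x = 1:5, y = 1:5)),
                                     "F1"), "xgb.Booster")
})

test_that("evaluations are deterministic and tidy into metric tables", {
  d <- small_processed()$turns
  a <- crossval_classify(d, "side", model_spec("svm", seed = 12), k = 5)
  b <- crossval_classify(d, "side", model_spec("svm", seed = 12), k = 5)
  expect_identical(tidy(a), tidy(b))
  expect_named(tidy(a), c("response", "family", "accuracy", "sensitivity",
                          "specificity", "auc"))
  r <- crossval_regress(d, "v_before", model_spec("svr", seed = 12), k = 5)
  expect_named(tidy(r), c("response", "family", "r2", "rmse", "mae"))
  expect_true(r$metrics$rmse >= r$metrics$mae)
  expect_equal(glance(r)$n, nrow(d))
})

test_that("nonlinear families match or beat the linear one on speeds", {
  # ordering emerges at the full cohort scale (~900 turns); fold assignment
  # varies with the spec seed, so average the gap over several seeds
  d <- acceptance_screened()
  for (resp in c("v_before", "v_after")) {
    lin <- mean(vapply(1:3, function(s) {
      crossval_regress(d, resp, model_spec("multilinear", seed = s), k = 10)$metrics$r2
    }, numeric(1)))
    for (fam in c("svr", "boosted_trees")) {
      nl <- mean(vapply(1:3, function(s) {
        crossval_regress(d, resp, model_spec(fam, seed = s), k = 10)$metrics$r2
      }, numeric(1)))
      expect_gt(nl, lin - 0.02)
    }
  }
})

test_that("adding pure-noise features does not inflate held-out accuracy", {
  d <- make_regression_data(n = 300, sigma = 1, seed = 71, p = 4)
  base <- crossval_regress(d, "y", model_spec("multilinear", seed = 9), k = 10,
                           features = paste0("F", 1:4))
  d_noise <- d
  for (j in 5:12) d_noise[[paste0("F", j)]] <- withr::with_seed(700 + j, rnorm(300))
  wide <- crossval_regress(d_noise, "y", model_spec("multilinear", seed = 9), k = 10,
                           features = paste0("F", 1:12))
  expect_lt(wide$metrics$r2, base$metrics$r2 + 0.05)
})
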