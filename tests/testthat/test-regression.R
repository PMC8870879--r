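make_design <- function(n = 100, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("f", seq_len(p))
  beta <- c(2, -1, 0.5, rep(0, p - 3))
  list(X = X, y = drop(X %*% beta) + rnorm(n, 0, 0.5), beta = beta)
}

test_that("lambda = 0 recovers ordinary least squares", {
  m0 <- fit_elastic_net(cbind(x = 0:2), c(0, 1, 2), lambda = 0)
  expect_equal(unname(m0$coefficients_original), 1, tolerance = 1e-7)
  expect_equal(m0$intercept, 0, tolerance = 1e-7)
  d <- make_design(200, 5)
  fit <- fit_elastic_net(d$X, d$y, lambda = 0)
  ols <- unname(coef(lm(d$y ~ d$X))[-1])
  expect_equal(unname(fit$coefficients_original), ols, tolerance = 1e-6)
})

test_that("alpha = 0 matches the ridge closed form", {
  for (s in 1:5) {
    d <- make_design(80, 4, seed = s)
    lam <- 10^runif(1, -1, 2)
    fit <- fit_elastic_net(d$X, d$y, lambda = lam, alpha = 0,
                           standardize = FALSE)
    closed <- solve(crossprod(d$X) + diag(4) * lam / 2,
                    crossprod(d$X, d$y - mean(d$y)))
    expect_equal(unname(fit$coefficients_original), unname(drop(closed)),
                 tolerance = 1e-6)
  }
})

test_that("alpha = 1 on an orthonormal design soft-thresholds the OLS solution", {
  set.seed(3)
  Q <- qr.Q(qr(matrix(rnorm(60 * 3), 60)))  # orthonormal columns
  colnames(Q) <- paste0("q", 1:3)
  beta <- c(3, -1.5, 0.2)
  y <- drop(Q %*% beta)
  y <- y - mean(y)
  for (lam in c(0.5, 1, 3)) {
    fit <- fit_elastic_net(Q, y, lambda = lam, alpha = 1, standardize = FALSE)
    bhat <- drop(crossprod(Q, y))
    expected <- unname(sign(bhat) * pmax(abs(bhat) - lam / 2, 0))
    expect_equal(unname(fit$coefficients_original), expected, tolerance = 1e-6)
  }
})

test_that("a dominant penalty zeroes all coefficients", {
  d <- make_design(100, 4)
  fit <- fit_elastic_net(d$X, d$y, lambda = 1e9, alpha = 1)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, mean(d$y))
  expect_equal(unname(predict(fit, d$X)), rep(mean(d$y), 100))
})

test_that("the objective trace is monotone non-increasing on every fit", {
  for (s in 1:5) {
    d <- make_design(60, 6, seed = s + 10)
    fit <- fit_elastic_net(d$X, d$y, lambda = 10^runif(1, -2, 2),
                           alpha = runif(1))
    expect_true(all(diff(fit$objective) <= 1e-8 * pmax(1, abs(fit$objective[-1]))))
  }
})

test_that("lasso solutions agree with an independent implementation", {
  skip_if_not_installed("glmnet")
  d <- make_design(150, 6, seed = 20)
  # pre-center so both solvers minimize the identical penalized objective
  Xc <- scale(d$X, center = TRUE, scale = FALSE)
  yc <- d$y - mean(d$y)
  n <- nrow(Xc)
  for (lam in c(10, 30, 100)) {
    mine <- fit_elastic_net(Xc, yc, lambda = lam, alpha = 1,
                            standardize = FALSE)
    g <- glmnet::glmnet(Xc, yc, alpha = 1, lambda = lam / (2 * n),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-12)
    expect_equal(unname(mine$coefficients_original),
                 unname(as.numeric(coef(g))[-1]), tolerance = 1e-4)
  }
})

test_that("elastic-net solutions satisfy the KKT optimality conditions", {
  d <- make_design(150, 6, seed = 21)
  Xc <- scale(d$X, center = TRUE, scale = FALSE)
  yc <- d$y - mean(d$y)
  for (a in c(0.25, 0.5, 1)) {
    lam <- 30
    fit <- fit_elastic_net(Xc, yc, lambda = lam, alpha = a,
                           standardize = FALSE, tol = 1e-10)
    b <- unname(fit$coefficients_original)
    r <- yc - drop(Xc %*% b)
    grad <- -2 * drop(crossprod(Xc, r)) + lam * (1 - a) * b
    active <- b != 0
    # active coordinates: subgradient vanishes; inactive: bounded by lam*a
    expect_true(all(abs(grad[active] + lam * a * sign(b[active])) < 1e-4))
    expect_true(all(abs(grad[!active]) <= lam * a + 1e-4))
  }
})

test_that("coefficients shrink toward zero along the lasso path", {
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(80 * 4), 80)))
  colnames(Q) <- paste0("q", 1:4)
  y <- drop(Q %*% c(3, 2, -1, 0.5)); y <- y - mean(y)
  lams <- c(0.1, 0.5, 1, 2, 4, 8)
  paths <- sapply(lams, function(l) {
    abs(fit_elastic_net(Q, y, lambda = l, alpha = 1,
                        standardize = FALSE)$coefficients_original)
  })
  expect_true(all(apply(paths, 1, function(r) all(diff(r) <= 1e-9))))
})

test_that("prediction standardization round-trips and validates columns", {
  d <- make_design(100, 3, seed = 5)
  fit <- fit_elastic_net(d$X, d$y, lambda = 1, alpha = 0.5)
  insample <- predict(fit, d$X)
  expect_lte(mean((insample - d$y)^2) * 100, utils::tail(fit$objective, 1) + 1e-6)
  expect_error(predict(fit, d$X[, 1:2]), "f3")
  expect_error(fit_elastic_net(cbind(c(1, NA)), c(1, 2)), "non-finite")
})

test_that("sign pattern of strong effects is recovered on synthetic data", {
  set.seed(6)
  n <- 300
  X <- matrix(rnorm(n * 5), n); colnames(X) <- paste0("f", 1:5)
  beta <- c(4, -4, 3, 0, 0)
  y <- drop(X %*% beta) + rnorm(n, 1, 1)
  fit <- fit_elastic_net(X, y, lambda = 5, alpha = 0.5)
  expect_identical(sign(unname(fit$coefficients[1:3])), c(1, -1, 1))
})

test_that("residual variance follows its degrees-of-freedom formula", {
  d <- make_design(500, 3, seed = 7)
  fit <- fit_elastic_net(d$X, d$y, lambda = 0)
  # perfect fit on noiseless data
  y0 <- drop(d$X %*% c(1, 2, 3))
  fit0 <- fit_elastic_net(d$X, y0, lambda = 0)
  expect_equal(residual_variance(fit0, d$X, y0), 0, tolerance = 1e-10)
  # OLS estimate lands within 20% of the generating variance (0.5^2)
  expect_lt(abs(residual_variance(fit, d$X, d$y) - 0.25) / 0.25, 0.2)
  # adding a pure-noise predictor barely changes the estimate
  set.seed(8)
  Xp <- cbind(d$X, junk = rnorm(500))
  fitp <- fit_elastic_net(Xp, d$y, lambda = 0)
  expect_lt(abs(residual_variance(fitp, Xp, d$y) -
                  residual_variance(fit, d$X, d$y)) /
              residual_variance(fit, d$X, d$y), 0.05)
  small <- fit_elastic_net(d$X[1:3, ], d$y[1:3], lambda = 0)
  expect_warning(rv <- residual_variance(small, d$X[1:3, ], d$y[1:3]),
                 "undefined")
  expect_true(is.na(rv))
})

test_that("cross-validation selects sensible penalties", {
  # pure-noise target: CV picks a heavy penalty and an (effectively) empty
  # model; under the one-SE rule the model is exactly null
  nulls <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(150 * 6), 150); colnames(X) <- paste0("f", 1:6)
    y <- rnorm(150)
    cv <- cv_select(X, y, lambda_grid = 10^seq(-2, 4, length.out = 15),
                    alpha_grid = c(0.5, 1), n_folds = 5, seed = s)
    cv1 <- cv_select(X, y, lambda_grid = 10^seq(-2, 4, length.out = 15),
                     alpha_grid = c(0.5, 1), n_folds = 5, seed = s,
                     one_se = TRUE)
    (sum(cv$model$coefficients != 0) <= 1 ||
       max(abs(cv$model$coefficients)) < 0.2) &&
      sum(cv1$model$coefficients != 0) == 0
  }, logical(1))
  expect_gte(mean(nulls), 0.9)
  # strong linear signal: CV-MSE at the optimum near the irreducible variance
  set.seed(30)
  X <- matrix(rnorm(200 * 4), 200); colnames(X) <- paste0("f", 1:4)
  y <- drop(X %*% c(5, -3, 2, 1)) + rnorm(200, 0, 1)
  cv <- cv_select(X, y, lambda_grid = 10^seq(-2, 2, length.out = 10),
                  alpha_grid = c(0, 1), n_folds = 5, seed = 30)
  expect_lte(min(cv$cv_curve$mean_mse), 1.2 * 1)
  # single grid point is returned unchanged
  cv1 <- cv_select(X, y, lambda_grid = 2, alpha_grid = 0.5, n_folds = 3,
                   seed = 1)
  expect_equal(cv1$best_lambda, 2)
  expect_equal(cv1$best_alpha, 0.5)
})

test_that("tidy and glance expose the model on both scales", {
  d <- make_design(100, 3, seed = 9)
  fit <- fit_elastic_net(d$X, d$y, lambda = 2, alpha = 0.5, target = "sbp")
  td <- tidy(fit)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 4)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_identical(gl$n_nonzero, sum(fit$coefficients != 0))
})
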