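#' Fit an elastic-net regression by cyclic coordinate descent
#'
#' Minimizes
#' \deqn{SSE(\beta) + \lambda\,\alpha \sum_j |\beta_j|
#'   + \frac{\lambda(1-\alpha)}{2} \sum_j \beta_j^2}
#' where SSE is the residual sum of squares. `alpha = 1` is the lasso,
#' `alpha = 0` ridge; `lambda = 0` recovers ordinary least squares. The
#' solver cycles soft-threshold coordinate updates until the largest
#' coefficient change falls below `tol` (or `max_sweeps` is hit, with a
#' warning), asserting a non-increasing objective every sweep. Predictors are
#' standardized internally (zero mean, unit variance) and the response
#' centered; coefficients are reported on both scales.
#'
#' @param X Numeric matrix or data frame of predictors (no missing cells).
#' @param y Numeric response (mmHg for pressure targets).
#' @param lambda Penalty scale (>= 0).
#' @param alpha Mix in \[0, 1\] between lasso (1) and ridge (0).
#' @param standardize Standardize predictors internally (default `TRUE`).
#'   With `FALSE`, coefficients are fit on the data as given (used when
#'   comparing against closed forms).
#' @param tol Convergence tolerance on the max coefficient change (1e-7).
#' @param max_sweeps Sweep cap (10000).
#' @param beta_init Optional warm-start coefficients on the standardized
#'   scale (as returned in `$coefficients`), e.g. from a fit at a nearby
#'   lambda on the regularization path.
#' @param target Optional label ("sbp"/"dbp") carried in the model.
#' @return A `"bp_enet"` model: coefficients (standardized + original scale),
#'   intercept, penalty settings, standardization parameters, objective
#'   trace, convergence flag.
#' @export
fit_elastic_net <- function(X, y, lambda = 0, alpha = 0.5, standardize = TRUE,
                            tol = 1e-7, max_sweeps = 10000L, beta_init = NULL,
                            target = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, lambda >= 0,
            alpha >= 0, alpha <= 1)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, p); scl <- rep(1, p)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ybar <- mean(y)
  yc <- y - ybar

  xx <- colSums(Xs^2)                 # denominators of the coordinate update
  beta <- if (is.null(beta_init)) numeric(p) else as.numeric(beta_init)
  stopifnot(length(beta) == p)
  r <- yc - drop(Xs %*% beta)          # running residual yc - Xs %*% beta
  obj <- function(b, res) {
    sum(res^2) + lambda * alpha * sum(abs(b)) +
      lambda * (1 - alpha) / 2 * sum(b^2)
  }
  obj_trace <- obj(beta, r)
  converged <- FALSE
  for (sweep_i in seq_len(max_sweeps)) {
    max_delta <- 0
    for (j in seq_len(p)) {
      if (xx[j] == 0) next
      rho <- sum(Xs[, j] * r) + xx[j] * beta[j]
      # soft threshold at lambda*alpha/2 (objective uses SSE, gradient 2x)
      bj <- sign(rho) * max(abs(rho) - lambda * alpha / 2, 0) /
        (xx[j] + lambda * (1 - alpha) / 2)
      delta <- bj - beta[j]
      if (delta != 0) {
        r <- r - Xs[, j] * delta
        beta[j] <- bj
        max_delta <- max(max_delta, abs(delta))
      }
    }
    o <- obj(beta, r)
    if (o > utils::tail(obj_trace, 1) + 1e-8 * max(1, abs(o))) {
      stop("internal error: objective increased during coordinate descent")
    }
    obj_trace <- c(obj_trace, o)
    if (max_delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("coordinate descent did not converge; returning best iterate")
  beta_orig <- beta / scl
  intercept <- ybar - sum(beta_orig * ctr)
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 coefficients_original = stats::setNames(beta_orig, colnames(X)),
                 intercept = intercept, lambda = lambda, alpha = alpha,
                 center = ctr, scale = scl, y_mean = ybar,
                 n = n, features = colnames(X), target = target,
                 objective = obj_trace, converged = converged,
                 cv_curve = NULL),
            class = "bp_enet")
}

#' Predict from an elastic-net model
#'
#' Applies the training standardization to new data and returns predictions
#' on the original (mmHg) scale.
#'
#' @param object A `"bp_enet"` model.
#' @param newdata Matrix or data frame containing the training feature
#'   columns (matched by name; unknown/missing columns are an error).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.bp_enet <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("newdata is missing feature column(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[object$features])
  drop(X %*% object$coefficients_original) + object$intercept
}

#' Residual variance of a fitted model
#'
#' \eqn{\hat\sigma^2 = (y - \hat y)^\top (y - \hat y) / (n - m)} with m the
#' number of nonzero coefficients plus one for the intercept.
#'
#' @param model A `"bp_enet"` model.
#' @param X,y Data to evaluate on (typically the training set).
#' @return Residual variance (mmHg^2); `NA` with a warning when `n <= m`.
#' @export
residual_variance <- function(model, X, y) {
  m <- sum(model$coefficients != 0) + 1L
  n <- length(y)
  if (n <= m) { warning("n <= number of parameters; variance undefined"); return(NA_real_) }
  res <- y - predict(model, X)
  sum(res^2) / (n - m)
}

#' Cross-validated selection of (lambda, alpha)
#'
#' Seeded k-fold assignment; for every grid pair the mean held-out MSE is
#' computed and the minimizing pair selected (optionally the one-standard-
#' error rule: the largest lambda within one SE of the minimum, at the
#' minimizing alpha).
#'
#' @param X,y Training data.
#' @param lambda_grid Penalty grid (default 50 log-spaced values, 1e-3..1e3).
#' @param alpha_grid Mixing grid (default 0, 0.25, 0.5, 0.75, 1).
#' @param n_folds Folds (default 10).
#' @param seed Seed for fold assignment.
#' @param one_se Use the one-standard-error rule (default `FALSE`).
#' @return List with `best_lambda`, `best_alpha`, `cv_curve` (tibble:
#'   lambda, alpha, mean_mse, se_mse) and the refit `model` on all data.
#' @export
cv_select <- function(X, y, lambda_grid = 10^seq(-3, 3, length.out = 50),
                      alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                      n_folds = 10L, seed = 1L, one_se = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n_folds >= 2, length(lambda_grid) >= 1, length(alpha_grid) >= 1)
  if (n < 2 * n_folds) n_folds <- max(2L, n %/% 2L)
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  if (min(table(fold)) < 2) stop("a fold has fewer than 2 rows")
  grid <- expand.grid(lambda = lambda_grid, alpha = alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)
  mse <- matrix(NA_real_, nrow(grid), n_folds)
  lam_desc <- sort(unique(lambda_grid), decreasing = TRUE)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    for (a in alpha_grid) {
      warm <- NULL # warm-start down the regularization path
      for (lam in lam_desc) {
        fit <- fit_elastic_net(X[tr, , drop = FALSE], y[tr],
                               lambda = lam, alpha = a,
                               tol = 1e-6, max_sweeps = 2000L,
                               beta_init = warm)
        warm <- fit$coefficients
        pred <- predict(fit, X[!tr, , drop = FALSE])
        g <- which(grid$lambda == lam & grid$alpha == a)
        mse[g, f] <- mean((pred - y[!tr])^2)
      }
    }
  }
  curve <- tibble::tibble(lambda = grid$lambda, alpha = grid$alpha,
                          mean_mse = rowMeans(mse),
                          se_mse = apply(mse, 1, stats::sd) / sqrt(n_folds))
  best <- which.min(curve$mean_mse)
  if (one_se) {
    a_star <- curve$alpha[best]
    thr <- curve$mean_mse[best] + curve$se_mse[best]
    cand <- curve[curve$alpha == a_star & curve$mean_mse <= thr, ]
    best_lambda <- max(cand$lambda); best_alpha <- a_star
  } else {
    best_lambda <- curve$lambda[best]; best_alpha <- curve$alpha[best]
  }
  # refit on all data with the same warm-started path the CV fits used, so
  # the returned model is the estimator the CV error actually measured
  warm <- NULL; model <- NULL
  for (lam in lam_desc[lam_desc >= best_lambda]) {
    model <- fit_elastic_net(X, y, lambda = lam, alpha = best_alpha,
                             tol = 1e-6, max_sweeps = 2000L, beta_init = warm)
    warm <- model$coefficients
  }
  model$cv_curve <- curve
  list(best_lambda = best_lambda, best_alpha = best_alpha,
       cv_curve = curve, model = model)
}

#' @export
print.bp_enet <- function(x, ...) {
  cat("Elastic-net model", if (!is.null(x$target)) paste0("(", x$target, ")"),
      ": lambda =", format(x$lambda, digits = 4),
      ", alpha =", format(x$alpha), "\n")
  nz <- sum(x$coefficients != 0)
  cat(" ", nz, "of", length(x$coefficients), "coefficients nonzero;",
      "intercept =", format(x$intercept, digits = 5), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an elastic-net model
#'
#' @param x A `"bp_enet"` model.
#' @param ... Unused.
#' @return Tibble with one row per term: `term`, `estimate` (original
#'   scale), `estimate_std` (standardized scale).
#' @export
tidy.bp_enet <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$features),
                 estimate = c(x$intercept, unname(x$coefficients_original)),
                 estimate_std = c(NA_real_, unname(x$coefficients)))
}

#' One-row model summary
#'
#' @param x A `"bp_enet"` model.
#' @param ... Unused.
#' @return Tibble: lambda, alpha, n, n_nonzero, converged, final objective.
#' @export
glance.bp_enet <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, alpha = x$alpha, n = x$n,
                 n_nonzero = sum(x$coefficients != 0),
                 converged = x$converged,
                 objective = utils::tail(x$objective, 1))
}

#' Tidy a feature-selection result
#'
#' @param x A `"bp_selection"` object.
#' @param ... Unused.
#' @return Tibble with one row per feature in the fused ranking plus its SU
#'   and ReliefF weight, and membership flags for S1 and S'.
#' @export
tidy.bp_selection <- function(x, ...) {
  su <- stats::setNames(x$su_ranking$su, x$su_ranking$feature)
  w <- stats::setNames(x$relieff$weight, x$relieff$feature)
  dplyr::mutate(x$fused,
                su = unname(su[.data$feature]),
                relieff_weight = unname(w[.data$feature]),
                in_s1 = .data$feature %in% x$s1,
                in_s_prime = .data$feature %in% x$s_prime)
}

#' @rdname tidy.bp_selection
#' @export
glance.bp_selection <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$su_ranking), n_s1 = length(x$s1),
                 n_s_prime = length(x$s_prime), final_p = x$final_p,
                 final_msu = x$final_msu, top_k = nrow(x$fused))
}
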