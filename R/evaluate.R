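#' Error summary: RMSE, MAE, mean error, SD of error
#'
#' Errors are defined as `pred - true` (predicted minus reference).
#'
#' @param pred,true Numeric vectors of equal, nonzero length (mmHg).
#' @return Tibble: `rmse`, `mae`, `mean_error`, `sd_error`, `n`.
#' @export
rmse_mae <- function(pred, true) {
  stopifnot(length(pred) == length(true), length(pred) > 0)
  e <- pred - true
  tibble::tibble(rmse = sqrt(mean(e^2)), mae = mean(abs(e)),
                 mean_error = mean(e), sd_error = stats::sd(e),
                 n = length(e))
}

bhs_thresholds <- function() {
  # cumulative-percentage floors within 5 / 10 / 15 mmHg
  list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
}

#' British Hypertension Society cumulative grading
#'
#' Computes the cumulative percentage of absolute errors within 5, 10 and
#' 15 mmHg and assigns the best grade whose all three floors are met
#' (A: 60/85/95, B: 50/75/90, C: 40/65/85; otherwise D).
#'
#' @param errors Signed or absolute errors in mmHg (non-empty).
#' @return List with `cumulative` (named percentages `within5`, `within10`,
#'   `within15`) and `grade` ("A".."D").
#' @export
bhs_grade <- function(errors) {
  stopifnot(length(errors) > 0)
  a <- abs(errors)
  cum <- c(within5 = 100 * mean(a <= 5),
           within10 = 100 * mean(a <= 10),
           within15 = 100 * mean(a <= 15))
  grade <- "D"
  for (g in c("C", "B", "A")) {
    if (all(cum >= bhs_thresholds()[[g]])) grade <- g
  }
  list(cumulative = cum, grade = grade)
}

#' AAMI-style accuracy check (advisory)
#'
#' Pass if |mean error| <= 5 mmHg and the error SD <= 8 mmHg. These
#' thresholds come from the AAMI device standard, external to this package's
#' method; the result is reported as advisory.
#'
#' @param errors Signed errors in mmHg (n >= 2).
#' @return Tibble: `mean_error`, `sd_error`, `pass`.
#' @export
aami_check <- function(errors) {
  stopifnot(length(errors) >= 2)
  me <- mean(errors); sde <- stats::sd(errors)
  tibble::tibble(mean_error = me, sd_error = sde,
                 pass = abs(me) <= 5 && sde <= 8)
}

#' Full evaluation report for one pressure target
#'
#' @param pred,true Predictions and references, mmHg.
#' @param target Label, `"sbp"` or `"dbp"`.
#' @return A `"bp_report"`: error metrics, BHS cumulative percentages and
#'   grade, advisory AAMI result, raw errors.
#' @export
evaluate_bp <- function(pred, true, target = c("sbp", "dbp")) {
  target <- match.arg(target)
  e <- pred - true
  structure(list(metrics = rmse_mae(pred, true), bhs = bhs_grade(e),
                 aami = aami_check(e), errors = e, target = target),
            class = "bp_report")
}

#' @export
print.bp_report <- function(x, ...) {
  m <- x$metrics
  cat(toupper(x$target), "evaluation (n =", m$n, ")\n")
  cat(sprintf("  RMSE %.2f mmHg | MAE %.2f mmHg | ME %+.2f | SD %.2f\n",
              m$rmse, m$mae, m$mean_error, m$sd_error))
  cum <- x$bhs$cumulative
  cat(sprintf("  BHS: %.1f%% <=5, %.1f%% <=10, %.1f%% <=15 mmHg -> Grade %s\n",
              cum["within5"], cum["within10"], cum["within15"], x$bhs$grade))
  cat(sprintf("  AAMI (advisory): %s\n", if (x$aami$pass) "pass" else "fail"))
  invisible(x)
}

#' @rdname tidy.bp_selection
#' @export
glance.bp_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(target = x$target),
    x$metrics,
    tibble::as_tibble(as.list(x$bhs$cumulative)),
    tibble::tibble(bhs_grade = x$bhs$grade, aami_pass = x$aami$pass))
}
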