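#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a waveform record with detected landmarks
#'
#' Stacked ECG/PPG/ABP traces over a time window; R peaks and PPG fiducials
#' are overlaid when supplied.
#'
#' @param record A record list (`ecg`, `ppg`, `abp`, `fs`).
#' @param r_peaks Optional R-peak indices.
#' @param fiducials Optional [detect_ppg_fiducials()] result.
#' @param xlim_s Time window in seconds (default first 10 s).
#' @return A ggplot object.
#' @export
plot_record <- function(record, r_peaks = NULL, fiducials = NULL,
                        xlim_s = c(0, 10)) {
  fs <- record$fs
  n <- length(record$ecg)
  t <- (seq_len(n) - 1) / fs
  df <- tibble::tibble(
    t = rep(t, 3),
    value = c(record$ecg, record$ppg, record$abp),
    channel = factor(rep(c("ECG", "PPG", "ABP"), each = n),
                     levels = c("ECG", "PPG", "ABP")))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::coord_cartesian(xlim = xlim_s) +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (!is.null(r_peaks)) {
    rp <- tibble::tibble(t = (r_peaks - 1) / fs,
                         value = record$ecg[r_peaks], channel = factor("ECG"))
    p <- p + ggplot2::geom_point(data = rp, colour = "red", size = 1)
  }
  if (!is.null(fiducials)) {
    ok <- fiducials[fiducials$ok, ]
    fd <- tidyr::pivot_longer(
      ok[c("foot", "sys_peak", "notch", "dia_peak")],
      cols = dplyr::everything(), names_to = "landmark", values_to = "idx")
    fd$t <- (fd$idx - 1) / fs
    fd$value <- record$ppg[fd$idx]
    fd$channel <- factor("PPG")
    p <- p + ggplot2::geom_point(
      data = fd, ggplot2::aes(colour = .data$landmark), size = 1)
  }
  p
}

#' Plot feature rankings from the hybrid selector
#'
#' @param object A `"bp_selection"` result.
#' @param ... Unused.
#' @return A ggplot bar chart of SU with the target, colored by membership
#'   in the predominant set.
#' @export
autoplot.bp_selection <- function(object, ...) {
  df <- dplyr::mutate(object$su_ranking,
                      set = dplyr::case_when(
                        .data$feature %in% object$s_prime ~ "S' (predominant)",
                        .data$feature %in% object$s1 ~ "S1 (relevant)",
                        TRUE ~ "dropped"))
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$feature, .data$su),
                                   .data$su, fill = .data$set)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$config$relevance_threshold,
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "symmetric uncertainty with target",
                  fill = NULL)
}

#' Plot the cross-validation curve of an elastic-net model
#'
#' @param object A `"bp_enet"` model with a CV curve.
#' @param ... Unused.
#' @return A ggplot of mean held-out MSE versus lambda per alpha.
#' @export
autoplot.bp_enet <- function(object, ...) {
  if (is.null(object$cv_curve)) stop("model has no CV curve; use cv_select()")
  ggplot2::ggplot(object$cv_curve,
                  ggplot2::aes(.data$lambda, .data$mean_mse,
                               colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::labs(x = expression(lambda), y = "mean CV MSE",
                  colour = expression(alpha))
}

#' Plot a BP evaluation report
#'
#' Histogram of signed errors with the 5/10/15 mmHg bands used by the BHS
#' grading.
#'
#' @param object A `"bp_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bp_report <- function(object, ...) {
  df <- tibble::tibble(error = object$errors)
  ggplot2::ggplot(df, ggplot2::aes(.data$error)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-15, -10, -5, 5, 10, 15),
                        linetype = 3, colour = "red") +
    ggplot2::labs(x = sprintf("%s error (mmHg), grade %s",
                              toupper(object$target), object$bhs$grade),
                  y = "windows")
}
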