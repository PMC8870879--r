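#' Pulse width at a fraction of peak amplitude
#'
#' Measures how long the pulse stays above `fraction * peak` amplitude
#' (relative to the foot baseline), split into the systolic part (upward
#' threshold crossing to peak) and the diastolic part (peak to downward
#' crossing). Crossing times are linearly interpolated between samples for
#' sub-sample accuracy. Lower fractions cut the pulse lower down, so widths
#' are monotone decreasing in the fraction.
#'
#' @param pulse Amplitude series covering the beat.
#' @param foot_idx,peak_idx,end_idx Sample indices (within `pulse`) of the
#'   foot, systolic peak and beat end.
#' @param fraction Amplitude fraction in (0, 1), e.g. 1/10, 1/4, 1/3, 1/2.
#' @param fs Sampling rate, Hz.
#' @return Named numeric vector `c(systolic, diastolic, total, ratio)` in
#'   seconds (ratio dimensionless = diastolic/systolic); all `NA` when the
#'   threshold is never crossed (degenerate pulse).
#' @export
width_at_fraction <- function(pulse, foot_idx, peak_idx, end_idx, fraction, fs) {
  stopifnot(fraction > 0, fraction < 1, foot_idx < peak_idx, peak_idx <= end_idx)
  base <- pulse[foot_idx]
  amp <- pulse[peak_idx] - base
  if (amp <= 0) return(c(systolic = NA, diastolic = NA, total = NA, ratio = NA))
  thr <- base + fraction * amp
  cross_up <- function(i0, i1) { # last upward crossing before the peak
    seg <- pulse[i0:i1]
    below <- which(seg[-length(seg)] < thr & seg[-1] >= thr)
    if (!length(below)) return(if (seg[1] >= thr) i0 else NA_real_)
    k <- below[length(below)]
    i0 + (k - 1) + (thr - seg[k]) / (seg[k + 1] - seg[k])
  }
  cross_down <- function(i0, i1) { # first downward crossing after the peak
    seg <- pulse[i0:i1]
    above <- which(seg[-length(seg)] >= thr & seg[-1] < thr)
    # still above threshold at the beat end (fast heart rate, low fraction):
    # the width is undefined for this beat and stays masked
    if (!length(above)) return(NA_real_)
    k <- above[1]
    i0 + (k - 1) + (seg[k] - thr) / (seg[k] - seg[k + 1])
  }
  up <- cross_up(foot_idx, peak_idx)
  dn <- cross_down(peak_idx, end_idx)
  if (is.na(up) || is.na(dn)) {
    return(c(systolic = NA, diastolic = NA, total = NA, ratio = NA))
  }
  sys_w <- (peak_idx - up) / fs
  dia_w <- (dn - peak_idx) / fs
  c(systolic = sys_w, diastolic = dia_w, total = sys_w + dia_w,
    ratio = if (sys_w > 0) dia_w / sys_w else NA_real_)
}

#' Extract per-beat morphological features
#'
#' Computes the beat-level feature set from the detected fiducials: heart
#' rate, pulse amplitudes and their ratio, pulse transit time (R peak to a
#' configurable PPG anchor, default the maximum-slope point), systolic and
#' diastolic times, fractional pulse widths at 1/10, 1/4, 1/3, 1/2 (systolic
#' + diastolic and their ratio) plus totals at 2/3 and 3/4, crest time,
#' delta-T, second-derivative amplitude ratios b/a, c/a, e/a, (b-e)/a, and
#' ECG wave durations/amplitudes for the P, QRS and T complexes. Beats with
#' missing or mis-ordered landmarks yield `NA` (masked) features.
#'
#' @param fiducials A [detect_ppg_fiducials()] result.
#' @param ecg,ppg Cleaned signals (`ppg` is min-max normalized internally).
#' @param fs Sampling rate, Hz.
#' @param ptt_anchor One of `"max_slope"` (default), `"foot"`, `"sys_peak"`.
#' @return Tibble, one row per beat, feature columns plus `ok`.
#' @export
extract_beat_features <- function(fiducials, ecg, ppg, fs,
                                  ptt_anchor = c("max_slope", "foot", "sys_peak")) {
  ptt_anchor <- match.arg(ptt_anchor)
  ppgn <- normalize_signal(ppg)
  fractions <- c(`1_10` = 1 / 10, `1_4` = 1 / 4, `1_3` = 1 / 3, `1_2` = 1 / 2)
  totals_only <- c(`2_3` = 2 / 3, `3_4` = 3 / 4)
  rows <- vector("list", nrow(fiducials))
  feet <- fiducials$foot
  for (i in seq_len(nrow(fiducials))) {
    b <- fiducials[i, ]
    rr <- (fiducials$r_peak[min(i + 1, nrow(fiducials))] - b$r_peak) / fs
    if (i == nrow(fiducials)) rr <- NA_real_
    beat_end <- if (i < nrow(fiducials) && !is.na(feet[i + 1])) {
      feet[i + 1]
    } else if (!is.na(b$dia_peak)) {
      min(length(ppgn), b$dia_peak + round(0.3 * fs))
    } else {
      NA_integer_
    }
    if (!isTRUE(b$ok) || is.na(beat_end) || is.na(rr) || rr <= 0) {
      rows[[i]] <- tibble::tibble(beat = b$beat, ok = FALSE); next
    }
    ppgmx <- ppgn[b$sys_peak]; ppgmn <- ppgn[b$foot]
    anchor_idx <- switch(ptt_anchor, max_slope = b$max_slope,
                         foot = b$foot, sys_peak = b$sys_peak)
    widths <- lapply(fractions, function(fr) {
      width_at_fraction(ppgn, b$foot, b$sys_peak, beat_end, fr, fs)
    })
    wtot <- lapply(totals_only, function(fr) {
      width_at_fraction(ppgn, b$foot, b$sys_peak, beat_end, fr, fs)
    })
    ecgw <- ecg_wave_features(ecg, b$r_peak, rr, fs)
    feat <- c(
      hr = 60 / rr,
      ppgmx = ppgmx, ppgmn = ppgmn,
      ac_amp = ppgmx - ppgmn,
      ppgir = if (ppgmn > 0) ppgmx / ppgmn else NA_real_,
      ptt = (anchor_idx - b$r_peak) / fs,
      s_t = (b$sys_peak - b$foot) / fs,
      d_t = (beat_end - b$sys_peak) / fs,
      stats::setNames(vapply(widths, `[[`, numeric(1), "diastolic"),
                      paste0("dias_", names(fractions))),
      stats::setNames(vapply(widths, `[[`, numeric(1), "total"),
                      paste0("d_s_", names(fractions))),
      stats::setNames(vapply(widths, `[[`, numeric(1), "ratio"),
                      paste0("ds_ratio_", names(fractions))),
      stats::setNames(vapply(wtot, `[[`, numeric(1), "total"),
                      paste0("d_s_", names(totals_only))),
      delta_t = b$delta_t_s,
      crest_time = b$crest_time_s,
      b_a = if (!is.na(b$a) && b$a != 0) b$b / b$a else NA_real_,
      c_a = if (!is.na(b$a) && b$a != 0) b$c / b$a else NA_real_,
      e_a = if (!is.na(b$a) && b$a != 0) b$e / b$a else NA_real_,
      be_a = if (!is.na(b$a) && b$a != 0) (b$b - b$e) / b$a else NA_real_,
      ecgw
    )
    rows[[i]] <- tibble::as_tibble(as.list(c(beat = b$beat, feat)))
    rows[[i]]$ok <- TRUE
  }
  dplyr::bind_rows(rows)
}

ecg_wave_features <- function(ecg, r_idx, rr_s, fs) {
  n <- length(ecg)
  win <- function(lo_s, hi_s) {
    lo <- max(1L, r_idx + round(lo_s * fs)); hi <- min(n, r_idx + round(hi_s * fs))
    if (hi <= lo) NULL else lo:hi
  }
  pick <- function(idx, fun) if (is.null(idx)) NA_integer_ else idx[fun(ecg[idx])]
  p_i <- pick(win(-0.26, -0.08), which.max)
  q_i <- pick(win(-0.07, -0.015), which.min)
  s_i <- pick(win(0.015, 0.07), which.min)
  t_i <- pick(win(0.12, min(0.45, 0.6 * rr_s)), which.max)
  half_width <- function(center, sign = 1) {
    if (is.na(center)) return(NA_real_)
    amp <- sign * ecg[center]
    lim <- round(0.12 * fs)
    lo <- max(1L, center - lim); hi <- min(n, center + lim)
    seg <- sign * ecg[lo:hi]
    thr <- amp / 2
    above <- which(seg >= thr)
    if (!length(above)) return(NA_real_)
    (max(above) - min(above)) / fs
  }
  c(p_dur = half_width(p_i), p_amp = if (is.na(p_i)) NA_real_ else ecg[p_i],
    qrs_dur = if (is.na(q_i) || is.na(s_i)) NA_real_ else (s_i - q_i) / fs,
    r_amp = ecg[r_idx],
    t_dur = half_width(t_i), t_amp = if (is.na(t_i)) NA_real_ else ecg[t_i])
}

#' Extract SBP/DBP reference targets from the ABP channel
#'
#' SBP is the per-beat maximum and DBP the per-beat minimum of the arterial
#' pressure within each beat window (consecutive R peaks).
#'
#' @param abp Calibrated arterial pressure, mmHg.
#' @param r_peaks R-peak sample indices delimiting beats.
#' @return Tibble with `beat`, `sbp`, `dbp` (mmHg).
#' @export
extract_targets_from_abp <- function(abp, r_peaks) {
  n_b <- length(r_peaks) - 1L
  if (n_b < 1) return(tibble::tibble(beat = integer(0), sbp = numeric(0), dbp = numeric(0)))
  sbp <- dbp <- numeric(n_b)
  for (i in seq_len(n_b)) {
    seg <- abp[r_peaks[i]:r_peaks[i + 1L]]
    sbp[i] <- max(seg); dbp[i] <- min(seg)
  }
  tibble::tibble(beat = seq_len(n_b), sbp = sbp, dbp = dbp)
}

#' Aggregate beat-level features into analysis-window rows
#'
#' Takes the per-feature median across accepted beats within each window
#' (robust to occasional per-beat detection noise). A window needs at least
#' `min_beats` accepted beats or it is dropped; a feature missing in more
#' than half the window's beats stays masked (`NA`) in the row.
#'
#' @param beat_features [extract_beat_features()] output joined with
#'   [extract_targets_from_abp()] targets (columns `sbp`, `dbp`).
#' @param r_peaks R-peak sample indices (for window assignment).
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, seconds (default 60).
#' @param min_beats Minimum accepted beats per window (default 5).
#' @return Tibble, one row per retained window, with feature medians, target
#'   medians and `n_beats`.
#' @export
aggregate_window <- function(beat_features, r_peaks, fs, window_s = 60,
                             min_beats = 5L) {
  bf <- dplyr::filter(beat_features, .data$ok)
  if (!nrow(bf)) return(tibble::tibble())
  bf$window <- floor(r_peaks[bf$beat] / (window_s * fs))
  feat_cols <- setdiff(names(bf), c("beat", "ok", "window"))
  med_masked <- function(v) {
    if (mean(is.na(v)) > 0.5) NA_real_ else stats::median(v, na.rm = TRUE)
  }
  out <- bf |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(n_beats = dplyr::n(),
                     dplyr::across(dplyr::all_of(feat_cols), med_masked),
                     .groups = "drop") |>
    dplyr::filter(.data$n_beats >= min_beats)
  out
}
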