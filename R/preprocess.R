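#' Filter specification for ECG/PPG cleaning
#'
#' Linear-phase FIR band-pass (order 50 by default) plus a powerline band-stop
#' notch and moving-average smoothing. The order must be even so the group
#' delay (`order/2` samples) is an integer shift and can be compensated
#' exactly. The default passband upper edge is clamped below the Nyquist
#' frequency of the supplied sampling rate.
#'
#' @param fs Sampling rate, Hz.
#' @param fir_order FIR order (even; default 50).
#' @param band Passband `c(low, high)` in Hz; default `c(0.5, min(100, 0.45*fs))`.
#' @param notch_hz Powerline frequency, 50 or 60 Hz (`NA` disables the notch,
#'   e.g. when the powerline band lies outside the passband anyway).
#' @param moving_avg_window Smoothing window length in samples (centered,
#'   zero delay); default 5.
#' @return A `"bp_filter_spec"` list.
#' @export
filter_spec <- function(fs, fir_order = 50L,
                        band = c(0.5, min(100, 0.45 * fs)),
                        notch_hz = 50, moving_avg_window = 5L) {
  stopifnot(fs > 0, fir_order > 0)
  if (fir_order %% 2 != 0) stop("`fir_order` must be even (integer group delay)")
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2)) {
    stop("passband must satisfy 0 < low < high < fs/2 = ", fs / 2, " Hz")
  }
  structure(list(fs = fs, fir_order = as.integer(fir_order), band = band,
                 notch_hz = notch_hz, moving_avg_window = as.integer(moving_avg_window)),
            class = "bp_filter_spec")
}

fir_apply <- function(x, b) {
  # causal linear-phase FIR; delay = (length(b)-1)/2 samples
  as.numeric(signal::filter(signal::Ma(b), x))
}

#' Compensate the group delay of a linear-phase FIR filter
#'
#' Advances the signal by `fir_order/2` samples and pads the tail with the
#' edge value, so that a filtered waveform re-aligns with the original (a
#' filtered delta impulse regains its maximum at the original index).
#'
#' @param x Filtered signal.
#' @param fir_order Even FIR order that produced the delay.
#' @return Aligned signal of the same length.
#' @export
compensate_group_delay <- function(x, fir_order) {
  if (fir_order %% 2 != 0) stop("`fir_order` must be even")
  d <- fir_order / 2
  if (d == 0) return(x)
  n <- length(x)
  c(x[(d + 1):n], rep(x[n], d))
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  pad <- floor(w / 2)
  xp <- c(rep(x[1], pad), x, rep(x[n], w - 1 - pad))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 1))[w:(n + w - 1)]
}

#' Clean an ECG trace
#'
#' Applies, in order: a zero-phase high-pass at the passband's low edge
#' (DC/baseline rejection that an order-50 FIR cannot realize at 0.5 Hz), a
#' powerline FIR band-stop notch, a linear-phase FIR band-pass, and a
#' centered moving-average smoother. Each FIR stage's group delay is
#' compensated (see [compensate_group_delay()]) so the output stays aligned
#' with the input and has the same length.
#'
#' @param x ECG amplitude series.
#' @param spec A [filter_spec()].
#' @param compensate Compensate FIR group delays (default `TRUE`).
#' @return Cleaned signal, same length as `x`.
#' @export
filter_ecg <- function(x, spec, compensate = TRUE) {
  stopifnot(inherits(spec, "bp_filter_spec"))
  if (length(x) <= 3 * spec$fir_order) {
    stop("signal too short for FIR order ", spec$fir_order)
  }
  fs <- spec$fs
  y <- remove_baseline(x, fs, cutoff_hz = spec$band[1])
  if (!is.na(spec$notch_hz) && spec$notch_hz < fs / 2) {
    bstop <- signal::fir1(spec$fir_order,
                          c(spec$notch_hz - 2, spec$notch_hz + 2) / (fs / 2),
                          type = "stop")
    y <- fir_apply(y, bstop)
    if (compensate) y <- compensate_group_delay(y, spec$fir_order)
  }
  bpass <- signal::fir1(spec$fir_order, spec$band / (fs / 2), type = "pass")
  y <- fir_apply(y, bpass)
  if (compensate) y <- compensate_group_delay(y, spec$fir_order)
  moving_average(y, spec$moving_avg_window)
}

#' Remove baseline wander / DC offset
#'
#' Zero-phase high-pass (order-4 Butterworth, forward-backward) attenuating
#' drift below `cutoff_hz`. The signal is reflection-padded before filtering
#' to suppress edge transients, so a constant input maps to ~0 everywhere.
#'
#' @param x Signal.
#' @param fs Sampling rate, Hz.
#' @param cutoff_hz High-pass cutoff (default 0.3 Hz, below cardiac band).
#' @return Detrended signal, same length.
#' @export
remove_baseline <- function(x, fs, cutoff_hz = 0.3) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  n <- length(x)
  if (stats::sd(x) == 0) return(numeric(n))
  pad <- min(n - 1L, as.integer(3 * fs / cutoff_hz))
  # odd (point-symmetric) reflection keeps the derivative continuous at the
  # joins, so no corner transient leaks into the retained segment
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "high")
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + n)]
}

#' Min-max normalize a signal to \[0, 1\]
#'
#' @param x Non-constant signal.
#' @return Signal affinely mapped so min = 0 and max = 1 (ordering preserved).
#' @export
normalize_signal <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) stop("constant signal cannot be normalized")
  (x - r[1]) / (r[2] - r[1])
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic QRS detector: band-pass 5-15 Hz, five-point derivative, squaring,
#' 150 ms moving-window integration, then dual adaptive thresholds on the
#' integrated signal with a search-back pass for missed beats and a 200 ms
#' refractory period. Each detection is refined to the local ECG maximum
#' within +/-60 ms.
#'
#' @param x Cleaned ECG.
#' @param fs Sampling rate, Hz.
#' @return Integer vector of R-peak sample indices (1-based); empty with a
#'   `"no_peaks"` warning-flag attribute when nothing is found (e.g. flatline).
#' @export
detect_r_peaks <- function(x, fs) {
  n <- length(x)
  if (n < fs || stats::sd(x) == 0) {
    out <- integer(0); attr(out, "quality_flag") <- "no_peaks"; return(out)
  }
  bp <- signal::fir1(50, c(5, 15) / (fs / 2), type = "pass")
  xf <- compensate_group_delay(fir_apply(x, bp), 50)
  # five-point derivative (Pan-Tompkins kernel), then squaring
  dk <- c(1, 2, 0, -2, -1) * fs / 8
  dx <- compensate_group_delay(as.numeric(signal::filter(signal::Ma(dk), xf)), 4)
  sq <- dx^2
  wi <- max(1L, round(0.150 * fs))
  mwi <- moving_average(sq, wi)

  refractory <- round(0.2 * fs)
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) {
    out <- integer(0); attr(out, "quality_flag") <- "no_peaks"; return(out)
  }
  spki <- max(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, 2 * fs))]) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  last <- -Inf
  for (p in cand) {
    v <- mwi[p]
    if (p - last < refractory) next
    if (v >= thr1) {
      peaks <- c(peaks, p); last <- p
      spki <- 0.125 * v + 0.875 * spki
    } else {
      npki <- 0.125 * v + 0.875 * npki
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  # search-back: re-scan long RR gaps with the lower threshold
  if (length(peaks) >= 2) {
    rr_avg <- mean(diff(peaks))
    thr2 <- 0.5 * (npki + 0.25 * (spki - npki))
    gaps <- which(diff(peaks) > 1.66 * rr_avg)
    for (g in gaps) {
      lo <- peaks[g] + refractory; hi <- peaks[g + 1] - refractory
      if (hi <= lo) next
      seg <- cand[cand > lo & cand < hi]
      seg <- seg[mwi[seg] >= thr2]
      if (length(seg)) peaks <- sort(c(peaks, seg[which.max(mwi[seg])]))
    }
  }
  if (!length(peaks)) {
    out <- integer(0); attr(out, "quality_flag") <- "no_peaks"; return(out)
  }
  # refine each detection to the local ECG maximum
  w <- round(0.06 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p - w)); hi <- min(n, as.integer(p + w))
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- unique(refined)
  # enforce refractory after refinement
  keep <- c(TRUE, diff(refined) >= refractory)
  refined[keep]
}

# ---- Daubechies-3 wavelet denoising -----------------------------------------

db3_scaling <- function() {
  # standard db3 (6-tap) orthonormal scaling filter coefficients
  c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
    -0.1350110200102546, -0.0854412738822415, 0.0352262918821007)
}

dwt_periodic <- function(x, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror (wavelet) filter
  n <- length(x)
  idx <- outer(seq(1, n, by = 2), seq_along(h) - 1L, "+")
  idx <- (idx - 1L) %% n + 1L
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = xm %*% h, d = xm %*% g)
}

idwt_periodic <- function(a, d, h) {
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n <- 2L * length(a)
  y <- numeric(n)
  for (k in seq_along(a)) {
    pos <- ((2 * (k - 1) + seq_along(h) - 1L) %% n) + 1L
    y[pos] <- y[pos] + a[k] * h + d[k] * g
  }
  y
}

#' Denoise a signal with a Daubechies-3 wavelet shrinkage
#'
#' Periodized db3 discrete wavelet transform to `levels` scales, universal
#' soft threshold (`sigma * sqrt(2 log n)`, sigma from the MAD of the finest
#' detail coefficients) on all detail bands, inverse transform. The db3
#' mother wavelet resembles a PPG upstroke, which is why it is the customary
#' choice for pulse-peak enhancement.
#'
#' @param x Signal (any length; internally zero-padded to a power of two).
#' @param levels Decomposition depth (default 4).
#' @return Denoised signal, same length as `x`.
#' @export
db3_denoise <- function(x, levels = 4L) {
  n <- length(x)
  if (n < 16) return(x)
  h <- db3_scaling()
  n2 <- 2^ceiling(log2(n))
  xp <- c(x, rep(x[n], n2 - n))
  levels <- min(levels, as.integer(log2(n2)) - 2L)
  a <- xp; details <- vector("list", levels)
  for (l in seq_len(levels)) {
    w <- dwt_periodic(a, h)
    a <- as.numeric(w$a); details[[l]] <- as.numeric(w$d)
  }
  sigma <- stats::mad(details[[1]])
  thr <- sigma * sqrt(2 * log(n2))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  for (l in rev(seq_len(levels))) {
    a <- idwt_periodic(a, soft(details[[l]]), h)
  }
  a[seq_len(n)]
}

local_extrema <- function(x, what = c("max", "min")) {
  what <- match.arg(what)
  s <- if (what == "max") x else -x
  which(diff(sign(diff(s))) < 0) + 1L
}

#' Detect per-beat PPG fiducial points
#'
#' For each beat (window between consecutive R peaks, extended by a transit
#' search margin) locates: the systolic peak (maximum of the db3-denoised
#' pulse), the preceding foot (local minimum), the maximum-slope point of the
#' upstroke, the dicrotic notch (local PPG minimum after the systolic peak,
#' falling back to the second-derivative zero-crossing pattern for weakly
#' pulsatile beats), and the diastolic peak. Derived timings: crest time
#' (foot to systolic peak), delta-T (interval between the positive-to-negative
#' zero crossings of the first derivative, i.e. systolic-to-diastolic peak
#' time), and the second-derivative landmark amplitudes a-e taken as the
#' successive alternating extrema starting in the systolic upstroke.
#'
#' @param ppg Cleaned PPG.
#' @param fs Sampling rate, Hz.
#' @param r_peaks R-peak sample indices.
#' @param search_margin_s Extra time after each RR window searched for the
#'   delayed pulse (default 0.6 s).
#' @return A tibble of class `"bp_fiducials"`, one row per beat, with sample
#'   indices `r_peak`, `foot`, `max_slope`, `sys_peak`, `notch`, `dia_peak`,
#'   times `crest_time_s`, `delta_t_s`, second-derivative amplitudes
#'   `a`,`b`,`c`,`d`,`e`, and a logical `ok` flag (beats with missing or
#'   mis-ordered landmarks are flagged, never imputed).
#' @export
detect_ppg_fiducials <- function(ppg, fs, r_peaks, search_margin_s = 0.6) {
  n <- length(ppg)
  den <- db3_denoise(ppg)
  d1 <- c(0, diff(den)) * fs
  d2 <- c(0, diff(d1)) * fs
  margin <- round(search_margin_s * fs)
  beats <- list()
  for (i in seq_len(length(r_peaks) - 1L)) {
    r0 <- r_peaks[i]; r1 <- r_peaks[i + 1L]
    hi <- min(n, r1 + margin)
    win <- r0:hi
    seg <- den[win]
    # systolic peak: first near-full-amplitude local max after the R peak
    # (a plain "first local max" can latch onto the previous beat's
    # diastolic wave when the transit time is long and the RR short)
    lm <- local_extrema(seg, "max")
    lm <- lm[seg[lm] >= min(seg) + 0.7 * (max(seg) - min(seg))]
    if (!length(lm)) {
      beats[[i]] <- fid_row(r0, ok = FALSE); beats[[i]]$beat <- i; next
    }
    sys_i <- win[lm[1]]
    # foot: last local minimum before the systolic peak (global min fallback)
    pre <- r0:sys_i
    mins <- local_extrema(den[pre], "min")
    foot_i <- if (length(mins)) pre[mins[length(mins)]] else pre[which.min(den[pre])]
    # max slope between foot and systolic peak
    up <- foot_i:sys_i
    slope_i <- up[which.max(d1[up])]
    # dicrotic notch: local min of PPG after systolic peak, before next foot
    post_hi <- min(hi, sys_i + round(0.6 * fs))
    post <- sys_i:post_hi
    nmins <- local_extrema(den[post], "min")
    notch_i <- if (length(nmins)) post[nmins[1]] else NA_integer_
    if (is.na(notch_i)) {
      # fallback: second-derivative positive-to-negative zero crossing pattern
      zc <- post[which(diff(sign(d2[post])) < 0)]
      if (length(zc)) notch_i <- zc[1]
    }
    dia_i <- NA_integer_
    if (!is.na(notch_i) && notch_i < post_hi) {
      dmax <- local_extrema(den[notch_i:post_hi], "max")
      if (length(dmax)) dia_i <- notch_i + dmax[1] - 1L
    }
    # delta-T: successive +/- zero crossings of the first derivative
    zc_pn <- win[which(d1[win][-length(win)] > 0 & d1[win][-1] <= 0)]
    delta_t <- if (length(zc_pn) >= 2) (zc_pn[2] - zc_pn[1]) / fs else NA_real_
    # a-e: alternating extrema of the second derivative from the upstroke on
    sd_win <- foot_i:post_hi
    ext <- sort(c(local_extrema(d2[sd_win], "max"), local_extrema(d2[sd_win], "min")))
    abcde <- rep(NA_real_, 5)
    if (length(ext) >= 1) {
      # start at the largest positive d2 extremum in the upstroke (the a wave)
      up_ext <- ext[sd_win[ext] <= sys_i]
      start <- if (length(up_ext)) up_ext[which.max(d2[sd_win][up_ext])] else ext[1]
      seq_ext <- ext[ext >= start]
      abcde[seq_len(min(5, length(seq_ext)))] <-
        d2[sd_win][seq_ext[seq_len(min(5, length(seq_ext)))]]
    }
    ok <- !anyNA(c(foot_i, slope_i, sys_i, notch_i, dia_i)) &&
      foot_i < sys_i && sys_i < notch_i && notch_i < dia_i
    beats[[i]] <- tibble::tibble(
      beat = i, r_peak = r0, foot = foot_i, max_slope = slope_i,
      sys_peak = sys_i, notch = notch_i, dia_peak = dia_i,
      crest_time_s = (sys_i - foot_i) / fs, delta_t_s = delta_t,
      a = abcde[1], b = abcde[2], c = abcde[3], d = abcde[4], e = abcde[5],
      ok = ok)
  }
  out <- dplyr::bind_rows(beats)
  class(out) <- c("bp_fiducials", class(out))
  attr(out, "fs") <- fs
  out
}

fid_row <- function(r0, ok = FALSE) {
  tibble::tibble(beat = NA_integer_, r_peak = r0, foot = NA_integer_,
                 max_slope = NA_integer_, sys_peak = NA_integer_,
                 notch = NA_integer_, dia_peak = NA_integer_,
                 crest_time_s = NA_real_, delta_t_s = NA_real_,
                 a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                 e = NA_real_, ok = ok)
}

#' Automated record quality screen
#'
#' Stand-in for manual record inspection: flags records with > 5% missing
#' samples, flatline segments longer than 2 s, heart rate outside
#' \[30, 200\] bpm, or arterial pressure outside \[30, 250\] mmHg. A record
#' is rejected if any flag is set.
#'
#' @param record List with `ecg`, `ppg`, `abp`, `fs` (a cohort record).
#' @return Named logical vector of flags with attribute `accepted`.
#' @export
screen_quality <- function(record) {
  fs <- record$fs
  flags <- c(missing = FALSE, flatline = FALSE, hr_range = FALSE, abp_range = FALSE)
  chans <- list(record$ecg, record$ppg, record$abp)
  miss <- vapply(chans, function(s) mean(!is.finite(s)), numeric(1))
  flags["missing"] <- any(miss > 0.05)
  flat_run <- function(s) {
    r <- rle(c(0, diff(s)) == 0)
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }
  flags["flatline"] <- any(vapply(chans, flat_run, integer(1)) > 2 * fs)
  if (!flags["missing"] && !flags["flatline"]) {
    rp <- detect_r_peaks(record$ecg, fs)
    hr <- if (length(rp) >= 2) 60 * fs / mean(diff(rp)) else NA_real_
    flags["hr_range"] <- is.na(hr) || hr < 30 || hr > 200
  } else {
    flags["hr_range"] <- TRUE
  }
  abp <- record$abp[is.finite(record$abp)]
  flags["abp_range"] <- length(abp) == 0 || min(abp) < 30 || max(abp) > 250
  attr(flags, "accepted") <- !any(flags)
  flags
}
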