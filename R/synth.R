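#' Configuration for the synthetic cohort generator
#'
#' The simulator emulates the study conditions of an ICU waveform dump:
#' synchronized single-lead ECG, fingertip PPG and arterial pressure sampled
#' at 125 Hz, one record per subject. Subject-level physiology (heart rate,
#' pulse transit time, pulse morphology) is drawn once per record, and the
#' per-record systolic/diastolic pressures follow a known generating model
#' \deqn{SBP = c_0 + c_1/PTT + c_2 HR + c_3 W_{50} + c_4 e^{-W_{10}/\tau} + \epsilon}
#' (and analogously for DBP with its own weights), so that every downstream
#' stage can be validated against exact ground truth. Exactly one nonlinear
#' term is planted per target so that information-theoretic and linear
#' rankings are guaranteed to differ when they should.
#'
#' @param n_subjects Number of records.
#' @param duration_s Seconds per record (default 30).
#' @param fs Sampling rate in Hz (default 125, the study convention).
#' @param hr_range Heart-rate interval in bpm, within \[30, 200\].
#' @param ptt_range Pulse-transit-time interval in seconds.
#' @param noise_sd White-noise SD as a fraction of signal amplitude.
#' @param bp_model Named list of generating coefficients; see
#'   `default_bp_model()`.
#' @param bp_noise_sd SD of the additive pressure noise, mmHg.
#' @param baseline_drift,powerline Amplitude fractions for sub-0.5 Hz drift
#'   and 50 Hz powerline contamination of the ECG (0 disables).
#' @param seed Integer seed; fixes all randomness, so equal configs give
#'   bit-identical cohorts.
#' @return A `"bp_synth_config"` list.
#' @export
synth_config <- function(n_subjects = 1L, duration_s = 30, fs = 125,
                         hr_range = c(55, 95), ptt_range = c(0.15, 0.35),
                         noise_sd = 0, bp_model = default_bp_model(),
                         bp_noise_sd = 0, baseline_drift = 0, powerline = 0,
                         seed = 1L) {
  stopifnot(fs > 0, duration_s > 0, n_subjects >= 1)
  if (hr_range[1] < 30 || hr_range[2] > 200 || hr_range[1] > hr_range[2]) {
    stop("`hr_range` must be an increasing interval within [30, 200] bpm")
  }
  if (ptt_range[1] <= 0) stop("`ptt_range` must be positive")
  structure(list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
                 fs = fs, hr_range = hr_range, ptt_range = ptt_range,
                 noise_sd = noise_sd, bp_model = bp_model,
                 bp_noise_sd = bp_noise_sd, baseline_drift = baseline_drift,
                 powerline = powerline, seed = as.integer(seed)),
            class = "bp_synth_config")
}

#' @rdname synth_config
#' @export
default_bp_model <- function() {
  list(
    # weights chosen to span a realistic adult pressure range (~95-165 SBP,
    # ~55-95 DBP) over the default HR/PTT/morphology draws
    sbp = c(c0 = 40, c1 = 14, c2 = 0.30, c3 = 60, c4 = 35),
    dbp = c(c0 = 25, c1 = 7, c2 = 0.15, c3 = 35, c4 = 18),
    tau = 0.5
  )
}

gauss_bump <- function(t, center, width, amp) {
  amp * exp(-0.5 * ((t - center) / width)^2)
}

# asymmetric bump: fast rise (width_l), slow decay (width_r) — the canonical
# PPG pulse shape with a steep systolic upstroke and gradual runoff
asym_bump <- function(t, center, width_l, width_r, amp) {
  w <- ifelse(t < center, width_l, width_r)
  amp * exp(-0.5 * ((t - center) / w)^2)
}

#' Generate a synthetic single-lead ECG with known R-peak times
#'
#' Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) at fixed
#' physiologic offsets from the R peak, which makes every landmark location
#' analytic and exact. Optional contamination: sub-0.5 Hz baseline drift, a
#' 50 Hz powerline sinusoid, and white noise.
#'
#' @param config A [synth_config()].
#' @param hr_bpm Optional fixed heart rate; when `NULL` one is drawn from
#'   `config$hr_range`.
#' @return List with `signal` (amplitude series), `t` (seconds),
#'   `r_peak_times` (seconds), `hr_bpm`.
#' @export
generate_ecg <- function(config, hr_bpm = NULL) {
  stopifnot(inherits(config, "bp_synth_config"))
  fs <- config$fs
  t <- seq(0, config$duration_s - 1 / fs, by = 1 / fs)
  if (is.null(hr_bpm)) hr_bpm <- stats::runif(1, config$hr_range[1], config$hr_range[2])
  rr <- 60 / hr_bpm
  r_times <- seq(rr / 2, config$duration_s - rr / 4, by = rr)
  sig <- numeric(length(t))
  waves <- list( # offset (s), width (s), amplitude — one row per ECG wave
    P = c(-0.17, 0.025, 0.12), Q = c(-0.035, 0.010, -0.10),
    R = c(0.000, 0.012, 1.00), S = c(0.035, 0.010, -0.18),
    T = c(0.22, 0.045, 0.28))
  for (rt in r_times) {
    for (w in waves) sig <- sig + gauss_bump(t, rt + w[1], w[2], w[3])
  }
  if (config$baseline_drift > 0) {
    sig <- sig + config$baseline_drift *
      sin(2 * pi * 0.25 * t + stats::runif(1, 0, 2 * pi))
  }
  if (config$powerline > 0) {
    sig <- sig + config$powerline * sin(2 * pi * 50 * t)
  }
  if (config$noise_sd > 0) sig <- sig + stats::rnorm(length(t), 0, config$noise_sd)
  list(signal = sig, t = t, r_peak_times = r_times, hr_bpm = hr_bpm)
}

#' Generate synchronized PPG and ABP pulses for given R-peak times
#'
#' Each PPG pulse is the sum of two positive Gaussian bumps — a systolic peak
#' and a delayed, smaller diastolic peak — giving a local minimum (the
#' dicrotic notch) between them. The pulse foot is delayed from the R peak by
#' the subject's pulse transit time. The ABP trace is an affine rescaling of
#' the same pulse shape so its per-beat maximum equals the true SBP and its
#' minimum the true DBP. True fractional-amplitude pulse widths (at 10% and
#' 50% of peak) are measured analytically on the noise-free pulse template
#' and recorded as generating covariates.
#'
#' @param config A [synth_config()].
#' @param r_peak_times R-peak times in seconds (increasing).
#' @param ptt_s,hr_bpm Optional fixed PTT (s) / heart rate; drawn from the
#'   config ranges when `NULL`.
#' @return List with `ppg`, `abp`, `t`, and a `truth` list carrying
#'   per-record fiducial times, `sbp_true`, `dbp_true`, morphology widths
#'   and the generating covariates.
#' @export
generate_ppg_abp <- function(config, r_peak_times, ptt_s = NULL, hr_bpm = NULL) {
  stopifnot(inherits(config, "bp_synth_config"), !is.unsorted(r_peak_times))
  fs <- config$fs
  t <- seq(0, config$duration_s - 1 / fs, by = 1 / fs)
  if (is.null(ptt_s)) ptt_s <- stats::runif(1, config$ptt_range[1], config$ptt_range[2])
  if (ptt_s <= 0) stop("sampled PTT must be positive")
  if (is.null(hr_bpm)) {
    hr_bpm <- if (length(r_peak_times) > 1) {
      60 / mean(diff(r_peak_times))
    } else {
      mean(config$hr_range)
    }
  }
  # subject-level pulse morphology (free choices; no quantitative PPG
  # amplitude model exists in the literature this emulates). The systolic
  # bump is asymmetric — steep upstroke, slow runoff — so the foot and
  # maximum-slope point are sharply identifiable, as in real pulses.
  rise_w <- stats::runif(1, 0.040, 0.060)     # systolic rise SD, s
  fall_w <- stats::runif(1, 0.090, 0.130)     # systolic decay SD, s
  dia_delay <- stats::runif(1, 0.32, 0.40)    # systolic-to-diastolic delay, s
  dia_amp <- stats::runif(1, 0.30, 0.45)      # diastolic relative amplitude
  rr <- if (length(r_peak_times) > 1) mean(diff(r_peak_times)) else 60 / hr_bpm
  sys_offset <- 2.5 * rise_w                  # foot-to-systolic-peak lag, s

  # bump separation is kept wide enough (delay >= 0.32, decay <= 0.13,
  # narrow diastolic rise) that a dicrotic notch provably exists between
  # the systolic and diastolic peaks for every draw
  pulse_template <- function(tt) {
    asym_bump(tt, sys_offset, rise_w, fall_w, 1) +
      asym_bump(tt, sys_offset + dia_delay, 0.06, 0.12, dia_amp)
  }
  # analytic template landmarks and widths on a fine grid (ground truth):
  # the composite extrema shift slightly off the bump centers because the
  # systolic runoff overlaps the diastolic wave, so record the true argmax
  tg <- seq(-0.2, rr, by = 1e-4)
  pv <- pulse_template(tg)
  w_at <- function(frac) {
    thr <- frac * max(pv)
    above <- which(pv >= thr)
    (tg[max(above)] - tg[min(above)])
  }
  w10 <- w_at(0.10); w50 <- w_at(0.50)
  sys_peak_lag <- tg[which.max(pv)]
  locmax <- which(diff(sign(diff(pv))) < 0) + 1L
  dia_cand <- locmax[tg[locmax] > sys_peak_lag + 0.5 * dia_delay]
  dia_peak_lag <- if (length(dia_cand)) tg[dia_cand[1]] else sys_offset + dia_delay

  onset_times <- r_peak_times + ptt_s
  ppg <- numeric(length(t))
  for (ot in onset_times) ppg <- ppg + pulse_template(t - ot)

  bp <- config$bp_model
  covars <- c(inv_ptt = 1 / ptt_s, hr = hr_bpm, w50 = w50,
              nl = exp(-w10 / bp$tau))
  lin <- function(cf) cf["c0"] + sum(cf[c("c1", "c2", "c3", "c4")] * covars)
  sbp_true <- unname(lin(bp$sbp)) + stats::rnorm(1, 0, config$bp_noise_sd)
  dbp_true <- unname(lin(bp$dbp)) + stats::rnorm(1, 0, config$bp_noise_sd)
  if (dbp_true >= sbp_true) dbp_true <- sbp_true - 10 # physiologic guard

  rng <- range(ppg)
  abp <- dbp_true + (sbp_true - dbp_true) * (ppg - rng[1]) / (rng[2] - rng[1])
  if (config$noise_sd > 0) {
    ppg <- ppg + stats::rnorm(length(t), 0, config$noise_sd)
    abp <- abp + stats::rnorm(length(t), 0, config$noise_sd)
  }
  truth <- list(
    r_peak_times = r_peak_times,
    ppg_fiducial_times = list(onset = onset_times,
                              systolic_peak = onset_times + sys_peak_lag,
                              diastolic_peak = onset_times + dia_peak_lag),
    sbp_true = sbp_true, dbp_true = dbp_true,
    ptt_s = ptt_s, hr_bpm = hr_bpm, w10 = w10, w50 = w50,
    covariates = covars,
    generating_coefficients = bp
  )
  list(ppg = ppg, abp = abp, t = t, truth = truth)
}

#' Simulate a cohort of synchronized ECG/PPG/ABP records
#'
#' Draws one record per subject from a single seeded generator. Subjects are
#' optionally corrupted (flatline segment injected) to exercise the quality
#' screen.
#'
#' @param config A [synth_config()].
#' @param corrupt_fraction Fraction of records receiving an injected 3 s
#'   flatline (default 0).
#' @return A `"bp_cohort"`: list of records, each a list with `record_id`,
#'   `ecg`, `ppg`, `abp`, `fs`, `truth`, `corrupted`.
#' @export
simulate_cohort <- function(config, corrupt_fraction = 0) {
  stopifnot(inherits(config, "bp_synth_config"))
  set.seed(config$seed)
  records <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    ecg <- generate_ecg(config)
    pa <- generate_ppg_abp(config, ecg$r_peak_times, hr_bpm = ecg$hr_bpm)
    corrupted <- stats::runif(1) < corrupt_fraction
    if (corrupted) {
      n <- length(ecg$signal)
      start <- sample.int(max(1L, n - 3L * config$fs), 1)
      idx <- start:min(n, start + 3L * config$fs)
      ecg$signal[idx] <- ecg$signal[idx][1]
    }
    records[[i]] <- list(record_id = sprintf("synth-%04d", i),
                         ecg = ecg$signal, ppg = pa$ppg, abp = pa$abp,
                         fs = config$fs, truth = pa$truth,
                         corrupted = corrupted)
  }
  structure(list(records = records, config = config), class = "bp_cohort")
}

#' Generate a feature table with planted dependence structure
#'
#' Builds a tabular test bed for the feature-selection stages: a target
#' \eqn{y = \sum a_i X_i + \sum b_j g(X_j) + \epsilon} with linear features,
#' nonlinear features through \eqn{g \in} \{square, sine, absolute value\} on
#' symmetric supports (so their Pearson correlation with y is ~0 by design),
#' redundant noisy copies of relevant columns, and independent noise columns.
#' Column roles are recorded in the `planted_roles` attribute.
#'
#' @param n_rows Number of rows (>= 50).
#' @param n_relevant_linear,n_relevant_nonlinear,n_redundant,n_noise Column
#'   counts per role.
#' @param effect_sizes List with `linear` and `nonlinear` coefficient
#'   magnitudes and `noise_sd` for the target noise; `copy_sd` is the SD of
#'   the perturbation added to redundant copies. The nonlinear default (2)
#'   roughly variance-matches a centered even transform of a Uniform(-1,1)
#'   variable to a unit-weight linear contribution; the copy default (0.3)
#'   keeps a copy strongly redundant with its parent while degrading its
#'   target dependence enough that the parent reliably outranks it.
#' @param seed Integer seed.
#' @return A tibble with columns `X1..` and `y`; attributes `planted_roles`
#'   (named character vector) and `generator` (coefficients used).
#' @export
generate_feature_table <- function(n_rows = 2000,
                                   n_relevant_linear = 3,
                                   n_relevant_nonlinear = 2,
                                   n_redundant = 0,
                                   n_noise = 10,
                                   effect_sizes = list(linear = 1, nonlinear = 2,
                                                       noise_sd = 0.1,
                                                       copy_sd = 0.3),
                                   seed = 1L) {
  stopifnot(n_rows >= 50, n_relevant_linear >= 0, n_relevant_nonlinear >= 0,
            n_redundant >= 0, n_noise >= 0)
  set.seed(as.integer(seed))
  n_rel <- n_relevant_linear + n_relevant_nonlinear
  if (n_redundant > 0 && n_rel == 0) stop("redundant columns need a relevant parent")
  gfuns <- c("square", "sine", "absolute")
  cols <- list(); roles <- character(0); coefs <- list()
  y <- numeric(n_rows)
  k <- 0
  for (i in seq_len(n_relevant_linear)) {
    k <- k + 1
    x <- stats::runif(n_rows, -1, 1)
    a <- effect_sizes$linear
    y <- y + a * x
    cols[[paste0("X", k)]] <- x
    roles[paste0("X", k)] <- "relevant_linear"
    coefs[[paste0("X", k)]] <- a
  }
  for (i in seq_len(n_relevant_nonlinear)) {
    k <- k + 1
    x <- stats::runif(n_rows, -1, 1)
    g <- gfuns[(i - 1) %% length(gfuns) + 1]
    # all transforms are even functions of x on a symmetric support, so the
    # planted nonlinear signal carries no linear component (Pearson ~ 0)
    gx <- switch(g, square = x^2, sine = abs(sin(pi * x)), absolute = abs(x))
    gx <- gx - mean(gx)
    b <- effect_sizes$nonlinear
    y <- y + b * gx
    cols[[paste0("X", k)]] <- x
    roles[paste0("X", k)] <- paste0("relevant_nonlinear_", g)
    coefs[[paste0("X", k)]] <- b
  }
  parents <- rep_len(names(roles)[startsWith(roles, "relevant")],
                     length.out = n_redundant)
  for (i in seq_len(n_redundant)) {
    k <- k + 1
    cols[[paste0("X", k)]] <- cols[[parents[i]]] +
      stats::rnorm(n_rows, 0, effect_sizes$copy_sd)
    roles[paste0("X", k)] <- paste0("redundant_of_", parents[i])
  }
  for (i in seq_len(n_noise)) {
    k <- k + 1
    cols[[paste0("X", k)]] <- stats::runif(n_rows, -1, 1)
    roles[paste0("X", k)] <- "noise"
  }
  y <- y + stats::rnorm(n_rows, 0, effect_sizes$noise_sd)
  out <- tibble::as_tibble(cols)
  out$y <- y
  attr(out, "planted_roles") <- roles
  attr(out, "generator") <- coefs
  out
}
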