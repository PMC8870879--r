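fs <- 125

test_that("filter spec enforces even order and Nyquist-bounded band", {
  expect_error(filter_spec(fs, fir_order = 51), "even")
  expect_error(filter_spec(fs, band = c(0.5, 80)), "fs/2")
  sp <- filter_spec(fs)
  expect_lt(sp$band[2], fs / 2)
})

test_that("powerline notch attenuates a pure 50 Hz tone", {
  t <- seq(0, 20, by = 1 / fs)
  tone <- sin(2 * pi * 50 * t)
  out <- filter_ecg(tone, filter_spec(fs))
  mid <- seq(2 * fs, length(out) - 2 * fs)
  expect_lt(sqrt(mean(out[mid]^2)), 0.05 * sqrt(mean(tone^2)))
})

test_that("band-pass rejects DC and preserves alignment after compensation", {
  t <- seq(0, 20, by = 1 / fs)
  offset <- rep(3, length(t))
  out <- filter_ecg(offset + 0.001 * sin(2 * pi * 10 * t), filter_spec(fs))
  expect_lt(abs(mean(out[(2 * fs):(length(out) - 2 * fs)])), 1e-3 * 3)
  # shape preservation: zero cross-correlation lag against the clean input
  set.seed(1)
  sig <- generate_ecg(synth_config(duration_s = 20, seed = 1), hr_bpm = 70)$signal
  filt <- filter_ecg(sig, filter_spec(fs))
  cc <- ccf(sig, filt, lag.max = 15, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("group-delay compensation recenters an impulse exactly", {
  imp <- numeric(2000); imp[500] <- 1
  b <- signal::fir1(50, c(5, 15) / (fs / 2), type = "pass")
  delayed <- as.numeric(signal::filter(signal::Ma(b), imp))
  expect_equal(which.max(abs(delayed)), 525)
  fixed <- compensate_group_delay(delayed, 50)
  expect_equal(which.max(abs(fixed)), 500)
  expect_identical(compensate_group_delay(imp, 0), imp)
  expect_error(compensate_group_delay(imp, 7), "even")
  # order 50 at 125 Hz corresponds to a 0.200 s shift
  expect_equal(25 / fs, 0.2)
})

test_that("baseline removal kills slow wander but not broadband content", {
  t <- seq(0, 60, by = 1 / fs)
  wander <- sin(2 * pi * 0.2 * t)
  set.seed(2)
  noise <- rnorm(length(t))
  out_w <- remove_baseline(wander, fs)
  expect_lt(max(abs(out_w)), 0.1) # >= 90% amplitude reduction
  out_n <- remove_baseline(noise, fs)
  expect_lt(abs(sd(out_n) / sd(noise) - 1), 0.1)
  expect_equal(remove_baseline(rep(5, 1000), fs), numeric(1000))
})

test_that("normalization maps to [0,1], preserves order, and is idempotent", {
  expect_equal(normalize_signal(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.3, 1, 0.6)
  expect_equal(normalize_signal(x), x)
  set.seed(3)
  z <- rnorm(100)
  expect_equal(which.max(normalize_signal(z)), which.max(z))
  expect_error(normalize_signal(rep(1, 10)), "constant")
})

test_that("Pan-Tompkins finds every beat of clean synthetic ECG within 3 samples", {
  cfg <- synth_config(duration_s = 60, seed = 4)
  set.seed(4)
  e <- generate_ecg(cfg, hr_bpm = 60)
  rp <- detect_r_peaks(filter_ecg(e$signal, filter_spec(fs)), fs)
  truth <- round(e$r_peak_times * fs) + 1
  expect_length(rp, length(truth))
  expect_true(all(vapply(truth, function(ti) min(abs(rp - ti)), numeric(1)) <= 3))
})

test_that("Pan-Tompkins keeps F1 >= 0.99 under 5% amplitude noise", {
  f1 <- vapply(1:20, function(s) {
    cfg <- synth_config(duration_s = 60, noise_sd = 0.05, seed = s)
    set.seed(s)
    e <- generate_ecg(cfg)
    rp <- detect_r_peaks(filter_ecg(e$signal, filter_spec(fs)), fs)
    peak_f1(rp, round(e$r_peak_times * fs) + 1, tol = 5)
  }, numeric(1))
  expect_true(all(f1 >= 0.99))
})

test_that("flatline input yields an empty detection with a quality flag", {
  out <- detect_r_peaks(rep(0.5, 10 * fs), fs)
  expect_length(out, 0)
  expect_identical(attr(out, "quality_flag"), "no_peaks")
})

test_that("PPG fiducials on noise-free pulses sit within one sample of truth", {
  cfg <- synth_config(duration_s = 30, seed = 6)
  set.seed(6)
  e <- generate_ecg(cfg, hr_bpm = 64)
  pa <- generate_ppg_abp(cfg, e$r_peak_times, ptt_s = 0.25, hr_bpm = 64)
  rp <- round(e$r_peak_times * fs) + 1
  fid <- detect_ppg_fiducials(pa$ppg, fs, rp)
  ok <- fid[fid$ok, ]
  expect_gt(nrow(ok), 0.9 * (length(rp) - 1))
  truth_sys <- pa$truth$ppg_fiducial_times$systolic_peak
  truth_dia <- pa$truth$ppg_fiducial_times$diastolic_peak
  off_sys <- vapply((ok$sys_peak - 1) / fs,
                    function(d) min(abs(truth_sys - d)), numeric(1))
  off_dia <- vapply((ok$dia_peak - 1) / fs,
                    function(d) min(abs(truth_dia - d)), numeric(1))
  expect_true(all(off_sys <= 1 / fs + 1e-9))
  expect_true(all(off_dia <= 1 / fs + 1e-9))
  # ordering invariants per accepted beat
  expect_true(all(ok$foot < ok$sys_peak & ok$sys_peak < ok$notch &
                    ok$notch < ok$dia_peak))
  expect_true(all(ok$crest_time_s > 0))
  expect_true(all(ok$delta_t_s > 0, na.rm = TRUE))
})

test_that("a constructed two-bump pulse has exactly one notch between peaks", {
  t <- seq(0, 1, by = 1 / fs)
  pulse <- exp(-0.5 * ((t - 0.3) / 0.05)^2) + 0.4 * exp(-0.5 * ((t - 0.55) / 0.07)^2)
  mins <- which(diff(sign(diff(pulse))) > 0) + 1
  between <- mins[t[mins] > 0.3 & t[mins] < 0.55]
  expect_length(between, 1)
})

test_that("quality screen rejects planted corruption at the planted rate", {
  rec_ok <- quiet_cohort(1, duration_s = 20, seed = 7)$records[[1]]
  flags <- screen_quality(rec_ok)
  expect_true(attr(flags, "accepted"))
  rec_bad <- rec_ok
  rec_bad$ecg[100:(100 + 3 * fs)] <- rec_bad$ecg[100]
  expect_false(attr(screen_quality(rec_bad), "accepted"))
  co <- simulate_cohort(synth_config(n_subjects = 40, duration_s = 20, seed = 8),
                        corrupt_fraction = 0.1)
  rejected <- !vapply(co$records, function(r) attr(screen_quality(r), "accepted"),
                      logical(1))
  planted <- vapply(co$records, `[[`, logical(1), "corrupted")
  expect_identical(rejected, planted)
})

test_that("db3 denoising preserves clean pulse peak locations", {
  t <- seq(0, 4, by = 1 / fs)
  clean <- sin(2 * pi * 1.2 * t)
  set.seed(9)
  noisy <- clean + rnorm(length(t), 0, 0.05)
  den <- db3_denoise(noisy)
  expect_length(den, length(noisy))
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})
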