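# Shared fixtures, built in code at test time.

quiet_cohort <- function(n_subjects = 2, duration_s = 30, seed = 1, ...) {
  simulate_cohort(synth_config(n_subjects = n_subjects, duration_s = duration_s,
                               seed = seed, ...))
}

# XOR-style interaction table: target depends on the sign product of two
# features, invisible to any marginal statistic.
xor_table <- function(n = 2000, n_noise = 10, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  x1 <- stats::runif(n, -1, 1); x2 <- stats::runif(n, -1, 1)
  noise <- as.data.frame(matrix(stats::runif(n * n_noise, -1, 1), n))
  names(noise) <- paste0("N", seq_len(n_noise))
  y <- sign(x1) * sign(x2) + stats::rnorm(n, 0, noise_sd)
  dplyr::bind_cols(tibble::tibble(x1 = x1, x2 = x2), noise,
                   tibble::tibble(y = y))
}

# F1 of detected vs true peak indices at a sample tolerance
peak_f1 <- function(detected, truth, tol = 5) {
  if (!length(detected) || !length(truth)) return(0)
  tp <- sum(vapply(truth, function(ti) any(abs(detected - ti) <= tol), logical(1)))
  2 * tp / (length(truth) + length(detected))
}
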