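## Shared fixtures and small independent oracles, all built in code.

## sinusoid EMG recording
sine_recording <- function(freq_hz, dur_s = 4, fs = 1024, muscle = "TA") {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  emg_recording(matrix(sin(2 * pi * freq_hz * t), 1), muscle, fs)
}

## circular supra-threshold burst count (merges a wrap-around run)
count_bursts <- function(h, rel = 0.20) {
  thr <- min(h) + rel * (max(h) - min(h))
  above <- h > thr
  r <- rle(above)
  n <- sum(r$values)
  if (length(r$values) > 1L && above[1L] && above[length(above)]) n <- n - 1L
  n
}

## circular left-rotation helper used to construct shifted profiles:
## delay x by k points
delay <- function(x, k) {
  n <- length(x)
  x[((seq_len(n) - 1L - k) %% n) + 1L]
}

## brute-force centered circular cross-correlation oracle (independent of
## circular_xcorr): explicit cor() at every rotation
xcorr_oracle <- function(x, y) {
  n <- length(x)
  r <- vapply(0:(n - 1L), function(k)
    stats::cor(x[((seq_len(n) - 1L + k) %% n) + 1L], y), numeric(1))
  half <- as.integer(floor(n / 2))
  lags <- as.integer(((0:(n - 1L) + half) %% n) - half)
  ord <- order(-r, abs(lags), -sign(lags))
  list(r_max = r[ord[1L]], lag = lags[ord[1L]], all = r)
}

## uniform cyclic piecewise-linear resampling oracle (independent of
## warp_profile's internals): knots at k/100, wrap back to the first point
uniform_resample_oracle <- function(p, L) {
  stats::approx(x = (0:100) / 100, y = c(p, p[1]), xout = (0:(L - 1)) / L)$y
}

## small random nonnegative synergy problem with known ground truth
random_synergy_problem <- function(N = 6, J = 3, Tn = 80, seed = 1) {
  set.seed(seed)
  W <- matrix(runif(N * J), N, J)
  H <- matrix(runif(J * Tn), J, Tn)
  list(W = W, H = H, M = W %*% H)
}

## canonical template + small cached cohort/threshold build shared by the
## slower end-to-end tests (built once per test run)
canonical_tpl <- make_canonical_template()

cohort_build_cache <- new.env()
get_cohort_build <- function() {
  if (is.null(cohort_build_cache$tb)) {
    coh <- make_healthy_cohort(canonical_tpl, seed = 42)
    cohort_build_cache$tb <- run_template_build(
      lapply(coh, `[[`, "stride_set"), n_synergies = 4,
      reference = canonical_tpl, seed = 42,
      n_restarts = 5, max_iter = 500, tol = 1e-5)
  }
  cohort_build_cache$tb
}

## Reference metric values and normative thresholds for two stroke
## patients (S1, S2), used as the worked classification example
reference_patient_metrics <- function(patient = c("S1", "S2")) {
  patient <- match.arg(patient)
  if (patient == "S1") {
    m <- rbind(WA = c(0.67, 0.95, 0.94, 0.85),
               PO = c(0.97, 0.89, 0.96, 0.71),
               FC = c(0.95, 0.77, 0.61, 0.65),
               LD = c(0.91, 0.92, 0.99, 0.77))
  } else {
    m <- rbind(WA = c(0.90, 0.96, 0.96, 0.99),
               PO = c(0.93, 0.93, 0.98, 0.83),
               FC = c(0.80, 0.79, 0.99, 0.97),
               LD = c(0.98, 0.85, 0.99, 0.99))
  }
  colnames(m) <- c("similarity", "correlation", "t_lag", "activation")
  m
}

reference_thresholds <- c(similarity = 0.79, correlation = 0.90,
                       t_lag = 0.96, activation = 0.82)
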