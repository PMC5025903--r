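## EMG envelope processing: filtering chain, stride segmentation and the
## two normalizations (time to 100 points, amplitude by median stride maximum).

#' Multi-channel EMG recording
#'
#' Container for a raw or envelope EMG recording: a muscles-by-samples numeric
#' matrix with muscle labels and a sampling rate.
#'
#' @param data numeric matrix, one row per muscle.
#' @param muscle_names character vector of unique muscle labels, one per row.
#' @param sample_rate sampling rate in Hz (default 1024).
#' @param side which leg the recording comes from: `"paretic"`,
#'   `"nonparetic"` or `"dominant"`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(data, muscle_names, sample_rate = 1024,
                          side = c("dominant", "paretic", "nonparetic")) {
  side <- match.arg(side)
  if (!is.matrix(data) || !is.numeric(data))
    sg_stop("invalid_input", "`data` must be a numeric matrix (muscles x samples)")
  if (anyDuplicated(muscle_names) || length(muscle_names) != nrow(data))
    sg_stop("invalid_input", "`muscle_names` must be unique, one per data row")
  check_number(sample_rate, "sample_rate", lower = .Machine$double.eps)
  rownames(data) <- muscle_names
  structure(list(muscle_names = as.character(muscle_names),
                 sample_rate = sample_rate, data = data, side = side),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d muscles x %d samples @ %g Hz (%s side)\n",
              nrow(x$data), ncol(x$data), x$sample_rate, x$side))
  cat("  muscles:", paste(x$muscle_names, collapse = ", "), "\n")
  invisible(x)
}

## zero-phase Butterworth filter applied row-wise
butter_filtfilt <- function(M, fs, cutoff, type, order) {
  wn <- cutoff / (fs / 2)
  if (any(wn >= 1) || any(wn <= 0))
    sg_stop("invalid_parameter",
            "cut-off %s Hz at or above Nyquist (%g Hz)",
            paste(cutoff, collapse = "/"), fs / 2)
  flt <- signal::butter(order, wn, type = type)
  minlen <- 3L * max(length(flt$b), length(flt$a))
  if (ncol(M) < minlen)
    sg_stop("too_short",
            "signal of %d samples shorter than filter warm-up (%d samples)",
            ncol(M), minlen)
  t(apply(M, 1L, function(row) signal::filtfilt(flt, row)))
}

#' Compute EMG envelopes
#'
#' Band-pass filters the raw EMG (3rd-order Butterworth, zero-phase),
#' full-wave rectifies it and low-pass filters the result (3rd-order
#' Butterworth, zero-phase) to obtain the linear envelope. Filtering is
#' forward-backward so envelope peaks stay aligned with gait events; tiny
#' negative low-pass undershoots are clipped at zero.
#'
#' @param raw an [emg_recording()].
#' @param band_lo,band_hi band-pass cut-off frequencies in Hz (defaults 40, 400).
#' @param env_cut envelope low-pass cut-off in Hz (default 5).
#' @param order Butterworth order per pass (default 3; effective order doubles
#'   under zero-phase filtering).
#' @return An `emg_recording` of the same shape with nonnegative values.
#' @export
compute_envelope <- function(raw, band_lo = 40, band_hi = 400, env_cut = 5,
                             order = 3) {
  stopifnot(inherits(raw, "emg_recording"))
  fs <- raw$sample_rate
  check_number(order, "order", lower = 1)
  if (!(band_lo < band_hi))
    sg_stop("invalid_parameter", "band_lo (%g) must be below band_hi (%g)",
            band_lo, band_hi)
  bp <- butter_filtfilt(raw$data, fs, c(band_lo, band_hi), "pass", order)
  env <- butter_filtfilt(abs(bp), fs, env_cut, "low", order)
  env <- pmax(env, 0)
  rownames(env) <- raw$muscle_names
  out <- raw
  out$data <- env
  out
}

#' Segment an envelope recording into strides
#'
#' Cuts the recording at consecutive ipsilateral initial-contact (IC) times.
#' Stride i spans the half-open window `[IC_i, IC_{i+1})`, so the samples
#' between the first and last IC are partitioned without duplication.
#'
#' @param env an [emg_recording()] (typically an envelope).
#' @param ic_times strictly increasing IC event times in seconds.
#' @return A list of muscles-by-samples matrices, one per stride
#'   (`length(ic_times) - 1` strides).
#' @export
segment_strides <- function(env, ic_times) {
  stopifnot(inherits(env, "emg_recording"))
  if (length(ic_times) < 2L)
    sg_stop("insufficient_events", "need at least 2 IC events, got %d",
            length(ic_times))
  if (any(diff(ic_times) <= 0))
    sg_stop("invalid_input", "IC times must be strictly increasing")
  n <- ncol(env$data)
  dur <- n / env$sample_rate
  if (any(ic_times < 0) || any(ic_times > dur))
    sg_stop("out_of_range", "IC event outside the recording span [0, %g] s", dur)
  ## sample index of each IC (0-based time -> 1-based column)
  idx <- floor(ic_times * env$sample_rate) + 1L
  idx <- pmin(idx, n + 1L)
  lapply(seq_len(length(idx) - 1L), function(i) {
    env$data[, idx[i]:(idx[i + 1L] - 1L), drop = FALSE]
  })
}

#' Time-normalize a stride to a fixed number of points
#'
#' Linearly interpolates each muscle's samples onto a uniform grid spanning
#' the stride, preserving the endpoints.
#'
#' @param stride muscles-by-samples numeric matrix.
#' @param n_points number of output points (default 100).
#' @return A muscles-by-`n_points` matrix.
#' @export
time_normalize <- function(stride, n_points = 100) {
  if (!is.matrix(stride)) stride <- matrix(stride, nrow = 1L)
  ns <- ncol(stride)
  if (ns < 2L)
    sg_stop("too_short", "stride has %d sample(s); need at least 2", ns)
  grid <- seq(1, ns, length.out = n_points)
  out <- t(apply(stride, 1L, function(row) approx(seq_len(ns), row, xout = grid)$y))
  rownames(out) <- rownames(stride)
  out
}

#' Time-normalized, amplitude-normalized stride set
#'
#' @param strides n_strides x muscles x 100 nonnegative array.
#' @param muscle_names muscle labels.
#' @param normalization_constants per-muscle divisors used for amplitude
#'   normalization (recorded so the scaling can be inverted).
#' @return An object of class `stride_set`.
#' @export
stride_set <- function(strides, muscle_names,
                       normalization_constants = rep(1, length(muscle_names))) {
  stopifnot(is.array(strides), length(dim(strides)) == 3L)
  if (dim(strides)[2] != length(muscle_names))
    sg_stop("invalid_input", "second axis must match muscle_names")
  structure(list(strides = strides,
                 muscle_names = as.character(muscle_names),
                 normalization_constants = normalization_constants),
            class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  d <- dim(x$strides)
  cat(sprintf("Stride set: %d strides x %d muscles x %d points\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Amplitude-normalize strides by the median stride maximum
#'
#' For each muscle, divides all samples by the median (across strides) of
#' that muscle's per-stride maximum, the per-condition amplitude scaling used
#' before synergy extraction. The median of an even number of strides is the
#' mean of the two middle values.
#'
#' @param strides either a list of muscles-by-100 matrices or an
#'   n_strides x muscles x 100 array.
#' @param muscle_names muscle labels (taken from row names when missing).
#' @param eps divisors at or below this are treated as a flat channel (error).
#' @return A [stride_set()] whose per-muscle median stride maximum is 1.
#' @export
amplitude_normalize <- function(strides, muscle_names = NULL, eps = 1e-12) {
  if (is.list(strides)) {
    if (is.null(muscle_names)) muscle_names <- rownames(strides[[1L]])
    arr <- aperm(simplify2array(strides), c(3L, 1L, 2L))
  } else {
    arr <- strides
  }
  stopifnot(length(dim(arr)) == 3L)
  if (is.null(muscle_names))
    muscle_names <- paste0("m", seq_len(dim(arr)[2]))
  if (dim(arr)[1] < 1L)
    sg_stop("insufficient_strides", "need at least one stride")
  ## per-stride maxima: strides x muscles
  maxima <- apply(arr, c(1L, 2L), max)
  divisors <- apply(maxima, 2L, median)
  if (any(divisors <= eps)) {
    bad <- muscle_names[divisors <= eps]
    sg_stop("degenerate_channel",
            "flat channel(s) with ~zero median maximum: %s",
            paste(bad, collapse = ", "))
  }
  norm <- sweep(arr, 2L, divisors, "/")
  stride_set(norm, muscle_names, normalization_constants = divisors)
}

#' Select representative strides
#'
#' Drops `n_trim_start` strides from the beginning (gait initiation /
#' acceleration) and `n_trim_end` from the end (deceleration), then keeps
#' `n_keep` consecutive strides centered in what remains.
#'
#' @param sset a [stride_set()].
#' @param n_keep number of strides to keep (default 20).
#' @param n_trim_start,n_trim_end strides discarded at each end (default 3).
#' @return A [stride_set()] with `n_keep` strides.
#' @export
select_representative_strides <- function(sset, n_keep = 20,
                                          n_trim_start = 3, n_trim_end = 3) {
  stopifnot(inherits(sset, "stride_set"))
  n <- dim(sset$strides)[1]
  avail <- n - n_trim_start - n_trim_end
  if (avail < n_keep)
    sg_stop("insufficient_strides",
            "%d strides after trimming %d+%d of %d; need %d",
            max(avail, 0L), n_trim_start, n_trim_end, n, n_keep)
  start <- n_trim_start + floor((avail - n_keep) / 2) + 1L
  sset$strides <- sset$strides[start:(start + n_keep - 1L), , , drop = FALSE]
  sset
}

#' Run the full envelope pipeline for one recording
#'
#' Convenience chain: [compute_envelope()], [segment_strides()],
#' [time_normalize()] per stride, [amplitude_normalize()], and optionally
#' [select_representative_strides()].
#'
#' @param raw an [emg_recording()].
#' @param ic_times ipsilateral IC times in seconds.
#' @param n_keep representative strides to keep; `NULL` keeps all.
#' @param n_trim_start,n_trim_end trim counts passed on when `n_keep` is set.
#' @inheritParams compute_envelope
#' @return A [stride_set()].
#' @export
process_recording <- function(raw, ic_times, n_keep = NULL,
                              n_trim_start = 3, n_trim_end = 3,
                              band_lo = 40, band_hi = 400, env_cut = 5) {
  env <- compute_envelope(raw, band_lo, band_hi, env_cut)
  segs <- segment_strides(env, ic_times)
  norm <- lapply(segs, time_normalize)
  sset <- amplitude_normalize(norm, muscle_names = raw$muscle_names)
  if (!is.null(n_keep))
    sset <- select_representative_strides(sset, n_keep, n_trim_start, n_trim_end)
  sset
}

#' Concatenate a stride set into an NMF-ready matrix
#'
#' @param sset a [stride_set()].
#' @return A muscles x (100 * n_strides) nonnegative matrix, strides in order.
#' @export
as_envelope_matrix <- function(sset) {
  stopifnot(inherits(sset, "stride_set"))
  d <- dim(sset$strides)
  M <- matrix(0, d[2], d[1] * d[3])
  for (i in seq_len(d[1]))
    M[, ((i - 1L) * d[3] + 1L):(i * d[3])] <- sset$strides[i, , ]
  rownames(M) <- sset$muscle_names
  M
}
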