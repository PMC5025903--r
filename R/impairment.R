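## Impairment metrics: similarity, circular cross-correlation, timing lag and
## activation duration, with mean - 2 SD normative thresholds and the
## at-least-one-metric-under-threshold impairment rule.

METRIC_NAMES <- c("similarity", "correlation", "t_lag", "activation")

#' Weight similarity
#'
#' Normalized scalar product (cosine) between a patient's reconstructed
#' weight vector and the healthy template weight vector; 1 means identical
#' muscle composition, 0 disjoint.
#'
#' @param w_patient,w_healthy nonnegative weight vectors of equal length.
#' @return Cosine similarity in `[0, 1]`.
#' @export
similarity <- function(w_patient, w_healthy) {
  if (length(w_patient) != length(w_healthy))
    sg_stop("invalid_input", "weight vectors differ in length")
  cosine_sim(w_patient, w_healthy)
}

#' Timing-lag metric
#'
#' `1 - |lag| / 100` where `lag` is the percent of gait cycle at which the
#' maximal circular cross-correlation between patient and healthy profiles
#' occurs; 1 means perfectly aligned timing, 0.5 the worst possible
#' half-cycle shift.
#'
#' @param lag signed lag in percent of gait cycle, in `[-50, 50]`.
#' @return The metric value in `[0.5, 1]`.
#' @export
t_lag_metric <- function(lag) {
  check_number(lag, "lag")
  if (abs(lag) > 50)
    sg_stop("invalid_parameter", "|lag| = %g exceeds 50%% of the gait cycle", abs(lag))
  1 - abs(lag) / 100
}

#' Activation duration of a profile
#'
#' Counts the samples of a 100-point activation profile strictly above the
#' onset/offset threshold, fixed at the profile minimum plus 20% of its
#' peak-to-peak amplitude. Multi-burst profiles contribute the total time of
#' all bursts. A flat profile (peak-to-peak below `1e-9`) gets duration 0
#' with a `"degenerate"` attribute set.
#'
#' @param h numeric 100-point activation profile.
#' @param rel_threshold fraction of peak-to-peak amplitude above the minimum
#'   defining onset/offset (default 0.20).
#' @return Duration in percent of gait cycle (integer count of samples).
#' @export
activation_duration <- function(h, rel_threshold = 0.20) {
  if (length(h) != 100L)
    sg_stop("invalid_input", "profile must have 100 points, got %d", length(h))
  p2p <- max(h) - min(h)
  if (p2p < 1e-9)
    return(structure(0L, degenerate = TRUE))
  thr <- min(h) + rel_threshold * p2p
  sum(h > thr)
}

#' Activation-duration metric
#'
#' `1 - |d_patient - d_healthy| / 100` comparing the supra-threshold
#' activation durations (percent of gait cycle) of patient and healthy
#' profiles; 1 means equal active time.
#'
#' @param d_patient,d_healthy durations in percent of gait cycle, in `[0, 100]`.
#' @return The metric value in `[0, 1]`.
#' @export
activation_metric <- function(d_patient, d_healthy) {
  check_number(d_patient, "d_patient", 0, 100)
  check_number(d_healthy, "d_healthy", 0, 100)
  1 - abs(d_patient - d_healthy) / 100
}

#' Normative thresholds from a healthy cohort
#'
#' Pools each metric's values across subjects and synergies and sets the
#' impairment cut-off at the pooled mean minus twice the pooled sample
#' standard deviation, one threshold per metric common to all synergies.
#'
#' @param metric_values a data frame or named list with numeric components
#'   `similarity`, `correlation`, `t_lag`, `activation`, each pooling at
#'   least 2 healthy values.
#' @return Named numeric vector of four thresholds.
#' @export
normative_thresholds <- function(metric_values) {
  vapply(METRIC_NAMES, function(m) {
    v <- metric_values[[m]]
    if (is.null(v) || length(v) < 2L)
      sg_stop("invalid_input", "need at least 2 values for metric '%s'", m)
    mean(v) - 2 * sd(v)
  }, numeric(1))
}

#' Classify impaired synergies
#'
#' A synergy is impaired when at least one of its four metrics falls
#' strictly below the corresponding threshold; a value exactly equal to the
#' threshold passes.
#'
#' @param metrics synergies x 4 matrix or data frame with columns
#'   `similarity`, `correlation`, `t_lag`, `activation` (rows named by
#'   synergy label).
#' @param thresholds named numeric vector of four thresholds.
#' @return Named logical vector, `TRUE` for impaired synergies.
#' @export
classify_impairment <- function(metrics, thresholds) {
  metrics <- as.data.frame(metrics)
  missing <- setdiff(METRIC_NAMES, names(metrics))
  if (length(missing))
    sg_stop("invalid_input", "missing metric(s): %s", paste(missing, collapse = ", "))
  if (!all(METRIC_NAMES %in% names(thresholds)))
    sg_stop("invalid_input", "thresholds must be named by the four metrics")
  flags <- apply(metrics[, METRIC_NAMES, drop = FALSE], 1L, function(v) {
    any(v < thresholds[METRIC_NAMES])
  })
  names(flags) <- rownames(metrics)
  flags
}

#' Compute the four impairment metrics for one synergy
#'
#' @param w_patient,w_healthy weight vectors.
#' @param h_patient,h_healthy 100-point activation profiles.
#' @return Named numeric vector `(similarity, correlation, t_lag, activation)`.
#' @export
synergy_metrics <- function(w_patient, w_healthy, h_patient, h_healthy) {
  cc <- max_circular_xcorr(h_patient, h_healthy)
  c(similarity = similarity(w_patient, w_healthy),
    correlation = cc$r_max,
    t_lag = t_lag_metric(cc$lag),
    activation = activation_metric(activation_duration(h_patient),
                                   activation_duration(h_healthy)))
}

#' Assess a patient's synergies against a healthy template
#'
#' Runs the two non-negative reconstructions of the patient's envelopes
#' against the healthy template — fixed weights (free activations) and fixed
#' activations (free weights) — then scores each synergy with the four
#' impairment metrics and flags those falling under the normative
#' thresholds. Weight similarity uses the weights estimated with the healthy
#' activations held fixed; correlation, timing lag and activation duration
#' use the mean activation profile estimated with the healthy weights held
#' fixed.
#'
#' @param patient either a [stride_set()] or a muscles x (100 * n_strides)
#'   envelope matrix for the paretic side.
#' @param template a [synergy_set()]: the mean healthy synergies (unit-norm
#'   weights, 100-point mean profiles), labels WA/PO/FC/LD.
#' @param thresholds named numeric vector from [normative_thresholds()], or
#'   `NULL` to skip classification.
#' @param ... passed to [nnr_fixed_w()] / [nnr_fixed_h()].
#' @return An object of class `impairment_report`: per-synergy metrics,
#'   thresholds, impaired flags, the two NNR fits and their VAFs.
#' @export
assess_patient <- function(patient, template, thresholds = NULL, ...) {
  M <- if (inherits(patient, "stride_set")) as_envelope_matrix(patient) else patient
  stopifnot(inherits(template, "synergy_set"))
  if (!is.null(rownames(M)) &&
      !identical(rownames(M), template$muscle_names))
    sg_stop("invalid_input", "muscle sets disagree: patient {%s} vs template {%s}",
            paste(rownames(M), collapse = ","),
            paste(template$muscle_names, collapse = ","))
  template <- normalize_unit(template)
  fit_w <- nnr_fixed_w(M, template$W, ...)
  fit_h <- nnr_fixed_h(M, template$H, ...)
  J <- ncol(template$W)
  metrics <- matrix(NA_real_, J, 4L,
                    dimnames = list(template$labels, METRIC_NAMES))
  for (j in seq_len(J)) {
    metrics[j, ] <- synergy_metrics(fit_h$W[, j], template$W[, j],
                                    fit_w$mean_profile[j, ], template$H[j, ])
  }
  flags <- if (is.null(thresholds)) NULL else
    classify_impairment(as.data.frame(metrics), thresholds)
  impairment_report(metrics, thresholds, flags,
                    vaf = c(fixed_W = fit_w$vaf_total, fixed_H = fit_h$vaf_total),
                    fits = list(fixed_w = fit_w, fixed_h = fit_h))
}

#' Impairment report
#'
#' @param metrics synergies x 4 metric matrix (rownames = synergy labels).
#' @param thresholds named threshold vector or `NULL`.
#' @param impaired named logical vector or `NULL`.
#' @param vaf,fits optional NNR diagnostics.
#' @return An object of class `impairment_report`.
#' @export
impairment_report <- function(metrics, thresholds = NULL, impaired = NULL,
                              vaf = NULL, fits = NULL) {
  structure(list(metrics = metrics, thresholds = thresholds,
                 impaired = impaired, vaf = vaf, fits = fits),
            class = "impairment_report")
}

#' @export
print.impairment_report <- function(x, digits = 2, ...) {
  cat("Impairment report\n")
  tab <- as.data.frame(round(x$metrics, digits))
  if (!is.null(x$impaired)) tab$impaired <- x$impaired[rownames(tab)]
  print(tab)
  if (!is.null(x$thresholds))
    cat("thresholds:", paste(sprintf("%s %.2f", names(x$thresholds), x$thresholds),
                             collapse = ", "), "\n")
  if (!is.null(x$vaf))
    cat(sprintf("NNR VAF: %.2f (fixed W), %.2f (fixed H)\n",
                x$vaf["fixed_W"], x$vaf["fixed_H"]))
  invisible(x)
}

#' Impaired synergy labels from a report
#'
#' @param report an `impairment_report`.
#' @return Character vector of impaired synergy labels.
#' @export
impaired_labels <- function(report) {
  stopifnot(inherits(report, "impairment_report"))
  if (is.null(report$impaired))
    sg_stop("invalid_input", "report has no impairment flags (no thresholds given)")
  names(report$impaired)[report$impaired]
}
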