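## Personalized stimulation strategy: muscle intensity profiles from the
## impaired synergies, 20% peak-to-peak gating, channel grouping, and the
## pulse-width mapping.

#' Build per-muscle stimulation profiles from the impaired synergies
#'
#' Reconstructs the target muscle activations as the product of the healthy
#' template weights and mean activation profiles restricted to the impaired
#' synergies, `EMG = W[, impaired] %*% H[impaired, ]`, then rescales each
#' recruited muscle's profile to peak 1 (the normalized stimulation drive;
#' scale factors are recorded in the `"scale"` attribute so the raw product
#' can be recovered). Muscles not recruited by any impaired synergy keep an
#' all-zero profile.
#'
#' @param template a [synergy_set()] with labeled, unit-norm synergies.
#' @param impaired character vector of impaired synergy labels (subset of
#'   the template labels). Empty means no stimulation is needed: an all-zero
#'   profile matrix with attribute `"no_stimulation" = TRUE` is returned.
#' @return Muscles x 100 nonnegative matrix of intensity profiles in `[0, 1]`.
#' @export
build_profiles <- function(template, impaired) {
  stopifnot(inherits(template, "synergy_set"))
  if (ncol(template$H) != 100L)
    sg_stop("invalid_input", "template profiles must be 100 points")
  if (length(impaired) == 0L) {
    out <- matrix(0, nrow(template$W), 100L,
                  dimnames = list(template$muscle_names, NULL))
    attr(out, "no_stimulation") <- TRUE
    attr(out, "scale") <- rep(0, nrow(out))
    return(out)
  }
  idx <- match(impaired, template$labels)
  if (anyNA(idx))
    sg_stop("invalid_input", "unknown synergy label(s): %s",
            paste(impaired[is.na(idx)], collapse = ", "))
  E <- template$W[, idx, drop = FALSE] %*% template$H[idx, , drop = FALSE]
  peaks <- apply(E, 1L, max)
  scale <- ifelse(peaks > 0, peaks, 0)
  out <- E
  nz <- peaks > 0
  out[nz, ] <- sweep(E[nz, , drop = FALSE], 1L, peaks[nz], "/")
  rownames(out) <- template$muscle_names
  attr(out, "scale") <- scale
  attr(out, "no_stimulation") <- FALSE
  out
}

#' Gate a profile at the 20% peak-to-peak onset threshold
#'
#' Sets to zero every sample strictly below the baseline (profile minimum)
#' plus 20% of the peak-to-peak amplitude, to avoid stimulating at
#' fatigue-inducing low intensities; samples at or above the threshold are
#' unchanged. A flat profile is zeroed entirely.
#'
#' @param profile 100-point nonnegative intensity profile.
#' @param rel_threshold fraction of peak-to-peak amplitude (default 0.20).
#' @return The gated profile.
#' @export
apply_activation_threshold <- function(profile, rel_threshold = 0.20) {
  if (any(profile < 0)) sg_stop("invalid_input", "profile must be nonnegative")
  p2p <- max(profile) - min(profile)
  if (p2p < 1e-9) return(rep(0, length(profile)))
  thr <- min(profile) + rel_threshold * p2p
  ifelse(profile < thr, 0, profile)
}

#' Group muscles with similar profiles into stimulation channels
#'
#' Greedy single-linkage agglomeration over the gated profiles: scanning
#' muscles in order, a muscle joins an existing channel when its cosine
#' similarity with any member's profile reaches `cosine_threshold`;
#' otherwise it starts a new channel. All-zero muscles are excluded. Each
#' channel's profile is the mean of its members' profiles, rescaled to
#' peak 1.
#'
#' @param profiles muscles x 100 matrix of gated intensity profiles with
#'   muscle row names.
#' @param cosine_threshold merge threshold (default 0.98: profiles must be near-identical to share a channel, since muscles recruited by the same synergy at low cross-talk already correlate above 0.9).
#' @return List of channels, each `list(muscles =, profile =)`; empty when
#'   all profiles are zero.
#' @export
group_channels <- function(profiles, cosine_threshold = 0.98) {
  nz <- rownames(profiles)[apply(profiles, 1L, function(p) any(p > 0))]
  channels <- list()
  for (m in nz) {
    placed <- FALSE
    for (k in seq_along(channels)) {
      sims <- vapply(channels[[k]]$muscles, function(o)
        cosine_sim(profiles[m, ], profiles[o, ]), numeric(1))
      if (any(sims >= cosine_threshold)) {
        channels[[k]]$muscles <- c(channels[[k]]$muscles, m)
        placed <- TRUE
        break
      }
    }
    if (!placed) channels[[length(channels) + 1L]] <- list(muscles = m)
  }
  lapply(channels, function(ch) {
    prof <- colMeans(profiles[ch$muscles, , drop = FALSE])
    if (max(prof) > 0) prof <- prof / max(prof)
    list(muscles = ch$muscles, profile = prof)
  })
}

#' Map normalized intensity to stimulation pulse width
#'
#' Linear map from intensity in `[0, 1]` to pulse width in microseconds,
#' 0 at rest and `pw_max_us` (default 400) at full drive, rounded to the
#' nearest integer microsecond.
#'
#' @param intensity numeric in `[0, 1]` (vectorized).
#' @param pw_max_us pulse-width ceiling in microseconds.
#' @return Integer pulse widths in `[0, pw_max_us]`.
#' @export
to_pulse_width <- function(intensity, pw_max_us = 400) {
  if (any(!is.finite(intensity)) || any(intensity < 0) || any(intensity > 1))
    sg_stop("invalid_parameter", "intensity must lie in [0, 1]")
  as.integer(round(intensity * pw_max_us))
}

#' Assemble a personalized stimulation strategy
#'
#' Full strategy construction: profiles from the impaired synergies
#' ([build_profiles()]), per-muscle gating
#' ([apply_activation_threshold()]), channel grouping ([group_channels()]),
#' and the stimulation parameters. Stimulation amplitudes come from clinical
#' calibration and are carried as configuration, never computed.
#'
#' @param template healthy [synergy_set()] (labeled, 100-point profiles).
#' @param impaired character vector of impaired synergy labels (e.g. from
#'   [impaired_labels()]).
#' @param amplitudes_mA named numeric vector of per-muscle calibrated
#'   amplitudes; a channel's amplitude is the maximum over its members.
#'   Defaults to `NA` placeholders.
#' @param pw_max_us pulse-width ceiling (default 400).
#' @param frequency_hz common stimulation frequency (default 20).
#' @param template_phase_bounds 6 positive fractions of the gait cycle
#'   summing to 1, partitioning the 100-point template into the six gait
#'   phases (default: equal to [canonical_phase_fractions()]).
#' @param cosine_threshold channel-grouping threshold (default 0.98).
#' @return An object of class `stimulation_strategy`.
#' @export
build_strategy <- function(template, impaired,
                           amplitudes_mA = NULL,
                           pw_max_us = 400, frequency_hz = 20,
                           template_phase_bounds = canonical_phase_fractions(),
                           cosine_threshold = 0.98) {
  check_number(pw_max_us, "pw_max_us", lower = 1)
  check_number(frequency_hz, "frequency_hz", lower = .Machine$double.eps)
  if (length(template_phase_bounds) != 6L || any(template_phase_bounds <= 0) ||
      abs(sum(template_phase_bounds) - 1) > 1e-9)
    sg_stop("invalid_parameter",
            "template_phase_bounds must be 6 positive fractions summing to 1")
  raw <- build_profiles(template, impaired)
  gated <- t(apply(raw, 1L, apply_activation_threshold))
  rownames(gated) <- rownames(raw)
  channels <- group_channels(gated, cosine_threshold)
  for (k in seq_along(channels)) {
    amp <- if (is.null(amplitudes_mA)) NA_real_ else
      max(amplitudes_mA[channels[[k]]$muscles], na.rm = FALSE)
    channels[[k]]$amplitude_mA <- amp
  }
  structure(list(channels = channels, impaired = impaired,
                 muscle_profiles = gated,
                 pw_max_us = pw_max_us, frequency_hz = frequency_hz,
                 template_phase_bounds = template_phase_bounds,
                 no_stimulation = isTRUE(attr(raw, "no_stimulation"))),
            class = "stimulation_strategy")
}

#' @export
print.stimulation_strategy <- function(x, ...) {
  cat(sprintf("Stimulation strategy: %d channel(s), %g Hz, pulse width 0-%g us\n",
              length(x$channels), x$frequency_hz, x$pw_max_us))
  cat("  impaired synergies:",
      if (length(x$impaired)) paste(x$impaired, collapse = ", ") else "(none)", "\n")
  for (k in seq_along(x$channels))
    cat(sprintf("  channel %d: %s\n", k,
                paste(x$channels[[k]]$muscles, collapse = " + ")))
  if (x$no_stimulation) cat("  no stimulation needed\n")
  invisible(x)
}
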