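## Six-phase gait timeline from IC/EC/MS events, the five-stride duration
## estimator, and warping of the 100-point stimulation template onto the
## subject's actual phase timing.

## The cycle of six gait phases and the event that closes each one.
## Phase 1 starts at a paretic initial contact.
PHASE_TABLE <- data.frame(
  phase_id = 1:6,
  name = c("paretic double support", "non-paretic initial swing",
           "non-paretic terminal swing", "non-paretic double support",
           "paretic initial swing", "paretic terminal swing"),
  end_event = c("EC", "MS", "IC", "EC", "MS", "IC"),
  end_side = c("nonparetic", "nonparetic", "nonparetic",
               "paretic", "paretic", "paretic"),
  stringsAsFactors = FALSE
)

#' Gait event stream
#'
#' Ordered initial-contact (IC), end-contact (EC) and mid-swing (MS) events
#' for both legs.
#'
#' @param time_s strictly increasing event times in seconds.
#' @param type event types, each one of `"IC"`, `"EC"`, `"MS"`.
#' @param side `"paretic"` or `"nonparetic"` per event.
#' @return An object of class `gait_event_stream` (a data frame).
#' @export
gait_event_stream <- function(time_s, type, side) {
  if (length(time_s) && any(diff(time_s) <= 0))
    sg_stop("invalid_input", "event times must be strictly increasing")
  if (!all(type %in% c("IC", "EC", "MS")))
    sg_stop("invalid_input", "event types must be IC, EC or MS")
  if (!all(side %in% c("paretic", "nonparetic")))
    sg_stop("invalid_input", "event side must be paretic or nonparetic")
  structure(data.frame(time_s = time_s, type = type, side = side,
                       stringsAsFactors = FALSE),
            class = c("gait_event_stream", "data.frame"))
}

#' Derive the six-phase timeline from a gait event stream
#'
#' Walks the event stream from the first paretic initial contact and cuts it
#' into the cyclic six-phase sequence: (1) paretic double support up to the
#' non-paretic end contact, (2) non-paretic initial swing up to non-paretic
#' mid-swing, (3) non-paretic terminal swing up to non-paretic initial
#' contact, (4) non-paretic double support up to paretic end contact,
#' (5) paretic initial swing up to paretic mid-swing, (6) paretic terminal
#' swing up to the next paretic initial contact. Any deviation from the
#' expected event order raises a sequence-violation error naming the
#' expected event.
#'
#' @param stream a [gait_event_stream()].
#' @return An object of class `phase_timeline`: data frame with `phase_id`,
#'   `stride`, `start_s`, `duration_s`.
#' @export
phases_from_events <- function(stream) {
  stopifnot(inherits(stream, "gait_event_stream"))
  start_i <- which(stream$type == "IC" & stream$side == "paretic")[1L]
  if (is.na(start_i))
    sg_stop("sequence_violation", "stream contains no paretic IC to start from")
  ev <- stream[start_i:nrow(stream), , drop = FALSE]
  phases <- list()
  t0 <- ev$time_s[1L]
  pos <- 2L
  phase <- 1L
  stride <- 1L
  while (pos <= nrow(ev)) {
    expect <- PHASE_TABLE[phase, ]
    got <- ev[pos, ]
    if (got$type != expect$end_event || got$side != expect$end_side)
      sg_stop("sequence_violation",
              "expected %s %s to end phase %d (%s), got %s %s at %g s",
              expect$end_side, expect$end_event, phase, expect$name,
              got$side, got$type, got$time_s)
    dur <- got$time_s - t0
    if (dur <= 0)
      sg_stop("invalid_input", "non-positive phase duration at %g s", got$time_s)
    phases[[length(phases) + 1L]] <-
      data.frame(phase_id = phase, stride = stride, start_s = t0, duration_s = dur)
    t0 <- got$time_s
    pos <- pos + 1L
    if (phase == 6L) { phase <- 1L; stride <- stride + 1L } else phase <- phase + 1L
  }
  out <- do.call(rbind, phases)
  structure(out, class = c("phase_timeline", "data.frame"))
}

#' Five-stride phase-duration estimator
#'
#' Maintains, per gait phase, the durations of the last (at most) five
#' strides; the running estimate is their arithmetic mean. With fewer than
#' five observations the mean of those available is used.
#'
#' @param history numeric vector of stored durations (oldest first), length
#'   at most 5.
#' @param new_duration the just-completed phase duration in seconds.
#' @return List with updated `history` and the new `estimate`.
#' @export
update_duration_estimate <- function(history, new_duration) {
  check_number(new_duration, "new_duration", lower = .Machine$double.eps)
  history <- c(history, new_duration)
  if (length(history) > 5L) history <- tail(history, 5L)
  list(history = history, estimate = mean(history))
}

## evaluate a 100-point cyclic, piecewise-linear template at cycle fractions
eval_template <- function(template, frac) {
  frac <- frac %% 1
  x <- frac * 100          # knots at 0, 1, ..., 99; wraps at 100 -> 0
  i0 <- floor(x)
  w <- x - i0
  v0 <- template[(i0 %% 100) + 1L]
  v1 <- template[((i0 + 1L) %% 100) + 1L]
  (1 - w) * v0 + w * v1
}

#' Warp a stimulation template onto actual phase durations
#'
#' Splits the 100-point template at the template phase bounds (six fractions
#' of the gait cycle) and linearly resamples each segment to
#' `round(duration_i * out_rate)` samples, so each gait phase's stimulation
#' segment is stretched or compressed to the subject's estimated phase
#' duration while the others are untouched. Segments are concatenated in
#' phase order; a phase so short that it maps to zero samples is skipped
#' with a degenerate-phase warning.
#'
#' @param template 100-point intensity profile in `[0, 1]`.
#' @param template_phase_bounds 6 positive fractions summing to 1.
#' @param estimates 6 positive phase durations in seconds.
#' @param out_rate output sampling rate in Hz (e.g. the 20 Hz stimulation
#'   frequency).
#' @return Numeric vector of length `sum(round(estimates * out_rate))` with
#'   per-segment sample counts in attribute `"segment_lengths"`.
#' @export
warp_profile <- function(template, template_phase_bounds, estimates, out_rate) {
  if (length(template) != 100L)
    sg_stop("invalid_input", "template must have 100 points")
  if (length(template_phase_bounds) != 6L ||
      abs(sum(template_phase_bounds) - 1) > 1e-9 || any(template_phase_bounds <= 0))
    sg_stop("invalid_parameter", "phase bounds must be 6 positive fractions summing to 1")
  if (length(estimates) != 6L || any(estimates <= 0))
    sg_stop("invalid_parameter", "estimates must be 6 positive durations")
  check_number(out_rate, "out_rate", lower = .Machine$double.eps)
  cuts <- c(0, cumsum(template_phase_bounds))
  segs <- vector("list", 6L)
  n_out <- integer(6L)
  for (i in 1:6) {
    m <- as.integer(round(estimates[i] * out_rate))
    n_out[i] <- m
    if (m == 0) {
      sg_warn("degenerate_phase", "phase %d maps to 0 samples; segment skipped", i)
      segs[[i]] <- numeric(0)
      next
    }
    ## sample fractions covering [cuts[i], cuts[i+1]) uniformly; the join
    ## point belongs to the next segment
    frac <- cuts[i] + (0:(m - 1L)) / m * (cuts[i + 1L] - cuts[i])
    segs[[i]] <- eval_template(template, frac)
  }
  out <- unlist(segs, use.names = FALSE)
  attr(out, "segment_lengths") <- n_out
  out
}

#' Simulate a stimulation session over a gait event stream
#'
#' Offline stand-in for the real-time control loop: for each stride of the
#' timeline the per-phase duration estimates (mean of the last five
#' completed strides; the first stride uses the template phase proportions
#' scaled to its own observed cycle time) are used to warp every channel's
#' profile, and time-stamped pulse-width commands are emitted at the
#' strategy's stimulation frequency. The log is bit-reproducible for fixed
#' inputs.
#'
#' @param strategy a [build_strategy()] result.
#' @param stream a [gait_event_stream()].
#' @return Data frame command log: `time_s`, `stride`, `channel`,
#'   `muscles`, `pulse_width_us`, `amplitude_mA`, `frequency_hz`.
#' @export
simulate_session <- function(strategy, stream) {
  stopifnot(inherits(strategy, "stimulation_strategy"))
  tl <- phases_from_events(stream)
  empty <- data.frame(time_s = numeric(0), stride = integer(0),
                      channel = integer(0), muscles = character(0),
                      pulse_width_us = integer(0), amplitude_mA = numeric(0),
                      frequency_hz = numeric(0))
  if (length(strategy$channels) == 0L) return(empty)
  strides <- split(tl, tl$stride)
  strides <- strides[vapply(strides, nrow, 0L) == 6L]  # complete strides only
  if (length(strides) == 0L) return(empty)
  hist <- rep(list(numeric(0)), 6L)
  bounds <- strategy$template_phase_bounds
  rate <- strategy$frequency_hz
  logs <- list()
  for (s in seq_along(strides)) {
    st <- strides[[s]]
    if (s == 1L) {
      ## warm-up: template proportions scaled to the first observed cycle
      est <- bounds * sum(st$duration_s)
    } else {
      est <- vapply(1:6, function(p) mean(hist[[p]]), numeric(1))
    }
    t_start <- st$start_s[1L]
    for (k in seq_along(strategy$channels)) {
      ch <- strategy$channels[[k]]
      intens <- warp_profile(ch$profile, bounds, est, rate)
      n <- length(intens)
      if (n == 0L) next
      logs[[length(logs) + 1L]] <- data.frame(
        time_s = t_start + (0:(n - 1L)) / rate,
        stride = as.integer(names(strides)[s]),
        channel = k,
        muscles = paste(ch$muscles, collapse = "+"),
        pulse_width_us = to_pulse_width(pmin(pmax(intens, 0), 1),
                                        strategy$pw_max_us),
        amplitude_mA = ch$amplitude_mA,
        frequency_hz = rate)
    }
    ## push the completed stride's observed durations
    for (p in 1:6)
      hist[[p]] <- update_duration_estimate(hist[[p]],
                                            st$duration_s[st$phase_id == p])$history
  }
  out <- do.call(rbind, logs)
  out[order(out$time_s, out$channel), , drop = FALSE]
}
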