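test_that("six phases come out of a canonical event cycle", {
  st <- make_event_stream(rep(0.2, 6), 0, n_strides = 2)
  tl <- phases_from_events(st)
  expect_identical(tl$phase_id, rep(1:6, 2))
  expect_equal(tl$duration_s, rep(0.2, 12), tolerance = 1e-12)
  expect_equal(sum(tl$duration_s[tl$stride == 1]), 1.2, tolerance = 1e-12)
})

test_that("event-sequence violations raise naming the expected event", {
  st <- make_event_stream(rep(0.2, 6), 0, n_strides = 2)
  drop_ms <- st[!(st$type == "MS" & st$side == "nonparetic" & st$time_s < 1), ]
  class(drop_ms) <- class(st)
  expect_error(phases_from_events(drop_ms), regexp = "nonparetic MS",
               class = "synergait_sequence_violation")
})

test_that("generated per-phase durations round-trip through the timeline", {
  means <- c(0.25, 0.12, 0.33, 0.18, 0.11, 0.21)
  st <- make_event_stream(means, 0, n_strides = 5)
  tl <- phases_from_events(st)
  expect_equal(tl$duration_s, rep(means, 5), tolerance = 1e-9)
  ## with variability, still a valid cyclic sequence and positive durations
  stv <- make_event_stream(means, 0.03, n_strides = 5, seed = 4)
  tlv <- phases_from_events(stv)
  expect_identical(tlv$phase_id, rep(1:6, 5))
  expect_true(all(tlv$duration_s > 0))
})

test_that("duration estimates use a five-stride window", {
  h <- update_duration_estimate(c(1, 1, 1, 1, 1), 1)
  expect_equal(h$estimate, 1)
  h <- update_duration_estimate(c(0.2, 0.3, 0.4, 0.5), 0.6)
  expect_equal(h$estimate, 0.4)
  expect_length(h$history, 5L)
  h <- update_duration_estimate(h$history, 0.7)   # sixth push evicts oldest
  expect_length(h$history, 5L)
  expect_equal(h$history[1], 0.3)
  expect_true(h$estimate >= min(h$history) && h$estimate <= max(h$history))
  expect_error(update_duration_estimate(c(1), 0), class = "synergait_invalid_parameter")
})

test_that("warping: uniform speed equals whole-template resampling", {
  p <- canonical_tpl$H[1, ] / max(canonical_tpl$H[1, ])
  b <- c(0.2, 0.1, 0.2, 0.1, 0.2, 0.2)
  w <- warp_profile(p, b, b * 1.0, 100)
  expect_length(w, 100L)
  expect_equal(as.numeric(w), uniform_resample_oracle(p, 100), tolerance = 1e-12)
  ## a uniform speed change is still a uniform resampling of the whole cycle
  w2 <- warp_profile(p, b, b * 2, 100)
  expect_equal(as.numeric(w2), uniform_resample_oracle(p, 200), tolerance = 1e-12)
})

test_that("warping is local: doubling one phase leaves other segments unchanged", {
  p <- canonical_tpl$H[2, ] / max(canonical_tpl$H[2, ])
  b <- c(0.2, 0.1, 0.2, 0.1, 0.2, 0.2)
  w1 <- warp_profile(p, b, b, 100)
  w2 <- warp_profile(p, b, c(0.4, b[2:6]), 100)
  s1 <- attr(w1, "segment_lengths"); s2 <- attr(w2, "segment_lengths")
  expect_identical(s2[1], 2L * s1[1])
  expect_identical(s2[2:6], s1[2:6])
  expect_equal(w2[(s2[1] + 1):length(w2)], w1[(s1[1] + 1):length(w1)])
  ## total length is exactly the sum of per-phase sample counts
  expect_length(w2, sum(s2))
})

test_that("warp then inverse-warp returns close to the template", {
  for (j in 1:2) {
    p <- canonical_tpl$H[j, ] / max(canonical_tpl$H[j, ])
    b <- canonical_phase_fractions()
    est <- c(0.30, 0.15, 0.20, 0.10, 0.12, 0.13)   # 1 s cycle, uneven phases
    w <- warp_profile(p, b, est, 200)
    ## invert: the warped signal's cycle fractions are known by construction
    sl <- attr(w, "segment_lengths")
    cuts <- c(0, cumsum(b))
    frac <- unlist(lapply(1:6, function(i)
      cuts[i] + (0:(sl[i] - 1)) / sl[i] * (cuts[i + 1] - cuts[i])))
    back <- stats::approx(c(frac, 1), c(w, w[1]), xout = (0:99) / 100)$y
    expect_lt(max(abs(back - p)), 0.02)
  }
})

test_that("degenerate phase durations are skipped with a warning", {
  p <- canonical_tpl$H[1, ]
  b <- canonical_phase_fractions()
  expect_warning(w <- warp_profile(p, b, c(0.001, rep(0.2, 5)), 20),
                 class = "synergait_degenerate_phase")
  expect_equal(attr(w, "segment_lengths")[1], 0L)
})

test_that("session simulation is stationary for constant gait timing", {
  strat <- build_strategy(canonical_tpl, c("WA", "PO", "FC", "LD"))
  st <- make_event_stream(rep(0.2, 6), 0, n_strides = 9)
  log <- simulate_session(strat, st)
  expect_true(all(log$pulse_width_us >= 0 & log$pulse_width_us <= 400))
  per <- split(log, log$stride)
  ## after the 5-stride warm-up the command pattern repeats exactly
  pat <- function(s) {
    d <- s[order(s$channel, s$time_s), c("channel", "pulse_width_us")]
    rownames(d) <- NULL
    d
  }
  expect_identical(pat(per[["7"]]), pat(per[["8"]]))
  ## identical from stride 2 on (the warm-up stride uses template
  ## proportions, not the observed constant phase durations)
  counts <- unname(vapply(per, nrow, 0L))
  expect_identical(counts[-1], rep(counts[7], length(per) - 1L))
  ## reproducibility
  expect_identical(simulate_session(strat, st), log)
})

test_that("speeding up shortens the per-stride command train after warm-up", {
  strat <- build_strategy(canonical_tpl, c("WA", "PO", "FC", "LD"))
  durs <- seq(0.60, 0.15, length.out = 10)
  ev <- lapply(seq_along(durs), function(i)
    make_event_stream(rep(durs[i], 6), 0, n_strides = 1)$time_s)
  t <- 0; time_s <- c(); type <- c(); side <- c()
  types <- c("IC", "EC", "MS", "IC", "EC", "MS")
  sides <- c("paretic", "nonparetic", "nonparetic", "nonparetic", "paretic", "paretic")
  for (d in durs) { time_s <- c(time_s, t + (0:5) * d); type <- c(type, types); side <- c(side, sides); t <- t + 6 * d }
  time_s <- c(time_s, t); type <- c(type, "IC"); side <- c(side, "paretic")
  st <- gait_event_stream(time_s, type, side)
  log <- simulate_session(strat, st)
  counts <- vapply(split(log, log$stride), nrow, 0L)
  expect_true(all(diff(counts[6:length(counts)]) < 0))
})

test_that("a no-stimulation strategy produces an empty command log", {
  strat <- build_strategy(canonical_tpl, character(0))
  st <- make_event_stream(rep(0.2, 6), 0, n_strides = 3)
  expect_identical(nrow(simulate_session(strat, st)), 0L)
})
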