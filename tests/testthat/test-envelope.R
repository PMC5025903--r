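test_that("envelope filtering chain: zero stays zero, DC is removed, sinusoid gives 2/pi", {
  fs <- 1024
  z <- compute_envelope(emg_recording(matrix(0, 1, 4096), "m", fs))
  expect_equal(max(abs(z$data)), 0)

  k <- compute_envelope(emg_recording(matrix(1, 1, 4096), "m", fs))
  expect_lt(max(abs(k$data[1, 513:3584])), 1e-4)

  ## 200 Hz unit sinusoid: band-pass passes it, |sin| has DC 2/pi, the 5 Hz
  ## low-pass keeps only that DC in the interior
  env <- compute_envelope(sine_recording(200))
  interior <- env$data[1, 513:3584]
  expect_lt(abs(mean(interior) - 2 / pi) / (2 / pi), 0.02)
})

test_that("envelopes are nonnegative and shaped like the input", {
  set.seed(7)
  raw <- emg_recording(matrix(rnorm(3 * 4096), 3), c("a", "b", "c"), 1024)
  env <- compute_envelope(raw)
  expect_identical(dim(env$data), dim(raw$data))
  expect_true(all(env$data >= 0))
})

test_that("envelope parameter validation: Nyquist and warm-up limits", {
  raw <- sine_recording(50)
  expect_error(compute_envelope(raw, band_hi = 512),
               class = "synergait_invalid_parameter")
  expect_error(compute_envelope(raw, env_cut = 600),
               class = "synergait_invalid_parameter")
  expect_error(compute_envelope(raw, band_lo = 400, band_hi = 40),
               class = "synergait_invalid_parameter")
  short <- emg_recording(matrix(rnorm(10), 1), "m", 1024)
  expect_error(compute_envelope(short), class = "synergait_too_short")
})

test_that("stride segmentation partitions samples between consecutive ICs", {
  fs <- 1024
  env <- emg_recording(matrix(seq_len(4096), 1), "m", fs)
  segs <- segment_strides(env, c(0, 1))
  expect_length(segs, 1L)
  expect_identical(ncol(segs[[1]]), 1024L)

  ic <- c(0, 1, 2.5, 3.2)
  segs <- segment_strides(env, ic)
  expect_length(segs, 3L)
  ## partition: concatenation reproduces the samples between first and last IC
  recon <- do.call(cbind, segs)
  i0 <- floor(ic[1] * fs) + 1L; i1 <- floor(ic[4] * fs)
  expect_identical(as.numeric(recon), as.numeric(env$data[, i0:i1]))

  expect_error(segment_strides(env, 1.0), class = "synergait_insufficient_events")
  expect_error(segment_strides(env, c(0, 5)), class = "synergait_out_of_range")
  expect_error(segment_strides(env, c(1, 1)), class = "synergait_invalid_input")
})

test_that("time normalization interpolates linearly and preserves endpoints", {
  ramp <- matrix(seq(0, 1, length.out = 200), 1)
  out <- time_normalize(ramp)
  expect_identical(ncol(out), 100L)
  expect_equal(out[1, 1], 0)
  expect_equal(out[1, 100], 1)
  expect_equal(out[1, ], seq(0, 1, length.out = 100), tolerance = 1e-12)

  ## identity on an already-100-point stride
  x <- matrix(runif(100), 1)
  expect_equal(time_normalize(x)[1, ], x[1, ])

  ## constants stay constant; monotone stays monotone
  expect_equal(time_normalize(matrix(3.7, 2, 57)), matrix(3.7, 2, 100))
  set.seed(1)
  mono <- matrix(cumsum(runif(150)), 1)
  expect_true(all(diff(time_normalize(mono)[1, ]) >= 0))

  expect_error(time_normalize(matrix(1, 1, 1)), class = "synergait_too_short")
})

test_that("amplitude normalization divides by the median stride maximum", {
  mk <- function(maxima) {
    arr <- array(0, c(length(maxima), 2, 100))
    for (i in seq_along(maxima)) arr[i, , ] <- maxima[i] * matrix(runif(200, 0.1, 1), 2)
    for (i in seq_along(maxima)) arr[i, 1, 1] <- maxima[i]  # pin the max
    for (i in seq_along(maxima)) arr[i, 2, 1] <- maxima[i]
    arr
  }
  set.seed(2)
  sset <- amplitude_normalize(mk(c(1, 2, 3)), c("a", "b"))
  expect_equal(unname(sset$normalization_constants), c(2, 2))
  ## even stride count: mean-of-middle-two median
  sset2 <- amplitude_normalize(mk(c(1, 3)), c("a", "b"))
  expect_equal(unname(sset2$normalization_constants), c(2, 2))
  ## per-muscle median of per-stride maxima is 1 after normalization
  maxima <- apply(sset$strides, c(1, 2), max)
  expect_equal(unname(apply(maxima, 2, median)), c(1, 1), tolerance = 1e-9)
  ## idempotence: renormalizing divides by 1
  again <- amplitude_normalize(sset$strides, c("a", "b"))
  expect_equal(unname(again$normalization_constants), c(1, 1), tolerance = 1e-9)
  ## flat channel error names the muscle
  flat <- array(0, c(3, 2, 100)); flat[, 2, ] <- 1
  expect_error(amplitude_normalize(flat, c("gm", "ta")),
               regexp = "gm", class = "synergait_degenerate_channel")
})

test_that("representative-stride selection trims then centers", {
  arr <- array(rep(1:30, each = 1), c(30, 1, 100))
  for (i in 1:30) arr[i, , ] <- i
  sset <- stride_set(arr, "m")
  kept <- select_representative_strides(sset, 20, 3, 3)
  expect_equal(kept$strides[, 1, 1], 6:25)  # centered in strides 4..27
  ident <- select_representative_strides(stride_set(arr[1:20, , , drop = FALSE], "m"), 20, 0, 0)
  expect_equal(ident$strides[, 1, 1], 1:20)
  expect_error(select_representative_strides(stride_set(arr[1:10, , , drop = FALSE], "m"), 20),
               class = "synergait_insufficient_strides")
})

test_that("process_recording chains to a normalized 100-point stride set", {
  set.seed(5)
  fs <- 1024
  x <- matrix(abs(rnorm(2 * 6 * fs)), 2)
  raw <- emg_recording(x, c("a", "b"), fs)
  sset <- process_recording(raw, ic_times = 0:5)
  expect_s3_class(sset, "stride_set")
  expect_identical(dim(sset$strides), c(5L, 2L, 100L))
  M <- as_envelope_matrix(sset)
  expect_identical(dim(M), c(2L, 500L))
  expect_true(all(M >= 0))
})
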