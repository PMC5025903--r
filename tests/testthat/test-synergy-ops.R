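test_that("circular cross-correlation matches an explicit rotation oracle", {
  set.seed(21)
  for (i in 1:10) {
    x <- runif(100); y <- runif(100)
    got <- max_circular_xcorr(x, y)
    want <- xcorr_oracle(x, y)
    expect_equal(got$r_max, want$r_max, tolerance = 1e-12)
    expect_identical(got$lag, want$lag)
    expect_true(all(abs(circular_xcorr(x, y) - want$all) < 1e-12))
  }
})

test_that("shifted profiles give correlation 1 at the construction lag", {
  h <- canonical_tpl$H[1, ]
  for (k in c(-7, 0, 5, 12)) {
    got <- max_circular_xcorr(delay(h, k), h)
    expect_equal(got$r_max, 1, tolerance = 1e-9)
    expect_identical(got$lag, as.integer(k))
  }
  expect_error(max_circular_xcorr(rep(1, 100), h),
               class = "synergait_degenerate_input")
})

test_that("synergy matching recovers shuffles and is scale-invariant", {
  ref <- canonical_tpl
  shuf <- ref
  ord <- c(3L, 1L, 4L, 2L)
  shuf$W <- ref$W[, ord]; shuf$H <- ref$H[ord, ]; shuf$labels <- rep("unlabeled", 4)
  m <- match_synergies(shuf, ref)
  expect_identical(m$assignment, ord)
  expect_equal(m$cosines, rep(1, 4), tolerance = 1e-12)
  expect_identical(m$matched$labels, ref$labels)
  expect_equal(m$matched$W, ref$W)

  scaled <- shuf; scaled$W[, 2] <- 2 * scaled$W[, 2]
  expect_equal(match_synergies(scaled, ref)$assignment, ord)
})

test_that("matching equals an exhaustive-permutation search on random sets", {
  set.seed(31)
  perms3 <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (i in 1:8) {
    Wc <- matrix(runif(15), 5, 3); Wr <- matrix(runif(15), 5, 3)
    cand <- synergy_set(Wc, matrix(runif(30), 3))
    ref <- synergy_set(Wr, matrix(runif(30), 3))
    got <- match_synergies(cand, ref)$assignment
    cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    tot <- apply(perms3, 1, function(p)
      sum(vapply(1:3, function(j) cs(Wc[, j], Wr[, p[j]]), numeric(1))))
    expect_equal(sum(vapply(1:3, function(j) cs(Wc[, j], Wr[, got[j]]), numeric(1))),
                 max(tot), tolerance = 1e-12)
  }
  expect_error(match_synergies(synergy_set(matrix(1, 2, 1), matrix(1, 1, 3),
                                           muscle_names = c("x", "y")),
                               canonical_tpl),
               class = "synergait_invalid_input")
})

test_that("group averaging: identical sets give the input back; noise shrinks", {
  sets <- replicate(3, canonical_tpl, simplify = FALSE)
  avg <- average_group(sets, canonical_tpl)
  expect_equal(avg$W, canonical_tpl$W, tolerance = 1e-9)
  expect_equal(avg$H, canonical_tpl$H, tolerance = 1e-9)

  ## 13 perturbed copies: elementwise mean near the template
  set.seed(13)
  noisy <- lapply(1:13, function(i) {
    s <- canonical_tpl
    s$W <- pmax(s$W + matrix(rnorm(length(s$W), 0, 0.05), nrow(s$W)), 0)
    s
  })
  avg13 <- average_group(noisy, canonical_tpl)
  ## zero-support entries keep a half-normal truncation bias ~ sd/sqrt(2*pi)
  ## and renormalization shrinks the large entries slightly
  expect_lt(max(abs(avg13$W - canonical_tpl$W)), 0.055)
  big <- canonical_tpl$W > 0.1
  expect_lt(max(abs(avg13$W[big] - canonical_tpl$W[big])), 0.04)
  expect_true(all(abs(sqrt(colSums(avg13$W^2)) - 1) < 1e-9))
})

test_that("two one-hot weight columns average to an equal mix", {
  ref <- synergy_set(cbind(c(1, 0)), matrix(1, 1, 100), muscle_names = c("a", "b"))
  s1 <- synergy_set(cbind(c(1, 0)), matrix(1, 1, 100), muscle_names = c("a", "b"))
  s2 <- synergy_set(cbind(c(0, 1)), matrix(1, 1, 100), muscle_names = c("a", "b"))
  avg <- average_group(list(s1, s2), ref)
  expect_equal(unname(avg$W[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
})

test_that("condition comparison: identity, constructed shift, oracle equality", {
  cmp <- compare_conditions(canonical_tpl, canonical_tpl)
  expect_equal(cmp$per_synergy$similarity, rep(1, 4), tolerance = 1e-12)
  expect_equal(cmp$per_synergy$correlation, rep(1, 4), tolerance = 1e-9)
  expect_identical(cmp$per_synergy$lag, rep(0L, 4))

  shifted <- canonical_tpl
  for (j in 1:4) shifted$H[j, ] <- delay(canonical_tpl$H[j, ], 5)
  cmp5 <- compare_conditions(canonical_tpl, shifted)
  expect_equal(cmp5$per_synergy$correlation, rep(1, 4), tolerance = 1e-9)
  expect_identical(cmp5$per_synergy$lag, rep(5L, 4))

  short <- canonical_tpl; short$H <- short$H[, 1:50]
  expect_error(compare_conditions(canonical_tpl, short),
               class = "synergait_invalid_input")
})

test_that("per-stride profiles collapse to the mean cycle", {
  H <- cbind(matrix(1, 2, 100), matrix(3, 2, 100))
  expect_equal(mean_cycle_profiles(H), matrix(2, 2, 100))
  expect_error(mean_cycle_profiles(matrix(1, 2, 150)),
               class = "synergait_invalid_input")
})
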