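test_that("weight similarity: identity, disjoint support, scale invariance", {
  w <- c(0.6, 0.8, 0, 0)
  expect_equal(similarity(w, w), 1)
  expect_equal(similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(similarity(2 * w, w), 1)
  expect_error(similarity(c(0, 0), w[1:2]), class = "synergait_degenerate_input")
  expect_error(similarity(w, w[1:2]), class = "synergait_invalid_input")
})

test_that("timing-lag metric and its bounds", {
  expect_equal(t_lag_metric(0), 1)
  expect_equal(t_lag_metric(-39), 0.61)
  expect_equal(t_lag_metric(50), 0.5)
  expect_error(t_lag_metric(51), class = "synergait_invalid_parameter")
})

test_that("activation duration counts supra-threshold samples, multi-burst included", {
  sq <- c(rep(1, 30), rep(0, 70))
  expect_equal(as.integer(activation_duration(sq)), 30L)  # threshold 0.2
  flat <- activation_duration(rep(0.4, 100))
  expect_identical(as.integer(flat), 0L)
  expect_true(isTRUE(attr(flat, "degenerate")))
  ## raised-cosine bump: equals a direct scan
  h <- canonical_tpl$H[3, ]   # two-burst profile
  thr <- min(h) + 0.2 * (max(h) - min(h))
  expect_equal(as.integer(activation_duration(h)), sum(h > thr))
  expect_error(activation_duration(h[1:50]), class = "synergait_invalid_input")
})

test_that("activation metric compares durations linearly", {
  expect_equal(activation_metric(40, 40), 1)
  expect_equal(activation_metric(50, 30), 0.8)
  expect_equal(activation_metric(100, 0), 0)
  expect_error(activation_metric(120, 10), class = "synergait_invalid_parameter")
})

test_that("normative thresholds are pooled mean minus two sample SDs", {
  same <- list(similarity = c(0.9, 0.9), correlation = c(1, 1),
               t_lag = c(0.5, 0.5), activation = c(0.7, 0.7))
  thr <- normative_thresholds(same)
  expect_equal(unname(thr), c(0.9, 1, 0.5, 0.7))

  two <- list(similarity = c(0.9, 1.0), correlation = c(0.9, 1.0),
              t_lag = c(0.9, 1.0), activation = c(0.9, 1.0))
  expect_equal(unname(normative_thresholds(two)),
               rep(0.95 - 2 * sd(c(0.9, 1)), 4))
  expect_equal(unname(normative_thresholds(two))[1], 0.8086, tolerance = 1e-4)

  ## spreadsheet-style recomputation on a random pool
  set.seed(41)
  pool <- list(similarity = runif(52, 0.7, 1), correlation = runif(52, 0.7, 1),
               t_lag = runif(52, 0.8, 1), activation = runif(52, 0.6, 1))
  thr <- normative_thresholds(pool)
  manual <- vapply(pool, function(v) {
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    m - 2 * s
  }, numeric(1))
  expect_equal(thr, manual[names(thr)], tolerance = 1e-12)
  expect_error(normative_thresholds(list(similarity = 1)),
               class = "synergait_invalid_input")
})

test_that("impairment rule: strictly below any threshold, equality passes", {
  m <- rbind(A = c(similarity = 1, correlation = 1, t_lag = 1, activation = 1),
             B = c(similarity = 0.79, correlation = 1, t_lag = 1, activation = 1),
             C = c(similarity = 0.789, correlation = 1, t_lag = 1, activation = 1))
  thr <- c(similarity = 0.79, correlation = 0.9, t_lag = 0.96, activation = 0.82)
  flags <- classify_impairment(m, thr)
  expect_identical(unname(flags), c(FALSE, FALSE, TRUE))
  expect_error(classify_impairment(m[, 1:3], thr), class = "synergait_invalid_input")
})

test_that("reference two-patient metric table classifies as expected", {
  f1 <- classify_impairment(reference_patient_metrics("S1"), reference_thresholds)
  expect_true(all(f1))   # all four synergies impaired
  f2 <- classify_impairment(reference_patient_metrics("S2"), reference_thresholds)
  expect_identical(names(which(f2)), c("FC", "LD"))
  ## boundary: WA t_lag 0.96 equals the 0.96 threshold and passes
  expect_false(f2[["WA"]])
})

test_that("full patient assessment mirrors its parts and validates muscles", {
  pat <- make_stroke_patient(canonical_tpl, seed = 77)
  rep <- assess_patient(pat$stride_set, canonical_tpl, thresholds = NULL, seed = 1)
  expect_s3_class(rep, "impairment_report")
  expect_identical(rownames(rep$metrics), c("WA", "PO", "FC", "LD"))
  expect_true(all(rep$metrics[, "similarity"] >= 0 & rep$metrics[, "similarity"] <= 1))
  expect_true(all(rep$metrics[, "t_lag"] >= 0.5 & rep$metrics[, "t_lag"] <= 1))
  expect_true(all(rep$metrics[, "activation"] >= 0 & rep$metrics[, "activation"] <= 1))
  expect_null(rep$impaired)

  M <- pat$envelope_matrix[c(2:8, 1), ]   # reordered muscle names
  expect_error(assess_patient(M, canonical_tpl, seed = 1),
               class = "synergait_invalid_input")
})
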