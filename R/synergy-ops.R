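## Operations on synergy sets: matching against a reference, group averaging,
## and the circular cross-correlation comparison of activation profiles.

## All permutations of 1..n (n small; synergy counts are <= 8)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

#' Centered circular cross-correlation over all integer lags
#'
#' Pearson-style circular cross-correlation between two equal-length
#' profiles: both are mean-subtracted and the correlation at each integer
#' lag is normalized by the product of the centered norms, so values lie in
#' `[-1, 1]`. A positive lag means `x` is delayed relative to `y` (i.e.
#' `x[t] = y[t - lag]` maximizes the correlation at that lag).
#'
#' @param x,y numeric profiles of equal length `T` (100 for one gait cycle).
#' @return Numeric vector of length `T`, correlations at lags
#'   `-floor(T/2) ... ceiling(T/2) - 1` in wrap order (lag 0 first); see
#'   [max_circular_xcorr()] for the usual summary.
#' @export
circular_xcorr <- function(x, y) {
  Tn <- length(x)
  if (length(y) != Tn)
    sg_stop("invalid_input", "profiles differ in length (%d vs %d)", Tn, length(y))
  xc <- x - mean(x); yc <- y - mean(y)
  nx <- sqrt(sum(xc^2)); ny <- sqrt(sum(yc^2))
  if (nx <= 1e-12 || ny <= 1e-12)
    sg_stop("degenerate_input", "zero-variance profile in circular cross-correlation")
  vapply(0:(Tn - 1L), function(k) {
    ## rotate x left by k: x[t + k] against y[t]
    xs <- xc[((seq_len(Tn) - 1L + k) %% Tn) + 1L]
    sum(xs * yc) / (nx * ny)
  }, numeric(1))
}

#' Maximal circular cross-correlation and its lag
#'
#' Evaluates [circular_xcorr()] at every integer lag and returns the maximum
#' with the signed lag (in samples, i.e. percent of gait cycle for 100-point
#' profiles) at which it occurs, in `[-T/2, T/2 - 1]`. Ties are broken
#' toward the smaller `|lag|` (and toward the positive lag on an exact
#' magnitude tie).
#'
#' @inheritParams circular_xcorr
#' @return List with `r_max` and `lag`.
#' @export
max_circular_xcorr <- function(x, y) {
  Tn <- length(x)
  r <- circular_xcorr(x, y)
  half <- as.integer(floor(Tn / 2))
  lags <- as.integer(((0:(Tn - 1L) + half) %% Tn) - half)  # 0,...,T/2-1,-T/2,...,-1
  ord <- order(-r, abs(lags), -sign(lags))
  best <- ord[1L]
  list(r_max = r[best], lag = lags[best])
}

#' Match a candidate synergy set to a reference
#'
#' Finds the one-to-one assignment of candidate synergies to reference
#' synergies that maximizes the total cosine similarity between weight
#' columns (exhaustive over permutations; synergy counts are small). Labels
#' are inherited from the reference; ties break by synergy index order.
#'
#' @param candidate,reference [synergy_set()]s with identical `muscle_names`;
#'   the candidate may have fewer synergies than the reference.
#' @return List with `assignment` (for each candidate synergy, the matched
#'   reference index), `cosines` (per matched pair) and `matched` (the
#'   candidate reordered/labeled to reference order, with `NA`-label gaps
#'   absent: synergies stay in candidate count).
#' @export
match_synergies <- function(candidate, reference) {
  stopifnot(inherits(candidate, "synergy_set"), inherits(reference, "synergy_set"))
  if (!identical(candidate$muscle_names, reference$muscle_names))
    sg_stop("invalid_input", "muscle names differ between candidate and reference")
  Jc <- ncol(candidate$W); Jr <- ncol(reference$W)
  if (Jc > Jr)
    sg_stop("invalid_input", "candidate has more synergies (%d) than reference (%d)",
            Jc, Jr)
  S <- matrix(0, Jc, Jr)
  for (i in seq_len(Jc)) for (j in seq_len(Jr))
    S[i, j] <- cosine_sim(candidate$W[, i], reference$W[, j])
  perms <- permutations(Jr)
  best_tot <- -Inf; best_assign <- NULL
  for (p in seq_len(nrow(perms))) {
    assign <- perms[p, seq_len(Jc)]
    tot <- sum(S[cbind(seq_len(Jc), assign)])
    if (tot > best_tot + 1e-12) { best_tot <- tot; best_assign <- unname(assign) }
  }
  cosines <- S[cbind(seq_len(Jc), best_assign)]
  matched <- candidate
  ord <- order(best_assign)
  matched$W <- candidate$W[, ord, drop = FALSE]
  matched$H <- candidate$H[ord, , drop = FALSE]
  matched$labels <- reference$labels[sort(best_assign)]
  list(assignment = best_assign, cosines = cosines, matched = matched)
}

#' Mean gait-cycle activation profiles
#'
#' Collapses concatenated per-stride activation profiles (J x 100*n_strides)
#' to the J x 100 mean cycle; profiles already one cycle long are returned
#' unchanged.
#'
#' @param H activation profile matrix whose column count is a multiple of
#'   `cycle_points`.
#' @param cycle_points points per gait cycle (default 100).
#' @return J x `cycle_points` matrix.
#' @export
mean_cycle_profiles <- function(H, cycle_points = 100L) {
  Tn <- ncol(H)
  if (Tn == cycle_points) return(H)
  if (Tn %% cycle_points != 0L)
    sg_stop("invalid_input", "profile length %d is not a multiple of %d",
            Tn, cycle_points)
  n_strides <- Tn %/% cycle_points
  arr <- array(H, dim = c(nrow(H), cycle_points, n_strides))
  apply(arr, c(1L, 2L), mean)
}

#' Average matched synergy sets across subjects
#'
#' Unit-normalizes each subject's set, collapses concatenated per-stride
#' activation profiles to the 100-point mean cycle, matches the set to the
#' reference, then takes the element-wise mean of the matched weights and
#' activation profiles. The mean weights are re-normalized to unit columns (scaling
#' absorbed into the mean profiles); per-entry standard deviations are kept
#' in `W_sd` / `H_sd`.
#'
#' @param sets list of [synergy_set()]s, one per subject.
#' @param reference a [synergy_set()] used for matching and labels.
#' @return A `synergy_set` (the group template) with `W_sd` and `H_sd` fields.
#' @export
average_group <- function(sets, reference) {
  stopifnot(length(sets) >= 1L)
  matched <- lapply(sets, function(s) {
    s <- normalize_unit(s)
    s$H <- mean_cycle_profiles(s$H)
    m <- match_synergies(s, reference)
    if (ncol(m$matched$W) != ncol(reference$W))
      sg_stop("invalid_input",
              "subject set has %d synergies after matching; reference has %d",
              ncol(m$matched$W), ncol(reference$W))
    m$matched
  })
  Ws <- simplify2array(lapply(matched, `[[`, "W"))
  Hs <- simplify2array(lapply(matched, `[[`, "H"))
  Wm <- apply(Ws, c(1L, 2L), mean)
  Hm <- apply(Hs, c(1L, 2L), mean)
  out <- synergy_set(Wm, Hm, muscle_names = reference$muscle_names,
                     labels = reference$labels)
  out <- normalize_unit(out)
  out$W_sd <- apply(Ws, c(1L, 2L), sd)
  out$H_sd <- apply(Hs, c(1L, 2L), sd)
  out
}

#' Compare two matched synergy sets (e.g. two walking conditions)
#'
#' For each synergy: cosine similarity of the weights, the maximal centered
#' circular cross-correlation of the 100-point mean activation profiles, and
#' the signed lag (percent of gait cycle) at that maximum. A positive lag
#' means `setB`'s profile is delayed relative to `setA`'s. Group mean and SD
#' of each metric are included.
#'
#' @param setA,setB matched [synergy_set()]s with equal synergy counts and
#'   100-point profiles.
#' @return An object of class `condition_comparison`: per-synergy data frame
#'   plus `mean` and `sd` rows.
#' @export
compare_conditions <- function(setA, setB) {
  stopifnot(inherits(setA, "synergy_set"), inherits(setB, "synergy_set"))
  if (ncol(setA$W) != ncol(setB$W))
    sg_stop("invalid_input", "synergy counts differ")
  if (ncol(setA$H) != 100L || ncol(setB$H) != 100L)
    sg_stop("invalid_input", "profiles must be 100 points per gait cycle")
  J <- ncol(setA$W)
  sim <- corr <- numeric(J)
  lag <- integer(J)
  for (j in seq_len(J)) {
    sim[j] <- cosine_sim(setA$W[, j], setB$W[, j])
    cc <- max_circular_xcorr(setB$H[j, ], setA$H[j, ])
    corr[j] <- cc$r_max
    lag[j] <- cc$lag
  }
  per <- data.frame(synergy = if (length(setA$labels) == J) setA$labels else seq_len(J),
                    similarity = sim, correlation = corr, lag = lag)
  structure(list(per_synergy = per,
                 mean = c(similarity = mean(sim), correlation = mean(corr),
                          lag = mean(lag)),
                 sd = c(similarity = sd(sim), correlation = sd(corr),
                        lag = sd(lag))),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (per synergy):\n")
  print(x$per_synergy, row.names = FALSE)
  cat(sprintf("mean (SD): similarity %.2f (%.2f), correlation %.2f (%.2f), lag %.1f (%.1f)\n",
              x$mean["similarity"], x$sd["similarity"],
              x$mean["correlation"], x$sd["correlation"],
              x$mean["lag"], x$sd["lag"]))
  invisible(x)
}
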