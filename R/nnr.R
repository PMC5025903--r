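## Non-negative matrix reconstruction (NNR): multiplicative updates with one
## factor frozen at the healthy template, projecting a patient's envelopes
## onto healthy synergy space.

nnr_fit_obj <- function(fixed_part, which_fixed, W, H, M, error_trace) {
  vaf <- compute_vaf(M, W, H)
  per_stride <- NULL; mean_profile <- NULL
  Tn <- ncol(H)
  if (which_fixed == "W" && Tn %% 100L == 0L) {
    n_strides <- Tn %/% 100L
    per_stride <- array(H, dim = c(nrow(H), 100L, n_strides))
    mean_profile <- apply(per_stride, c(1L, 2L), mean)
  }
  structure(list(fixed = which_fixed, fixed_part = fixed_part, W = W, H = H,
                 vaf_total = vaf$vaf_total, vaf_per_muscle = vaf$vaf_per_muscle,
                 per_stride_profiles = per_stride, mean_profile = mean_profile,
                 error_trace = error_trace),
            class = "nnr_fit")
}

#' @export
print.nnr_fit <- function(x, ...) {
  cat(sprintf("NNR fit (fixed %s): %d synergies, %d muscles, total VAF %s\n",
              x$fixed, nrow(x$H), nrow(x$W),
              if (is.na(x$vaf_total)) "undefined" else sprintf("%.3f", x$vaf_total)))
  invisible(x)
}

## shared iteration driver; exactly one of the two factors updates
nnr_iterate <- function(M, W, H, update, max_iter, tol, eps = 1e-12) {
  err <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    if (update == "H") {
      H <- H * (crossprod(W, M) / (crossprod(W, W %*% H) + eps))
    } else {
      W <- W * (tcrossprod(M, H) / (W %*% tcrossprod(H) + eps))
    }
    e <- sum((M - W %*% H)^2)
    err[it] <- e
    if (e == 0) break
    if (is.finite(prev) && prev > 0 && (prev - e) / prev < tol) break
    prev <- e
  }
  list(W = W, H = H, error_trace = err)
}

#' NNR with fixed synergy weights
#'
#' Reconstructs envelopes `M` against a fixed, unit-norm healthy weight
#' matrix, updating only the activation coefficients by the multiplicative
#' rule `H <- H * (W' M) / (W' W H)` (a small epsilon guards the
#' denominator). The fixed weights are returned untouched. When `M` holds
#' concatenated 100-point strides, per-stride activation profiles and their
#' mean over strides are also returned.
#'
#' @param M nonnegative muscles x time envelope matrix.
#' @param W_fixed muscles x J nonnegative weights with unit-norm columns.
#' @param max_iter,tol iteration cap and relative-error stopping tolerance.
#' @param seed seed for the random initialization of `H`.
#' @return An `nnr_fit` with fields `H`, `vaf_total`, `vaf_per_muscle`,
#'   `per_stride_profiles`, `mean_profile` and the error trace.
#' @export
nnr_fixed_w <- function(M, W_fixed, max_iter = 1000, tol = 1e-8, seed = 1L) {
  if (!is_nonneg_matrix(M) || !is_nonneg_matrix(W_fixed))
    sg_stop("invalid_input", "M and W_fixed must be nonnegative matrices")
  if (nrow(M) != nrow(W_fixed))
    sg_stop("invalid_input", "M has %d muscles but W_fixed has %d rows",
            nrow(M), nrow(W_fixed))
  norms <- sqrt(colSums(W_fixed^2))
  if (any(norms <= 1e-12))
    sg_stop("degenerate_input", "W_fixed has a zero column")
  if (any(abs(norms - 1) > 1e-6))
    sg_stop("invalid_input", "W_fixed columns must be unit norm (normalize first)")
  J <- ncol(W_fixed); Tn <- ncol(M)
  H0 <- with_seed(seed, matrix(runif(J * Tn, 0.1, 1), J, Tn))
  res <- nnr_iterate(M, W_fixed, H0, "H", max_iter, tol)
  nnr_fit_obj(W_fixed, "W", W_fixed, res$H, M, res$error_trace)
}

#' NNR with fixed activation profiles
#'
#' Reconstructs envelopes `M` against fixed healthy activation profiles,
#' updating only the weights by `W <- W * (M H') / (W H H')`. When
#' `H_fixed` is a single J x 100 mean cycle and `M` spans several strides,
#' the profiles are tiled across strides to match `M`'s columns.
#'
#' @param M nonnegative muscles x time envelope matrix.
#' @param H_fixed J x 100 (or J x ncol(M)) nonnegative activation profiles.
#' @param max_iter,tol iteration cap and relative-error stopping tolerance.
#' @param seed seed for the random initialization of `W`.
#' @return An `nnr_fit` with the estimated weights in `W`.
#' @export
nnr_fixed_h <- function(M, H_fixed, max_iter = 1000, tol = 1e-8, seed = 1L) {
  if (!is_nonneg_matrix(M) || !is_nonneg_matrix(H_fixed))
    sg_stop("invalid_input", "M and H_fixed must be nonnegative matrices")
  Tn <- ncol(M)
  if (ncol(H_fixed) != Tn) {
    if (Tn %% ncol(H_fixed) != 0L)
      sg_stop("invalid_input",
              "cannot tile H_fixed (%d cols) across M (%d cols)",
              ncol(H_fixed), Tn)
    reps <- Tn %/% ncol(H_fixed)
    H_fixed <- do.call(cbind, rep(list(H_fixed), reps))
  }
  if (all(rowSums(H_fixed) == 0))
    sg_stop("degenerate_input", "H_fixed is all zero")
  J <- nrow(H_fixed); N <- nrow(M)
  W0 <- with_seed(seed, matrix(runif(N * J, 0.1, 1), N, J))
  res <- nnr_iterate(M, W0, H_fixed, "W", max_iter, tol)
  nnr_fit_obj(H_fixed, "H", res$W, H_fixed, M, res$error_trace)
}
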