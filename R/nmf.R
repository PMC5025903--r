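## Non-negative matrix factorization of EMG envelopes by Lee-Seung
## multiplicative updates, VAF-based model-order selection, and the
## synergy_set container with its methods.

SYNERGY_LABELS <- c("WA", "PO", "FC", "LD")

#' Muscle synergy set
#'
#' Holds a weight matrix `W` (muscles x J) and activation profiles `H`
#' (J x T), with optional synergy labels (WA = weight acceptance,
#' PO = push off, FC = foot clearance, LD = leg deceleration) and VAF
#' diagnostics. `T` is 100 for a single mean gait cycle or `100 * n_strides`
#' for concatenated per-stride profiles.
#'
#' @param W nonnegative muscles x J matrix of synergy weights.
#' @param H nonnegative J x T matrix of activation profiles.
#' @param muscle_names muscle labels, one per row of `W`.
#' @param labels per-synergy tags (`"unlabeled"` by default).
#' @param vaf_total,vaf_per_muscle optional VAF diagnostics.
#' @return An object of class `synergy_set`.
#' @export
synergy_set <- function(W, H, muscle_names = rownames(W),
                        labels = rep("unlabeled", ncol(W)),
                        vaf_total = NA_real_, vaf_per_muscle = NULL) {
  if (!is_nonneg_matrix(W) || !is_nonneg_matrix(H))
    sg_stop("invalid_input", "W and H must be nonnegative numeric matrices")
  if (ncol(W) != nrow(H))
    sg_stop("invalid_input", "ncol(W) (%d) must equal nrow(H) (%d)",
            ncol(W), nrow(H))
  if (is.null(muscle_names)) muscle_names <- paste0("m", seq_len(nrow(W)))
  rownames(W) <- muscle_names
  structure(list(W = W, H = H, muscle_names = as.character(muscle_names),
                 labels = as.character(labels),
                 vaf_total = vaf_total, vaf_per_muscle = vaf_per_muscle),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("Synergy set: %d muscles, %d synergies, profiles of length %d\n",
              nrow(x$W), ncol(x$W), ncol(x$H)))
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  if (!is.na(x$vaf_total))
    cat(sprintf("  total VAF: %.3f\n", x$vaf_total))
  invisible(x)
}

#' @export
coef.synergy_set <- function(object, ...) object$W

#' @export
fitted.synergy_set <- function(object, ...) object$W %*% object$H

#' Plot synergy weights and activation profiles
#'
#' One row per synergy: weight barplot on the left, activation profile over
#' the gait cycle on the right.
#'
#' @param x a [synergy_set()].
#' @param ... unused.
#' @export
plot.synergy_set <- function(x, ...) {
  J <- ncol(x$W)
  op <- graphics::par(mfrow = c(J, 2), mar = c(2.5, 3.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (j in seq_len(J)) {
    graphics::barplot(x$W[, j], names.arg = x$muscle_names, las = 2,
                      main = x$labels[j], cex.names = 0.7)
    graphics::plot(seq_len(ncol(x$H)), x$H[j, ], type = "l",
                   xlab = "", ylab = "activation")
  }
  invisible(x)
}

## one multiplicative-update run from a given init; returns W, H, error trace
nmf_run <- function(M, J, max_iter, tol, W0, H0, eps = 1e-12) {
  W <- W0; H <- H0
  err <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    ## Lee & Seung squared-error updates
    H <- H * (crossprod(W, M) / (crossprod(W, W %*% H) + eps))
    W <- W * (tcrossprod(M, H) / (W %*% tcrossprod(H) + eps))
    e <- sum((M - W %*% H)^2)
    err[it] <- e
    if (e == 0) break
    if (is.finite(prev) && prev > 0 && (prev - e) / prev < tol) break
    prev <- e
  }
  list(W = W, H = H, error_trace = err, n_iter = length(err))
}

#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factorizes a nonnegative envelope matrix `M` (muscles x time) as
#' `M ~ W %*% H` with `J` synergies, using multiplicative updates that
#' monotonically decrease the squared reconstruction error. Several random
#' restarts are run and the solution with the lowest final error is kept;
#' with a fixed `seed` the result is bit-reproducible. The returned weights
#' are unit-normalized (each column of `W` has Euclidean norm 1, with the
#' inverse scaling absorbed into `H` so `W %*% H` is unchanged).
#'
#' @param M nonnegative muscles x time matrix (e.g. [as_envelope_matrix()]).
#' @param n_synergies number of synergies J, `1 <= J <= min(dim(M))`.
#' @param n_restarts random restarts (default 20).
#' @param max_iter maximum update iterations per restart (default 1000).
#' @param tol relative decrease of squared error at which to stop (default 1e-6).
#' @param seed integer seed for the random initializations, or `NULL`.
#' @return An object of classes `synergy_nmf` and `synergy_set`, with the
#'   error trace of the winning restart, iteration count and VAF fields.
#' @export
synergy_nmf <- function(M, n_synergies, n_restarts = 20, max_iter = 1000,
                        tol = 1e-6, seed = NULL) {
  if (!is_nonneg_matrix(M))
    sg_stop("invalid_input", "M must be a nonnegative numeric matrix")
  if (all(M == 0))
    sg_stop("degenerate_input", "M is all zero; nothing to factorize")
  J <- as.integer(n_synergies)
  if (J < 1L || J > min(dim(M)))
    sg_stop("invalid_parameter", "n_synergies = %d outside [1, %d]",
            J, min(dim(M)))
  N <- nrow(M); Tn <- ncol(M)
  scale0 <- sqrt(mean(M^2))
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      W0 <- matrix(runif(N * J, 0.1, 1) * scale0, N, J)
      H0 <- matrix(runif(J * Tn, 0.1, 1), J, Tn)
      run <- nmf_run(M, J, max_iter, tol, W0, H0)
      if (is.null(best) || tail(run$error_trace, 1L) < tail(best$error_trace, 1L))
        best <- run
    }
  })
  vaf <- compute_vaf(M, best$W, best$H)
  fit <- synergy_set(best$W, best$H, muscle_names = rownames(M),
                     vaf_total = vaf$vaf_total, vaf_per_muscle = vaf$vaf_per_muscle)
  fit$error_trace <- best$error_trace
  fit$n_iter <- best$n_iter
  fit$seed <- seed
  fit$M <- M
  fit <- normalize_unit(fit)
  class(fit) <- c("synergy_nmf", "synergy_set")
  fit
}

#' @export
print.synergy_nmf <- function(x, ...) {
  cat("NMF muscle-synergy fit\n")
  NextMethod()
  cat(sprintf("  converged in %d iterations; final SSE %.4g\n",
              x$n_iter, tail(x$error_trace, 1L)))
  invisible(x)
}

#' @export
summary.synergy_nmf <- function(object, ...) {
  out <- list(n_synergies = ncol(object$W), vaf_total = object$vaf_total,
              vaf_per_muscle = object$vaf_per_muscle, n_iter = object$n_iter,
              final_sse = tail(object$error_trace, 1L))
  class(out) <- "summary.synergy_nmf"
  out
}

#' @export
print.summary.synergy_nmf <- function(x, ...) {
  cat(sprintf("NMF fit with %d synergies\n  total VAF %.4f, %d iterations, SSE %.4g\n",
              x$n_synergies, x$vaf_total, x$n_iter, x$final_sse))
  cat("  per-muscle VAF:\n")
  print(round(x$vaf_per_muscle, 4))
  invisible(x)
}

#' @export
residuals.synergy_nmf <- function(object, ...) {
  if (is.null(object$M)) sg_stop("invalid_input", "fit carries no data matrix")
  object$M - object$W %*% object$H
}

#' Project new envelopes onto a fitted synergy basis
#'
#' For a fitted synergy set, estimates activation profiles for new envelope
#' data with the weights held fixed (fixed-W NNR).
#'
#' @param object a `synergy_set` (e.g. a [synergy_nmf()] fit or template).
#' @param newdata nonnegative muscles x time matrix.
#' @param ... passed to [nnr_fixed_w()].
#' @return An [nnr_fit] object.
#' @export
predict.synergy_set <- function(object, newdata, ...) {
  nnr_fixed_w(newdata, normalize_unit(object)$W, ...)
}

#' Variability accounted for (VAF)
#'
#' `1 - SSE/SST` with uncentered SST (total sum of squared entries), overall
#' and per muscle (row-wise). A zero-SST row yields `NA` for that muscle
#' rather than a silent 0.
#'
#' @param M data matrix; `W`, `H` its factorization.
#' @return List with `vaf_total` and `vaf_per_muscle`.
#' @export
compute_vaf <- function(M, W, H) {
  R <- M - W %*% H
  sst <- sum(M^2)
  vaf_total <- if (sst == 0) NA_real_ else 1 - sum(R^2) / sst
  sst_row <- rowSums(M^2)
  vaf_row <- ifelse(sst_row == 0, NA_real_, 1 - rowSums(R^2) / sst_row)
  names(vaf_row) <- rownames(M)
  list(vaf_total = vaf_total, vaf_per_muscle = vaf_row)
}

#' Select the number of synergies by the VAF criterion
#'
#' Ascends J = 1, 2, ... and returns the smallest J whose reconstruction
#' reaches a total VAF above `vaf_threshold` (default 0.90), or for which
#' adding one more synergy improves no single muscle's VAF by more than
#' `muscle_gain` (default 0.05). If no J up to `j_max` satisfies either
#' clause, `j_max` is returned with a warning.
#'
#' @param M nonnegative muscles x time matrix.
#' @param j_max largest order considered (default `nrow(M)`).
#' @param vaf_threshold total-VAF clause threshold.
#' @param muscle_gain per-muscle improvement clause threshold.
#' @param ... passed to [synergy_nmf()] (restarts, tolerance, seed, ...).
#' @return The selected J (integer) with attribute `"fits"` holding the
#'   per-order fits computed along the way.
#' @export
select_model_order <- function(M, j_max = nrow(M), vaf_threshold = 0.90,
                               muscle_gain = 0.05, ...) {
  j_max <- min(as.integer(j_max), min(dim(M)))
  fits <- vector("list", j_max + 1L)
  get_fit <- function(j) {
    if (j > length(fits)) return(NULL)
    if (is.null(fits[[j]])) fits[[j]] <<- synergy_nmf(M, j, ...)
    fits[[j]]
  }
  chosen <- NA_integer_
  for (j in seq_len(j_max)) {
    fit <- get_fit(j)
    if (fit$vaf_total > vaf_threshold) { chosen <- j; break }
    if (j < min(dim(M))) {
      nxt <- get_fit(j + 1L)
      gain <- max(nxt$vaf_per_muscle - fit$vaf_per_muscle, na.rm = TRUE)
      if (gain <= muscle_gain) { chosen <- j; break }
    }
  }
  if (is.na(chosen)) {
    sg_warn("order_not_found", "no order up to %d met the VAF criterion", j_max)
    chosen <- j_max
  }
  structure(as.integer(chosen), fits = fits[!vapply(fits, is.null, logical(1))])
}

#' Normalize synergy weights to unit norm
#'
#' Scales each column of `W` to Euclidean norm 1 and multiplies the matching
#' row of `H` by the old norm, leaving the product `W %*% H` unchanged.
#'
#' @param syn a [synergy_set()].
#' @return The normalized `synergy_set`.
#' @export
normalize_unit <- function(syn) {
  stopifnot(inherits(syn, "synergy_set"))
  norms <- sqrt(colSums(syn$W^2))
  if (any(norms <= 1e-12))
    sg_stop("degenerate_synergy", "zero-norm weight column (synergy %s)",
            paste(which(norms <= 1e-12), collapse = ", "))
  syn$W <- sweep(syn$W, 2L, norms, "/")
  syn$H <- sweep(syn$H, 1L, norms, "*")
  syn
}
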