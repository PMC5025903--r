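#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx median rnorm runif sd setNames
#' @importFrom utils head read.csv tail write.csv
NULL

## Classed error helper: every validation failure carries a condition class
## (e.g. "synergait_invalid_parameter") so callers can dispatch on it.
sg_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(paste0("synergait_", class), "synergait_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

sg_warn <- function(class, fmt, ...) {
  warning(structure(
    class = c(paste0("synergait_", class), "synergait_warning", "warning", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

## Run code with a temporarily seeded RNG, restoring global state afterwards,
## so generators are bit-reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## scalar checks --------------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    sg_stop("invalid_parameter", "`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    sg_stop("invalid_parameter", "`%s` = %g outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

is_nonneg_matrix <- function(M) {
  is.matrix(M) && is.numeric(M) && all(is.finite(M)) && all(M >= 0)
}

## cosine of two nonnegative (or general) vectors
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    sg_stop("degenerate_input", "cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}
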