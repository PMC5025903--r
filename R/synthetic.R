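## Synthetic ground-truth generator: canonical 4-synergy gait template,
## healthy cohorts, stroke-like patients (merged / shifted / widened
## synergies) and gait-event streams. Everything is seeded and
## bit-reproducible so the whole pipeline is testable without recordings.

CANONICAL_MUSCLES <- c("GM", "RF", "VM", "HM", "HL", "MG", "SO", "TA")

#' Canonical gait-phase fractions
#'
#' Default partition of the 100-point gait-cycle template into the six gait
#' phases (paretic double support, non-paretic initial swing, non-paretic
#' terminal swing, non-paretic double support, paretic initial swing,
#' paretic terminal swing), using textbook symmetric-gait proportions:
#' double supports ~12% each, swings split ~= 38% per side.
#'
#' @return Numeric vector of 6 fractions summing to 1.
#' @export
canonical_phase_fractions <- function() {
  c(0.12, 0.19, 0.19, 0.12, 0.19, 0.19)
}

## raised-cosine burst of given center and width (points of a 100-pt cycle),
## wrapping circularly; peak 1
raised_cosine <- function(center, width, n = 100L) {
  t <- 0:(n - 1L)
  d <- (t - center + n / 2) %% n - n / 2   # circular distance in [-50, 50)
  ifelse(abs(d) < width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

#' Canonical healthy synergy template
#'
#' Builds the four-synergy gait template used as synthetic ground truth:
#' WA (weight acceptance) loads the hip/knee extensors (GM, VM) with an
#' early-stance burst; PO (push off) loads the plantar-flexors (MG, SO)
#' with a late-stance burst; FC (foot clearance) loads rectus femoris and
#' tibialis anterior (RF, TA) with a two-burst early-stance + early-swing
#' profile; LD (leg deceleration) loads the hamstrings (HM, HL) with a
#' late-swing burst wrapping into early stance. Cross-talk weights are kept
#' at or below 0.15, and the plantar-flexors are given no weight in FC or
#' LD (those synergies do not recruit the calf). Weight columns are unit
#' norm; profiles are nonnegative with peak 1.
#'
#' @param muscle_names muscle set; must contain the canonical eight
#'   (GM, RF, VM, HM, HL, MG, SO, TA).
#' @return A labeled [synergy_set()] with `J = 4` and 100-point profiles.
#' @export
make_canonical_template <- function(muscle_names = CANONICAL_MUSCLES) {
  missing <- setdiff(CANONICAL_MUSCLES, muscle_names)
  if (length(missing))
    sg_stop("invalid_input", "muscle set lacks canonical muscle(s): %s",
            paste(missing, collapse = ", "))
  N <- length(muscle_names)
  W <- matrix(0, N, 4L, dimnames = list(muscle_names, c("WA", "PO", "FC", "LD")))
  w <- function(syn, vals) W[names(vals), syn] <<- vals
  w("WA", c(GM = 0.50, VM = 0.70, RF = 0.15))
  w("PO", c(MG = 0.70, SO = 0.70, GM = 0.15))
  w("FC", c(RF = 0.45, TA = 0.80, VM = 0.12))
  w("LD", c(HM = 0.68, HL = 0.68, GM = 0.15, TA = 0.15))
  W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
  H <- rbind(
    WA = raised_cosine(20, 26),
    PO = raised_cosine(45, 26),
    FC = pmax(raised_cosine(2, 12), 0.95 * raised_cosine(65, 20)),
    LD = raised_cosine(94, 24)
  )
  synergy_set(W, H, muscle_names = muscle_names,
              labels = c("WA", "PO", "FC", "LD"))
}

## circular shift of a profile by s points (positive = delayed)
shift_profile <- function(h, s) {
  n <- length(h)
  h[((seq_len(n) - 1L - round(s)) %% n) + 1L]
}

## widen (f > 1) or narrow (f < 1) a profile's bursts about its peak
scale_width <- function(h, f) {
  n <- length(h)
  c0 <- which.max(h) - 1L
  t <- 0:(n - 1L)
  d <- ((t - c0 + n / 2) %% n) - n / 2
  eval_template(h, ((c0 + d / f) %% n) / n)
}

## per-stride envelope block from weights + jittered profiles + noise
synth_strides <- function(W, H, n_strides, noise_sd, timing_jitter_sd) {
  N <- nrow(W); J <- nrow(H)
  arr <- array(0, dim = c(n_strides, N, 100L))
  peak <- max(W %*% H)
  for (s in seq_len(n_strides)) {
    Hs <- H
    if (timing_jitter_sd > 0) {
      for (j in seq_len(J))
        Hs[j, ] <- shift_profile(H[j, ], rnorm(1L, 0, timing_jitter_sd))
    }
    M <- W %*% Hs
    if (noise_sd > 0)
      M <- M + matrix(rnorm(N * 100L, 0, noise_sd * peak), N, 100L)
    arr[s, , ] <- pmax(M, 0)
  }
  arr
}

#' Generate a synthetic healthy cohort
#'
#' Emulates a healthy walking study: each subject gets weights perturbed
#' with truncated-at-zero Gaussian noise (then re-unit-normalized),
#' subject-level timing shifts and burst-width scaling of the activation
#' profiles (healthy people differ systematically in when and for how long
#' each synergy fires), per-stride timing jitter, and additive envelope
#' noise clipped at zero. Defaults model a cohort of 13 subjects walking 20
#' strides with envelope noise of 5% of the signal peak.
#'
#' @param template a labeled [synergy_set()] (e.g.
#'   [make_canonical_template()]).
#' @param n_subjects number of subjects (default 13).
#' @param n_strides strides per subject (default 20).
#' @param between_subject_sd SD of the weight perturbation (default 0.10).
#' @param noise_sd envelope noise SD as a fraction of the signal peak
#'   (default 0.05).
#' @param timing_jitter_sd per-stride circular shift SD in points
#'   (default 2).
#' @param subject_timing_sd SD of each subject's per-synergy systematic
#'   timing shift in points (default 3).
#' @param width_scale_sd SD of each subject's per-synergy burst-width
#'   factor about 1 (default 0.20).
#' @param seed integer seed; fixed seed gives a bit-identical cohort.
#' @return List of subjects; each has `stride_set` (a [stride_set()]),
#'   `envelope_matrix` (muscles x 2000) and the subject's true `W` and `H`.
#' @export
make_healthy_cohort <- function(template, n_subjects = 13, n_strides = 20,
                                between_subject_sd = 0.10, noise_sd = 0.05,
                                timing_jitter_sd = 2, subject_timing_sd = 3,
                                width_scale_sd = 0.20, seed = 1L) {
  stopifnot(inherits(template, "synergy_set"))
  J <- ncol(template$W)
  with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      W <- pmax(template$W + matrix(rnorm(length(template$W), 0, between_subject_sd),
                                    nrow(template$W)), 0)
      W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
      rownames(W) <- template$muscle_names
      H <- template$H
      for (j in seq_len(J)) {
        if (subject_timing_sd > 0)
          H[j, ] <- shift_profile(H[j, ], rnorm(1L, 0, subject_timing_sd))
        if (width_scale_sd > 0)
          H[j, ] <- scale_width(H[j, ], max(rnorm(1L, 1, width_scale_sd), 0.5))
      }
      arr <- synth_strides(W, H, n_strides, noise_sd, timing_jitter_sd)
      sset <- stride_set(arr, template$muscle_names)
      list(stride_set = sset, envelope_matrix = as_envelope_matrix(sset),
           W = W, H = H)
    })
  })
}

#' Generate a synthetic stroke-like patient
#'
#' Injects the deficits described for hemiparetic gait into the template
#' before generating envelopes: `merge_pairs` replaces each pair of
#' synergies with a single merged module (summed then re-unit-normalized
#' weights, driven by the union of the two activation profiles);
#' `lag_shift` circularly shifts a synergy's profile (negative = early
#' recruitment); `duration_scale` widens (>1) or narrows (<1) a synergy's
#' bursts about their peak.
#'
#' @param template a labeled [synergy_set()].
#' @param merge_pairs list of disjoint label pairs to merge, e.g.
#'   `list(c("WA", "LD"))`.
#' @param lag_shift named numeric vector of circular shifts in points per
#'   synergy label (negative = early).
#' @param duration_scale named numeric vector of burst-width factors per
#'   label.
#' @param n_strides,noise_sd,timing_jitter_sd as in [make_healthy_cohort()].
#' @param seed integer seed.
#' @return List with `stride_set`, `envelope_matrix`, the generative `W`,
#'   `H` and `n_generative_synergies`.
#' @export
make_stroke_patient <- function(template, merge_pairs = list(),
                                lag_shift = c(), duration_scale = c(),
                                n_strides = 20, noise_sd = 0.05,
                                timing_jitter_sd = 2, seed = 1L) {
  stopifnot(inherits(template, "synergy_set"))
  labels <- template$labels
  merged_lbls <- unlist(merge_pairs)
  if (anyDuplicated(merged_lbls))
    sg_stop("invalid_input", "merge pairs must be disjoint")
  if (!all(merged_lbls %in% labels))
    sg_stop("invalid_input", "unknown label in merge_pairs")
  W <- template$W; H <- template$H
  ## apply per-synergy timing deficits first
  for (lbl in names(lag_shift))
    H[match(lbl, labels), ] <- shift_profile(H[match(lbl, labels), ],
                                             lag_shift[[lbl]])
  for (lbl in names(duration_scale))
    H[match(lbl, labels), ] <- scale_width(H[match(lbl, labels), ],
                                           duration_scale[[lbl]])
  ## merge pairs: summed weights (renormalized), union of activations
  keep <- rep(TRUE, length(labels))
  for (pair in merge_pairs) {
    j1 <- match(pair[1L], labels); j2 <- match(pair[2L], labels)
    wm <- W[, j1] + W[, j2]
    W[, j1] <- wm / sqrt(sum(wm^2))
    hm <- pmax(H[j1, ], H[j2, ])
    H[j1, ] <- hm / max(hm)
    keep[j2] <- FALSE
  }
  W <- W[, keep, drop = FALSE]
  H <- H[keep, , drop = FALSE]
  arr <- with_seed(seed,
                   synth_strides(W, H, n_strides, noise_sd, timing_jitter_sd))
  sset <- stride_set(arr, template$muscle_names)
  list(stride_set = sset, envelope_matrix = as_envelope_matrix(sset),
       W = W, H = H, n_generative_synergies = ncol(W))
}

#' Generate a synthetic gait-event stream
#'
#' Emits the alternating IC/EC/MS event sequence consistent with the
#' six-phase cycle, starting at a paretic initial contact at time 0, with
#' per-stride per-phase durations drawn around the given means (Gaussian,
#' truncated at 10% of the mean so durations stay positive).
#'
#' @param phase_means 6 mean phase durations in seconds.
#' @param variability_sd duration SD in seconds (default 0; common to all
#'   phases).
#' @param n_strides number of complete strides (0 gives an empty stream).
#' @param seed integer seed.
#' @return A [gait_event_stream()].
#' @export
make_event_stream <- function(phase_means, variability_sd = 0, n_strides = 10,
                              seed = 1L) {
  if (length(phase_means) != 6L || any(phase_means <= 0))
    sg_stop("invalid_parameter", "phase_means must be 6 positive durations")
  if (n_strides == 0L) return(gait_event_stream(numeric(0), character(0), character(0)))
  ## event that STARTS each phase: phase 1 starts at paretic IC, phase i+1
  ## starts at the event ending phase i
  types <- c("IC", PHASE_TABLE$end_event[1:5])
  sides <- c("paretic", PHASE_TABLE$end_side[1:5])
  with_seed(seed, {
    t <- 0
    time_s <- type <- side <- c()
    for (s in seq_len(n_strides)) {
      for (p in 1:6) {
        time_s <- c(time_s, t)
        type <- c(type, types[p])
        side <- c(side, sides[p])
        d <- phase_means[p]
        if (variability_sd > 0)
          d <- max(phase_means[p] + rnorm(1L, 0, variability_sd),
                   0.1 * phase_means[p])
        t <- t + d
      }
    }
    ## closing paretic IC so the last stride is complete
    time_s <- c(time_s, t); type <- c(type, "IC"); side <- c(side, "paretic")
    gait_event_stream(time_s, type, side)
  })
}
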