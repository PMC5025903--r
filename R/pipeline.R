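## End-to-end pipeline stages with run manifests: template building from a
## healthy cohort, patient assessment, strategy construction + session
## simulation. These functions back the command-line interface in
## inst/cli/synergait.R.

run_manifest <- function(command, config, seed, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(command = command,
       config = config,
       seed = seed,
       input_digests = digests,
       tool_version = as.character(utils::packageVersion("synergait")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

stage <- function(name, expr) {
  tryCatch(expr, synergait_error = function(e) {
    sg_stop("stage_failure", "[%s] %s", name, conditionMessage(e))
  })
}

#' Build a healthy synergy template and normative thresholds from a cohort
#'
#' For each subject: NMF extraction at the selected (or given) model order
#' and unit normalization. Subject sets are matched to a reference (the
#' first subject's set, or `reference` if supplied), averaged into the
#' group template, and each subject is then reassessed against that
#' template with the two NNRs to pool the four metric values from which the
#' mean − 2 SD normative thresholds are computed.
#'
#' @param cohort list of subjects, each a [stride_set()] or a muscles x T
#'   envelope matrix (e.g. from [make_healthy_cohort()], taking
#'   `$stride_set`).
#' @param n_synergies fixed synergy count, or `NULL` to select per subject
#'   by the VAF criterion and use the modal count.
#' @param reference optional labeled [synergy_set()] used for matching and
#'   labels; default: the first subject's fit with canonical labels applied
#'   by best match to [make_canonical_template()] when the muscle set is
#'   canonical.
#' @param seed integer seed driving all factorizations.
#' @param n_restarts,max_iter,tol NMF solver settings (see [synergy_nmf()]).
#' @param out_dir optional directory to write `template.json`,
#'   `thresholds.json` and `manifest.json` into.
#' @return List with `template` (a [synergy_set()]), `thresholds`,
#'   `metric_pool` (the pooled healthy metric values), per-subject fits and
#'   the run `manifest`.
#' @export
run_template_build <- function(cohort, n_synergies = NULL, reference = NULL,
                               seed = 1L, n_restarts = 10, max_iter = 500,
                               tol = 1e-6, out_dir = NULL) {
  if (length(cohort) < 2L)
    sg_stop("insufficient_cohort", "need at least 2 subjects, got %d",
            length(cohort))
  mats <- lapply(cohort, function(s)
    if (inherits(s, "stride_set")) as_envelope_matrix(s) else s)
  seeds <- seed + seq_along(mats) * 1000L
  orders <- NULL
  if (is.null(n_synergies)) {
    orders <- vapply(seq_along(mats), function(i)
      stage(sprintf("order selection, subject %d", i),
            as.integer(select_model_order(mats[[i]], seed = seeds[i],
                                          n_restarts = n_restarts,
                                          max_iter = max_iter, tol = tol))),
      integer(1))
    n_synergies <- as.integer(names(which.max(table(orders))))
  }
  fits <- lapply(seq_along(mats), function(i)
    stage(sprintf("extraction, subject %d", i),
          synergy_nmf(mats[[i]], n_synergies, n_restarts = n_restarts,
                      max_iter = max_iter, tol = tol, seed = seeds[i])))
  if (is.null(reference)) {
    reference <- fits[[1L]]
    canon <- tryCatch(make_canonical_template(fits[[1L]]$muscle_names),
                      synergait_error = function(e) NULL)
    if (!is.null(canon) && ncol(canon$W) == n_synergies)
      reference <- match_synergies(fits[[1L]], canon)$matched
  }
  template <- stage("group averaging", average_group(fits, reference))
  ## healthy normality ranges: assess every subject against the template
  pool <- list(similarity = c(), correlation = c(), t_lag = c(), activation = c())
  for (i in seq_along(mats)) {
    rep_i <- stage(sprintf("normative assessment, subject %d", i),
                   assess_patient(mats[[i]], template, thresholds = NULL,
                                  seed = seeds[i]))
    for (m in METRIC_NAMES) pool[[m]] <- c(pool[[m]], rep_i$metrics[, m])
  }
  thresholds <- normative_thresholds(pool)
  manifest <- run_manifest("template", list(n_synergies = n_synergies,
                                            n_restarts = n_restarts,
                                            max_iter = max_iter, tol = tol),
                           seed)
  out <- list(template = template, thresholds = thresholds,
              metric_pool = pool, subject_fits = fits,
              subject_orders = orders, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_synergy_json(template, file.path(out_dir, "template.json"))
    jsonlite::write_json(as.list(thresholds),
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Assess a patient against a template and thresholds
#'
#' Thin wrapper over [assess_patient()] with muscle-set validation, report
#' serialization and a manifest.
#'
#' @param patient a [stride_set()] or envelope matrix for the paretic side.
#' @param template healthy [synergy_set()].
#' @param thresholds named threshold vector.
#' @param seed integer seed for the NNR initializations.
#' @param out_dir optional output directory (`report.json`, `report.csv`,
#'   `manifest.json`).
#' @return List with `report` and `manifest`.
#' @export
run_patient_assessment <- function(patient, template, thresholds,
                                   seed = 1L, out_dir = NULL) {
  report <- stage("patient assessment",
                  assess_patient(patient, template, thresholds, seed = seed))
  manifest <- run_manifest("assess", list(), seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "report.json"))
    write_report_csv(report, file.path(out_dir, "report.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, manifest = manifest)
}

#' Build the stimulation strategy and simulate a session
#'
#' Chains [build_strategy()] on the report's impaired synergies with
#' [simulate_session()] over a gait-event stream.
#'
#' @param report an [impairment_report()] with impairment flags.
#' @param template healthy [synergy_set()].
#' @param stream a [gait_event_stream()].
#' @param seed integer seed recorded in the manifest.
#' @param out_dir optional output directory (`strategy.json`,
#'   `commands.csv`, `manifest.json`).
#' @param ... passed to [build_strategy()] (amplitudes, pulse-width ceiling,
#'   frequency, phase bounds, grouping threshold).
#' @return List with `strategy`, `commands` and `manifest`.
#' @export
run_strategy_and_simulate <- function(report, template, stream, seed = 1L,
                                      out_dir = NULL, ...) {
  strategy <- stage("strategy construction",
                    build_strategy(template, impaired_labels(report), ...))
  commands <- stage("session simulation", simulate_session(strategy, stream))
  manifest <- run_manifest("strategy", list(...), seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_strategy_json(strategy, file.path(out_dir, "strategy.json"))
    write_command_log(commands, file.path(out_dir, "commands.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(strategy = strategy, commands = commands, manifest = manifest)
}
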