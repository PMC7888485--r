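# Plain-text persistence: parcellated runs and connectivity matrices as TSV,
# motion traces as single-column text, cohort manifests and ground truth as
# JSON. All writers produce deterministic byte streams for a given input.

#' Write a parcellated run to TSV (+ RMS trace)
#'
#' @param run A [parcellated_run()].
#' @param signal_path Output path for the signal TSV (header row of region
#'   names, one row per timepoint).
#' @param rms_path Output path for the single-column RMS text file.
#' @return Invisibly, the signal path.
#' @export
write_run_tsv <- function(run, signal_path, rms_path) {
  stopifnot(inherits(run, "parcellated_run"))
  utils::write.table(run$signal, signal_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  writeLines(format_num(run$rms), rms_path)
  invisible(signal_path)
}

#' Read a parcellated run from TSV (+ RMS trace)
#'
#' @param signal_path Signal TSV path (header = region names).
#' @param rms_path Single-column RMS text path.
#' @param tr_seconds Sampling interval.
#' @return A [parcellated_run()].
#' @export
read_run_tsv <- function(signal_path, rms_path, tr_seconds = 0.72) {
  signal <- as.matrix(utils::read.delim(signal_path, check.names = FALSE))
  rms <- as.numeric(readLines(rms_path))
  parcellated_run(signal, rms, tr_seconds)
}

#' Write a synthetic cohort to disk
#'
#' Lays out one TSV + RMS file per run under `dir`, plus `manifest.json`
#' (subject -> session -> run -> file paths) and `truth.json` (generator
#' parameters, per-subject global amplitudes and spike frames).
#'
#' @param cohort A `synthetic_cohort` from [generate_timeseries_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tr_seconds = cohort$spec$tr_seconds, subjects = list())
  for (sub in cohort$subjects) {
    sessions <- list()
    for (sess in seq_along(sub$sessions)) {
      runs <- list()
      for (r in seq_along(sub$sessions[[sess]])) {
        base <- sprintf("%s_ses%d_run%d", sub$subject_id, sess, r)
        sig <- file.path(dir, paste0(base, "_timeseries.tsv"))
        rms <- file.path(dir, paste0(base, "_rms.txt"))
        write_run_tsv(sub$sessions[[sess]][[r]], sig, rms)
        runs[[r]] <- list(signal = basename(sig), rms = basename(rms))
      }
      sessions[[paste0("session", sess)]] <- runs
    }
    manifest$subjects[[sub$subject_id]] <- sessions
  }
  if (!is.null(cohort$network_labels)) {
    utils::write.table(cohort$network_labels,
                       file.path(dir, "network_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$network_labels <- "network_labels.tsv"
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  truth <- list(
    spec = cohort$spec[c("n_subjects", "n_regions", "n_runs_per_session",
                         "n_timepoints_per_run", "tr_seconds",
                         "subject_dev_sd", "session_dev_sd",
                         "global_amp_mean", "global_amp_sd",
                         "spike_rate", "spike_rms", "seed")],
    global_amplitude = cohort$truth$global_amplitude,
    spike_frames = cohort$truth$spike_frames
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest_path)
}

#' Load a cohort from a manifest
#'
#' Reads the `manifest.json` layout produced by [write_cohort()] (or an
#' equivalent manifest pointing at any external parcellation's TSV output).
#'
#' @param manifest_path Path to `manifest.json`.
#' @return A list shaped like a `synthetic_cohort` (elements `subjects` and
#'   `network_labels`; no `truth`).
#' @export
read_cohort <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  tr <- as.numeric(manifest$tr_seconds)
  subjects <- vector("list", length(manifest$subjects))
  for (si in seq_along(manifest$subjects)) {
    sid <- names(manifest$subjects)[si]
    sessions <- lapply(manifest$subjects[[si]], function(sess) {
      lapply(sess, function(run) {
        read_run_tsv(file.path(dir, run$signal), file.path(dir, run$rms), tr)
      })
    })
    names(sessions) <- NULL
    subjects[[si]] <- list(subject_id = sid, sessions = sessions)
  }
  labels <- NULL
  if (!is.null(manifest$network_labels)) {
    labels <- utils::read.delim(file.path(dir, manifest$network_labels),
                                stringsAsFactors = FALSE)
  }
  structure(list(spec = NULL, subjects = subjects, truth = NULL,
                 network_labels = labels),
            class = "synthetic_cohort")
}

#' Write a connectivity (or any region x region) matrix as TSV
#'
#' @param values Square matrix with region dimnames.
#' @param path Output path. The first column holds region names.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(values, path) {
  df <- data.frame(region = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return Matrix with region dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

# Deterministic full-precision number formatting for text output.
format_num <- function(x) {
  formatC(x, digits = 17, format = "g")
}
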