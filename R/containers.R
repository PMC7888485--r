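#' Parcellated timeseries for a single run
#'
#' Bundles one run's region-averaged signal matrix with its framewise motion
#' trace. This is the atomic input of the preprocessing pipeline: one scanner
#' run, rows are timepoints, columns are atlas regions.
#'
#' @param signal Numeric matrix, timepoints x regions.
#' @param rms Numeric vector of framewise relative root-mean-square
#'   displacement (mm), one value per timepoint. By convention the first
#'   frame of a run has no predecessor and carries 0.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param region_names Character vector of region labels, one per column.
#'   Defaults to the column names of `signal`.
#'
#' @return An object of class `parcellated_run`: a list with elements
#'   `signal`, `rms`, `tr_seconds`, `region_names`.
#' @export
parcellated_run <- function(signal, rms, tr_seconds = 0.72,
                            region_names = colnames(signal)) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("'signal' must be a numeric matrix")
  rms <- as.numeric(rms)
  if (length(rms) != nrow(signal)) {
    stop("'rms' must have one value per timepoint (", nrow(signal),
         "), got ", length(rms))
  }
  if (any(!is.finite(rms)) || any(rms < 0)) {
    stop("'rms' values must be finite and non-negative")
  }
  if (is.null(region_names)) {
    region_names <- paste0("R", seq_len(ncol(signal)))
  }
  region_names <- as.character(region_names)
  if (length(region_names) != ncol(signal)) {
    stop("'region_names' must have one label per region")
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("'tr_seconds' must be a single positive number")
  }
  colnames(signal) <- region_names
  structure(
    list(signal = signal, rms = rms, tr_seconds = tr_seconds,
         region_names = region_names),
    class = "parcellated_run"
  )
}

#' @export
print.parcellated_run <- function(x, ...) {
  cat("parcellated_run:", nrow(x$signal), "timepoints x",
      ncol(x$signal), "regions, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

#' Concatenated within-session timeseries
#'
#' @param signal Numeric matrix of stacked (already demeaned) run signals.
#' @param flagged_fraction_per_run Numeric vector, the fraction of frames
#'   removed by motion scrubbing in each contributing run.
#' @param region_names Region labels.
#'
#' @return An object of class `session_timeseries` with elements `signal`,
#'   `kept_frame_count`, `flagged_fraction_per_run`, `region_names`.
#' @export
session_timeseries <- function(signal, flagged_fraction_per_run,
                               region_names = colnames(signal)) {
  signal <- as.matrix(signal)
  structure(
    list(signal = signal,
         kept_frame_count = nrow(signal),
         flagged_fraction_per_run = as.numeric(flagged_fraction_per_run),
         region_names = as.character(region_names)),
    class = "session_timeseries"
  )
}

#' Canonical upper-triangle edge index
#'
#' Enumerates the unordered region pairs (i, j), i < j, of an R-region
#' connectome in row-major upper-triangle order: (1,2), (1,3), ..., (1,R),
#' (2,3), .... All edge vectors and edge panels in this package follow this
#' ordering.
#'
#' @param n_regions Number of regions R (>= 2), or a character vector of
#'   region names.
#' @return A data.frame with integer columns `i`, `j`, a character column
#'   `edge_id` ("i_j", using region names when supplied), and attribute
#'   `n_regions`.
#' @export
edge_index <- function(n_regions) {
  names <- NULL
  if (is.character(n_regions)) {
    names <- n_regions
    n_regions <- length(names)
  }
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 2L) {
    stop("'n_regions' must be an integer >= 2")
  }
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- sequence((n_regions - 1L):1L) + i
  id <- if (is.null(names)) paste0(i, "_", j) else paste0(names[i], "_", names[j])
  out <- data.frame(i = i, j = j, edge_id = id, stringsAsFactors = FALSE)
  attr(out, "n_regions") <- n_regions
  out
}

#' Subjects-by-edges panel for one session
#'
#' @param values Numeric matrix, subjects x edges, columns in canonical
#'   row-major upper-triangle order (see [edge_index()]).
#' @param edge_index Edge index data.frame from [edge_index()].
#' @param subject_ids Character vector of subject identifiers.
#' @param session_id Session label (1 or 2).
#'
#' @return An object of class `edge_panel`.
#' @export
edge_panel <- function(values, edge_index, subject_ids = rownames(values),
                       session_id = NA_integer_) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(edge_index)) {
    stop("panel has ", ncol(values), " columns but edge_index lists ",
         nrow(edge_index), " edges")
  }
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(nrow(values)))
  rownames(values) <- subject_ids
  colnames(values) <- edge_index$edge_id
  structure(
    list(values = values, edge_index = edge_index,
         subject_ids = as.character(subject_ids), session_id = session_id),
    class = "edge_panel"
  )
}

#' @export
print.edge_panel <- function(x, ...) {
  cat("edge_panel:", nrow(x$values), "subjects x", ncol(x$values),
      "edges (session ", x$session_id, ")\n", sep = "")
  invisible(x)
}

# Internal: check that two panels cover the same subjects and edges in the
# same order; the edge-wise ICC machinery relies on positional alignment.
check_panel_alignment <- function(panel_s1, panel_s2) {
  stopifnot(inherits(panel_s1, "edge_panel"), inherits(panel_s2, "edge_panel"))
  if (!identical(dim(panel_s1$values), dim(panel_s2$values))) {
    stop("session panels have different dimensions")
  }
  if (!identical(panel_s1$subject_ids, panel_s2$subject_ids)) {
    stop("session panels list different subjects (or a different order)")
  }
  if (!identical(panel_s1$edge_index$edge_id, panel_s2$edge_index$edge_id)) {
    stop("session panels list different edges (or a different order)")
  }
  invisible(TRUE)
}
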