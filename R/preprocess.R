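#' Global signal regression
#'
#' Removes the cross-region mean timeseries (the "global signal") from every
#' region by ordinary least squares. Each region's series is replaced by the
#' residuals of its regression on an intercept plus the global mean series,
#' so every output column is orthogonal to the global signal. The regressor
#' is computed from the run as given, i.e. before any temporal filtering.
#'
#' @param run A [parcellated_run()].
#' @return A `parcellated_run` with residualized signal (same dimensions,
#'   same motion trace).
#' @export
regress_global_signal <- function(run) {
  stopifnot(inherits(run, "parcellated_run"))
  x <- run$signal
  if (nrow(x) < 2L) stop("global signal regression needs >= 2 timepoints")
  g <- rowMeans(x)
  gc <- g - mean(g)
  denom <- sum(gc^2)
  if (denom <= .Machine$double.eps * nrow(x)) {
    warning("global mean series has zero variance; removing column means only")
    res <- sweep(x, 2L, colMeans(x))
  } else {
    # residuals of each column on {1, g}: demean, then project out centered g
    xc <- sweep(x, 2L, colMeans(x))
    beta <- crossprod(gc, xc) / denom   # 1 x regions
    res <- xc - tcrossprod(gc, as.numeric(beta))
  }
  out <- run
  out$signal <- res
  out
}

#' Zero-phase high-pass filter
#'
#' Applies a 4th-order Butterworth high-pass filter forward and backward
#' (zero phase) to every region's timeseries. The default 0.008 Hz cut-off
#' removes slow scanner drift while retaining almost all of the resting-state
#' band.
#'
#' @param run A [parcellated_run()].
#' @param cutoff_hz High-pass cut-off frequency in Hz; must be below the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @param order Filter order (default 4).
#' @return A filtered `parcellated_run`.
#' @export
highpass_filter <- function(run, cutoff_hz = 0.008, order = 4L) {
  stopifnot(inherits(run, "parcellated_run"))
  nyquist <- 1 / (2 * run$tr_seconds)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop("'cutoff_hz' must lie in (0, Nyquist = ", signif(nyquist, 4), ") Hz")
  }
  w <- cutoff_hz / nyquist
  bf <- signal::butter(order, W = w, type = "high")
  min_len <- 3L * (2L * order + 1L)
  if (nrow(run$signal) <= min_len) {
    stop("run too short for zero-phase filtering (needs > ", min_len,
         " timepoints)")
  }
  out <- run
  out$signal <- apply(run$signal, 2L, function(col)
    filtfilt_padded(bf, col, w))
  dimnames(out$signal) <- dimnames(run$signal)
  out
}

# Zero-phase filtering with odd-extension padding: the series is demeaned and
# reflected around both endpoints before the forward-backward pass so that
# startup transients decay inside the padding, not inside the data.
filtfilt_padded <- function(bf, x, w) {
  n <- length(x)
  xc <- x - mean(x)
  pad <- min(n - 1L, as.integer(ceiling(3 / w)))
  left <- 2 * xc[1L] - xc[seq(pad + 1L, 2L)]
  right <- 2 * xc[n] - xc[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, xc, right))
  y[seq(pad + 1L, pad + n)]
}

#' Motion scrubbing
#'
#' Deletes frames whose relative RMS displacement strictly exceeds the
#' threshold; surviving frames keep their original order. Frames exactly at
#' the threshold are kept.
#'
#' @param run A [parcellated_run()].
#' @param rms_threshold Displacement threshold in mm (default 0.30).
#' @return A list with elements `run` (the scrubbed `parcellated_run`) and
#'   `flagged_fraction` (flagged frames / total frames).
#' @export
scrub <- function(run, rms_threshold = 0.30) {
  stopifnot(inherits(run, "parcellated_run"))
  flagged <- run$rms > rms_threshold
  frac <- mean(flagged)
  if (all(flagged)) {
    stop("all ", length(flagged), " frames exceed RMS ", rms_threshold,
         "; nothing left to analyze")
  }
  out <- run
  out$signal <- run$signal[!flagged, , drop = FALSE]
  out$rms <- run$rms[!flagged]
  list(run = out, flagged_fraction = frac)
}

#' Subject-level motion exclusion rule
#'
#' A subject is kept only if no run has more than `max_fraction` of its
#' frames flagged for motion (strict inequality: exactly 15% passes).
#'
#' @param flagged_fractions Numeric vector, one flagged fraction per run.
#' @param max_fraction Exclusion threshold (default 0.15).
#' @return `TRUE` if the subject passes, `FALSE` otherwise.
#' @export
subject_passes_motion <- function(flagged_fractions, max_fraction = 0.15) {
  flagged_fractions <- as.numeric(flagged_fractions)
  if (length(flagged_fractions) == 0L) stop("no runs supplied")
  if (any(!is.finite(flagged_fractions))) stop("non-finite flagged fraction")
  !any(flagged_fractions > max_fraction)
}

#' Concatenate the runs of one session
#'
#' Each run's columns are demeaned before stacking so that baseline offsets
#' between runs do not masquerade as shared signal in the pooled correlation.
#'
#' @param run_a,run_b [parcellated_run()] objects with identical region order.
#' @param flagged_fractions Optional per-run flagged fractions to record.
#' @return A [session_timeseries()].
#' @export
concatenate_session <- function(run_a, run_b, flagged_fractions = c(NA, NA)) {
  stopifnot(inherits(run_a, "parcellated_run"),
            inherits(run_b, "parcellated_run"))
  if (!identical(run_a$region_names, run_b$region_names)) {
    stop("runs have different region sets or ordering; refusing to reconcile")
  }
  concatenate_runs(list(run_a, run_b), flagged_fractions)
}

# Demean each run's columns and stack any number of runs (first run first).
concatenate_runs <- function(runs, flagged_fractions = rep(NA_real_, length(runs))) {
  stopifnot(length(runs) >= 1L)
  region_names <- runs[[1L]]$region_names
  for (r in runs) {
    if (!identical(r$region_names, region_names)) {
      stop("runs have different region sets or ordering; refusing to reconcile")
    }
  }
  demeaned <- lapply(runs, function(r) sweep(r$signal, 2L, colMeans(r$signal)))
  session_timeseries(do.call(rbind, demeaned), flagged_fractions, region_names)
}

#' Preprocess one run
#'
#' Applies the conditioning chain in fixed order: global signal regression
#' (optional), high-pass filtering, then motion scrubbing. The order is not
#' configurable; the GSR regressor is always the raw (unfiltered) global
#' mean.
#'
#' @param run A [parcellated_run()].
#' @param gsr Logical, run global signal regression first?
#' @param hp_cutoff_hz High-pass cut-off in Hz; `NA` skips filtering.
#' @param rms_threshold Scrubbing threshold in mm.
#' @return A list with `run` (conditioned `parcellated_run`) and
#'   `flagged_fraction`.
#' @export
preprocess_run <- function(run, gsr = FALSE, hp_cutoff_hz = 0.008,
                           rms_threshold = 0.30) {
  if (gsr) run <- regress_global_signal(run)
  if (!is.na(hp_cutoff_hz)) run <- highpass_filter(run, hp_cutoff_hz)
  scrub(run, rms_threshold)
}
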