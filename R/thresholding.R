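#' Absolute threshold of a connectivity matrix
#'
#' Sets every off-diagonal entry strictly below `t` to zero. The comparison
#' is on signed values, so all negative correlations are removed at any
#' positive threshold. The diagonal is untouched.
#'
#' @param matrix A `connectivity_matrix` or plain symmetric matrix.
#' @param t Threshold in r units, in (0, 1].
#' @return Same type as the input, thresholded.
#' @export
threshold_absolute <- function(matrix, t) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 1) {
    stop("'t' must be a single value in (0, 1]")
  }
  m <- as_conn_values(matrix)
  d <- diag(m)
  m[m < t] <- 0
  diag(m) <- d
  replace_conn_values(matrix, m)
}

#' Relative (proportional) threshold of a connectivity matrix
#'
#' Retains the `ceiling(p * E)` strongest of the E unique edges (ranked by
#' signed value, largest first) and zeroes the rest. Ties at the cut are
#' broken by canonical edge order (lower (i, j) first). The diagonal is
#' untouched and the output stays symmetric.
#'
#' @param matrix A `connectivity_matrix` or plain symmetric matrix.
#' @param p Proportion of edges to retain, in (0, 1].
#' @return Same type as the input, thresholded.
#' @export
threshold_relative <- function(matrix, p) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1) {
    stop("'p' must be a single proportion in (0, 1]")
  }
  m <- as_conn_values(matrix)
  edges <- t(m)[lower.tri(m)]
  keep <- relative_keep_mask(edges, p)
  keepm <- matrix(TRUE, nrow(m), ncol(m))
  keepm[lower.tri(keepm)] <- keep      # canonical order lands on the upper
  keepm <- t(keepm)                    # triangle after transposition
  keepm[lower.tri(keepm)] <- t(keepm)[lower.tri(keepm)]
  diag(keepm) <- TRUE
  out <- m
  out[!keepm] <- 0
  replace_conn_values(matrix, out)
}

# Logical mask over a canonical edge vector: TRUE for the ceiling(p * E)
# largest signed values, ties broken toward earlier canonical order. p = 0
# retains nothing (used by the sweep's most stringent relative endpoint).
relative_keep_mask <- function(edges, p) {
  e <- length(edges)
  m <- min(max(as.integer(ceiling(p * e)), 0L), e)
  keep <- logical(e)
  if (m > 0L) {
    ord <- order(edges, seq_along(edges) * -1, decreasing = TRUE)
    keep[ord[seq_len(m)]] <- TRUE
  }
  keep
}

replace_conn_values <- function(original, values) {
  if (inherits(original, "connectivity_matrix")) {
    original$values <- values
    original
  } else {
    values
  }
}

#' Per-subject, per-session retention masks under a threshold
#'
#' Applies one threshold independently to every subject's session edge
#' vectors, as done before computing the consistency ratio.
#'
#' @param panel An [edge_panel()] (subjects x edges).
#' @param t Threshold value: r units for `mode = "absolute"`, proportion for
#'   `mode = "relative"`.
#' @param mode `"absolute"` or `"relative"`.
#' @return Logical subjects x edges matrix: `TRUE` where the edge is retained.
#' @export
retention_mask <- function(panel, t, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  v <- panel$values
  if (mode == "absolute") {
    v >= t
  } else {
    t(apply(v, 1L, relative_keep_mask, p = t))
  }
}

#' Ratio of consistently retained edges
#'
#' For each edge, the number of subjects in which the edge survives
#' thresholding in both sessions divided by the number in which it survives
#' in at least one. Edges retained by no subject in either session are
#' excluded (ratio undefined).
#'
#' @param retained_s1,retained_s2 Aligned logical subjects x edges masks.
#' @return Numeric vector of per-edge ratios in \[0, 1\] (`NA` where the
#'   denominator is zero).
#' @export
consistency_ratio <- function(retained_s1, retained_s2) {
  if (!identical(dim(retained_s1), dim(retained_s2))) {
    stop("retention masks are misaligned")
  }
  num <- colSums(retained_s1 & retained_s2)
  den <- colSums(retained_s1 | retained_s2)
  ifelse(den > 0L, num / den, NA_real_)
}

#' Edge-wise ICC restricted to consistently retained subjects
#'
#' For each edge, recomputes ICC(3,1) using only the subjects in which the
#' edge was retained in both sessions, so the estimate is not biased by
#' values zeroed in one session only. Edges with fewer than `min_subjects`
#' such subjects are reported missing.
#'
#' @param panel_s1,panel_s2 Aligned session [edge_panel()]s (raw FC values).
#' @param retained_s1,retained_s2 Aligned logical retention masks.
#' @param min_subjects Minimum both-session subject count per edge (default
#'   10).
#' @param alpha Confidence parameter.
#' @return A data.frame with one row per edge: `edge_id`, `icc`, `n_used`.
#' @export
thresholded_icc <- function(panel_s1, panel_s2, retained_s1, retained_s2,
                            min_subjects = 10L, alpha = 0.05) {
  check_panel_alignment(panel_s1, panel_s2)
  if (!identical(dim(retained_s1), dim(panel_s1$values)) ||
      !identical(dim(retained_s2), dim(panel_s2$values))) {
    stop("retention masks are misaligned with the panels")
  }
  both <- retained_s1 & retained_s2
  e <- ncol(both)
  icc <- rep(NA_real_, e)
  n_used <- colSums(both)
  for (j in which(n_used >= max(min_subjects, 3L))) {
    rows <- both[, j]
    x <- cbind(panel_s1$values[rows, j], panel_s2$values[rows, j])
    ms <- icc_mean_squares(x)
    icc[j] <- icc_from_mean_squares(ms$bms, ms$ems, n = nrow(x), k = 2L,
                                    alpha = alpha)$icc
  }
  data.frame(edge_id = panel_s1$edge_index$edge_id, icc = icc,
             n_used = as.integer(n_used), stringsAsFactors = FALSE)
}

#' Default 20-point threshold grid
#'
#' Twenty evenly spaced values from 0.05 to 1.00.
#' @return Numeric vector of length 20.
#' @export
threshold_grid <- function() {
  seq(0.05, 1, by = 0.05)
}

#' Threshold sweep over a grid
#'
#' For each threshold: thresholds every subject's two session connectomes
#' independently, computes the per-edge consistency ratio, and recomputes
#' edge ICC on the subjects retaining each edge in both sessions. Summaries
#' use the same bin cutoffs as ICC for convenience. Finally, the median
#' consistency ratio and the median thresholded ICC are each rank-correlated
#' (Spearman) against the threshold value.
#'
#' In both modes a larger threshold value is more stringent. Absolute mode
#' zeroes edges below the r-value `t`. Relative mode removes the weakest
#' proportion `t` of each connectome's edges, i.e. retains the strongest
#' `1 - t` (the `t = 1` endpoint is clamped to retain a single strongest
#' edge so the whole grid stays evaluable).
#'
#' @param panel_s1,panel_s2 Aligned session [edge_panel()]s.
#' @param mode `"absolute"` or `"relative"`.
#' @param thresholds Threshold grid (default [threshold_grid()]).
#' @param min_subjects Floor for the per-edge thresholded ICC.
#' @param alpha Confidence parameter.
#' @return An object of class `threshold_sweep_report`: list with `mode`,
#'   `thresholds`, `summary` (data.frame, one row per threshold: median /
#'   min / max consistency ratio, ratio bin proportions, median thresholded
#'   ICC, number of evaluable edges), `ratio` and `icc` matrices (thresholds
#'   x edges), and `trend` (Spearman rho and p of each median against the
#'   threshold).
#' @export
threshold_sweep <- function(panel_s1, panel_s2,
                            mode = c("absolute", "relative"),
                            thresholds = threshold_grid(),
                            min_subjects = 10L, alpha = 0.05) {
  mode <- match.arg(mode)
  check_panel_alignment(panel_s1, panel_s2)
  if (nrow(panel_s1$values) == 0L) stop("empty cohort")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("'thresholds' must be strictly increasing")
  }
  nt <- length(thresholds)
  e <- ncol(panel_s1$values)
  ratio_mat <- matrix(NA_real_, nt, e)
  icc_mat <- matrix(NA_real_, nt, e)
  labels4 <- bin_scheme("cicchetti4")$labels
  summary <- data.frame(threshold = thresholds,
                        median_ratio = NA_real_, min_ratio = NA_real_,
                        max_ratio = NA_real_,
                        median_icc = NA_real_, n_edges_ratio = NA_integer_,
                        n_edges_icc = NA_integer_)
  for (lbl in labels4) summary[[paste0("ratio_", lbl)]] <- NA_real_
  for (lbl in labels4) summary[[paste0("icc_", lbl)]] <- NA_real_
  for (ti in seq_len(nt)) {
    t <- thresholds[ti]
    # relative stringency t removes the weakest proportion t of edges
    tt <- if (mode == "relative") 1 - t else t
    m1 <- retention_mask(panel_s1, tt, mode)
    m2 <- retention_mask(panel_s2, tt, mode)
    ratio <- consistency_ratio(m1, m2)
    ratio_mat[ti, ] <- ratio
    th_icc <- thresholded_icc(panel_s1, panel_s2, m1, m2,
                              min_subjects = min_subjects, alpha = alpha)$icc
    icc_mat[ti, ] <- th_icc
    ok_r <- is.finite(ratio)
    ok_i <- is.finite(th_icc)
    summary$median_ratio[ti] <- if (any(ok_r)) stats::median(ratio[ok_r]) else NA_real_
    summary$min_ratio[ti] <- if (any(ok_r)) min(ratio[ok_r]) else NA_real_
    summary$max_ratio[ti] <- if (any(ok_r)) max(ratio[ok_r]) else NA_real_
    summary$median_icc[ti] <- if (any(ok_i)) stats::median(th_icc[ok_i]) else NA_real_
    summary$n_edges_ratio[ti] <- sum(ok_r)
    summary$n_edges_icc[ti] <- sum(ok_i)
    if (any(ok_r)) {
      pr <- bin_proportions(ratio[ok_r], "cicchetti4")
      for (lbl in labels4) summary[[paste0("ratio_", lbl)]][ti] <- pr[[lbl]]
    }
    if (any(ok_i)) {
      pi_ <- bin_proportions(th_icc[ok_i], "cicchetti4")
      for (lbl in labels4) summary[[paste0("icc_", lbl)]][ti] <- pi_[[lbl]]
    }
  }
  trend <- list(
    ratio = sweep_trend(thresholds, summary$median_ratio),
    icc = sweep_trend(thresholds, summary$median_icc)
  )
  structure(
    list(mode = mode, thresholds = thresholds, summary = summary,
         ratio = ratio_mat, icc = icc_mat, trend = trend,
         min_subjects = min_subjects),
    class = "threshold_sweep_report"
  )
}

# Spearman trend of a per-threshold median against the grid; constant or
# all-missing medians yield rho = NA rather than an error.
sweep_trend <- function(thresholds, medians) {
  ok <- is.finite(medians)
  if (sum(ok) < 3L || length(unique(medians[ok])) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
  }
  out <- spearman(thresholds[ok], medians[ok])
  list(rho = out$statistic, p_value = out$p_value, n = out$n)
}

#' @export
print.threshold_sweep_report <- function(x, ...) {
  cat("threshold_sweep_report (", x$mode, " mode, ",
      length(x$thresholds), " thresholds)\n", sep = "")
  cat("  trend of median consistency ratio: rho =",
      signif(x$trend$ratio$rho, 4), "\n")
  cat("  trend of median retained-edge ICC: rho =",
      signif(x$trend$icc$rho, 4), "\n")
  invisible(x)
}
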