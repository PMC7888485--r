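#' Consistency intraclass correlation ICC(3,1)
#'
#' Single-measure consistency ICC from a two-way mixed model with subjects as
#' random rows and sessions as fixed columns (McGraw & Wong's "C-1", Shrout &
#' Fleiss's ICC(3,1)). With BMS the between-subject mean square and EMS the
#' residual mean square after removing subject and session effects,
#'
#'   ICC = (BMS - EMS) / (BMS + (k - 1) EMS)
#'
#' Confidence bounds use the F distribution: with F = BMS/EMS,
#' FL = F / qf(1 - alpha/2; n-1, (n-1)(k-1)) and
#' FU = F * qf(1 - alpha/2; (n-1)(k-1), n-1), the interval is
#' ((FL - 1)/(FL + k - 1), (FU - 1)/(FU + k - 1)). Negative estimates are
#' reported as-is, never clamped to zero.
#'
#' @param x Numeric matrix, subjects x measurements (k >= 2 columns, no
#'   missing cells, n >= 3 rows).
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @return A one-row data.frame: `icc`, `f_stat`, `ci_lower`, `ci_upper`,
#'   `n`, `k`, `bin4`, `bin5`.
#' @export
icc_c1 <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L) stop("ICC(3,1) needs at least 3 subjects, got ", n)
  if (k < 2L) stop("ICC(3,1) needs at least 2 measurements per subject")
  if (anyNA(x)) stop("missing cells; subset complete rows before calling")
  ms <- icc_mean_squares(x)
  res <- icc_from_mean_squares(ms$bms, ms$ems, n = n, k = k, alpha = alpha)
  data.frame(icc = res$icc, f_stat = res$f_stat,
             ci_lower = res$ci_lower, ci_upper = res$ci_upper,
             n = n, k = k,
             bin4 = bin_icc(res$icc, "cicchetti4"),
             bin5 = bin_icc(res$icc, "xingzuo5"),
             stringsAsFactors = FALSE)
}

# Two-way ANOVA (subjects x sessions, no interaction) mean squares.
icc_mean_squares <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(bms = ss_rows / (n - 1L),
       jms = ss_cols / (k - 1L),
       ems = ss_err / ((n - 1L) * (k - 1L)))
}

# Shared ICC + CI arithmetic, vectorized over bms/ems.
icc_from_mean_squares <- function(bms, ems, n, k, alpha = 0.05) {
  icc <- (bms - ems) / (bms + (k - 1) * ems)
  f <- bms / ems
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  lo <- (fl - 1) / (fl + k - 1)
  hi <- (fu - 1) / (fu + k - 1)
  # Degenerate cases: no residual variance at all.
  perfect <- ems <= 0 & bms > 0
  icc[perfect] <- 1
  f[perfect] <- Inf
  lo[perfect] <- 1
  hi[perfect] <- 1
  undefined <- ems <= 0 & bms <= 0
  icc[undefined] <- NA_real_
  f[undefined] <- NA_real_
  lo[undefined] <- NA_real_
  hi[undefined] <- NA_real_
  list(icc = icc, f_stat = f, ci_lower = lo, ci_upper = hi)
}

#' Edge-wise ICC(3,1) over two session panels
#'
#' Vectorized application of [icc_c1()] to every edge column of two aligned
#' subjects x edges panels (k = 2 sessions). Agrees with the scalar
#' computation edge by edge to numerical precision.
#'
#' @param panel_s1,panel_s2 Aligned session [edge_panel()]s (same subjects,
#'   same edges, same order).
#' @param alpha Confidence parameter, interval level `1 - alpha`.
#' @return A data.frame with one row per edge: `edge_id`, `icc`, `f_stat`,
#'   `ci_lower`, `ci_upper`, `n`, `k`, `bin4`, `bin5`.
#' @export
edgewise_icc <- function(panel_s1, panel_s2, alpha = 0.05) {
  check_panel_alignment(panel_s1, panel_s2)
  s1 <- panel_s1$values
  s2 <- panel_s2$values
  n <- nrow(s1)
  if (n < 3L) stop("ICC needs at least 3 subjects, got ", n)
  res <- icc_two_sessions(s1, s2, alpha = alpha)
  data.frame(edge_id = panel_s1$edge_index$edge_id,
             icc = res$icc, f_stat = res$f_stat,
             ci_lower = res$ci_lower, ci_upper = res$ci_upper,
             n = n, k = 2L,
             bin4 = bin_icc(res$icc, "cicchetti4"),
             bin5 = bin_icc(res$icc, "xingzuo5"),
             stringsAsFactors = FALSE)
}

# Column-wise ICC(3,1) for the k = 2 case, fully vectorized over columns.
icc_two_sessions <- function(s1, s2, alpha = 0.05) {
  n <- nrow(s1)
  grand <- (colMeans(s1) + colMeans(s2)) / 2
  subj_m <- (s1 + s2) / 2
  ss_rows <- 2 * colSums((subj_m - rep(grand, each = n))^2)
  m1 <- colMeans(s1)
  m2 <- colMeans(s2)
  ss_cols <- n * ((m1 - grand)^2 + (m2 - grand)^2)
  ss_tot <- colSums((s1 - rep(grand, each = n))^2) +
    colSums((s2 - rep(grand, each = n))^2)
  ss_err <- pmax(ss_tot - ss_rows - ss_cols, 0)
  bms <- ss_rows / (n - 1L)
  ems <- ss_err / (n - 1L)
  icc_from_mean_squares(bms, ems, n = n, k = 2L, alpha = alpha)
}

#' Reliability bin of an ICC value
#'
#' Two conventional binnings of reliability coefficients. `cicchetti4`:
#' poor (< 0.40), fair (0.40-0.60), good (0.60-0.75), excellent (> 0.75).
#' `xingzuo5`: slight (< 0.20), fair (0.20-0.40), moderate (0.40-0.60),
#' substantial (0.60-0.80), perfect (> 0.80). Intervals are closed on the
#' left: a value exactly at a lower cutoff takes the higher bin (0.40 is
#' "fair" under `cicchetti4`, 0.80 is "perfect" under `xingzuo5`).
#'
#' @param value Numeric vector of ICC (or other ratio) values.
#' @param scheme `"cicchetti4"` or `"xingzuo5"`.
#' @return Character vector of bin labels; `NA` for non-finite input.
#' @export
bin_icc <- function(value, scheme = c("cicchetti4", "xingzuo5")) {
  scheme <- match.arg(scheme)
  cfg <- bin_scheme(scheme)
  out <- as.character(cut(value, breaks = cfg$breaks, labels = cfg$labels,
                          right = FALSE))
  out[!is.finite(value)] <- NA_character_
  out
}

bin_scheme <- function(scheme) {
  switch(scheme,
    cicchetti4 = list(breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
                      labels = c("poor", "fair", "good", "excellent")),
    xingzuo5   = list(breaks = c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
                      labels = c("slight", "fair", "moderate",
                                 "substantial", "perfect")))
}

#' Summarize a collection of ICC results
#'
#' @param results A data.frame from [edgewise_icc()] (or any frame with
#'   columns `icc`, `ci_lower`, `ci_upper`), or a bare numeric vector of ICC
#'   values.
#' @return A list with `n_features`, `n_missing`, `median`, `min`, `max`,
#'   `median_ci_width`, and bin proportion tables `prop_bin4`, `prop_bin5`.
#' @export
summarize_icc <- function(results) {
  if (is.numeric(results)) {
    results <- data.frame(icc = results, ci_lower = NA_real_,
                          ci_upper = NA_real_)
  }
  icc <- results$icc
  ok <- is.finite(icc)
  if (!any(ok)) stop("no non-missing ICC values to summarize")
  width <- results$ci_upper - results$ci_lower
  prop4 <- bin_proportions(icc[ok], "cicchetti4")
  prop5 <- bin_proportions(icc[ok], "xingzuo5")
  list(n_features = length(icc),
       n_missing = sum(!ok),
       median = stats::median(icc[ok]),
       min = min(icc[ok]),
       max = max(icc[ok]),
       median_ci_width = stats::median(width[ok], na.rm = TRUE),
       prop_bin4 = prop4,
       prop_bin5 = prop5)
}

bin_proportions <- function(values, scheme) {
  labels <- bin_scheme(scheme)$labels
  bins <- factor(bin_icc(values, scheme), levels = labels)
  p <- as.numeric(table(bins)) / length(values)
  stats::setNames(p, labels)
}

#' Network-wise ICC(3,1)
#'
#' Computes within-network mean FC per subject and session, then the
#' consistency ICC of each network's aggregate across sessions.
#'
#' @param matrices_s1,matrices_s2 Lists of per-subject `connectivity_matrix`
#'   objects for sessions 1 and 2 (same subject order).
#' @param labels Region/network label table (see [network_average_fc()]).
#' @param alpha Confidence parameter.
#' @return A data.frame with one row per network: `network`, `icc`, `f_stat`,
#'   `ci_lower`, `ci_upper`, `n`, `k`, `bin4`, `bin5`, `mean_fc`.
#' @export
networkwise_icc <- function(matrices_s1, matrices_s2, labels, alpha = 0.05) {
  if (length(matrices_s1) != length(matrices_s2)) {
    stop("sessions cover different numbers of subjects")
  }
  a1 <- t(vapply(matrices_s1, network_average_fc, labels = labels,
                 FUN.VALUE = network_average_fc(matrices_s1[[1L]], labels)))
  a2 <- t(vapply(matrices_s2, network_average_fc, labels = labels,
                 FUN.VALUE = network_average_fc(matrices_s2[[1L]], labels)))
  res <- icc_two_sessions(a1, a2, alpha = alpha)
  data.frame(network = colnames(a1),
             icc = res$icc, f_stat = res$f_stat,
             ci_lower = res$ci_lower, ci_upper = res$ci_upper,
             n = nrow(a1), k = 2L,
             bin4 = bin_icc(res$icc, "cicchetti4"),
             bin5 = bin_icc(res$icc, "xingzuo5"),
             mean_fc = (colMeans(a1) + colMeans(a2)) / 2,
             stringsAsFactors = FALSE, row.names = NULL)
}
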