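#' Kruskal-Wallis rank-sum test
#'
#' Rank-based comparison of two or more groups of values (e.g. edge ICC
#' distributions from different atlases), with tie correction and the
#' chi-square approximation for the p-value. Thin wrapper around
#' [stats::kruskal.test()] returning the package's common test-outcome shape;
#' the degenerate all-identical case is reported as H = 0, p = 1.
#'
#' @param groups A list of two or more numeric vectors.
#' @return A list: `statistic` (H), `p_value`, `df`, `n` (per-group sizes).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of >= 2 value collections")
  }
  groups <- lapply(groups, function(g) as.numeric(g[is.finite(g)]))
  sizes <- lengths(groups)
  if (any(sizes < 1L) || sum(sizes) < 3L) {
    stop("each group needs >= 1 value and >= 3 in total")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L,
                n = sizes))
  }
  g <- factor(rep.int(seq_along(groups), sizes))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = sizes)
}

#' Wilcoxon signed-rank test (paired)
#'
#' Paired rank test (e.g. GSR+ vs GSR- edge ICCs across the same edges)
#' using the normal approximation with tie correction and a continuity
#' correction, reporting a signed Z statistic and its two-sided p-value.
#' Zero differences are dropped before ranking.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return A list: `statistic` (Z, positive when `y` tends to exceed `x`),
#'   `p_value` (two-sided), `w_plus` (rank sum of positive `y - x`
#'   differences), `n` (nonzero pairs), `median_difference` (median of
#'   `y - x` over all pairs).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must be paired (equal length)")
  d <- as.numeric(y) - as.numeric(x)
  ok <- is.finite(d)
  med_d <- stats::median(d[ok])
  d <- d[ok & d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero or missing")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie_counts <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_counts^3 - tie_counts) / 48
  z_num <- w_plus - mu
  correction <- sign(z_num) * 0.5
  z <- (z_num - correction) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(statistic = z, p_value = min(p, 1), w_plus = w_plus, n = n,
       median_difference = med_d)
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average-tie) ranks with the t-approximation
#' p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list: `statistic` (rho), `p_value` (two-sided), `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance in ranks; correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(statistic = rho, p_value = p, n = n)
}

#' Sample size for detecting an ICC
#'
#' Minimum number of subjects needed to reject `icc0` in favor of
#' `icc1 > icc0` with `k` measurements per subject, using the
#' Walter-Eliasziw-Donner approximation: with
#' `theta(rho) = (1 + (k-1) rho) / (1 - rho)` and
#' `C0 = theta(rho0) / theta(rho1)`,
#'
#'   n = 1 + 2 k (z_(1-alpha) + z_(1-beta))^2 / ((k - 1) (ln C0)^2)
#'
#' rounded up to the next integer. `alpha` is one-sided.
#'
#' @param icc1 Alternative-hypothesis ICC, in (`icc0`, 1).
#' @param icc0 Null-hypothesis ICC (default 0).
#' @param k Measurements per subject (default 2).
#' @param alpha One-sided type-I error rate (default 0.05).
#' @param power Target power (default 0.80).
#' @return Integer minimum number of subjects.
#' @export
icc_sample_size <- function(icc1, icc0 = 0, k = 2L, alpha = 0.05,
                            power = 0.80) {
  if (!is.numeric(icc1) || icc1 <= icc0 || icc1 >= 1 || icc0 < 0) {
    stop("need 0 <= icc0 < icc1 < 1")
  }
  if (k < 2L) stop("'k' must be >= 2")
  theta <- function(rho) (1 + (k - 1) * rho) / (1 - rho)
  c0 <- theta(icc0) / theta(icc1)
  za <- stats::qnorm(1 - alpha)
  zb <- stats::qnorm(power)
  n <- 1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)
  as.integer(ceiling(n))
}
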