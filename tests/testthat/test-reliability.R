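test_that("consistency ICC ignores a constant session offset", {
  s1 <- c(1, 2, 3, 4)
  res <- icc_c1(cbind(s1, s1 + 0.5))
  expect_equal(res$icc, 1)
  expect_equal(res$ci_lower, 1)
  expect_equal(res$ci_upper, 1)
})

test_that("ICC matches the hand-computed two-way ANOVA example", {
  res <- icc_c1(cbind(c(1, 2, 3, 4), c(1.2, 1.9, 3.1, 4.0)))
  # BMS = 3.208333, EMS = 0.008333
  expect_equal(res$f_stat, 3.2083333333 / 0.0083333333, tolerance = 1e-6)
  expect_equal(res$icc, (3.2083333333 - 0.0083333333) /
                 (3.2083333333 + 0.0083333333), tolerance = 1e-8)
  expect_equal(res$icc, 0.9948, tolerance = 1e-4)
  expect_lte(res$ci_lower, res$icc)
  expect_gte(res$ci_upper, res$icc)
})

test_that("independent sessions give near-zero ICC at large n", {
  set.seed(1)
  res <- icc_c1(cbind(rnorm(1000), rnorm(1000)))
  expect_lt(abs(res$icc), 0.1)
})

test_that("degenerate tables are rejected or reported missing", {
  expect_error(icc_c1(cbind(1:2, 1:2)), "3 subjects")
  allsame <- icc_c1(matrix(5, 4, 2))
  expect_true(is.na(allsame$icc))
  expect_error(icc_c1(cbind(c(1, NA, 3), c(1, 2, 3))), "missing")
})

test_that("vectorized edge-wise ICC agrees with scalar and aov oracles", {
  set.seed(2)
  n_tables <- 100
  tables <- lapply(seq_len(n_tables), function(i) {
    n <- sample(3:10, 1)
    matrix(rnorm(2 * n), n, 2)
  })
  for (x in tables[1:20]) {
    expect_equal(icc_c1(x)$icc, icc_oracle_aov(x), tolerance = 1e-10)
  }
  # same subject count so the tables stack into one panel
  set.seed(3)
  n <- 8
  vals1 <- matrix(rnorm(n * n_tables), n, n_tables)
  vals2 <- matrix(rnorm(n * n_tables), n, n_tables)
  ei <- edge_index(16)[1:n_tables, ]
  attr(ei, "n_regions") <- 16L
  p1 <- edge_panel(vals1, ei)
  p2 <- edge_panel(vals2, ei)
  vec <- edgewise_icc(p1, p2)
  for (j in seq_len(n_tables)) {
    scalar <- icc_c1(cbind(vals1[, j], vals2[, j]))
    expect_equal(vec$icc[j], scalar$icc, tolerance = 1e-10)
    expect_equal(vec$ci_lower[j], scalar$ci_lower, tolerance = 1e-10)
    expect_equal(vec$ci_upper[j], scalar$ci_upper, tolerance = 1e-10)
  }
  # single-edge panel reduces to the scalar computation
  single <- edgewise_icc(edge_panel(vals1[, 1, drop = FALSE], edge_index(2)),
                         edge_panel(vals2[, 1, drop = FALSE], edge_index(2)))
  expect_equal(single$icc, icc_c1(cbind(vals1[, 1], vals2[, 1]))$icc)
})

test_that("identical panels give ICC 1 everywhere", {
  set.seed(4)
  ei <- edge_index(4)
  v <- matrix(rnorm(30), 5, 6)
  p <- edge_panel(v, ei)
  expect_equal(edgewise_icc(p, p)$icc, rep(1, 6))
})

test_that("ICC is invariant to session offsets and common rescaling", {
  set.seed(5)
  x <- cbind(rnorm(20, sd = 2), rnorm(20, sd = 2) + rnorm(20, sd = 0.5))
  base <- icc_c1(x)$icc
  shifted <- icc_c1(cbind(x[, 1] + 3, x[, 2] - 1))$icc
  scaled <- icc_c1(7 * x)$icc
  expect_equal(shifted, base, tolerance = 1e-10)
  expect_equal(scaled, base, tolerance = 1e-10)
})

test_that("95% intervals cover a true ICC of 0.5 at the nominal rate", {
  tr <- edge_truth_from_icc(50, 2000, icc = 0.5, seed = 6)
  p <- generate_edge_panel(tr)
  res <- edgewise_icc(p$session1, p$session2)
  coverage <- mean(res$ci_lower <= 0.5 & res$ci_upper >= 0.5)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("estimated ICC regresses on truth with slope near one", {
  set.seed(7)
  truths <- runif(1000, 0, 0.9)
  tr <- edge_truth_from_icc(200, 1000, icc = truths, seed = 7)
  p <- generate_edge_panel(tr)
  est <- edgewise_icc(p$session1, p$session2)$icc
  slope <- coef(lm(est ~ truths))[2]
  expect_gte(slope, 0.9)
  expect_lte(slope, 1.1)
  expect_lt(mean(abs(est - truths)), 0.06)
})

test_that("reliability bins use left-closed cutoffs in both schemes", {
  expect_equal(bin_icc(c(0.39, 0.40, 0.59, 0.60, 0.74, 0.75, -0.05)),
               c("poor", "fair", "fair", "good", "good", "excellent", "poor"))
  expect_equal(bin_icc(c(0.19, 0.20, 0.40, 0.60, 0.80, 0.95), "xingzuo5"),
               c("slight", "fair", "moderate", "substantial", "perfect",
                 "perfect"))
  expect_true(is.na(bin_icc(NA_real_)))
  expect_true(is.na(bin_icc(Inf)))
})

test_that("ICC summaries report median, extremes, and bin proportions", {
  s <- summarize_icc(c(0.1, 0.5, 0.9))
  expect_equal(s$median, 0.5)
  expect_equal(s$min, 0.1)
  expect_equal(s$max, 0.9)
  s2 <- summarize_icc(rep(0.65, 10))
  expect_equal(unname(s2$prop_bin4["good"]), 1)
  # a large null panel is almost entirely "poor"
  tr <- edge_panel_truth(50, 1000, sigma_b = 0, sigma_w = 1, seed = 8)
  p <- generate_edge_panel(tr)
  s3 <- summarize_icc(edgewise_icc(p$session1, p$session2))
  expect_gt(unname(s3$prop_bin4["poor"]), 0.95)
  expect_error(summarize_icc(NA_real_), "no non-missing")
})

test_that("network-wise ICC matches a manual per-network computation", {
  set.seed(9)
  labels <- data.frame(region = paste0("R", 1:6),
                       network = rep(c("A", "B"), each = 3))
  mats1 <- lapply(1:6, function(i)
    correlation_matrix(matrix(rnorm(240), 40, 6,
                              dimnames = list(NULL, paste0("R", 1:6))),
                       subject_id = i, session_id = 1))
  mats2 <- lapply(1:6, function(i)
    correlation_matrix(matrix(rnorm(240), 40, 6,
                              dimnames = list(NULL, paste0("R", 1:6))),
                       subject_id = i, session_id = 2))
  nw <- networkwise_icc(mats1, mats2, labels)
  a1 <- vapply(mats1, function(m) network_average_fc(m, labels)["A"],
               numeric(1))
  a2 <- vapply(mats2, function(m) network_average_fc(m, labels)["A"],
               numeric(1))
  expect_equal(nw$icc[nw$network == "A"], icc_c1(cbind(a1, a2))$icc,
               tolerance = 1e-10)
})
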