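test_that("edge panel truth enforces the variance decomposition", {
  tr <- edge_panel_truth(10, 5, sigma_b = 0.1, sigma_w = 0.2)
  expect_equal(tr$true_icc, rep(0.01 / 0.05, 5))
  expect_true(all(tr$true_icc >= 0 & tr$true_icc < 1))
  tr2 <- edge_truth_from_icc(10, 7, icc = seq(0.1, 0.7, 0.1))
  expect_equal(tr2$true_icc, seq(0.1, 0.7, 0.1))
  expect_equal(tr2$true_icc,
               tr2$sigma_b^2 / (tr2$sigma_b^2 + tr2$sigma_w^2))
  expect_error(edge_panel_truth(1, 5, sigma_b = 1, sigma_w = 1), "n_subjects")
  expect_error(edge_panel_truth(10, 5, sigma_b = -1, sigma_w = 1), ">= 0")
})

test_that("edge panel generation is seed-deterministic", {
  tr <- edge_truth_from_icc(20, 30, icc = 0.5, seed = 42)
  a <- generate_edge_panel(tr)
  b <- generate_edge_panel(tr)
  expect_identical(a$session1$values, b$session1$values)
  expect_identical(a$session2$values, b$session2$values)
  c <- generate_edge_panel(edge_truth_from_icc(20, 30, icc = 0.5, seed = 43))
  expect_false(identical(a$session1$values, c$session1$values))
})

test_that("no within-subject variance gives ICC of exactly 1", {
  tr <- edge_panel_truth(10, 8, sigma_b = 0.3, sigma_w = 0, seed = 3)
  p <- generate_edge_panel(tr)
  icc <- edgewise_icc(p$session1, p$session2)
  expect_equal(icc$icc, rep(1, 8))
})

test_that("no between-subject signal gives ICC scattered around zero", {
  tr <- edge_panel_truth(500, 200, sigma_b = 0, sigma_w = 0.2, seed = 4)
  p <- generate_edge_panel(tr)
  icc <- edgewise_icc(p$session1, p$session2)
  expect_lt(abs(median(icc$icc)), 0.1)
})

test_that("estimated ICC tracks true ICC across edges", {
  set.seed(7)
  truths <- runif(300, 0.1, 0.9)
  tr <- edge_truth_from_icc(200, 300, icc = truths, seed = 7)
  p <- generate_edge_panel(tr)
  icc <- edgewise_icc(p$session1, p$session2)
  expect_gt(cor(icc$icc, truths), 0.9)
})

test_that("ICC estimates are unbiased at true ICC 0.5", {
  tr <- edge_truth_from_icc(200, 1000, icc = 0.5, seed = 11)
  p <- generate_edge_panel(tr)
  icc <- edgewise_icc(p$session1, p$session2)
  expect_lt(abs(mean(icc$icc - 0.5)), 0.03)
})

test_that("nearest_valid_correlation projects and is idempotent", {
  expect_identical(nearest_valid_correlation(diag(4)), diag(4))
  set.seed(2)
  valid <- default_population_corr(10)
  attributes(valid)$network_labels <- NULL
  expect_equal(nearest_valid_correlation(valid), valid, tolerance = 1e-12)
  # 3x3 symmetric matrix with a negative eigenvalue
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(bad, symmetric = TRUE)$values), 0)
  fixed <- nearest_valid_correlation(bad)
  expect_equal(diag(fixed), rep(1, 3))
  expect_gte(min(eigen(fixed, symmetric = TRUE)$values), -1e-10)
  expect_equal(fixed, nearest_valid_correlation(fixed), tolerance = 1e-12)
  expect_error(nearest_valid_correlation(matrix(1, 2, 3)), "square")
  expect_error(nearest_valid_correlation(matrix(c(1, 2, 3, 4), 2, 2)),
               "symmetric")
})

test_that("timeseries cohorts are seed-deterministic with expected shape", {
  spec <- smoke_spec(n_subjects = 3, n_regions = 8, n_timepoints = 80)
  a <- generate_timeseries_cohort(spec)
  b <- generate_timeseries_cohort(spec)
  expect_identical(a$subjects[[2]]$sessions[[1]][[1]]$signal,
                   b$subjects[[2]]$sessions[[1]][[1]]$signal)
  expect_length(a$subjects, 3)
  expect_length(a$subjects[[1]]$sessions, 2)
  expect_length(a$subjects[[1]]$sessions[[1]], 2)
  run <- a$subjects[[1]]$sessions[[1]][[1]]
  expect_equal(dim(run$signal), c(80, 8))
  expect_equal(length(run$rms), 80)
  expect_equal(run$rms[1], 0)
})

test_that("motion spikes drive the RMS trace above threshold at the set rate", {
  spec <- cohort_spec(n_subjects = 4, n_regions = 6,
                      n_timepoints_per_run = 500, spike_rate = 0.2,
                      spike_rms = 0.5, seed = 9)
  coh <- generate_timeseries_cohort(spec)
  rms <- unlist(lapply(coh$subjects, function(s)
    lapply(s$sessions, function(sess) lapply(sess, `[[`, "rms"))))
  frac <- mean(rms > 0.30)
  n <- length(rms)
  expect_lt(abs(frac - 0.2), 4 * sqrt(0.2 * 0.8 / n))
  expect_true(all(rms[rms <= 0.30] < 0.30))
})

test_that("a degenerate cohort has no between-subject or session variance", {
  spec <- cohort_spec(n_subjects = 4, n_regions = 10,
                      n_timepoints_per_run = 600, n_runs_per_session = 1,
                      subject_dev_sd = 0, session_dev_sd = 0,
                      global_amp_sd = 0, global_amp_mean = 0,
                      spike_rate = 0, seed = 21)
  coh <- generate_timeseries_cohort(spec)
  expect_equal(coh$truth$latent[[1]], coh$truth$latent[[3]])
  # session FC matrices agree up to sampling error that shrinks with run length
  mean_gap <- function(nt) {
    sp <- cohort_spec(n_subjects = 4, n_regions = 10,
                      n_timepoints_per_run = nt, n_runs_per_session = 1,
                      subject_dev_sd = 0, session_dev_sd = 0,
                      global_amp_sd = 0, global_amp_mean = 0,
                      spike_rate = 0, seed = 21)
    coh <- generate_timeseries_cohort(sp)
    gaps <- vapply(coh$subjects, function(s) {
      f1 <- vectorize_upper(correlation_matrix(s$sessions[[1]][[1]]$signal))
      f2 <- vectorize_upper(correlation_matrix(s$sessions[[2]][[1]]$signal))
      mean(abs(f1 - f2))
    }, numeric(1))
    mean(gaps)
  }
  expect_lt(mean_gap(1600), mean_gap(100))
})

test_that("the shared global component inflates FC and GSR removes it", {
  spec <- cohort_spec(n_subjects = 6, n_regions = 12,
                      n_timepoints_per_run = 800, n_runs_per_session = 1,
                      global_amp_mean = 1, global_amp_sd = 0.4,
                      spike_rate = 0, seed = 13)
  coh <- generate_timeseries_cohort(spec)
  latent_mean <- mean(vapply(coh$truth$latent, function(l)
    mean(l[upper.tri(l)]), numeric(1)))
  fc_raw <- fc_gsr <- numeric(0)
  for (s in coh$subjects) {
    run <- s$sessions[[1]][[1]]
    fc_raw <- c(fc_raw, mean(vectorize_upper(correlation_matrix(run$signal))))
    res <- regress_global_signal(run)
    fc_gsr <- c(fc_gsr, mean(vectorize_upper(correlation_matrix(res$signal))))
  }
  expect_gt(mean(fc_raw), latent_mean)
  expect_lt(abs(mean(fc_gsr) - latent_mean), abs(mean(fc_raw) - latent_mean))
})

test_that("edges with larger between-subject dispersion get larger ICC", {
  spec <- cohort_spec(n_subjects = 100, n_regions = 16,
                      n_timepoints_per_run = 300, n_runs_per_session = 1,
                      spike_rate = 0, seed = 31)
  coh <- generate_timeseries_cohort(spec)
  conn <- cohort_connectomes(coh, gsr = TRUE, hp_cutoff_hz = NA)
  icc <- edgewise_icc(conn$panel_s1, conn$panel_s2)
  # per-edge between-subject dispersion of the generated latent values
  lat <- vapply(coh$truth$latent, function(l) t(l)[lower.tri(l)],
                numeric(16 * 15 / 2))
  disp <- apply(lat, 1L, sd)
  tst <- spearman(disp, icc$icc)
  expect_gt(tst$statistic, 0)
  expect_lt(tst$p_value, 0.01)
})

test_that("cohorts round-trip through the TSV/manifest layout", {
  spec <- smoke_spec(n_subjects = 2, n_regions = 6, n_timepoints = 50)
  coh <- generate_timeseries_cohort(spec)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(coh, dir)
  expect_true(file.exists(manifest))
  back <- read_cohort(manifest)
  expect_length(back$subjects, 2)
  orig <- coh$subjects[[1]]$sessions[[2]][[1]]
  got <- back$subjects[[1]]$sessions[[2]][[1]]
  expect_equal(got$signal, orig$signal, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(got$rms, orig$rms, tolerance = 1e-12)
  expect_equal(back$network_labels, coh$network_labels)
})
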