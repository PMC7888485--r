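test_that("GSR zeroes runs whose regions all carry the same series", {
  set.seed(1)
  g <- rnorm(60)
  run <- parcellated_run(cbind(g, g, g), rep(0, 60))
  res <- regress_global_signal(run)
  expect_lt(max(abs(res$signal)), 1e-12)
})

test_that("GSR recovers the component orthogonal to the global mean", {
  set.seed(2)
  nt <- 200
  g <- rnorm(nt)
  o <- rnorm(nt)
  o <- residuals(lm(o ~ g))          # orthogonal to {1, g}
  run <- parcellated_run(cbind(g + o, g - o), rep(0, nt))
  res <- regress_global_signal(run)  # mean series is exactly g
  expect_lt(max(abs(res$signal[, 1] - o)), 1e-10)
  expect_lt(max(abs(res$signal[, 2] + o)), 1e-10)
})

test_that("GSR residuals match an explicit least-squares solve", {
  set.seed(3)
  nt <- 150
  shared <- rnorm(nt)
  x <- cbind(2 + 1.5 * shared + rnorm(nt, sd = 0.3),
             -1 + 0.5 * shared + rnorm(nt, sd = 0.3),
             0.8 * shared + rnorm(nt, sd = 0.3))
  run <- parcellated_run(x, rep(0, nt))
  res <- regress_global_signal(run)
  g <- rowMeans(x)
  for (j in 1:3) {
    oracle <- residuals(lm(x[, j] ~ g))
    expect_lt(max(abs(res$signal[, j] - oracle)), 1e-10)
  }
  # orthogonality contract
  for (j in 1:3) {
    ip <- abs(sum(res$signal[, j] * (g - mean(g))))
    expect_lt(ip, 1e-8 * sqrt(sum(res$signal[, j]^2)) *
                sqrt(sum((g - mean(g))^2)))
  }
})

test_that("GSR on an all-constant run warns and demeans", {
  run <- parcellated_run(matrix(3, 50, 2), rep(0, 50))
  expect_warning(res <- regress_global_signal(run), "zero variance")
  expect_equal(res$signal, matrix(0, 50, 2), ignore_attr = TRUE)
})

test_that("high-pass filter removes DC and respects its frequency response", {
  nt <- 4096
  tr <- 0.72
  tt <- (seq_len(nt) - 1) * tr
  run <- parcellated_run(cbind(rep(5, nt),
                               sin(2 * pi * 0.05 * tt)),
                         rep(0, nt), tr_seconds = tr)
  out <- highpass_filter(run)
  expect_lt(max(abs(out$signal[, 1])), 1e-8)
  mid <- seq(nt %/% 4, 3 * nt %/% 4)
  amp_ratio <- sd(out$signal[mid, 2]) / sd(run$signal[mid, 2])
  expect_lt(abs(amp_ratio - 1), 0.02)

  nt2 <- 16384
  tt2 <- (seq_len(nt2) - 1) * tr
  slow <- parcellated_run(cbind(sin(2 * pi * 0.001 * tt2)), rep(0, nt2),
                          tr_seconds = tr)
  out2 <- highpass_filter(slow)
  mid2 <- seq(nt2 %/% 4, 3 * nt2 %/% 4)
  expect_lt(sd(out2$signal[mid2, 1]) / sd(slow$signal[mid2, 1]), 0.20)
})

test_that("high-pass filter validates its cutoff and run length", {
  run <- make_run(nt = 100, r = 2)
  expect_error(highpass_filter(run, cutoff_hz = 1), "Nyquist")
  expect_error(highpass_filter(make_run(nt = 20, r = 2)), "too short")
})

test_that("scrubbing removes frames strictly above threshold, keeping order", {
  run <- parcellated_run(matrix(seq_len(8), 4, 2), c(0, 0.1, 0.5, 0.2))
  out <- scrub(run)
  expect_equal(nrow(out$run$signal), 3)
  expect_equal(out$flagged_fraction, 0.25)
  expect_equal(out$run$signal[, 1], c(1, 2, 4))

  boundary <- parcellated_run(matrix(1:8, 4, 2), rep(0.30, 4))
  expect_equal(scrub(boundary)$flagged_fraction, 0)
  expect_equal(nrow(scrub(boundary)$run$signal), 4)

  set.seed(4)
  rms <- runif(200, 0, 0.6)
  k <- sum(rms > 0.30)
  rnd <- parcellated_run(matrix(rnorm(400), 200, 2), rms)
  expect_equal(nrow(scrub(rnd)$run$signal), 200 - k)

  allbad <- parcellated_run(matrix(1:4, 2, 2), c(0.9, 0.9))
  expect_error(scrub(allbad), "nothing left")
})

test_that("subject motion exclusion uses a strict 15% rule per run", {
  expect_false(subject_passes_motion(c(0.05, 0.10, 0.16, 0.02)))
  expect_true(subject_passes_motion(c(0.15, 0.15, 0.15, 0.15)))
  expect_true(subject_passes_motion(c(0, 0, 0, 0)))
  expect_error(subject_passes_motion(numeric(0)), "no runs")
})

test_that("session concatenation demeans runs and preserves correlations", {
  a <- make_run(nt = 100, r = 3, seed = 10)
  b <- make_run(nt = 90, r = 3, seed = 11)
  sess <- concatenate_session(a, b)
  expect_equal(nrow(sess$signal), 190)
  expect_equal(sess$kept_frame_count, 190)

  dup <- concatenate_session(a, a)
  expect_equal(cor(dup$signal), cor(a$signal), tolerance = 1e-12)

  # identical structure, different baselines: demeaning prevents offset
  # inflation relative to pooling the raw rows
  set.seed(12)
  base <- matrix(rnorm(200 * 3), 200, 3)
  r1 <- parcellated_run(base[1:100, ], rep(0, 100))
  r2 <- parcellated_run(base[101:200, ] + 50, rep(0, 100))
  pooled_raw <- cor(rbind(r1$signal, r2$signal))
  pooled_dm <- cor(concatenate_session(r1, r2)$signal)
  ref <- cor(base)
  expect_gt(mean(abs(pooled_raw - ref)), 10 * mean(abs(pooled_dm - ref)))
  expect_lt(max(abs(pooled_dm - ref)), 0.2)

  bad <- parcellated_run(matrix(rnorm(300), 100, 3), rep(0, 100),
                         region_names = c("X", "Y", "Z"))
  expect_error(concatenate_session(a, bad), "different region")
})

test_that("conditioning steps preserve region count and scrub commutes with
           column selection", {
  run <- make_run(nt = 120, r = 5, seed = 20,
                  rms = c(rep(0.05, 100), rep(0.6, 20)))
  expect_equal(ncol(regress_global_signal(run)$signal), 5)
  expect_equal(ncol(highpass_filter(run)$signal), 5)
  scr_then_sel <- scrub(run)$run$signal[, 2:3]
  sel_run <- parcellated_run(run$signal[, 2:3], run$rms)
  sel_then_scr <- scrub(sel_run)$run$signal
  expect_identical(scr_then_sel, sel_then_scr)
})
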