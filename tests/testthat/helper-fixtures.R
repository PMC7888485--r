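# Shared fixture builders; everything is generated in code at test time.

make_run <- function(nt = 100L, r = 4L, seed = 1L, tr = 0.72,
                     rms = rep(0.05, nt)) {
  set.seed(seed)
  parcellated_run(matrix(rnorm(nt * r), nt, r), rms, tr_seconds = tr)
}

# A small symmetric matrix with unit diagonal built from a canonical edge
# vector.
make_conn <- function(edges, n_regions) {
  m <- edges_to_matrix(edges, n_regions, diag_value = 1)
  dimnames(m) <- list(paste0("R", seq_len(n_regions)),
                      paste0("R", seq_len(n_regions)))
  m
}

# Tiny smoke cohort used by the pipeline tests.
smoke_spec <- function(n_subjects = 12L, n_regions = 16L,
                       n_timepoints = 300L, seed = 5L, ...) {
  cohort_spec(n_subjects = n_subjects, n_regions = n_regions,
              n_runs_per_session = 2L, n_timepoints_per_run = n_timepoints,
              seed = seed, ...)
}

# Independent scalar ICC(3,1) oracle built on stats::aov: two-way ANOVA with
# subject and session factors, mean squares read off the aov table.
icc_oracle_aov <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  df <- data.frame(
    y = as.vector(x),
    subject = factor(rep(seq_len(n), times = k)),
    session = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + session, data = df))[[1]]
  bms <- tab["subject", "Mean Sq"]
  ems <- tab["Residuals", "Mean Sq"]
  (bms - ems) / (bms + (k - 1) * ems)
}
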