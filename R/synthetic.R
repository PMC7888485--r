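#' Ground-truth specification for a direct edge-level panel
#'
#' Describes a cohort of subjects measured twice at `n_edges` features, with
#' per-edge population mean `mu`, between-subject standard deviation
#' `sigma_b`, and within-subject (session) standard deviation `sigma_w`. The
#' implied true reliability of edge e is
#' `sigma_b[e]^2 / (sigma_b[e]^2 + sigma_w[e]^2)`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_edges Number of edges.
#' @param mu Per-edge population mean FC (recycled).
#' @param sigma_b Per-edge between-subject SD (recycled, >= 0).
#' @param sigma_w Per-edge within-subject SD (recycled, >= 0).
#' @param seed Integer seed.
#' @return An object of class `edge_panel_truth` with the expanded parameter
#'   vectors and `true_icc`.
#' @export
edge_panel_truth <- function(n_subjects, n_edges, mu = 0,
                             sigma_b, sigma_w, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_edges <- as.integer(n_edges)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop("'n_subjects' must be an integer >= 2")
  }
  if (is.na(n_edges) || n_edges < 1L) stop("'n_edges' must be >= 1")
  mu <- rep_len(as.numeric(mu), n_edges)
  sigma_b <- rep_len(as.numeric(sigma_b), n_edges)
  sigma_w <- rep_len(as.numeric(sigma_w), n_edges)
  if (any(sigma_b < 0) || any(sigma_w < 0)) {
    stop("standard deviations must be >= 0")
  }
  tot <- sigma_b^2 + sigma_w^2
  if (any(tot <= 0)) stop("each edge needs sigma_b^2 + sigma_w^2 > 0")
  structure(
    list(n_subjects = n_subjects, n_edges = n_edges, mu = mu,
         sigma_b = sigma_b, sigma_w = sigma_w,
         true_icc = sigma_b^2 / tot, seed = as.integer(seed)),
    class = "edge_panel_truth"
  )
}

#' Edge-panel truth from target reliabilities
#'
#' Convenience parameterization: fixes the total per-edge variance and splits
#' it so that the true ICC equals `icc` exactly.
#'
#' @param n_subjects,n_edges Cohort dimensions.
#' @param icc Target per-edge true ICC in \[0, 1) (recycled).
#' @param total_sd Per-edge total SD `sqrt(sigma_b^2 + sigma_w^2)`
#'   (default 0.2, a typical edge-FC dispersion).
#' @param mu Per-edge mean (default 0).
#' @param seed Integer seed.
#' @return An `edge_panel_truth`.
#' @export
edge_truth_from_icc <- function(n_subjects, n_edges, icc, total_sd = 0.2,
                                mu = 0, seed = 1L) {
  icc <- rep_len(as.numeric(icc), n_edges)
  if (any(icc < 0 | icc >= 1)) stop("'icc' must lie in [0, 1)")
  total_sd <- rep_len(as.numeric(total_sd), n_edges)
  edge_panel_truth(n_subjects, n_edges, mu = mu,
                   sigma_b = sqrt(icc) * total_sd,
                   sigma_w = sqrt(1 - icc) * total_sd, seed = seed)
}

#' Generate a two-session edge panel with known reliability
#'
#' Draws value(e, i, s) = mu_e + b_ei + eps_eis with
#' b ~ N(0, sigma_b_e^2) shared across sessions and
#' eps ~ N(0, sigma_w_e^2) independent per session. The same seed always
#' reproduces the same panels bit for bit.
#'
#' @param truth An [edge_panel_truth()].
#' @return A list with `session1`, `session2` ([edge_panel()]s) and `truth`.
#' @export
generate_edge_panel <- function(truth) {
  stopifnot(inherits(truth, "edge_panel_truth"))
  n <- truth$n_subjects
  e <- truth$n_edges
  set.seed(truth$seed)
  b <- matrix(stats::rnorm(n * e), n, e) * rep(truth$sigma_b, each = n)
  eps1 <- matrix(stats::rnorm(n * e), n, e) * rep(truth$sigma_w, each = n)
  eps2 <- matrix(stats::rnorm(n * e), n, e) * rep(truth$sigma_w, each = n)
  mu <- rep(truth$mu, each = n)
  ei <- synthetic_edge_index(e)
  ids <- sprintf("sub%03d", seq_len(n))
  list(
    session1 = edge_panel(mu + b + eps1, ei, subject_ids = ids, session_id = 1L),
    session2 = edge_panel(mu + b + eps2, ei, subject_ids = ids, session_id = 2L),
    truth = truth
  )
}

# Canonical-prefix edge index for abstract (non-matrix) edge collections:
# the first n_edges pairs of the smallest connectome that has that many.
synthetic_edge_index <- function(n_edges) {
  r <- 2L
  while (r * (r - 1L) / 2L < n_edges) r <- r + 1L
  out <- edge_index(r)[seq_len(n_edges), , drop = FALSE]
  attr(out, "n_regions") <- r
  out
}

#' Project a symmetric matrix to a valid correlation matrix
#'
#' Clips negative eigenvalues to a small positive floor, reconstructs, and
#' rescales to unit diagonal. Inputs that are already valid correlation
#' matrices (unit diagonal, smallest eigenvalue >= -1e-10) are returned
#' unchanged, making the operation idempotent.
#'
#' @param m Square symmetric numeric matrix.
#' @param eig_floor Eigenvalue floor used for clipping (default 1e-8).
#' @return A symmetric matrix with unit diagonal and smallest eigenvalue
#'   >= -1e-10.
#' @export
nearest_valid_correlation <- function(m, eig_floor = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("input must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("input must be symmetric")
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10 && max(abs(diag(m) - 1)) < 1e-12) {
    return(m)
  }
  ed <- eigen(m, symmetric = TRUE)
  lam <- pmax(ed$values, eig_floor)
  rebuilt <- ed$vectors %*% (lam * t(ed$vectors))
  d <- diag(rebuilt)
  if (any(d <= 0)) {
    stop("projection failed: zero diagonal after eigenvalue clipping")
  }
  scale <- 1 / sqrt(d)
  out <- rebuilt * tcrossprod(scale)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Block-structured population correlation matrix
#'
#' Builds the default population region-by-region correlation structure used
#' by the timeseries cohort generator: regions grouped into equally sized
#' "networks", with within-network coupling stronger than between-network
#' coupling, and with block strengths and edge-level variation drawn smoothly
#' so that edge strengths form a continuum (as empirical FC distributions
#' do) rather than a few discrete values. The construction is deterministic
#' for a given `structure_seed`.
#'
#' @param n_regions Number of regions.
#' @param n_networks Number of blocks (default: about one per 5 regions,
#'   between 2 and 12).
#' @param within_r,between_r Mean within- and between-block correlation.
#' @param edge_jitter SD of smooth edge-level variation around the block
#'   means.
#' @param structure_seed Seed fixing the block strengths and jitter.
#' @return Correlation matrix with a `network_labels` attribute (data.frame
#'   with columns `region`, `network`).
#' @export
default_population_corr <- function(n_regions,
                                    n_networks = max(2L, min(12L, n_regions %/% 5L)),
                                    within_r = 0.35, between_r = 0.08,
                                    edge_jitter = 0.06,
                                    structure_seed = 20260101L) {
  if (n_regions < 4L) stop("need at least 4 regions")
  block <- sort(rep_len(seq_len(n_networks), n_regions))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(structure_seed)
  # per-block-pair mean coupling: stronger and more variable on the diagonal
  pair_mean <- matrix(0, n_networks, n_networks)
  pair_mean[upper.tri(pair_mean)] <-
    stats::runif(n_networks * (n_networks - 1L) / 2L,
                 max(between_r - 0.05, 0), between_r + 0.05)
  pair_mean <- pair_mean + t(pair_mean)
  diag(pair_mean) <- stats::runif(n_networks, within_r - 0.1, within_r + 0.1)
  m <- pair_mean[block, block]
  jitter <- matrix(0, n_regions, n_regions)
  jitter[upper.tri(jitter)] <-
    stats::rnorm(n_regions * (n_regions - 1L) / 2L, sd = edge_jitter)
  m <- m + jitter + t(jitter)
  diag(m) <- 1
  m <- nearest_valid_correlation(m)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  region <- sprintf("R%03d", seq_len(n_regions))
  dimnames(m) <- list(region, region)
  attr(m, "network_labels") <- data.frame(
    region = region,
    network = sprintf("net%02d", block),
    stringsAsFactors = FALSE
  )
  m
}

#' Specification of a synthetic timeseries cohort
#'
#' Describes a cohort of subjects scanned in two sessions of
#' `n_runs_per_session` runs each. Each subject carries a latent correlation
#' matrix (population structure plus a subject-specific perturbation), each
#' session perturbs it again (the within-subject, between-session variance),
#' and each run samples correlated Gaussian timeseries from the session
#' matrix. A shared low-frequency global component with subject-specific
#' amplitude is added to all regions, and motion spikes corrupt whole frames
#' while driving the framewise RMS trace above the scrubbing threshold.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of atlas regions.
#' @param n_runs_per_session Runs per session (default 2).
#' @param n_timepoints_per_run Frames per run (default 1200).
#' @param tr_seconds Sampling interval in seconds (default 0.72).
#' @param pop_corr Population correlation matrix (default
#'   [default_population_corr()]).
#' @param subject_dev_sd SD of the subject-specific additive perturbation of
#'   `pop_corr` (default 0.06).
#' @param session_dev_sd SD of the session-specific perturbation of the
#'   subject matrix (default 0.05); this is the main source of within-subject
#'   variance.
#' @param global_amp_mean,global_amp_sd Per-subject global-signal amplitude
#'   distribution, in units of regional signal SD (defaults 1 and 0.5).
#' @param spike_rate Per-frame motion spike probability (default 0.02).
#' @param spike_rms RMS value assigned to spiked frames; must exceed the
#'   0.30 mm scrubbing threshold (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_regions,
                        n_runs_per_session = 2L,
                        n_timepoints_per_run = 1200L,
                        tr_seconds = 0.72,
                        pop_corr = default_population_corr(n_regions),
                        subject_dev_sd = 0.10,
                        session_dev_sd = 0.08,
                        global_amp_mean = 1,
                        global_amp_sd = 0.5,
                        spike_rate = 0.02,
                        spike_rms = 0.5,
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  n_regions <- as.integer(n_regions)
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1")
  if (n_runs_per_session < 1L) stop("'n_runs_per_session' must be >= 1")
  if (n_timepoints_per_run < 2L) stop("'n_timepoints_per_run' must be >= 2")
  pop_corr_m <- as.matrix(pop_corr)
  if (nrow(pop_corr_m) != n_regions || ncol(pop_corr_m) != n_regions) {
    stop("'pop_corr' must be n_regions x n_regions")
  }
  if (max(abs(pop_corr_m - t(pop_corr_m))) > 1e-8 ||
      max(abs(diag(pop_corr_m) - 1)) > 1e-8) {
    stop("'pop_corr' must be symmetric with unit diagonal")
  }
  if (min(eigen(pop_corr_m, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("'pop_corr' must be positive semi-definite")
  }
  if (spike_rate < 0 || spike_rate >= 1) stop("'spike_rate' must be in [0, 1)")
  if (spike_rate > 0 && spike_rms <= 0.30) {
    stop("'spike_rms' must exceed the 0.30 mm scrubbing threshold")
  }
  if (subject_dev_sd < 0 || session_dev_sd < 0 || global_amp_sd < 0) {
    stop("dispersion parameters must be >= 0")
  }
  labels <- attr(pop_corr, "network_labels")
  structure(
    list(n_subjects = n_subjects, n_regions = n_regions,
         n_runs_per_session = as.integer(n_runs_per_session),
         n_timepoints_per_run = as.integer(n_timepoints_per_run),
         tr_seconds = tr_seconds, pop_corr = pop_corr_m,
         subject_dev_sd = subject_dev_sd, session_dev_sd = session_dev_sd,
         global_amp_mean = global_amp_mean, global_amp_sd = global_amp_sd,
         spike_rate = spike_rate, spike_rms = spike_rms,
         seed = as.integer(seed), network_labels = labels),
    class = "cohort_spec"
  )
}

#' Generate a synthetic timeseries cohort
#'
#' Samples the cohort described by a [cohort_spec()]. All randomness derives
#' from the single cohort seed through per-subject substreams, so the same
#' spec always regenerates the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `spec`,
#'   `subjects` (per subject: `subject_id`, `sessions` — each a list of
#'   [parcellated_run()]s), and `truth` (per-subject latent correlation
#'   matrices, per-session matrices, global amplitudes, spike frames).
#' @export
generate_timeseries_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  subject_seeds <- sample.int(.Machine$integer.max, spec$n_subjects)
  subjects <- vector("list", spec$n_subjects)
  truth <- list(latent = vector("list", spec$n_subjects),
                session_latent = vector("list", spec$n_subjects),
                global_amplitude = numeric(spec$n_subjects),
                spike_frames = vector("list", spec$n_subjects))
  region_names <- rownames(spec$pop_corr)
  if (is.null(region_names)) {
    region_names <- sprintf("R%03d", seq_len(spec$n_regions))
  }
  for (s in seq_len(spec$n_subjects)) {
    set.seed(subject_seeds[s])
    latent <- perturb_correlation(spec$pop_corr, spec$subject_dev_sd)
    amp <- stats::rnorm(1L, spec$global_amp_mean, spec$global_amp_sd)
    sessions <- vector("list", 2L)
    sess_latents <- vector("list", 2L)
    spikes <- vector("list", 2L)
    for (sess in 1:2) {
      sess_latent <- perturb_correlation(latent, spec$session_dev_sd)
      sess_latents[[sess]] <- sess_latent
      chol_l <- chol(sess_latent)
      runs <- vector("list", spec$n_runs_per_session)
      run_spikes <- vector("list", spec$n_runs_per_session)
      for (r in seq_len(spec$n_runs_per_session)) {
        sim <- simulate_run(chol_l, spec, amp, region_names)
        runs[[r]] <- sim$run
        run_spikes[[r]] <- sim$spike_frames
      }
      sessions[[sess]] <- runs
      spikes[[sess]] <- run_spikes
    }
    subjects[[s]] <- list(subject_id = sprintf("sub%03d", s),
                          sessions = sessions)
    truth$latent[[s]] <- latent
    truth$session_latent[[s]] <- sess_latents
    truth$global_amplitude[s] <- amp
    truth$spike_frames[[s]] <- spikes
  }
  structure(
    list(spec = spec, subjects = subjects, truth = truth,
         network_labels = spec$network_labels),
    class = "synthetic_cohort"
  )
}

# Additive symmetric perturbation followed by projection back to a valid
# correlation matrix; sd = 0 short-circuits to the input.
perturb_correlation <- function(corr, sd) {
  if (sd == 0) return(corr)
  r <- nrow(corr)
  noise <- matrix(0, r, r)
  noise[upper.tri(noise)] <- stats::rnorm(r * (r - 1L) / 2L, sd = sd)
  noise <- noise + t(noise)
  out <- nearest_valid_correlation(corr + noise)
  dimnames(out) <- dimnames(corr)
  out
}

# One run: correlated Gaussian signals + scaled global component + motion
# spikes with a matching framewise RMS trace (first frame fixed at 0 by the
# relative-displacement convention).
simulate_run <- function(chol_latent, spec, amp, region_names) {
  nt <- spec$n_timepoints_per_run
  r <- spec$n_regions
  x <- matrix(stats::rnorm(nt * r), nt, r) %*% chol_latent
  g <- lowfreq_global(nt, spec$tr_seconds)
  x <- x + amp * g
  spike <- stats::runif(nt) < spec$spike_rate
  spike[1L] <- FALSE
  if (any(spike)) {
    x[spike, ] <- x[spike, ] + matrix(stats::rnorm(sum(spike) * r, sd = 6),
                                      sum(spike), r)
  }
  rms <- stats::runif(nt, 0.02, 0.25)
  rms[spike] <- spec$spike_rms
  rms[1L] <- 0
  colnames(x) <- region_names
  list(run = parcellated_run(x, rms, spec$tr_seconds, region_names),
       spike_frames = which(spike))
}

# Shared low-frequency component: random walk low-passed below 0.05 Hz,
# standardized to zero mean and unit SD.
lowfreq_global <- function(nt, tr_seconds) {
  walk <- cumsum(stats::rnorm(nt))
  nyquist <- 1 / (2 * tr_seconds)
  w <- min(0.05 / nyquist, 0.99)
  bf <- signal::butter(2, W = w, type = "low")
  g <- signal::filtfilt(bf, walk)
  g <- g - mean(g)
  s <- stats::sd(g)
  if (s > 0) g <- g / s
  g
}
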