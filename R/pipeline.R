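#' Configuration for a full reliability analysis
#'
#' @param simulation A [cohort_spec()], or `NULL` when loading from a
#'   manifest.
#' @param manifest_path Path to a cohort `manifest.json`, or `NULL` when
#'   simulating.
#' @param gsr_modes Logical vector of global-signal-regression branches to
#'   run; `c(FALSE, TRUE)` runs both GSR- and GSR+.
#' @param hp_cutoff_hz High-pass cut-off (Hz).
#' @param rms_threshold Motion scrubbing threshold (mm).
#' @param max_flagged_fraction Subject exclusion threshold on the per-run
#'   flagged fraction.
#' @param min_subjects Per-edge subject floor for thresholded ICC.
#' @param thresholds Threshold grid for the sweeps.
#' @param subject_subset Optional character vector (or file with one id per
#'   line) restricting the analysis to a subject subset, e.g. for an
#'   unrelated-subsample confirmation run.
#' @param network_labels Optional region/network table overriding the
#'   cohort's own labels.
#' @param alpha Confidence parameter for ICC intervals.
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed recorded in the provenance (and used when `simulation`
#'   carries no seed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulation = NULL, manifest_path = NULL,
                       gsr_modes = c(FALSE, TRUE), hp_cutoff_hz = 0.008,
                       rms_threshold = 0.30, max_flagged_fraction = 0.15,
                       min_subjects = 10L, thresholds = threshold_grid(),
                       subject_subset = NULL, network_labels = NULL,
                       alpha = 0.05, out_dir, seed = 1L) {
  if (is.null(simulation) && is.null(manifest_path)) {
    stop("provide either a simulation spec or a manifest path")
  }
  if (length(gsr_modes) < 1L) stop("at least one GSR mode is required")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("'thresholds' must be strictly increasing")
  }
  if (is.character(subject_subset) && length(subject_subset) == 1L &&
      file.exists(subject_subset)) {
    subject_subset <- readLines(subject_subset)
    subject_subset <- subject_subset[nzchar(subject_subset)]
  }
  structure(
    list(simulation = simulation, manifest_path = manifest_path,
         gsr_modes = as.logical(gsr_modes), hp_cutoff_hz = hp_cutoff_hz,
         rms_threshold = rms_threshold,
         max_flagged_fraction = max_flagged_fraction,
         min_subjects = as.integer(min_subjects), thresholds = thresholds,
         subject_subset = subject_subset, network_labels = network_labels,
         alpha = alpha, out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Preprocess a cohort and build session connectomes
#'
#' Applies the per-run conditioning chain (optional GSR, high-pass filter,
#' scrubbing), applies the subject-level motion exclusion rule, concatenates
#' each session's runs, and correlates. Motion flags depend only on the RMS
#' traces, so both GSR branches of an analysis exclude exactly the same
#' subjects.
#'
#' @param cohort A `synthetic_cohort` (simulated or loaded).
#' @param gsr Logical, apply global signal regression?
#' @param hp_cutoff_hz,rms_threshold,max_flagged_fraction Preprocessing
#'   parameters (see [run_config()]).
#' @return A list: `matrices_s1`, `matrices_s2` (per-subject
#'   `connectivity_matrix` lists), `panel_s1`, `panel_s2` ([edge_panel()]s),
#'   `included`, `excluded` (subject ids), `flagged` (per-subject, per-run
#'   flagged fractions).
#' @export
cohort_connectomes <- function(cohort, gsr = FALSE, hp_cutoff_hz = 0.008,
                               rms_threshold = 0.30,
                               max_flagged_fraction = 0.15) {
  stopifnot(length(cohort$subjects) >= 1L)
  matrices_s1 <- list()
  matrices_s2 <- list()
  included <- character()
  excluded <- character()
  flagged <- list()
  for (sub in cohort$subjects) {
    if (length(sub$sessions) != 2L) {
      excluded <- c(excluded, sub$subject_id)
      next
    }
    fracs <- unlist(lapply(sub$sessions, function(sess) {
      vapply(sess, function(run) mean(run$rms > rms_threshold), numeric(1L))
    }))
    flagged[[sub$subject_id]] <- fracs
    if (!subject_passes_motion(fracs, max_flagged_fraction)) {
      excluded <- c(excluded, sub$subject_id)
      next
    }
    sessions <- lapply(sub$sessions, function(sess) {
      pre <- lapply(sess, preprocess_run, gsr = gsr,
                    hp_cutoff_hz = hp_cutoff_hz,
                    rms_threshold = rms_threshold)
      concatenate_runs(lapply(pre, `[[`, "run"),
                       vapply(pre, `[[`, numeric(1L), "flagged_fraction"))
    })
    matrices_s1[[sub$subject_id]] <-
      correlation_matrix(sessions[[1L]], sub$subject_id, 1L)
    matrices_s2[[sub$subject_id]] <-
      correlation_matrix(sessions[[2L]], sub$subject_id, 2L)
    included <- c(included, sub$subject_id)
  }
  if (length(included) == 0L) stop("no subjects left after motion exclusion")
  list(matrices_s1 = unname(matrices_s1), matrices_s2 = unname(matrices_s2),
       panel_s1 = panel_from_matrices(unname(matrices_s1), 1L),
       panel_s2 = panel_from_matrices(unname(matrices_s2), 2L),
       included = included, excluded = excluded, flagged = flagged)
}

#' Run the full reliability analysis
#'
#' End-to-end orchestration: simulate or load the cohort, optionally restrict
#' to a subject subset, then per GSR branch compute edge-wise ICC (with masks
#' written to disk), network-wise ICC, per-node average ICC, the
#' strength-vs-ICC Spearman correlation, and absolute and relative threshold
#' sweeps. When both GSR branches run, their edge ICCs are compared with a
#' Wilcoxon signed-rank test. A provenance record (config, seed, subject
#' counts before/after motion exclusion) accompanies the bundle.
#'
#' @param config A [run_config()].
#' @return Invisibly, the in-memory report bundle (a list, one entry per GSR
#'   mode plus `comparison` and `provenance`). All artifacts are also written
#'   under `config$out_dir`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$simulation)) {
    generate_timeseries_cohort(config$simulation)
  } else {
    read_cohort(config$manifest_path)
  }
  if (!is.null(config$subject_subset)) {
    keep <- vapply(cohort$subjects, function(s) s$subject_id, character(1L)) %in%
      config$subject_subset
    if (!any(keep)) stop("subject subset matches no cohort subject")
    cohort$subjects <- cohort$subjects[keep]
  }
  labels <- config$network_labels
  if (is.null(labels)) labels <- cohort$network_labels
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  n_before <- length(cohort$subjects)
  bundle <- list()
  mode_names <- ifelse(config$gsr_modes, "gsr_plus", "gsr_minus")
  for (mi in seq_along(config$gsr_modes)) {
    gsr <- config$gsr_modes[mi]
    mode_dir <- file.path(config$out_dir, mode_names[mi])
    dir.create(mode_dir, showWarnings = FALSE)
    conn <- cohort_connectomes(cohort, gsr = gsr,
                               hp_cutoff_hz = config$hp_cutoff_hz,
                               rms_threshold = config$rms_threshold,
                               max_flagged_fraction = config$max_flagged_fraction)
    icc <- edgewise_icc(conn$panel_s1, conn$panel_s2, alpha = config$alpha)
    icc_summary <- summarize_icc(icc)
    region_names <- conn$matrices_s1[[1L]]$region_names
    write_masks(icc, conn$panel_s1$edge_index, region_names, mode_dir)
    utils::write.table(icc, file.path(mode_dir, "edge_icc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    node <- data.frame(region = region_names,
                       mean_icc = node_average(icc$icc, conn$panel_s1$edge_index))
    utils::write.table(node, file.path(mode_dir, "node_icc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    network <- NULL
    if (!is.null(labels)) {
      network <- networkwise_icc(conn$matrices_s1, conn$matrices_s2, labels,
                                 alpha = config$alpha)
      utils::write.table(network, file.path(mode_dir, "network_icc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    strength <- edge_strength(conn$panel_s1, conn$panel_s2)
    strength_icc <- spearman(strength, icc$icc)
    sweeps <- list(
      absolute = threshold_sweep(conn$panel_s1, conn$panel_s2, "absolute",
                                 thresholds = config$thresholds,
                                 min_subjects = config$min_subjects,
                                 alpha = config$alpha),
      relative = threshold_sweep(conn$panel_s1, conn$panel_s2, "relative",
                                 thresholds = config$thresholds,
                                 min_subjects = config$min_subjects,
                                 alpha = config$alpha)
    )
    for (mode in names(sweeps)) {
      utils::write.table(sweeps[[mode]]$summary,
                         file.path(mode_dir, paste0("sweep_", mode, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(sweeps[[mode]]$trend,
                           file.path(mode_dir, paste0("sweep_", mode,
                                                      "_trend.json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    jsonlite::write_json(
      c(icc_summary[c("n_features", "n_missing", "median", "min", "max",
                      "median_ci_width")],
        list(prop_bin4 = as.list(icc_summary$prop_bin4),
             prop_bin5 = as.list(icc_summary$prop_bin5),
             strength_vs_icc = strength_icc)),
      file.path(mode_dir, "icc_summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    bundle[[mode_names[mi]]] <- list(
      gsr = gsr, connectomes = conn, edge_icc = icc,
      icc_summary = icc_summary, network_icc = network,
      node_icc = node, strength = strength,
      strength_vs_icc = strength_icc, sweeps = sweeps
    )
  }

  comparison <- NULL
  if (all(c("gsr_minus", "gsr_plus") %in% names(bundle))) {
    comparison <- wilcoxon_signed_rank(bundle$gsr_minus$edge_icc$icc,
                                       bundle$gsr_plus$edge_icc$icc)
    jsonlite::write_json(comparison,
                         file.path(config$out_dir, "comparison_gsr.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  first_mode <- bundle[[1L]]
  provenance <- list(
    seed = config$seed,
    gsr_modes = mode_names,
    hp_cutoff_hz = config$hp_cutoff_hz,
    rms_threshold = config$rms_threshold,
    max_flagged_fraction = config$max_flagged_fraction,
    min_subjects = config$min_subjects,
    alpha = config$alpha,
    thresholds = config$thresholds,
    n_subjects_before_exclusion = n_before,
    n_subjects_after_exclusion = length(first_mode$connectomes$included),
    excluded_subjects = as.list(first_mode$connectomes$excluded),
    n_regions = length(first_mode$connectomes$matrices_s1[[1L]]$region_names),
    n_edges = nrow(first_mode$edge_icc)
  )
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle$comparison <- comparison
  bundle$provenance <- provenance
  invisible(bundle)
}

#' Write edge-reliability masks
#'
#' Persists four region x region TSV matrices — ICC, CI lower, CI upper, and
#' reliability bin — mirroring each edge statistic across the diagonal, with
#' the diagonal marked not-applicable (`NA`).
#'
#' @param icc_results Data.frame from [edgewise_icc()].
#' @param edge_index Canonical edge index of the panel.
#' @param region_names Region labels.
#' @param outdir Output directory.
#' @return Invisibly, the four file paths.
#' @export
write_masks <- function(icc_results, edge_index, region_names, outdir) {
  n <- length(region_names)
  if (nrow(icc_results) != nrow(edge_index)) {
    stop("ICC results not aligned with edge index")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(4L)
  numeric_fields <- c(icc = "icc", ci_lower = "ci_lower",
                      ci_upper = "ci_upper")
  i <- 1L
  for (field in names(numeric_fields)) {
    m <- edges_to_matrix(icc_results[[field]], n)
    dimnames(m) <- list(region_names, region_names)
    paths[i] <- write_matrix_tsv(m, file.path(outdir,
                                              paste0("mask_", field, ".tsv")))
    i <- i + 1L
  }
  bins <- matrix(NA_character_, n, n)
  bins[lower.tri(bins)] <- icc_results$bin4
  bins <- t(bins)
  bins[lower.tri(bins)] <- t(bins)[lower.tri(bins)]
  dimnames(bins) <- list(region_names, region_names)
  paths[4L] <- write_matrix_tsv(bins, file.path(outdir, "mask_bin.tsv"))
  invisible(paths)
}
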