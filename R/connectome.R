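#' Session-wise Pearson connectivity matrix
#'
#' Correlates every pair of region timeseries in a concatenated session. The
#' raw correlation scale is kept throughout the package (no Fisher z
#' transform): thresholds, averages, and reliability statistics all operate
#' in r units. Regions with zero temporal variance get `NA` correlations and
#' a warning; downstream operations treat these as missing.
#'
#' @param session A [session_timeseries()] (or plain timepoints x regions
#'   matrix).
#' @param subject_id,session_id Identifiers stored with the result.
#' @return An object of class `connectivity_matrix`: list with `values`
#'   (regions x regions symmetric matrix, unit diagonal), `region_names`,
#'   `subject_id`, `session_id`.
#' @export
correlation_matrix <- function(session, subject_id = NA_character_,
                               session_id = NA_integer_) {
  x <- if (inherits(session, "session_timeseries")) session$signal else as.matrix(session)
  region_names <- colnames(x)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(ncol(x)))
  if (nrow(x) < 3L) stop("need >= 3 timepoints to correlate")
  v <- apply(x, 2L, stats::var)
  degenerate <- v <= .Machine$double.eps
  r <- suppressWarnings(stats::cor(x))
  if (any(degenerate)) {
    warning(sum(degenerate), " region(s) with zero variance; ",
            "their correlations are set to NA")
    r[degenerate, ] <- NA_real_
    r[, degenerate] <- NA_real_
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(region_names, region_names)
  structure(
    list(values = r, region_names = region_names,
         subject_id = subject_id, session_id = session_id),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("connectivity_matrix:", length(x$region_names), "regions, subject",
      x$subject_id, "session", x$session_id, "\n")
  invisible(x)
}

# Internal: coerce connectivity_matrix or plain matrix to a symmetric matrix.
as_conn_values <- function(matrix, tol = 1e-8) {
  m <- if (inherits(matrix, "connectivity_matrix")) matrix$values else as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  asym <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(asym) && asym > tol) {
    stop("matrix is asymmetric beyond tolerance (max |m - t(m)| = ",
         signif(asym, 3), ")")
  }
  m
}

#' Vectorize the upper triangle of a connectivity matrix
#'
#' Emits the R(R-1)/2 unique edges in canonical row-major order
#' (1,2), (1,3), ..., (1,R), (2,3), ... matching [edge_index()].
#'
#' @param matrix A `connectivity_matrix` or plain symmetric matrix.
#' @return Named numeric vector of edge values.
#' @export
vectorize_upper <- function(matrix) {
  m <- as_conn_values(matrix)
  # t(m)[lower.tri(m)] walks the upper triangle of m in row-major order
  v <- t(m)[lower.tri(m)]
  names <- rownames(m)
  if (is.null(names)) names <- paste0("R", seq_len(nrow(m)))
  names(v) <- edge_index(names)$edge_id
  v
}

#' Reassemble a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorize_upper()] for the off-diagonal part.
#'
#' @param edges Edge vector in canonical order.
#' @param n_regions Number of regions R.
#' @param diag_value Value placed on the diagonal (default `NA`).
#' @return An R x R symmetric matrix.
#' @export
edges_to_matrix <- function(edges, n_regions, diag_value = NA_real_) {
  if (length(edges) != n_regions * (n_regions - 1L) / 2L) {
    stop("edge vector length does not match n_regions")
  }
  m <- matrix(diag_value, n_regions, n_regions)
  m[lower.tri(m)] <- edges     # fills column-major lower = row-major upper
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}

#' Mean functional connectivity within labeled networks
#'
#' For each network, averages the connectivity matrix entries over all
#' unordered pairs of member regions (within-network edges only; diagonal
#' and between-network entries never contribute). Regions without a label
#' are ignored.
#'
#' @param matrix A `connectivity_matrix`.
#' @param labels A data.frame with columns `region` and `network`, or a named
#'   character vector mapping region -> network.
#' @return Named numeric vector of per-network mean FC; networks with fewer
#'   than two labeled member regions are `NA` (with a warning).
#' @export
network_average_fc <- function(matrix, labels) {
  m <- as_conn_values(matrix)
  region_names <- rownames(m)
  if (is.null(region_names)) stop("matrix must carry region names")
  map <- normalize_network_labels(labels)
  unknown <- setdiff(names(map), region_names)
  if (length(unknown)) {
    stop("labeled region(s) absent from matrix: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  networks <- sort(unique(unname(map)))
  out <- stats::setNames(rep(NA_real_, length(networks)), networks)
  for (nw in networks) {
    members <- match(names(map)[map == nw], region_names)
    if (length(members) < 2L) {
      warning("network '", nw, "' has < 2 member regions; mean FC undefined")
      next
    }
    block <- m[members, members]
    out[nw] <- mean(block[upper.tri(block)], na.rm = TRUE)
  }
  out
}

normalize_network_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("region", "network") %in% names(labels))) {
      stop("label table needs 'region' and 'network' columns")
    }
    map <- stats::setNames(as.character(labels$network),
                           as.character(labels$region))
  } else if (is.character(labels) && !is.null(names(labels))) {
    map <- labels
  } else {
    stop("'labels' must be a region/network data.frame or named vector")
  }
  if (anyDuplicated(names(map))) stop("duplicate region labels")
  map
}

#' Per-node average of an edge statistic
#'
#' Averages an edge-wise statistic (e.g. ICC) over the R-1 edges incident to
#' each node. Missing edges are excluded from both numerator and denominator;
#' a node whose incident edges are all missing gets `NA`.
#'
#' @param edge_stat Numeric vector aligned with `edge_index`.
#' @param edge_index Edge index from [edge_index()].
#' @return Numeric vector of length R (named by region when the index was
#'   built from names).
#' @export
node_average <- function(edge_stat, edge_index) {
  if (length(edge_stat) != nrow(edge_index)) {
    stop("'edge_stat' not aligned with 'edge_index'")
  }
  n_regions <- attr(edge_index, "n_regions")
  ok <- !is.na(edge_stat)
  idx <- c(edge_index$i[ok], edge_index$j[ok])
  val <- c(edge_stat[ok], edge_stat[ok])
  sums <- tabulate_weighted(idx, val, n_regions)
  counts <- tabulate(idx, nbins = n_regions)
  out <- ifelse(counts > 0L, sums / counts, NA_real_)
  out
}

tabulate_weighted <- function(bin, w, nbins) {
  as.numeric(rowsum(w, group = factor(bin, levels = seq_len(nbins)),
                    reorder = FALSE))
}

#' Per-edge connection strength
#'
#' Strength of an edge is its FC averaged over both sessions and all
#' subjects; this is the quantity correlated with reliability in the
#' strength-vs-ICC analysis.
#'
#' @param panel_s1,panel_s2 Aligned session [edge_panel()]s.
#' @return Named numeric vector of per-edge mean FC.
#' @export
edge_strength <- function(panel_s1, panel_s2) {
  check_panel_alignment(panel_s1, panel_s2)
  (colMeans(panel_s1$values) + colMeans(panel_s2$values)) / 2
}

#' Build session edge panels from connectivity matrices
#'
#' @param matrices List (one per subject) of `connectivity_matrix` objects
#'   from the same session, identical region order.
#' @param session_id Session label.
#' @return An [edge_panel()].
#' @export
panel_from_matrices <- function(matrices, session_id = NA_integer_) {
  stopifnot(length(matrices) >= 1L)
  region_names <- matrices[[1L]]$region_names
  for (m in matrices) {
    if (!identical(m$region_names, region_names)) {
      stop("subjects have different region sets or ordering")
    }
  }
  ei <- edge_index(region_names)
  values <- t(vapply(matrices, vectorize_upper, numeric(nrow(ei))))
  ids <- vapply(matrices, function(m) as.character(m$subject_id), character(1L))
  if (anyNA(ids) || anyDuplicated(ids)) ids <- paste0("sub", seq_along(matrices))
  edge_panel(values, ei, subject_ids = ids, session_id = session_id)
}
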