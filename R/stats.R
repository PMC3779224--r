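#' Normalized connectivity
#'
#' The ratio between a scan's connection count and the mean count of the
#' reference scans (the three repeated high-resolution DSI scans in the
#' scheme-comparison design).
#'
#' @param count connection count of the scan.
#' @param ref_counts connection counts of the reference scans.
#' @return the ratio `count / mean(ref_counts)`.
#' @export
normalized_connectivity <- function(count, ref_counts) {
  if (!length(ref_counts) || any(ref_counts <= 0))
    stop("ref_counts must be nonempty and positive")
  count / mean(ref_counts)
}

#' Fiber limitation: match fiber counts across schemes
#'
#' Sets \eqn{F_s} to the minimum fiber count across the schemes and replaces
#' every scheme's fiber set by a uniform without-replacement sample of
#' exactly \eqn{F_s} fibers, so that every connection matrix of a subject is
#' built from the same number of fibers. Deterministic given `rng_seed`.
#'
#' @param sets named list of `streamline_set` objects (>= 2, all nonempty).
#' @param rng_seed RNG seed for the subsampling.
#' @return named list of subsampled `streamline_set` objects.
#' @export
fiber_limitation <- function(sets, rng_seed = 1L) {
  if (length(sets) < 2) stop("need at least two schemes")
  counts <- vapply(sets, `[[`, numeric(1), "count")
  if (any(counts == 0)) stop("fiber limitation requires nonempty sets")
  Fs <- min(counts)
  set.seed(as.integer(rng_seed))
  lapply(sets, function(s) {
    keep <- sort(sample.int(s$count, Fs))
    s$streamlines <- s$streamlines[keep]
    if (!is.null(s$endpoint_labels))
      s$endpoint_labels <- s$endpoint_labels[keep, , drop = FALSE]
    s$count <- Fs
    s$provenance$fiber_limitation <- Fs
    s
  })
}

#' Paired Student t-test
#'
#' Classical paired t on the differences: \eqn{t = \bar d / (s_d/\sqrt n)},
#' \eqn{df = n - 1}, two-sided p from the t distribution. All-zero
#' differences give t = 0, p = 1.
#'
#' @param x,y paired samples of equal length n >= 2.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least two pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) 0 else mean(d) / (sd_d / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Bonferroni correction
#'
#' @param p_values raw p-values.
#' @param m number of tests (must be at least `length(p_values)`).
#' @return adjusted p-values `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1")
  if (m < length(p_values)) stop("m must cover all tests")
  pmin(1, p_values * m)
}

#' Scan-rescan and inter-subject variability of connection counts
#'
#' Scan-rescan: the mean over subjects of the sample (n-1) standard
#' deviation of each subject's replicate counts. Inter-subject: the mean
#' over replicates of the sample standard deviation across subjects (one of
#' several possible definitions; reported for orientation, see the
#' vignette).
#'
#' @param counts numeric matrix, rows = subjects, columns = replicate scans
#'   of the same scheme.
#' @return list with `scan_rescan_sigma` and `inter_subject_sigma`.
#' @export
variability <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two replicates per subject")
  list(scan_rescan_sigma = mean(apply(counts, 1, stats::sd)),
       inter_subject_sigma = mean(apply(counts, 2, stats::sd)))
}

#' Maximum within-subject normalized spread across replicates
#'
#' Per subject, replicate counts are normalized by their mean; the return
#' value is the largest (max - min) of those normalized counts over
#' subjects — the "variation" across repeated reference scans.
#'
#' @inheritParams variability
#' @return maximum normalized spread (dimensionless fraction).
#' @export
spread_across_replicates <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need at least two replicates per subject")
  max(apply(counts, 1, function(x) (max(x) - min(x)) / mean(x)))
}

#' Scheme-comparison report from a connection-count table
#'
#' Assembles the comparison statistics for a subjects-by-schemes table of
#' connection counts: per-scan normalized connectivity (each subject's
#' reference is the mean of that subject's reference-scheme replicates),
#' scheme-averaged normalized connectivity, all pairwise paired t-tests with
#' Bonferroni correction over the number of scheme pairs, and the
#' variability block computed on the reference replicates.
#'
#' @param counts numeric matrix or data frame, rows = subjects, columns =
#'   scans (column names identify the schemes).
#' @param reference character vector of column names forming the reference
#'   replicates.
#' @param n_f fiber threshold the counts were computed at (recorded in the
#'   report).
#' @return An object of class `comparison_report`: `normalized` (matrix),
#'   `normalized_mean` (per scheme, in percent), `pairwise` (data frame with
#'   t, df, raw and Bonferroni-adjusted p per scheme pair), `variability`,
#'   `spread`, `reference`, `n_f`.
#' @export
compare_report <- function(counts, reference, n_f = 1L) {
  counts <- as.matrix(counts)
  if (!all(reference %in% colnames(counts)))
    stop("reference scheme(s) missing from the count table")
  ref_mean <- rowMeans(counts[, reference, drop = FALSE])
  normalized <- counts / ref_mean
  schemes <- colnames(counts)
  pairs <- utils::combn(schemes, 2)
  m <- ncol(pairs)
  pw <- data.frame(a = pairs[1, ], b = pairs[2, ], t = NA_real_,
                   df = NA_integer_, p = NA_real_)
  for (k in seq_len(m)) {
    r <- paired_t_test(counts[, pairs[1, k]], counts[, pairs[2, k]])
    pw$t[k] <- r$t; pw$df[k] <- r$df; pw$p[k] <- r$p
  }
  pw$p_bonferroni <- bonferroni(pw$p, m)
  structure(list(
    normalized = normalized,
    normalized_mean = 100 * colMeans(normalized),
    pairwise = pw,
    variability = variability(counts[, reference, drop = FALSE]),
    spread = spread_across_replicates(counts[, reference, drop = FALSE]),
    reference = reference, n_f = n_f),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Scheme comparison report\n")
  cat(sprintf("  reference: %s (n_f = %d)\n",
              paste(x$reference, collapse = ", "), x$n_f))
  cat("  mean normalized connectivity (%):\n")
  print(round(x$normalized_mean, 1))
  cat(sprintf("  scan-rescan sigma = %.1f, max replicate spread = %.1f%%\n",
              x$variability$scan_rescan_sigma, 100 * x$spread))
  ns <- subset(x$pairwise, x$pairwise$p > 0.05)
  if (nrow(ns)) {
    cat("  pairs not rejected at p > 0.05:\n")
    for (k in seq_len(nrow(ns)))
      cat(sprintf("    %s vs %s (p = %.2f)\n", ns$a[k], ns$b[k], ns$p[k]))
  }
  invisible(x)
}

#' Load the packaged connection-count table
#'
#' The published per-subject connection counts for the eight encoding
#' schemes (three repeated DSI q5 b8000 scans, DSI q5 b6400, DSI q4, QBI,
#' DTI65, DTI21), shipped as a CSV fixture for the statistics module.
#'
#' @return numeric matrix, 5 subjects x 8 scans.
#' @export
connection_count_table <- function() {
  path <- system.file("extdata", "connection_counts.csv",
                      package = "dwiconn", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
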