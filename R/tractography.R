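#' Tracking parameters
#'
#' Defaults follow the deterministic streamline protocol: 1 mm step, walks
#' aborted at trajectory changes sharper than 60 degrees/mm, 32 seeds per
#' direction vector per voxel, and post-filtering to fibers between 5 and
#' 200 mm whose both endpoints lie in an ROI.
#'
#' @param step step size in mm.
#' @param max_turn maximum trajectory change in degrees per mm.
#' @param seeds_per_vector seeds per direction vector per voxel.
#' @param min_len,max_len retained fiber length bounds in mm.
#' @param rng_seed seed for the uniform-in-voxel seed positions.
#' @return an object of class `tracking_params`.
#' @export
tracking_params <- function(step = 1, max_turn = 60, seeds_per_vector = 32L,
                            min_len = 5, max_len = 200, rng_seed = 1L) {
  if (step <= 0) stop("step must be positive")
  if (max_turn <= 0 || max_turn > 90) stop("max_turn must be in (0, 90]")
  if (min_len >= max_len) stop("min_len must be below max_len")
  structure(list(step = step, max_turn = max_turn,
                 seeds_per_vector = as.integer(seeds_per_vector),
                 min_len = min_len, max_len = max_len,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

# flatten a peak_field into the C++ layout: per-grid-voxel offsets into one
# stacked direction matrix
.flatten_peaks <- function(peaks, wm_mask) {
  nvox <- prod(peaks$dim)
  counts <- integer(nvox)
  counts[peaks$index] <- peaks$n_peaks
  if (!is.null(wm_mask)) counts[!as.vector(wm_mask)] <- 0L
  off <- c(0L, cumsum(counts))
  vecs <- matrix(0, sum(counts), 3)
  pos <- off[peaks$index] # 0-based start per listed voxel
  for (j in seq_along(peaks$peaks)) {
    k <- peaks$n_peaks[j]
    if (k > 0 && counts[peaks$index[j]] > 0)
      vecs[pos[j] + seq_len(k), ] <- peaks$peaks[[j]]
  }
  list(vecs = vecs, off = as.integer(off))
}

#' Generate tractography seed points
#'
#' Per white-matter voxel with \eqn{n_v \ge 1} direction vectors:
#' `seeds_per_vector` seeds per vector, positions uniform within the voxel
#' volume, each carrying its generating vector as the initial direction.
#' Deterministic given `params$rng_seed`.
#'
#' @param peaks a `peak_field`.
#' @param wm_mask logical 3-D array (voxels outside it yield no seeds).
#' @param params a [tracking_params()].
#' @return matrix with columns x, y, z (mm) and dx, dy, dz.
#' @export
generate_seeds <- function(peaks, wm_mask, params = tracking_params()) {
  set.seed(params$rng_seed)
  vs <- peaks$voxel_size
  in_wm <- if (is.null(wm_mask)) rep(TRUE, length(peaks$peaks)) else
    as.vector(wm_mask)[peaks$index]
  sel <- which(in_wm & peaks$n_peaks >= 1L)
  if (!length(sel)) return(matrix(numeric(0), 0, 6))
  reps <- peaks$n_peaks[sel] * params$seeds_per_vector
  vox_idx <- rep(peaks$index[sel], reps)
  dirs <- do.call(rbind, lapply(sel, function(j)
    peaks$peaks[[j]][rep(seq_len(peaks$n_peaks[j]),
                         each = params$seeds_per_vector), , drop = FALSE]))
  n <- length(vox_idx)
  ijk <- arrayInd(vox_idx, peaks$dim)
  pos <- (ijk - 1 + matrix(stats::runif(3 * n), n, 3)) %*% diag(vs)
  cbind(pos, dirs)
}

#' Propagate one seed into a streamline
#'
#' Bidirectional deterministic walk from a seed: at each step the direction
#' set of the current voxel is looked up (nearest-neighbor), the axial vector
#' closest to the incoming trajectory is followed (sign-aligned), the walk
#' aborts when the turn would exceed `max_turn * step`, and ends one step
#' after leaving the white matter. The two walks are concatenated through
#' the seed.
#'
#' @param seed numeric length-6 vector (position mm, initial axial vector).
#' @param peaks a `peak_field`.
#' @param wm_mask logical 3-D array.
#' @param params a [tracking_params()].
#' @return matrix of streamline points (mm), or `NULL` if the seed lies
#'   outside the white matter.
#' @export
propagate <- function(seed, peaks, wm_mask, params = tracking_params()) {
  vox <- floor(seed[1:3] / peaks$voxel_size) + 1
  if (any(vox < 1) || any(vox > peaks$dim) ||
      !wm_mask[vox[1], vox[2], vox[3]]) return(NULL)
  fp <- .flatten_peaks(peaks, wm_mask)
  propagate_streamlines(
    matrix(seed, 1, 6), fp$vecs, fp$off,
    as.integer(as.vector(wm_mask)), as.integer(peaks$dim),
    peaks$voxel_size, params$step,
    cos(params$max_turn * params$step * pi / 180),
    as.integer(ceiling(params$max_len / params$step) + 2L))[[1]]
}

#' Filter fibers by length and endpoint ROI membership
#'
#' Keeps streamlines whose length lies in `[min_len, max_len]` and whose
#' both endpoint voxels carry a nonzero ROI label; fills endpoint labels.
#'
#' @param set a `streamline_set`.
#' @param roi_labels integer 3-D array of ROI labels (0 = background).
#' @param params a [tracking_params()].
#' @return the filtered `streamline_set` with `endpoint_labels` set.
#' @export
filter_fibers <- function(set, roi_labels, params = tracking_params()) {
  if (!length(set$streamlines)) {
    set$endpoint_labels <- matrix(integer(0), 0, 2)
    return(set)
  }
  lens <- vapply(set$streamlines, function(m)
    (nrow(m) - 1) * params$step, numeric(1))
  lab_at <- function(p) {
    vox <- floor(p / set$voxel_size) + 1
    if (any(vox < 1) || any(vox > dim(roi_labels))) return(0L)
    roi_labels[vox[1], vox[2], vox[3]]
  }
  labs <- t(vapply(set$streamlines, function(m)
    c(lab_at(m[1, ]), lab_at(m[nrow(m), ])), integer(2)))
  keep <- lens >= params$min_len & lens <= params$max_len &
    labs[, 1] > 0 & labs[, 2] > 0
  set$streamlines <- set$streamlines[keep]
  set$endpoint_labels <- labs[keep, , drop = FALSE]
  set$count <- sum(keep)
  set
}

#' Whole-phantom deterministic streamline tractography
#'
#' [generate_seeds()], bidirectional propagation of every seed, then
#' [filter_fibers()]. Deterministic given `params$rng_seed`.
#'
#' @param peaks a `peak_field`.
#' @param wm_mask logical 3-D array.
#' @param roi_labels integer 3-D array.
#' @param params a [tracking_params()].
#' @param scheme_id optional label stored in the provenance.
#' @return An object of class `streamline_set`: `streamlines` (list of
#'   point matrices in mm), `count`, `endpoint_labels` (n x 2),
#'   `voxel_size`, `dim` and `provenance`.
#' @export
track_wholebrain <- function(peaks, wm_mask, roi_labels,
                             params = tracking_params(), scheme_id = NULL) {
  seeds <- generate_seeds(peaks, wm_mask, params)
  if (nrow(seeds)) {
    fp <- .flatten_peaks(peaks, wm_mask)
    lines <- propagate_streamlines(
      seeds, fp$vecs, fp$off, as.integer(as.vector(wm_mask)),
      as.integer(peaks$dim), peaks$voxel_size, params$step,
      cos(params$max_turn * params$step * pi / 180),
      as.integer(ceiling(params$max_len / params$step) + 2L))
  } else lines <- list()
  set <- structure(list(streamlines = lines, count = length(lines),
                        endpoint_labels = NULL,
                        voxel_size = peaks$voxel_size, dim = peaks$dim,
                        params = params,
                        provenance = list(scheme_id = scheme_id,
                                          rng_seed = params$rng_seed,
                                          n_seeds = nrow(seeds))),
                   class = "streamline_set")
  filter_fibers(set, roi_labels, params)
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set: %d fibers%s>\n", x$count,
              if (!is.null(x$provenance$scheme_id))
                paste0(", scheme ", x$provenance$scheme_id) else ""))
  invisible(x)
}

#' Fiber lengths of a streamline set
#' @param set a `streamline_set`.
#' @return numeric vector of polyline lengths in mm.
#' @export
fiber_lengths <- function(set) {
  vapply(set$streamlines, function(m) {
    if (nrow(m) < 2) return(0)
    sum(sqrt(rowSums((m[-1, , drop = FALSE] -
                        m[-nrow(m), , drop = FALSE])^2)))
  }, numeric(1))
}
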