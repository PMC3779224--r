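#' Known-truth fiber-bundle phantoms
#'
#' A phantom is a voxel grid holding one or more tubular fiber bundles
#' (white matter), terminal gray-matter ROI caps at both ends of each bundle,
#' and the ground-truth ROI connectivity. It stands in for the anatomical
#' white-matter mask and cortical parcellation of an in vivo pipeline.
#'
#' @name phantom
NULL

#' Bundle specification
#'
#' @param centerline k x 3 matrix of points in mm (k >= 2).
#' @param radius bundle radius in mm.
#' @param weight relative volume-fraction weight where bundles overlap.
#' @param diffusivities c(axial, radial) in mm^2/s.
#' @return an object of class `bundle_spec`.
#' @export
bundle_spec <- function(centerline, radius, weight = 1,
                        diffusivities = c(1.7e-3, 0.3e-3)) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2) stop("centerline needs at least 2 points")
  if (radius <= 0) stop("radius must be positive")
  if (diffusivities[1] < diffusivities[2] || diffusivities[2] <= 0)
    stop("need axial >= radial > 0 diffusivities")
  structure(list(centerline = centerline, radius = radius, weight = weight,
                 diffusivities = diffusivities),
            class = "bundle_spec")
}

# closest point on a polyline: returns distance, tangent at closest segment,
# and arc-length parameter, for a matrix of query points
.polyline_closest <- function(points, poly) {
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_tan <- matrix(0, n, 3)
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]; b <- poly[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2] +
            (points[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- points[, 1] - (a[1] + t * ab[1])
    dy <- points[, 2] - (a[2] + t * ab[2])
    dz <- points[, 3] - (a[3] + t * ab[3])
    d2 <- dx^2 + dy^2 + dz^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    if (any(upd)) {
      tn <- ab / sqrt(len2)
      best_tan[upd, 1] <- tn[1]; best_tan[upd, 2] <- tn[2]
      best_tan[upd, 3] <- tn[3]
    }
  }
  list(dist = sqrt(best_d2), tangent = best_tan)
}

#' Build a known-truth fiber phantom
#'
#' Constructs the white-matter mask, per-voxel fiber directions and terminal
#' ROI labels for one of the built-in geometries, or for an explicit list of
#' [bundle_spec()] objects. A voxel whose center lies within `radius` of a
#' bundle centerline becomes white matter and receives that bundle's local
#' tangent; voxels within `radius` of the short extension beyond each
#' centerline end become the terminal ROI caps (labels 2i-1 and 2i for bundle
#' i). White matter and ROI voxels are disjoint; ROI assignment wins at the
#' junction.
#'
#' @param geometry `"straight"`, `"crossing"`, `"three_bundle_crossing"`,
#'   `"arc"`, or `"custom"` (then supply `bundles`).
#' @param length_mm bundle length in mm.
#' @param radius_mm bundle radius in mm.
#' @param angle_deg crossing angle for `"crossing"` (degrees).
#' @param grid_dim integer 3-vector of voxel counts; `NULL` fits the bundles.
#' @param voxel_size mm, scalar or 3-vector (default 2 mm isotropic; the
#'   anisotropic in vivo geometry, e.g. 2.21 x 2.21 x 3 mm, is supported).
#' @param roi_depth_mm depth of the terminal ROI caps along the bundle.
#' @param diffusivities c(axial, radial) in mm^2/s for all bundles.
#' @param bundles list of [bundle_spec()] for `geometry = "custom"`.
#' @return An object of class `phantom_truth`: `dim`, `voxel_size`,
#'   `wm_mask` and `roi_labels` (3-D arrays), `bundles`, `true_pairs`
#'   (2-column matrix of connected ROI labels), `wm_index` (linear indices of
#'   WM voxels), `dirs` (list of k x 3 direction matrices per WM voxel) and
#'   `fracs` (volume fractions per WM voxel, summing to 1).
#' @export
build_phantom <- function(geometry = c("straight", "crossing",
                                       "three_bundle_crossing", "arc",
                                       "custom"),
                          length_mm = 40, radius_mm = 3, angle_deg = 90,
                          grid_dim = NULL, voxel_size = 2, roi_depth_mm = 4,
                          diffusivities = c(1.7e-3, 0.3e-3), bundles = NULL) {
  geometry <- match.arg(geometry)
  if (radius_mm <= 0 && geometry != "custom") stop("radius must be positive")
  voxel_size <- rep(as.numeric(voxel_size), length.out = 3)
  if (is.null(grid_dim)) {
    need <- length_mm + 2 * roi_depth_mm + 2 * radius_mm + 2 * max(voxel_size)
    grid_dim <- pmax(6L, as.integer(ceiling(need / voxel_size)))
  }
  grid_dim <- as.integer(rep(grid_dim, length.out = 3))
  ctr <- grid_dim * voxel_size / 2
  seg <- function(dir) {
    dir <- dir / sqrt(sum(dir^2))
    rbind(ctr - dir * length_mm / 2, ctr + dir * length_mm / 2)
  }
  if (geometry == "custom") {
    if (is.null(bundles)) stop("geometry = 'custom' needs a bundles list")
  } else {
    bundles <- switch(geometry,
      straight = list(seg(c(1, 0, 0))),
      crossing = {
        th <- angle_deg * pi / 180
        list(seg(c(1, 0, 0)), seg(c(cos(th), sin(th), 0)))
      },
      three_bundle_crossing =
        list(seg(c(1, 0, 0)), seg(c(0, 1, 0)), seg(c(0, 0, 1))),
      arc = {
        # quarter arc in the x-y plane with arc length length_mm
        rad <- length_mm * 2 / pi
        ang <- seq(0, pi / 2, length.out = 65)
        pts <- cbind(ctr[1] - rad / 2 + rad * cos(ang),
                     ctr[2] - rad / 2 + rad * sin(ang),
                     ctr[3] + 0 * ang)
        list(pts)
      })
    bundles <- lapply(bundles, bundle_spec, radius = radius_mm,
                      diffusivities = diffusivities)
  }
  nb <- length(bundles)
  nvox <- prod(grid_dim)
  idx <- arrayInd(seq_len(nvox), grid_dim)
  centers <- (idx - 0.5) %*% diag(voxel_size)

  roi_labels <- integer(nvox)
  wm_hit <- matrix(FALSE, nvox, nb)
  tangents <- vector("list", nb)
  for (i in seq_len(nb)) {
    b <- bundles[[i]]
    cl <- b$centerline
    q <- .polyline_closest(centers, cl)
    wm_hit[, i] <- q$dist <= b$radius
    tangents[[i]] <- q$tangent
    # terminal caps: cylinders of the bundle radius extending strictly
    # beyond each centerline end along the local tangent, so the white
    # matter keeps the full centerline span
    for (end in 1:2) {
      if (end == 1) {
        p0 <- cl[1, ]; dir <- p0 - cl[2, ]
      } else {
        p0 <- cl[nrow(cl), ]; dir <- p0 - cl[nrow(cl) - 1, ]
      }
      dir <- dir / sqrt(sum(dir^2))
      rel <- sweep(centers, 2, p0)
      s <- rel %*% dir                    # axial coordinate beyond the end
      lat2 <- rowSums(rel^2) - s^2
      in_cap <- s > 0 & s <= roi_depth_mm & lat2 <= b$radius^2
      lab <- 2L * (i - 1L) + end
      clash <- in_cap & roi_labels > 0 & roi_labels != lab
      if (any(clash))
        stop("overlapping ROI caps from distinct bundles; enlarge the grid ",
             "or separate the bundles")
      roi_labels[in_cap] <- lab
    }
  }
  is_roi <- roi_labels > 0
  wm_hit[is_roi, ] <- FALSE            # ROI wins at the junction
  wm <- rowSums(wm_hit) > 0
  wm_index <- which(wm)
  weights <- vapply(bundles, `[[`, numeric(1), "weight")
  dirs <- vector("list", length(wm_index))
  fracs <- vector("list", length(wm_index))
  bidx <- vector("list", length(wm_index))
  for (j in seq_along(wm_index)) {
    v <- wm_index[j]
    hit <- which(wm_hit[v, ])
    d <- do.call(rbind, lapply(hit, function(i) tangents[[i]][v, ]))
    w <- weights[hit]
    dirs[[j]] <- d
    fracs[[j]] <- w / sum(w)
    bidx[[j]] <- hit
  }
  structure(list(
    dim = grid_dim, voxel_size = voxel_size,
    wm_mask = array(wm, grid_dim),
    roi_labels = array(roi_labels, grid_dim),
    bundles = bundles,
    true_pairs = cbind(2L * seq_len(nb) - 1L, 2L * seq_len(nb)),
    wm_index = wm_index, dirs = dirs, fracs = fracs, bundle_idx = bidx,
    geometry = geometry), class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth: %s, %d bundle(s), grid %s @ %s mm, %d WM voxels, %d ROIs>\n",
    x$geometry, length(x$bundles), paste(x$dim, collapse = "x"),
    paste(format(x$voxel_size), collapse = "x"), length(x$wm_index),
    max(x$roi_labels)))
  invisible(x)
}

# noise-free multi-tensor signal for every voxel; returns nvox x nsamples
# matrix. WM voxels: S0 * sum_k f_k exp(-b (rad + (ax - rad)(g.d_k)^2)).
# ROI voxels: isotropic at iso_diffusivity. Other voxels: background_frac*S0.
.noise_free_signal <- function(truth, scheme, S0, iso_diffusivity,
                               background_frac) {
  nvox <- prod(truth$dim)
  ns <- n_samples(scheme)
  sig <- matrix(S0 * background_frac, nvox, ns)
  iso <- S0 * exp(-scheme$bval * iso_diffusivity)
  roi_idx <- which(truth$roi_labels > 0)
  if (length(roi_idx))
    sig[roi_idx, ] <- matrix(iso, length(roi_idx), ns, byrow = TRUE)
  # group WM voxels by identical (directions, fractions, bundles) so the
  # mixture is evaluated once per class (bundle tangents are constant along
  # straight segments, so classes are few)
  keys <- vapply(seq_along(truth$wm_index), function(j)
    paste(c(round(truth$dirs[[j]], 6), round(truth$fracs[[j]], 6),
            truth$bundle_idx[[j]]), collapse = ","), character(1))
  diffs <- do.call(rbind, lapply(truth$bundles, `[[`, "diffusivities"))
  grp <- split(seq_along(truth$wm_index), keys)
  for (g in grp) {
    j <- g[[1]]
    d <- truth$dirs[[j]]
    f <- truth$fracs[[j]]
    bi <- truth$bundle_idx[[j]]
    s <- numeric(ns)
    for (k in seq_len(nrow(d))) {
      ax <- diffs[bi[k], 1]; rad <- diffs[bi[k], 2]
      proj2 <- (scheme$grad %*% d[k, ])^2
      s <- s + f[k] * exp(-scheme$bval * (rad + (ax - rad) * proj2))
    }
    sig[truth$wm_index[g], ] <- matrix(S0 * s, length(g), ns, byrow = TRUE)
  }
  sig
}

#' Simulate a diffusion-weighted acquisition of a phantom
#'
#' Evaluates the noise-free multi-tensor mixture signal
#' \deqn{S(q) = S_0 \sum_k f_k \exp(-b(q)\, g^T D_k g)}
#' in every voxel (axially symmetric tensors along the local bundle
#' tangents), then adds independent complex Gaussian noise of standard
#' deviation \eqn{S_0/\mathrm{snr}} per repeat and takes magnitudes (Rician
#' noise). Repeats are combined either by complex averaging (mean of complex
#' values, then magnitude — the noise floor falls as \eqn{1/\sqrt{N}}) or by
#' magnitude averaging.
#'
#' ROI (gray matter) voxels carry an isotropic signal at `iso_diffusivity`;
#' voxels outside the phantom carry `background_frac * S0` (0 by default, so
#' the background shows the pure Rician noise floor).
#'
#' @param truth a [build_phantom()] result.
#' @param scheme a `qscheme`.
#' @param S0 non-diffusion-weighted signal amplitude.
#' @param snr signal-to-noise ratio on the b0 signal; `Inf` for noiseless.
#' @param n_averages number of repeats to combine.
#' @param averaging `"complex"` or `"magnitude"`.
#' @param seed RNG seed (the simulation is deterministic given the seed).
#' @param iso_diffusivity mm^2/s for gray-matter ROI voxels.
#' @param background_frac fraction of S0 outside the phantom.
#' @return An object of class `dwi_dataset`: 4-D `signal` array
#'   (x, y, z, sample), `scheme`, `voxel_size`, `wm_mask`, `roi_labels` and
#'   a `provenance` list.
#' @export
simulate_dwi <- function(truth, scheme, S0 = 100, snr = Inf, n_averages = 1,
                         averaging = c("complex", "magnitude"), seed = 1L,
                         iso_diffusivity = 0.8e-3, background_frac = 0) {
  averaging <- match.arg(averaging)
  if (!(is.infinite(snr) || snr > 0)) stop("snr must be positive or Inf")
  if (n_averages < 1) stop("n_averages must be >= 1")
  bad <- vapply(truth$fracs, function(f) abs(sum(f) - 1) > 1e-6, logical(1))
  if (any(bad)) stop("voxel volume fractions must sum to 1")
  base <- .noise_free_signal(truth, scheme, S0, iso_diffusivity,
                             background_frac)
  ns <- n_samples(scheme)
  if (is.infinite(snr)) {
    out <- base
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sigma <- S0 / snr
    acc <- matrix(0, nrow(base), ns)
    acc_im <- if (averaging == "complex") matrix(0, nrow(base), ns) else NULL
    for (r in seq_len(n_averages)) {
      re <- base + matrix(stats::rnorm(length(base), 0, sigma), nrow(base))
      im <- matrix(stats::rnorm(length(base), 0, sigma), nrow(base))
      if (averaging == "complex") {
        acc <- acc + re
        acc_im <- acc_im + im
      } else {
        acc <- acc + sqrt(re^2 + im^2)
      }
    }
    out <- if (averaging == "complex")
      sqrt((acc / n_averages)^2 + (acc_im / n_averages)^2)
    else acc / n_averages
  }
  new_dwi_dataset(array(out, c(truth$dim, ns)), scheme, truth$voxel_size,
                  truth$wm_mask, truth$roi_labels,
                  provenance = list(seed = seed, snr = snr,
                                    n_averages = n_averages,
                                    averaging = averaging, S0 = S0))
}

#' Simulate one complex-valued noisy repeat (no magnitude taken)
#'
#' Building block for explicit [complex_average()]; the returned dataset's
#' `signal` array is complex.
#'
#' @inheritParams simulate_dwi
#' @return a `dwi_dataset` with complex `signal`.
#' @export
simulate_dwi_repeat <- function(truth, scheme, S0 = 100, snr = Inf,
                                seed = 1L, iso_diffusivity = 0.8e-3,
                                background_frac = 0) {
  base <- .noise_free_signal(truth, scheme, S0, iso_diffusivity,
                             background_frac)
  ns <- n_samples(scheme)
  if (is.infinite(snr)) {
    sig <- base + 0i
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    sigma <- S0 / snr
    sig <- complex(
      real = base + stats::rnorm(length(base), 0, sigma),
      imaginary = stats::rnorm(length(base), 0, sigma))
  }
  new_dwi_dataset(array(sig, c(truth$dim, ns)), scheme, truth$voxel_size,
                  truth$wm_mask, truth$roi_labels,
                  provenance = list(seed = seed, snr = snr, n_averages = 1,
                                    averaging = "none", S0 = S0))
}

#' Complex averaging of repeated acquisitions
#'
#' Voxelwise mean of the complex signals followed by the magnitude. Compared
#' to magnitude averaging this lowers the Rician noise floor by the square
#' root of the number of repeats. A single repeat is returned unchanged (up
#' to the magnitude).
#'
#' @param repeats list of `dwi_dataset` objects with identical schemes and
#'   grids (complex or real signal).
#' @return a `dwi_dataset` with real (magnitude) signal.
#' @export
complex_average <- function(repeats) {
  if (length(repeats) < 1) stop("need at least one repeat")
  ref <- repeats[[1]]
  for (r in repeats[-1]) {
    if (!identical(dim(r$signal), dim(ref$signal)))
      stop("repeat grids do not match")
    if (!isTRUE(all.equal(r$scheme$qvec, ref$scheme$qvec)) ||
        !isTRUE(all.equal(r$scheme$bval, ref$scheme$bval)))
      stop("repeat schemes do not match")
  }
  acc <- Reduce(`+`, lapply(repeats, function(r) r$signal))
  sig <- Mod(acc / length(repeats))
  new_dwi_dataset(array(sig, dim(ref$signal)), ref$scheme, ref$voxel_size,
                  ref$wm_mask, ref$roi_labels,
                  provenance = utils::modifyList(
                    ref$provenance,
                    list(n_averages = length(repeats),
                         averaging = "complex")))
}

# internal constructor shared by the simulator and the NIfTI reader
new_dwi_dataset <- function(signal, scheme, voxel_size, wm_mask = NULL,
                            roi_labels = NULL, provenance = list()) {
  stopifnot(length(dim(signal)) == 4L,
            dim(signal)[4] == n_samples(scheme))
  if (!all(is.finite(Mod(signal)))) stop("signal must be finite")
  if (is.double(signal) && any(signal < 0))
    stop("magnitude signal must be nonnegative")
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = rep(as.numeric(voxel_size), length.out = 3),
                 wm_mask = wm_mask, roi_labels = roi_labels,
                 provenance = provenance),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<dwi_dataset: %s grid @ %s mm, %d volumes (%s scheme, b_max %g)%s>\n",
    paste(d[1:3], collapse = "x"),
    paste(format(x$voxel_size), collapse = "x"), d[4], x$scheme$kind,
    x$scheme$b_max,
    if (!is.null(x$provenance$snr))
      sprintf(", snr %s x%d %s", format(x$provenance$snr),
              x$provenance$n_averages, x$provenance$averaging) else ""))
  invisible(x)
}
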