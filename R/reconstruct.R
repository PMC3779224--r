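#' Orientation reconstruction
#'
#' Turns a `dwi_dataset` into per-voxel orientation information: a tensor
#' field ([fit_tensor()]) for DTI schemes, ODF fields for Cartesian DSI
#' ([dsi_odf()]), Funk-Radon q-ball ([qbi_odf()]) and solid-angle q-ball
#' ([csa_odf()]) reconstructions, and extracted peak directions
#' ([extract_peaks()], [tensor_peaks()]) for tractography.
#'
#' @name reconstruct
NULL

# signal matrix (nvox_in_mask x nsamples) and the mask's linear indices
.masked_signal <- function(dwi) {
  d <- dim(dwi$signal)
  nvox <- prod(d[1:3])
  sig <- matrix(dwi$signal, nvox, d[4])
  idx <- if (!is.null(dwi$wm_mask)) which(dwi$wm_mask) else seq_len(nvox)
  list(sig = sig[idx, , drop = FALSE], index = idx, dim = d[1:3])
}

#' Log-linear least-squares tensor fit
#'
#' Per white-matter voxel, solves \eqn{\ln(S/S_0) = -b\, g^T D g} for the six
#' unique tensor elements by ordinary least squares over the
#' diffusion-weighted samples; \eqn{S_0} is the mean of the b0 samples. The
#' fit is exact on noiseless single-tensor data. Signals are clamped to a
#' small positive floor before the log.
#'
#' @param dwi a `dwi_dataset` whose scheme has at least 6 non-collinear
#'   diffusion-weighted directions and one b0.
#' @param floor relative signal floor applied before the log.
#' @return An object of class `tensor_field`: `coef` (n x 6 matrix, order
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, in mm^2/s), `index` (linear voxel
#'   indices), `valid`, `dim`, `voxel_size`.
#' @export
fit_tensor <- function(dwi, floor = 1e-4) {
  sch <- dwi$scheme
  dw <- !sch$is_b0
  g <- sch$grad[dw, , drop = FALSE]
  b <- sch$bval[dw]
  if (sum(dw) < 6 || qr(g)$rank < 3)
    stop("tensor fit needs at least 6 non-collinear DW directions")
  X <- -b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                  2 * g[, 2] * g[, 3])
  ms <- .masked_signal(dwi)
  s0 <- rowMeans(ms$sig[, sch$is_b0, drop = FALSE])
  valid <- s0 > 0
  E <- ms$sig[, dw, drop = FALSE] / pmax(s0, .Machine$double.eps)
  E <- pmax(E, floor)
  Y <- t(log(E))
  coef <- matrix(NA_real_, nrow(ms$sig), 6)
  if (any(valid))
    coef[valid, ] <- t(qr.solve(X, Y[, valid, drop = FALSE]))
  structure(list(coef = coef, index = ms$index, valid = valid,
                 dim = ms$dim, voxel_size = dwi$voxel_size),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field: %d voxels (%d valid), grid %s>\n",
              nrow(x$coef), sum(x$valid), paste(x$dim, collapse = "x")))
  invisible(x)
}

.tensor_eigen <- function(coef6) {
  D <- matrix(c(coef6[1], coef6[4], coef6[5],
                coef6[4], coef6[2], coef6[6],
                coef6[5], coef6[6], coef6[3]), 3, 3)
  eigen(D, symmetric = TRUE)
}

#' Fractional anisotropy and mean diffusivity maps
#'
#' FA uses the standard eigenvalue formula with negative eigenvalues clamped
#' to zero (FA only); ADC is the mean eigenvalue.
#'
#' @param tf a `tensor_field`.
#' @return list with 3-D arrays `fa` and `adc` (NA outside the valid mask).
#' @export
fa_adc <- function(tf) {
  fa <- adc <- rep(NA_real_, prod(tf$dim))
  for (i in which(tf$valid)) {
    ev <- .tensor_eigen(tf$coef[i, ])$values
    adc[tf$index[i]] <- mean(ev)
    l <- pmax(ev, 0)
    m <- mean(l)
    denom <- sum(l^2)
    fa[tf$index[i]] <- if (denom == 0) 0 else
      sqrt(3 / 2) * sqrt(sum((l - m)^2) / denom)
  }
  list(fa = array(fa, tf$dim), adc = array(adc, tf$dim))
}

#' Principal-direction peaks from a tensor field
#'
#' One axial peak per valid voxel: the unit eigenvector of the largest
#' eigenvalue. A degenerate leading eigenvalue (ties within `tol`) is
#' resolved deterministically to the first eigenvector and flagged.
#'
#' @param tf a `tensor_field`.
#' @param tol eigenvalue tie tolerance.
#' @return a `peak_field` (see [extract_peaks()]).
#' @export
tensor_peaks <- function(tf, tol = 1e-9) {
  n <- nrow(tf$coef)
  peaks <- vector("list", n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    if (!tf$valid[i]) { peaks[[i]] <- matrix(0, 0, 3); next }
    e <- .tensor_eigen(tf$coef[i, ])
    v <- e$vectors[, 1]
    degen[i] <- (e$values[1] - e$values[2]) <= tol * max(abs(e$values[1]), 1e-12)
    peaks[[i]] <- matrix(v / sqrt(sum(v^2)), 1, 3)
  }
  new_peak_field(peaks, tf$index, tf$dim, tf$voxel_size,
                 max_peaks = 1L, degenerate = degen)
}

# ---------------------------------------------------------------------------
# spherical harmonics (real, even orders; orthonormal basis)

# design matrix of even real SH up to order L at unit directions (n x 3)
.sh_basis <- function(dirs, L) {
  theta <- acos(pmin(1, pmax(-1, dirs[, 3])))
  phi <- atan2(dirs[, 2], dirs[, 1])
  x <- cos(theta)
  cols <- list()
  for (l in seq(0, L, by = 2)) {
    P <- pracma::legendre(l, x)           # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, ncol = length(x))
    for (m in -l:l) {
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  factorial(l - am) / factorial(l + am))
      base <- N * P[am + 1, ]
      cols[[length(cols) + 1]] <- if (m < 0) {
        sqrt(2) * base * sin(am * phi)
      } else if (m == 0) base else sqrt(2) * base * cos(m * phi)
    }
  }
  B <- do.call(cbind, cols)
  attr(B, "l_per_coef") <- unlist(lapply(seq(0, L, 2), function(l)
    rep(l, 2 * l + 1)))
  B
}

# Legendre polynomial at 0 for even l: (-1)^(l/2) (l-1)!! / l!!
.legendre_p0 <- function(l) {
  if (l == 0) return(1)
  k <- l / 2
  (-1)^k * prod(seq(1, l - 1, 2)) / prod(seq(2, l, 2))
}

.default_sh_order <- function(ndir, requested = NULL) {
  if (!is.null(requested)) return(as.integer(requested))
  L <- 8L
  while (L > 0 && (L + 1) * (L + 2) / 2 > ndir) L <- L - 2L
  L
}

# regularized SH fit + per-band scaling, evaluated on the tessellation.
# values: nvox x ndir matrix of spherical functions sampled at dirs.
.sh_transform <- function(values, dirs, tess, L, reg, band_scale) {
  B <- .sh_basis(dirs, L)
  lpc <- attr(B, "l_per_coef")
  ncoef <- ncol(B)
  if (nrow(B) < ncoef)
    stop(sprintf(
      "%d directions cannot support SH order %d (needs >= %d); reduce sh_order",
      nrow(B), L, ncoef))
  LB <- diag(lpc^2 * (lpc + 1)^2)        # Laplace-Beltrami penalty
  fit <- solve(crossprod(B) + reg * LB, t(B))   # ncoef x ndir
  scale <- vapply(lpc, band_scale, numeric(1))
  Btess <- .sh_basis(tess$vertices, L)
  coefs <- fit %*% t(values)             # ncoef x nvox
  t(Btess %*% (coefs * scale))           # nvox x nvert
}

#' Q-ball ODF via the Funk-Radon transform
#'
#' Fits even real spherical-harmonic coefficients to the normalized
#' single-shell signal \eqn{S/S_0} by Laplace-Beltrami-regularized least
#' squares, then applies the Funk-Radon transform analytically (each order-l
#' band scaled by \eqn{2\pi P_l(0)}) and evaluates the resulting ODF on the
#' tessellation vertices.
#'
#' @param dwi a shell-scheme `dwi_dataset`.
#' @param tess a [sphere_tessellation()].
#' @param sh_order even spherical-harmonic order; default 8 when the scheme
#'   supports it, else the largest feasible even order.
#' @param reg Laplace-Beltrami regularization weight.
#' @return An object of class `odf_field`: `values` (nvox x nvert), `tess`,
#'   `index`, `dim`, `voxel_size`, `method`.
#' @export
qbi_odf <- function(dwi, tess, sh_order = NULL, reg = 0.006) {
  if (dwi$scheme$kind != "shell")
    stop("qbi_odf requires a single-shell scheme")
  sch <- dwi$scheme
  dw <- !sch$is_b0
  L <- .default_sh_order(sum(dw), sh_order)
  ms <- .masked_signal(dwi)
  s0 <- rowMeans(ms$sig[, sch$is_b0, drop = FALSE])
  E <- ms$sig[, dw, drop = FALSE] / pmax(s0, .Machine$double.eps)
  vals <- .sh_transform(E, sch$grad[dw, , drop = FALSE], tess, L, reg,
                        function(l) 2 * pi * .legendre_p0(l))
  new_odf_field(vals, tess, ms$index, ms$dim, dwi$voxel_size, "qbi")
}

#' Solid-angle ("corrected") q-ball ODF
#'
#' The constant-solid-angle q-ball reconstruction: the signal is clamped into
#' (0, 1), double-log transformed \eqn{\ln(-\ln(S/S_0))}, fitted with even
#' spherical harmonics, and the Funk-Radon transform of its spherical
#' Laplacian added to the isotropic term:
#' \deqn{\psi = \frac{1}{4\pi} + \frac{1}{16\pi^2}
#'       \mathrm{FRT}\{\Delta_b \ln(-\ln E)\}.}
#' By construction this yields sharper ODFs than [qbi_odf()].
#'
#' @inheritParams qbi_odf
#' @param floor clamp bound: E is restricted to `[floor, 1 - floor]`.
#' @return an `odf_field` with method `"csa"`.
#' @export
csa_odf <- function(dwi, tess, sh_order = NULL, reg = 0.006, floor = 1e-4) {
  if (dwi$scheme$kind != "shell")
    stop("csa_odf requires a single-shell scheme")
  sch <- dwi$scheme
  dw <- !sch$is_b0
  L <- .default_sh_order(sum(dw), sh_order)
  ms <- .masked_signal(dwi)
  s0 <- rowMeans(ms$sig[, sch$is_b0, drop = FALSE])
  E <- ms$sig[, dw, drop = FALSE] / pmax(s0, .Machine$double.eps)
  E <- pmin(pmax(E, floor), 1 - floor)
  Y <- log(-log(E))
  vals <- .sh_transform(Y, sch$grad[dw, , drop = FALSE], tess, L, reg,
                        function(l) {
                          if (l == 0) 0 else
                            -l * (l + 1) * .legendre_p0(l) / (8 * pi)
                        })
  vals <- vals + 1 / (4 * pi)
  new_odf_field(vals, tess, ms$index, ms$dim, dwi$voxel_size, "csa")
}

#' DSI ODF by Fourier transform and radial projection
#'
#' The diffusion-spectrum reconstruction: per voxel, the hemisphere q-space
#' samples and their antipodal mirrors are placed on a centered
#' \eqn{(2R+1)^3} lattice, tapered by a radial Hanning window, zero-padded
#' into an \eqn{N^3} grid (N odd so the propagator has an unambiguous
#' center), and 3-D Fourier transformed; the propagator magnitude is then
#' radially projected onto the tessellation —
#' \eqn{ODF(u) = \sum_r w_r P(r u)} with trilinear interpolation.
#'
#' @param dwi a Cartesian-scheme `dwi_dataset`.
#' @param tess a [sphere_tessellation()].
#' @param grid_n odd FFT grid size. The default 25 zero-pads the signal
#'   lattice, which sinc-interpolates the propagator: on the native 17-grid
#'   the trilinear footprint of crossing fiber lobes overlaps at small radii
#'   and produces spurious diagonal maxima.
#' @param radii radial samples in grid units (scaled to `grid_n`; the
#'   default covers the informative part of the propagator while excluding
#'   the noise-dominated outermost shells).
#' @param hanning apply the Hanning window
#'   \eqn{w(|q|) = (1 + \cos(\pi |q| / (R + 1)))/2}.
#' @param r2_weight weight the radial sum by \eqn{r^2} (the solid-angle
#'   measure; the default, as the unweighted sum over-weights the poorly
#'   resolved small-radius shells).
#' @return an `odf_field` with method `"dsi"`.
#' @export
dsi_odf <- function(dwi, tess, grid_n = 25L, radii = 4:9, hanning = TRUE,
                    r2_weight = TRUE) {
  if (dwi$scheme$kind != "cartesian")
    stop("dsi_odf requires a Cartesian lattice scheme")
  if (grid_n %% 2 == 0) stop("grid_n must be odd")
  sch <- dwi$scheme
  R <- sch$lattice_radius
  if (max(radii) > (grid_n - 1) / 2)
    stop("radii exceed the FFT grid")
  q <- sch$qvec
  # full symmetric sample set: each non-origin sample plus its mirror
  nz <- rowSums(q^2) > 0
  qfull <- rbind(q, -q[nz, , drop = FALSE])
  src <- c(seq_len(nrow(q)), which(nz))
  w <- if (hanning)
    0.5 * (1 + cos(pi * sqrt(rowSums(qfull^2)) / (R + 1))) else
      rep(1, nrow(qfull))
  ctr <- (grid_n + 1) / 2
  # place each lattice sample at its circularly wrapped grid index; the
  # propagator at displacement r then sits at index (r mod N) + 1, and a
  # circular reorder recenters it on ctr exactly (N odd)
  wq <- qfull %% grid_n
  lin <- wq[, 1] + wq[, 2] * grid_n + wq[, 3] * grid_n^2 + 1
  reord <- ((seq_len(grid_n) - ctr) %% grid_n) + 1

  proj <- .radial_projection_matrix(tess, grid_n, radii, r2_weight)
  ms <- .masked_signal(dwi)
  nvox <- nrow(ms$sig)
  vals <- matrix(0, nvox, nrow(tess$vertices))
  grid <- array(0, c(grid_n, grid_n, grid_n))
  for (v in seq_len(nvox)) {
    grid[] <- 0
    grid[lin] <- ms$sig[v, src] * w
    P <- Mod(stats::fft(grid))[reord, reord, reord]  # centered propagator
    vals[v, ] <- as.vector(proj %*% as.vector(P))
  }
  new_odf_field(vals, tess, ms$index, ms$dim, dwi$voxel_size, "dsi")
}

# sparse matrix mapping a flattened grid_n^3 propagator to tessellation
# vertices by trilinear interpolation at radii r along each vertex direction
.radial_projection_matrix <- function(tess, grid_n, radii, r2_weight) {
  ctr <- (grid_n + 1) / 2
  verts <- tess$vertices
  ii <- jj <- xx <- list()
  for (r in radii) {
    p <- verts * r + ctr                  # 1-based fractional grid coords
    f0 <- floor(p)
    fr <- p - f0
    wr <- if (r2_weight) r^2 else 1
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      wt <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
        (if (cy) fr[, 2] else 1 - fr[, 2]) *
        (if (cz) fr[, 3] else 1 - fr[, 3]) * wr
      gx <- f0[, 1] + cx; gy <- f0[, 2] + cy; gz <- f0[, 3] + cz
      ok <- gx >= 1 & gx <= grid_n & gy >= 1 & gy <= grid_n &
        gz >= 1 & gz <= grid_n & wt > 0
      ii[[length(ii) + 1]] <- which(ok)
      jj[[length(jj) + 1]] <- (gx[ok] - 1) + (gy[ok] - 1) * grid_n +
        (gz[ok] - 1) * grid_n^2 + 1
      xx[[length(xx) + 1]] <- wt[ok]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nrow(verts), grid_n^3))
}

new_odf_field <- function(values, tess, index, dim, voxel_size, method) {
  structure(list(values = values, tess = tess, index = index, dim = dim,
                 voxel_size = voxel_size, method = method),
            class = "odf_field")
}

#' @export
print.odf_field <- function(x, ...) {
  cat(sprintf("<odf_field (%s): %d voxels x %d vertices>\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

new_peak_field <- function(peaks, index, dim, voxel_size, max_peaks,
                           degenerate = NULL) {
  structure(list(peaks = peaks, index = index, dim = dim,
                 voxel_size = voxel_size,
                 n_peaks = vapply(peaks, nrow, integer(1)),
                 max_peaks = as.integer(max_peaks),
                 degenerate = degenerate),
            class = "peak_field")
}

#' @export
print.peak_field <- function(x, ...) {
  cat(sprintf("<peak_field: %d voxels, n_v distribution: %s>\n",
              length(x$peaks),
              paste(names(table(x$n_peaks)), table(x$n_peaks),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Extract ODF peak directions
#'
#' Per voxel: min-max normalizes the ODF, takes as candidates the vertices
#' that are greater than or equal to all tessellation neighbors with a
#' normalized value of at least `rel_thresh`, merges antipodal duplicates
#' into single axial peaks, and greedily keeps the highest candidates subject
#' to a pairwise axial separation of at least `min_sep` degrees, up to
#' `max_peaks`. A constant ODF yields zero peaks.
#'
#' @param odf an `odf_field`.
#' @param rel_thresh relative threshold on the normalized ODF.
#' @param min_sep minimum axial separation between peaks, degrees.
#' @param max_peaks maximum number of peaks per voxel.
#' @return a `peak_field`: `peaks` (list of k x 3 unit axial vectors per
#'   voxel), `n_peaks`, `index`, `dim`, `voxel_size`.
#' @export
extract_peaks <- function(odf, rel_thresh = 0.4, min_sep = 25,
                          max_peaks = 3L) {
  tess <- odf$tess
  nb <- tess$neighbors
  ant <- tess$antipode
  verts <- tess$vertices
  upper <- which(seq_along(ant) < ant)   # one vertex per antipodal pair
  cos_sep <- cos(min_sep * pi / 180)
  n <- nrow(odf$values)
  peaks <- vector("list", n)
  for (v in seq_len(n)) {
    val <- odf$values[v, ]
    rng <- max(val) - min(val)
    if (rng <= 0 || !is.finite(rng)) { peaks[[v]] <- matrix(0, 0, 3); next }
    nv <- (val - min(val)) / rng
    # axial value: max of vertex and its antipode, evaluated on one hemisphere
    cand <- upper[vapply(upper, function(i) {
      a <- ant[i]
      is_max <- nv[i] >= max(nv[nb[[i]]]) || nv[a] >= max(nv[nb[[a]]])
      is_max && max(nv[i], nv[a]) >= rel_thresh
    }, logical(1))]
    if (!length(cand)) { peaks[[v]] <- matrix(0, 0, 3); next }
    ord <- cand[order(pmax(nv[cand], nv[ant[cand]]), decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (length(kept) >= max_peaks) break
      if (!length(kept) ||
          all(abs(verts[kept, , drop = FALSE] %*% verts[i, ]) < cos_sep))
        kept <- c(kept, i)
    }
    peaks[[v]] <- verts[kept, , drop = FALSE]
  }
  new_peak_field(peaks, odf$index, odf$dim, odf$voxel_size, max_peaks)
}

#' Write a peak field as a zero-padded NIfTI volume
#'
#' Peaks are stored as an x,y,z,3*max_peaks float volume (dir1_x, dir1_y,
#' dir1_z, dir2_x, ...), zero-padded for voxels with fewer peaks.
#'
#' @param pf a `peak_field`.
#' @param path output NIfTI path.
#' @return invisibly, the path.
#' @export
write_peaks_nifti <- function(pf, path) {
  arr <- array(0, c(pf$dim, 3L * pf$max_peaks))
  flat <- matrix(arr, prod(pf$dim), 3L * pf$max_peaks)
  for (v in seq_along(pf$peaks)) {
    p <- pf$peaks[[v]]
    if (nrow(p)) flat[pf$index[v], seq_len(3 * nrow(p))] <- as.vector(t(p))
  }
  arr <- array(flat, c(pf$dim, 3L * pf$max_peaks))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(pf$voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
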