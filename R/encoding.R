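#' Diffusion encoding schemes
#'
#' A `qscheme` is an ordered set of q-space samples, each a lattice vector
#' (Cartesian DSI schemes) or a unit direction (shell schemes) with an
#' associated b-value. Constructors are [cartesian_hemisphere_scheme()] and
#' [uniform_sphere_scheme()].
#'
#' @param qvec matrix of q-space sample vectors (rows), lattice units for
#'   Cartesian schemes, unit vectors for shell schemes.
#' @param bval numeric vector of b-values in s/mm^2, one per sample.
#' @param kind `"cartesian"` or `"shell"`.
#' @param b_max maximum b-value of the scheme in s/mm^2.
#' @param lattice_radius integer lattice radius (Cartesian schemes only).
#' @return An object of class `qscheme` with components `qvec` (n x 3 matrix),
#'   `bval`, `grad` (n x 3 unit gradient matrix, zero rows for b0 samples),
#'   `is_b0` (logical), `kind`, `b_max` and, for Cartesian schemes,
#'   `lattice_radius`.
#' @keywords internal
new_qscheme <- function(qvec, bval, kind, b_max, lattice_radius = NULL) {
  qvec <- as.matrix(qvec)
  dimnames(qvec) <- NULL
  storage.mode(qvec) <- "double"
  stopifnot(ncol(qvec) == 3L, length(bval) == nrow(qvec))
  is_b0 <- bval == 0
  nrm <- sqrt(rowSums(qvec^2))
  grad <- qvec
  grad[!is_b0, ] <- qvec[!is_b0, , drop = FALSE] / nrm[!is_b0]
  grad[is_b0, ] <- 0
  if (anyDuplicated(qvec))
    stop("duplicate q-space samples in scheme")
  if (!any(is_b0))
    stop("scheme must contain at least one b0 sample")
  structure(
    list(qvec = qvec, bval = as.numeric(bval), grad = grad, is_b0 = is_b0,
         kind = match.arg(kind, c("cartesian", "shell")),
         b_max = b_max, lattice_radius = lattice_radius),
    class = "qscheme")
}

#' @export
print.qscheme <- function(x, ...) {
  cat(sprintf("<qscheme: %s, %d samples (%d b0), b_max = %g s/mm^2%s>\n",
              x$kind, nrow(x$qvec), sum(x$is_b0), x$b_max,
              if (!is.null(x$lattice_radius))
                sprintf(", lattice radius %d", x$lattice_radius) else ""))
  invisible(x)
}

#' Number of samples in a scheme
#' @param scheme a `qscheme`.
#' @return integer sample count (including b0 samples).
#' @export
n_samples <- function(scheme) nrow(scheme$qvec)

#' Cartesian-lattice hemisphere encoding scheme (DSI)
#'
#' Samples q-space at the points of a cubic integer lattice inside a
#' hemisphere of radius `R` lattice units: the origin (b0) plus exactly one
#' member of each antipodal pair of lattice points with \eqn{|q|^2 \le R^2}.
#' Because the diffusion-weighted signal is antipodally symmetric in q, one
#' hemisphere suffices; the kept representative is the one with
#' \eqn{q_z > 0}, or \eqn{q_z = 0, q_y > 0}, or \eqn{q_z = q_y = 0, q_x > 0}.
#' At fixed diffusion time the b-value grows quadratically with \eqn{|q|},
#' so each sample carries \eqn{b = b_{max} |q|^2 / R^2}.
#'
#' With `R = 5` this yields the classical 258-sample DSI scheme; `R = 4`
#' yields 129 samples.
#'
#' @param R positive integer lattice radius.
#' @param b_max maximum b-value in s/mm^2 (attained on the outer shell).
#' @return a [`qscheme`][new_qscheme] of kind `"cartesian"`.
#' @examples
#' n_samples(cartesian_hemisphere_scheme(5, 8000))  # 258
#' n_samples(cartesian_hemisphere_scheme(4, 6400))  # 129
#' @export
cartesian_hemisphere_scheme <- function(R, b_max) {
  if (length(R) != 1L || R < 1 || R != round(R))
    stop("R must be a positive integer")
  if (length(b_max) != 1L || b_max <= 0)
    stop("b_max must be positive")
  R <- as.integer(R)
  g <- as.matrix(expand.grid(x = -R:R, y = -R:R, z = -R:R))
  g <- g[rowSums(g^2) <= R^2, , drop = FALSE]
  keep <- g[, 3] > 0 |
    (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0)
  q <- g[keep, , drop = FALSE]
  # origin first, then by |q|^2 then lexicographic, for a stable sample order
  ord <- order(rowSums(q^2), q[, 3], q[, 2], q[, 1])
  q <- q[ord, , drop = FALSE]
  dimnames(q) <- NULL
  bval <- b_max * rowSums(q^2) / R^2
  new_qscheme(q, bval, "cartesian", b_max, lattice_radius = R)
}

#' b-value of a Cartesian lattice sample
#'
#' Quadratic b-q relation at fixed diffusion time:
#' \eqn{b = b_{max} |q|^2 / R^2}.
#'
#' @param qvec integer lattice 3-vector.
#' @param R lattice radius.
#' @param b_max maximum b-value in s/mm^2.
#' @return b-value in s/mm^2.
#' @export
bvalue_of <- function(qvec, R, b_max) {
  q2 <- sum(qvec^2)
  if (q2 > R^2) stop("|qvec| exceeds the lattice radius R")
  b_max * q2 / R^2
}

#' Single-shell encoding scheme with quasi-uniform directions
#'
#' One b0 sample plus `n_total - 1` unit gradient directions quasi-uniformly
#' distributed as axes over the sphere, at a single b-value — the acquisition
#' geometry of HARDI/QBI (e.g. 257 samples at b = 3000 s/mm^2) and DTI
#' schemes (65 or 21 samples at b = 1000 s/mm^2).
#'
#' Directions are initialized on a hemispherical Fibonacci spiral and refined
#' by electrostatic repulsion acting on axes (antipodally symmetric Coulomb
#' energy), the standard construction for diffusion gradient tables. The
#' result is deterministic for a given `seed`, which only randomizes the
#' spiral's azimuthal offset.
#'
#' @param n_total total number of samples including the single b0.
#' @param b shell b-value in s/mm^2.
#' @param seed integer seed for the azimuthal offset.
#' @param repulsion_iter iterations of axial electrostatic refinement.
#' @return a [`qscheme`][new_qscheme] of kind `"shell"`.
#' @export
uniform_sphere_scheme <- function(n_total, b, seed = 1L, repulsion_iter = 400L) {
  if (length(n_total) != 1L || n_total < 2 || n_total != round(n_total))
    stop("n_total must be an integer >= 2")
  if (b <= 0) stop("b must be positive")
  n <- as.integer(n_total) - 1L
  dirs <- fibonacci_hemisphere(n, seed)
  if (n >= 3 && repulsion_iter > 0)
    dirs <- repel_axes(dirs, repulsion_iter)
  q <- rbind(c(0, 0, 0), dirs)
  new_qscheme(q, c(0, rep(b, n)), "shell", b)
}

# Fibonacci spiral on the upper hemisphere (axes, so one hemisphere is the
# natural domain). seed only rotates the spiral in azimuth.
fibonacci_hemisphere <- function(n, seed) {
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  phi0 <- stats::runif(1, 0, 2 * pi)
  k <- seq_len(n)
  z <- (k - 0.5) / n                      # uniform in z over (0, 1]
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))                # golden angle
  az <- phi0 + k * ga
  cbind(r * cos(az), r * sin(az), z)
}

# Descent on the axial Coulomb energy sum_{i<j} 1/sin(theta_ij), theta_ij
# the angle between axes; the step is normalized by the largest force and
# decays, which keeps near-collisions stable. Axes are canonicalized to the
# z >= 0 hemisphere at the end for reproducible signs.
repel_axes <- function(dirs, iters, step0 = 0.5) {
  for (it in seq_len(iters)) {
    G <- tcrossprod(dirs)                 # cos angles, signed
    A <- abs(G)
    diag(A) <- 0
    s2 <- pmax(1 - A^2, 1e-9)             # sin^2 of axial angle
    W <- sign(G) * A / s2^1.5
    diag(W) <- 0
    F <- -W %*% dirs                      # repulsive: minus energy gradient
    F <- F - dirs * rowSums(F * dirs)     # tangent projection
    mx <- max(sqrt(rowSums(F^2)))
    if (mx < 1e-12) break
    dirs <- dirs + (step0 / (1 + it / 20) / mx) * F
    dirs <- dirs / sqrt(rowSums(dirs^2))
  }
  flip <- dirs[, 3] < 0 |
    (dirs[, 3] == 0 & dirs[, 2] < 0) |
    (dirs[, 3] == 0 & dirs[, 2] == 0 & dirs[, 1] < 0)
  dirs[flip, ] <- -dirs[flip, , drop = FALSE]
  dirs
}

#' Minimum pairwise axial angle of a scheme's gradient set
#' @param scheme a `qscheme`.
#' @return smallest angle in degrees between any two gradient axes.
#' @export
min_axial_angle <- function(scheme) {
  g <- scheme$grad[!scheme$is_b0, , drop = FALSE]
  if (nrow(g) < 2) return(Inf)
  cosang <- abs(tcrossprod(g))
  diag(cosang) <- 0
  acos(pmin(1, max(cosang))) * 180 / pi
}

#' Write a scheme as FSL-dialect bvals/bvecs text files
#'
#' `bvals` holds one row of b-values; `bvecs` three rows (x, y, z components
#' of the unit gradients, zeros for b0 samples).
#'
#' @param scheme a `qscheme`.
#' @param bvals_path,bvecs_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(scheme, bvals_path, bvecs_path) {
  writeLines(paste(format(scheme$bval, trim = TRUE, scientific = FALSE),
                   collapse = " "), bvals_path)
  vec <- t(scheme$grad)
  writeLines(apply(vec, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecs_path)
  invisible(c(bvals_path, bvecs_path))
}

#' Read an FSL-dialect gradient table into a shell scheme
#'
#' Rows with b = 0 become b0 samples; non-unit gradient rows are renormalized
#' with a warning. The scheme kind is `"shell"` (a Cartesian lattice cannot
#' be recovered from a gradient table alone); `b_max` is the largest b-value.
#'
#' @param bvals_path,bvecs_path input file paths.
#' @return a `qscheme`.
#' @export
read_bvals_bvecs <- function(bvals_path, bvecs_path) {
  bval <- scan(bvals_path, quiet = TRUE)
  vec <- matrix(scan(bvecs_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(vec) != length(bval))
    stop(sprintf("bvals has %d entries but bvecs has %d columns",
                 length(bval), ncol(vec)))
  g <- t(vec)
  nrm <- sqrt(rowSums(g^2))
  dw <- bval > 0
  if (any(abs(nrm[dw] - 1) > 1e-6)) {
    warning("non-unit gradient rows renormalized")
    g[dw, ] <- g[dw, , drop = FALSE] / nrm[dw]
  }
  g[!dw, ] <- 0
  new_qscheme(g, bval, "shell", max(bval))
}
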