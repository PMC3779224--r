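# uniform peak field: every voxel of the grid carries the same axial vector
uniform_peak_field <- function(dim, voxel_size, dir, wm) {
  idx <- which(wm)
  dwiconn:::new_peak_field(
    rep(list(matrix(dir / sqrt(sum(dir^2)), 1, 3)), length(idx)),
    idx, dim, rep(voxel_size, length.out = 3), max_peaks = 1L)
}

test_that("seed generation follows the 32 * n_v law and stays in-voxel", {
  ph <- phantom_cross90
  dwi <- simulate_dwi(ph, scheme_dsi_q5, snr = Inf)
  pk <- extract_peaks(dsi_odf(dwi, tess3))
  params <- tracking_params(rng_seed = 3)
  seeds <- generate_seeds(pk, ph$wm_mask, params)
  expect_equal(nrow(seeds), 32L * sum(pk$n_peaks))
  # seeds fall inside their generating voxel's bounds
  vox <- floor(seeds[, 1:3] %*% diag(1 / ph$voxel_size))
  expect_true(all(vox >= 0) && all(sweep(vox, 2, ph$dim, `<`)))
  # voxel with n_v = 2 receives 64 seeds
  two <- which(pk$n_peaks == 2)[1]
  lin <- pk$index[two]
  counts <- table(vox[, 1] + vox[, 2] * ph$dim[1] +
                    vox[, 3] * ph$dim[1] * ph$dim[2] + 1)
  expect_equal(unname(counts[as.character(lin)]), 64)
  # masked-out voxels yield nothing
  none <- generate_seeds(pk, array(FALSE, ph$dim), params)
  expect_equal(nrow(none), 0)
  # determinism
  expect_identical(seeds, generate_seeds(pk, ph$wm_mask, params))
})

test_that("propagation walks a uniform corridor end to end", {
  # 30 x 6 x 6 mm WM corridor of 1 mm voxels, +x field everywhere
  dim <- c(30L, 6L, 6L)
  wm <- array(TRUE, dim)
  pf <- uniform_peak_field(dim, 1, c(1, 0, 0), wm)
  params <- tracking_params(step = 1)
  line <- propagate(c(15, 3, 3, 1, 0, 0), pf, wm, params)
  len <- (nrow(line) - 1) * params$step
  expect_lt(abs(len - 30), 2 * params$step)
  expect_equal(diff(line[, 1]), rep(1, nrow(line) - 1))
  # consecutive spacing equals the step
  spac <- sqrt(rowSums((line[-1, ] - line[-nrow(line), ])^2))
  expect_equal(spac, rep(params$step, length(spac)), tolerance = 1e-6)
  # seed outside WM: nothing
  expect_null(propagate(c(-5, 3, 3, 1, 0, 0), pf, wm, params))
})

test_that("the 60 degrees/mm turn limit stops walks at a 90-degree
           interface", {
  dim <- c(30L, 6L, 6L)
  wm <- array(TRUE, dim)
  idx <- which(wm)
  ijk <- arrayInd(idx, dim)
  dirs <- lapply(seq_along(idx), function(k)
    if (ijk[k, 1] <= 15) matrix(c(1, 0, 0), 1, 3) else matrix(c(0, 1, 0), 1, 3))
  pf <- dwiconn:::new_peak_field(dirs, idx, dim, c(1, 1, 1), 1L)
  line <- propagate(c(5, 3, 3, 1, 0, 0), pf, wm, tracking_params())
  # forward walk must stop at the x = 15/16 interface, never entering y-land
  expect_lt(max(line[, 1]), 16.5)
  expect_equal(max(abs(line[, 2] - 3)), 0)
  # a voxel with no direction stops the walk there
  dirs2 <- dirs
  dirs2[ijk[, 1] > 15] <- list(matrix(0, 0, 3))
  pf2 <- dwiconn:::new_peak_field(dirs2, idx, dim, c(1, 1, 1), 1L)
  line2 <- propagate(c(5, 3, 3, 1, 0, 0), pf2, wm, tracking_params())
  expect_lt(max(line2[, 1]), 17.5)
})

test_that("fiber filtering enforces length bounds and endpoint ROIs", {
  roi <- array(0L, c(12, 10, 10))
  roi[1, , ] <- 1L; roi[5, , ] <- 2L; roi[11, , ] <- 2L
  mk <- function(from, by, n) cbind(seq(from, by = by, length.out = n),
                                    5, 5)
  set <- structure(list(
    streamlines = list(mk(0.5, 1, 5),     # 4 mm, ROI to ROI: too short
                       mk(0.5, 1, 11),    # 10 mm, endpoints in ROI 1 and 2
                       cbind(0.5, 5, 5)[rep(1, 251), ],  # 250 mm: too long
                       mk(1.5, 1, 8)),    # one endpoint in background
    count = 4L, endpoint_labels = NULL, voxel_size = c(1, 1, 1),
    dim = c(12L, 10L, 10L), params = NULL, provenance = list()),
    class = "streamline_set")
  out <- filter_fibers(set, roi, tracking_params())
  expect_equal(out$count, 1L)
  expect_equal(nrow(out$streamlines[[1]]), 11)
  expect_equal(out$endpoint_labels, cbind(1L, 2L), ignore_attr = TRUE)
  empty <- filter_fibers(structure(list(
    streamlines = list(), count = 0L, endpoint_labels = NULL,
    voxel_size = c(1, 1, 1), dim = c(12L, 10L, 10L), params = NULL,
    provenance = list()), class = "streamline_set"), roi, tracking_params())
  expect_equal(empty$count, 0L)
})

test_that("whole-phantom tracking connects the true pair, respects all
           filters, and is deterministic", {
  ph <- phantom_straight
  dwi <- simulate_dwi(ph, scheme_dti21, snr = Inf)
  pk <- tensor_peaks(fit_tensor(dwi))
  params <- tracking_params(rng_seed = 7)
  ts <- track_wholebrain(pk, ph$wm_mask, ph$roi_labels, params)
  expect_gt(ts$count, 0)
  lens <- fiber_lengths(ts)
  expect_true(all(lens >= params$min_len & lens <= params$max_len))
  expect_true(all(ts$endpoint_labels > 0))
  # >= 95% of retained fibers connect the two true ROIs
  ok <- rowSums(ts$endpoint_labels == 1) == 1 &
    rowSums(ts$endpoint_labels == 2) == 1
  expect_gte(mean(ok), 0.95)
  # per-step turning angle within the limit for sampled fibers
  max_cos <- cos(params$max_turn * params$step * pi / 180 + 1e-9)
  for (m in ts$streamlines[seq(1, ts$count, length.out = 20)]) {
    segs <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
    segs <- segs / sqrt(rowSums(segs^2))
    if (nrow(segs) > 1) {
      cosang <- rowSums(segs[-1, , drop = FALSE] *
                          segs[-nrow(segs), , drop = FALSE])
      expect_true(all(cosang >= max_cos))
    }
  }
  # bit-identical rerun
  ts2 <- track_wholebrain(pk, ph$wm_mask, ph$roi_labels, params)
  expect_identical(ts$streamlines, ts2$streamlines)
  # isotropic phantom (no peaks anywhere) yields an empty set
  nopk <- dwiconn:::new_peak_field(
    rep(list(matrix(0, 0, 3)), length(ph$wm_index)),
    ph$wm_index, ph$dim, ph$voxel_size, 1L)
  empty <- track_wholebrain(nopk, ph$wm_mask, ph$roi_labels, params)
  expect_equal(empty$count, 0L)
})

test_that("crossing phantom: DSI peaks traverse the crossing, DTI peaks do
           not", {
  ph <- phantom_cross90
  params <- tracking_params(rng_seed = 21)
  rate <- function(pk) {
    ts <- track_wholebrain(pk, ph$wm_mask, ph$roi_labels, params)
    if (ts$count == 0) return(0)
    good <- (ts$endpoint_labels[, 1] %in% c(1, 2) &
               ts$endpoint_labels[, 2] %in% c(1, 2) &
               ts$endpoint_labels[, 1] != ts$endpoint_labels[, 2]) |
      (ts$endpoint_labels[, 1] %in% c(3, 4) &
         ts$endpoint_labels[, 2] %in% c(3, 4) &
         ts$endpoint_labels[, 1] != ts$endpoint_labels[, 2])
    mean(good)
  }
  rates <- vapply(1:5, function(seed) {
    dsi <- simulate_dwi(ph, scheme_dsi_q5, snr = 20,
                        seed = derive_seed(seed, "dsi"))
    dti <- simulate_dwi(ph, scheme_dti21, snr = 20,
                        seed = derive_seed(seed, "dti"))
    c(rate(extract_peaks(dsi_odf(dsi, tess3))),
      rate(tensor_peaks(fit_tensor(dti))))
  }, numeric(2))
  expect_true(all(rates[1, ] > rates[2, ]))
})
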