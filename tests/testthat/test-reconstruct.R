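test_that("tessellation is antipodally complete with a connected graph", {
  expect_equal(nrow(tess3$vertices), 642)
  expect_equal(sqrt(rowSums(tess3$vertices^2)), rep(1, 642),
               tolerance = 1e-9)
  expect_equal(tess3$vertices[tess3$antipode, ], -tess3$vertices,
               ignore_attr = TRUE)
  g <- igraph::graph_from_edgelist(
    cbind(rep(seq_along(tess3$neighbors), lengths(tess3$neighbors)),
          unlist(tess3$neighbors)), directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_lt(tess3$edge_deg, 12)
})

test_that("tensor fit recovers a noiseless tensor to machine precision", {
  ph <- phantom_straight
  dwi <- simulate_dwi(ph, scheme_dti21, snr = Inf)
  tf <- fit_tensor(dwi)
  for (j in c(1, 10, 50)) {
    D <- tf$coef[j, ]
    expect_equal(D[1], 1.7e-3, tolerance = 1e-9)
    expect_equal(D[2], 0.3e-3, tolerance = 1e-9)
    expect_equal(D[3], 0.3e-3, tolerance = 1e-9)
    expect_equal(D[4:6], rep(0, 3), tolerance = 1e-12, ignore_attr = TRUE)
  }
  # insufficient scheme errors
  sixdir <- dwiconn:::new_qscheme(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                        c(0, 0, 1), c(1, 1, 0), c(1, 0, 1),
                                        c(0, 1, 1)),
                                  c(0, rep(1000, 6)), "shell", 1000)
  d2 <- simulate_dwi(ph, sixdir, snr = Inf)
  expect_silent(fit_tensor(d2))          # 6 directions is the minimum
  few <- dwiconn:::new_qscheme(rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 1000),
                               "shell", 1000)
  expect_error(fit_tensor(simulate_dwi(ph, few, snr = Inf)), "6")
})

test_that("FA and ADC follow the eigenvalue formulas", {
  iso <- c(1e-3, 1e-3, 1e-3, 0, 0, 0)
  tf <- structure(list(coef = rbind(iso, c(1.7e-3, 0.3e-3, 0.3e-3, 0, 0, 0)),
                       index = 1:2, valid = c(TRUE, TRUE), dim = c(2, 1, 1),
                       voxel_size = c(1, 1, 1)), class = "tensor_field")
  m <- fa_adc(tf)
  expect_equal(m$fa[1], 0, tolerance = 1e-9)
  expect_equal(m$adc[1], 1e-3, tolerance = 1e-12)
  # frozen from sqrt(3/2) * ||lambda - mean|| / ||lambda||
  expect_equal(m$fa[2], 0.7990222, tolerance = 1e-6)
  expect_equal(m$adc[2], 0.7667e-3, tolerance = 1e-4)
  # single nonzero eigenvalue: FA = 1
  tf$coef[1, ] <- c(1e-3, 0, 0, 0, 0, 0)
  expect_equal(fa_adc(tf)$fa[1], 1, tolerance = 1e-9)
})

test_that("tensor peaks align with the principal axis, ties are flagged", {
  ph <- phantom_straight
  tf <- fit_tensor(simulate_dwi(ph, scheme_dti21, snr = Inf))
  pk <- tensor_peaks(tf)
  expect_true(all(pk$n_peaks == 1))
  errs <- vapply(pk$peaks, function(p) axial_angle(p[1, ], c(1, 0, 0)),
                 numeric(1))
  expect_lt(max(errs), 1e-5)
  # prolate tensor along (1,1,0)/sqrt(2): rotation equivariance of the fit
  axis <- c(1, 1, 0) / sqrt(2)
  ph2 <- build_phantom("custom", bundles = list(bundle_spec(
    rbind(c(9, 9, 29) , c(49, 49, 29)), radius = 3)),
    grid_dim = c(29, 29, 29), voxel_size = 2)
  pk2 <- tensor_peaks(fit_tensor(simulate_dwi(ph2, scheme_dti21, snr = Inf)))
  errs2 <- vapply(pk2$peaks, function(p) axial_angle(p[1, ], axis),
                  numeric(1))
  expect_lt(max(errs2), 1e-4)
  # isotropic voxel: one peak, flagged degenerate
  iso <- structure(list(coef = rbind(c(1e-3, 1e-3, 1e-3, 0, 0, 0)),
                        index = 1L, valid = TRUE, dim = c(1, 1, 1),
                        voxel_size = c(1, 1, 1)), class = "tensor_field")
  pki <- tensor_peaks(iso)
  expect_equal(pki$n_peaks, 1L)
  expect_true(pki$degenerate[1])
})

test_that("DSI ODF recovers single fibers and resolves the 90-degree
           crossing; isotropic signal gives a flat ODF", {
  dwi <- simulate_dwi(phantom_straight, scheme_dsi_q5, snr = Inf)
  odf <- dsi_odf(dwi, tess3)
  # antipodal symmetry of every voxel's ODF
  expect_equal(odf$values, odf$values[, odf$tess$antipode],
               tolerance = 1e-6, ignore_attr = TRUE)
  am <- apply(odf$values, 1, which.max)
  errs <- vapply(am, function(i)
    axial_angle(tess3$vertices[i, ], c(1, 0, 0)), numeric(1))
  expect_lt(max(errs), 12)
  # isotropic voxel: coefficient of variation below 2%
  iso_truth <- build_phantom("custom", bundles = list(bundle_spec(
    rbind(c(9, 29, 29), c(49, 29, 29)), radius = 3,
    diffusivities = c(1e-3, 1e-3))), grid_dim = c(29, 29, 29),
    voxel_size = 2)
  iso_odf <- dsi_odf(simulate_dwi(iso_truth, scheme_dsi_q5, snr = Inf), tess3)
  cv <- apply(iso_odf$values, 1, function(v) stats::sd(v) / mean(v))
  expect_lt(max(cv), 0.02)
  # 90-degree crossing: two peaks near the two true axes
  dwic <- simulate_dwi(phantom_cross90, scheme_dsi_q5, snr = Inf)
  pk <- extract_peaks(dsi_odf(dwic, tess3))
  two <- which(vapply(seq_along(phantom_cross90$dirs), function(j)
    nrow(phantom_cross90$dirs[[j]]) == 2, logical(1)))
  for (j in two) {
    expect_equal(pk$n_peaks[j], 2L)
    errs <- c(axial_angle(pk$peaks[[j]][1, ], phantom_cross90$dirs[[j]][1, ]),
              axial_angle(pk$peaks[[j]][1, ], phantom_cross90$dirs[[j]][2, ]))
    expect_lt(min(errs), 12)
  }
  expect_error(dsi_odf(simulate_dwi(phantom_straight, scheme_qbi, snr = Inf),
                       tess3), "Cartesian")
})

test_that("QBI ODF: single-fiber recovery, flat on isotropic, crossing at
           60 degrees resolved", {
  dwi <- simulate_dwi(phantom_straight, scheme_qbi, snr = Inf)
  odf <- qbi_odf(dwi, tess3)
  expect_equal(odf$values, odf$values[, odf$tess$antipode],
               tolerance = 1e-6, ignore_attr = TRUE)
  am <- apply(odf$values, 1, which.max)
  errs <- vapply(am, function(i)
    axial_angle(tess3$vertices[i, ], c(1, 0, 0)), numeric(1))
  expect_lt(max(errs), 12)
  # isotropic: constant within 1% relative
  iso_truth <- build_phantom("custom", bundles = list(bundle_spec(
    rbind(c(9, 29, 29), c(49, 29, 29)), radius = 3,
    diffusivities = c(1e-3, 1e-3))), grid_dim = c(29, 29, 29),
    voxel_size = 2)
  iso_odf <- qbi_odf(simulate_dwi(iso_truth, scheme_qbi, snr = Inf), tess3)
  rel <- apply(iso_odf$values, 1, function(v) (max(v) - min(v)) / mean(v))
  expect_lt(max(rel), 0.01)
  # 60-degree crossing
  cr60 <- build_phantom("crossing", angle_deg = 60)
  pk <- extract_peaks(qbi_odf(simulate_dwi(cr60, scheme_qbi, snr = Inf),
                              tess3))
  two <- which(vapply(seq_along(cr60$dirs), function(j)
    nrow(cr60$dirs[[j]]) == 2, logical(1)))
  hits <- 0
  for (j in two) {
    if (pk$n_peaks[j] != 2) next
    e1 <- min(axial_angle(pk$peaks[[j]][1, ], cr60$dirs[[j]][1, ]),
              axial_angle(pk$peaks[[j]][1, ], cr60$dirs[[j]][2, ]))
    e2 <- min(axial_angle(pk$peaks[[j]][2, ], cr60$dirs[[j]][1, ]),
              axial_angle(pk$peaks[[j]][2, ], cr60$dirs[[j]][2, ]))
    if (e1 < 15 && e2 < 15) hits <- hits + 1
  }
  expect_gte(hits / length(two), 0.8)
  expect_error(qbi_odf(simulate_dwi(phantom_straight, scheme_dsi_q5,
                                    snr = Inf), tess3), "shell")
  expect_error(qbi_odf(dwi, tess3, sh_order = 30), "order")
})

test_that("solid-angle QBI is sharper than standard QBI and still accurate", {
  dwi <- simulate_dwi(phantom_straight, scheme_qbi, snr = Inf)
  q <- qbi_odf(dwi, tess3)
  cs <- csa_odf(dwi, tess3)
  expect_equal(cs$values, cs$values[, cs$tess$antipode],
               tolerance = 1e-6, ignore_attr = TRUE)
  am <- apply(cs$values, 1, which.max)
  errs <- vapply(am, function(i)
    axial_angle(tess3$vertices[i, ], c(1, 0, 0)), numeric(1))
  expect_lt(max(errs), 12)
  sharp <- function(v) (max(v) - min(v)) / mean(v)
  for (j in c(1, 20, 80))
    expect_gt(sharp(cs$values[j, ]), sharp(q$values[j, ]))
  # isotropic signal: constant within 1%
  iso_truth <- build_phantom("custom", bundles = list(bundle_spec(
    rbind(c(9, 29, 29), c(49, 29, 29)), radius = 3,
    diffusivities = c(1e-3, 1e-3))), grid_dim = c(29, 29, 29),
    voxel_size = 2)
  iso <- csa_odf(simulate_dwi(iso_truth, scheme_qbi, snr = Inf), tess3)
  rel <- apply(iso$values, 1, function(v) (max(v) - min(v)) / mean(v))
  expect_lt(max(rel), 0.01)
})

test_that("peak extraction: delta, constant and threshold behavior", {
  n <- nrow(tess3$vertices)
  mk_odf <- function(vals) dwiconn:::new_odf_field(
    matrix(vals, 1, n), tess3, 1L, c(1, 1, 1), c(1, 1, 1), "dsi")
  # delta at one antipodal pair: exactly one axial peak there
  v <- numeric(n); v[5] <- 1; v[tess3$antipode[5]] <- 1
  pk <- extract_peaks(mk_odf(v))
  expect_equal(pk$n_peaks, 1L)
  expect_lt(axial_angle(pk$peaks[[1]][1, ], tess3$vertices[5, ]), 1e-9)
  # constant ODF: zero peaks
  expect_equal(extract_peaks(mk_odf(rep(2, n)))$n_peaks, 0L)
  # secondary lobe below rel_thresh is suppressed
  v2 <- numeric(n); v2[5] <- 1; v2[tess3$antipode[5]] <- 1
  far <- which.max(apply(tess3$vertices, 1, function(u)
    min(axial_angle(u, tess3$vertices[5, ]))))
  v2[far] <- 0.2; v2[tess3$antipode[far]] <- 0.2
  expect_equal(extract_peaks(mk_odf(v2), rel_thresh = 0.4)$n_peaks, 1L)
  expect_equal(extract_peaks(mk_odf(v2), rel_thresh = 0.1)$n_peaks, 2L)
})

test_that("rotation equivariance: a vertex-aligned rotation rotates the
           recovered peaks for all three reconstructions", {
  # 90-degree rotation about z maps the tessellation's axes setup: compare
  # x-aligned and y-aligned bundles
  ph_x <- phantom_straight
  ph_y <- build_phantom("custom", bundles = list(bundle_spec(
    rbind(c(29, 9, 29), c(29, 49, 29)), radius = 3)),
    grid_dim = c(29, 29, 29), voxel_size = 2)
  for (setup in list(list(scheme_dsi_q5, "dsi"), list(scheme_qbi, "qbi"),
                     list(scheme_dti21, "tensor"))) {
    px <- reconstruct_peaks(simulate_dwi(ph_x, setup[[1]], snr = Inf),
                            setup[[2]], tess = tess3)
    py <- reconstruct_peaks(simulate_dwi(ph_y, setup[[1]], snr = Inf),
                            setup[[2]], tess = tess3)
    ex <- median(vapply(px$peaks[px$n_peaks == 1], function(p)
      axial_angle(p[1, ], c(1, 0, 0)), numeric(1)))
    ey <- median(vapply(py$peaks[py$n_peaks == 1], function(p)
      axial_angle(p[1, ], c(0, 1, 0)), numeric(1)))
    expect_lt(ex, 10)
    expect_lt(ey, 10)
    expect_lt(abs(ex - ey), 10)
  }
})
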