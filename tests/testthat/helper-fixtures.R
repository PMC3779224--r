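# Shared fixtures, built once per test run. Everything is generated in code;
# the only file fixture is the packaged connection-count CSV.

tess3 <- sphere_tessellation(3)

# schemes matching the compared acquisition geometries
scheme_dsi_q5 <- cartesian_hemisphere_scheme(5, 8000)
scheme_dsi_q4 <- cartesian_hemisphere_scheme(4, 6400)
scheme_qbi <- uniform_sphere_scheme(257, 3000, seed = 11)
scheme_dti65 <- uniform_sphere_scheme(65, 1000, seed = 12)
scheme_dti21 <- uniform_sphere_scheme(21, 1000, seed = 13)

phantom_straight <- build_phantom("straight")
phantom_cross90 <- build_phantom("crossing", angle_deg = 90)

# angle between two axial unit vectors, degrees
axial_angle <- function(a, b) acos(pmin(1, abs(sum(a * b)))) * 180 / pi

# noiseless single-sample scheme along an arbitrary gradient, for
# closed-form signal checks
two_sample_scheme <- function(g, b) {
  g <- g / sqrt(sum(g^2))
  dwiconn:::new_qscheme(rbind(c(0, 0, 0), g), c(0, b), "shell", b)
}

wm_voxel_coord <- function(truth, j = 1) arrayInd(truth$wm_index[j], truth$dim)

signal_at <- function(dwi, ijk) dwi$signal[ijk[1], ijk[2], ijk[3], ]
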