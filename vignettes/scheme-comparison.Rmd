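---
title: "Comparing diffusion encoding schemes on known-truth phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing diffusion encoding schemes on known-truth phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwiconn)
```

## The problem

Structural connectomics counts the streamline "fibers" that deterministic
tractography draws between pairs of gray-matter regions, and a central
methodological question is how much that count depends on the diffusion
encoding scheme: a 258-sample Cartesian q-space acquisition (DSI), a
single-shell high-angular-resolution acquisition reconstructed by q-ball
(QBI), or a low-b tensor acquisition (DTI). With in vivo data there is no
ground truth, so `dwiconn` rebuilds the whole comparison on synthetic fiber
phantoms where the true connectivity is known by construction, and ships the
comparison statistics that operate on connection-count tables.

The pipeline is the classical four-stage chain: encoding scheme →
diffusion-weighted signal → per-voxel orientations → streamline tractography
→ ROI connection matrix, plus a statistics layer.

## Encoding schemes

`cartesian_hemisphere_scheme(R, b_max)` enumerates the integer lattice
points with $|q|^2 \le R^2$ and keeps the origin plus one member of each
antipodal pair ($q_z>0$, or $q_z=0,q_y>0$, or $q_z=q_y=0,q_x>0$ — the
choice is immaterial because the diffusion signal is antipodally symmetric,
so any selection gives identical reconstructions after mirroring). At fixed
diffusion time $b \propto |q|^2$, so a sample carries
$b = b_{max}|q|^2/R^2$. $R=5$ gives 258 samples, $R=4$ gives 129.

`uniform_sphere_scheme(n, b)` builds single-shell schemes (one $b_0$ plus
$n-1$ directions). Directions are initialized on a hemispherical Fibonacci
spiral and refined by electrostatic repulsion on *axes* (Coulomb energy
$\sum 1/\sin\theta_{ij}$ on the axial angles), the standard construction for
gradient tables; the seed only rotates the spiral, so schemes are
reproducible. A regression property asserts the minimum pairwise axial angle
stays above $60^\circ\sqrt{2/n}$.

## The phantom generator

`build_phantom()` places tubular bundles (radius 3 mm by default) on a voxel
grid (2 mm isotropic by default; the anisotropic in vivo geometry is a
config option). A voxel within one radius of a centerline becomes white
matter and accumulates that bundle's local tangent; cylindrical caps
*strictly beyond* each centerline end become the terminal gray-matter ROIs,
so white matter and ROIs are disjoint and the white-matter span equals the
centerline length. Built-in geometries: a straight bundle, two bundles
crossing at a configurable angle, three orthogonal bundles through a common
center, and an arc.

`simulate_dwi()` evaluates the standard multi-tensor mixture per voxel,

$$S(q) = S_0 \sum_k f_k \exp\!\big(-b(q)\, g^T D_k g\big),$$

with axially symmetric tensors along the bundle tangents. Default
diffusivities are (1.7, 0.3)$\times 10^{-3}$ mm²/s (typical deep
white matter) and $S_0 = 100$; ROI voxels get an isotropic gray-matter
signal (0.8$\times 10^{-3}$ mm²/s), and voxels outside the phantom carry
zero true signal so the noise floor is directly observable on the
background. Noise is complex Gaussian with standard deviation $S_0/\mathrm{SNR}$
per channel — SNR is defined on the $b_0$ signal and spatially uniform —
and magnitudes are Rician. Repeats are combined by complex averaging
(mean of complex values, then magnitude; the noise floor falls as
$1/\sqrt{N}$) or magnitude averaging (floor unchanged), and a Monte-Carlo
test checks both laws on $>10^4$ background voxels.

What the generator does *not* emulate: subject motion, eddy currents,
susceptibility distortion, partial-volume $T_2$ effects, and coil-profile
SNR inhomogeneity. Passing tests therefore demonstrate correctness of the
reconstruction/tracking/statistics chain under the mixture model, not
robustness to those in vivo confounds.

## Reconstructions

* **Tensor** (`fit_tensor`): log-linear least squares of
  $\ln(S/S_0) = -b\,g^T D g$ over the diffusion-weighted samples; exact on
  noiseless single-tensor data (a consistent linear system), which the
  tests assert at $10^{-9}$. `fa_adc` gives the standard FA/ADC maps;
  `tensor_peaks` the principal eigenvector (ties broken deterministically
  and flagged).
* **DSI** (`dsi_odf`): hemisphere samples and their mirrors are placed on
  the centered $(2R+1)^3$ lattice, tapered by the Hanning window
  $\tfrac12(1+\cos(\pi|q|/(R+1)))$, zero-padded into an odd $N^3$ grid and
  3-D Fourier transformed; the propagator magnitude is radially projected
  onto an icosphere: $ODF(u) = \sum_r w_r P(ru)$ with trilinear
  interpolation.
* **QBI** (`qbi_odf`): even real spherical harmonics (order 8 when the
  scheme supports it; Laplace–Beltrami regularization $\lambda = 0.006$)
  fitted to $S/S_0$, then the Funk–Radon transform applied analytically by
  scaling each degree-$l$ band by $2\pi P_l(0)$.
* **Corrected (solid-angle) QBI** (`csa_odf`): the same machinery applied
  to $\ln(-\ln S/S_0)$ (signal clamped into $(0,1)$), with
  $\psi = \tfrac{1}{4\pi} + \tfrac{1}{16\pi^2}\mathrm{FRT}\{\Delta_b
  \ln(-\ln E)\}$; sharper than standard QBI by construction, which the
  tests assert voxelwise.

`extract_peaks` min–max normalizes each voxel's ODF, takes vertices that
dominate their tessellation neighborhood and exceed a relative threshold
(0.4), merges antipodal duplicates, and greedily enforces a minimum axial
separation (25°) up to 3 peaks — typical deterministic-tracking settings,
exposed as arguments because results depend on them. A constant ODF yields
zero peaks by definition.

### Numerical choices worth knowing

* Tessellation: icosahedron subdivision 3 (642 vertices, maximum edge
  ≈ 9.4°); single-fiber recovery is asserted within one edge (≤ 12°).
* DSI grid $N = 25$ with radii 4–9 (grid units) and $r^2$ weighting.
  This was a genuinely open corner: on the native 17-grid the trilinear
  footprint of two crossing fiber lobes overlaps at small radii and
  produces a spurious *diagonal* ODF maximum at a 90° crossing (normalized
  value ≈ 0.6, well above the peak threshold), while the outermost radii
  are dominated by rectified noise at SNR 20 and degrade fiber routing.
  Zero-padding the lattice sinc-interpolates the propagator and resolves
  both: exactly two peaks in every noiseless 90°-crossing voxel and perfect
  SNR-20 routing. The unweighted sum and other radii remain options.
* Signals are clamped to $[10^{-4}, 1-10^{-4}]$ relative before log and
  double-log transforms.

## Tractography

The deterministic streamline algorithm: in every white-matter voxel with
$n_v \ge 1$ extracted directions, $32\,n_v$ seeds are placed uniformly at
random in the voxel (the seed-count law is asserted exactly). From each
seed two walks start along $\pm$ the generating vector with a fixed 1 mm
step, each step following the current voxel's axial vector closest to the
incoming trajectory (nearest-neighbor lookup, no interpolation — the FACT
family convention; the original toolkit's choice is not documented, so this
is declared, not inferred). A walk aborts when the turn would exceed
60°/mm × step, and ends one step after leaving the white matter, so the
endpoint lies in the first non-WM voxel; its ROI label (possibly 0) is the
endpoint label. Retained fibers must be 5–200 mm long with both endpoints
in ROIs. There is no FA or amplitude stopping criterion — mask exit and the
turn limit are the only terminators. All geometry is in millimeters, so
anisotropic voxels need no special casing. The inner loop is compiled
(Rcpp); all randomness stays in R's RNG, making whole runs bit-identical
for a fixed seed.

## Connectome matrices

`build_connection_matrix` counts fibers per unordered ROI pair; self-pairs
are discarded and the diagonal is zero. An exact bookkeeping test checks
upper-triangle + discarded self-fibers = retained fiber count.

`geodesic_distance_matrix` implements connection distance $d(i,j)$ as the
shortest path confined to the white matter: a graph over WM voxel centers
with 26-neighborhood edges weighted by physical center-to-center distance,
ROIs attached through WM voxels 6-adjacent to their labeled voxels
(6-adjacency avoids diagonal leakage through corners), multi-source
Dijkstra between attachment sets. The publication this design follows never
specifies its algorithm, so this literal reading is declared. Note one
consequence checked in the tests: an L-shaped corridor is measured as
$8+\sqrt2 \approx 9.41$ mm, not 10, because the 26-connected path may turn
a corner diagonally; geodesics still dominate straight-line distances.
Distance bins are half-open $[lo, hi)$ with the last bin closed
(0–50/50–100/100–200 mm by default); unreachable pairs are reported
separately, and bins + unreachable conserve the connection count.

## Comparison statistics

The statistics layer operates on subjects × scans connection-count tables
(`connection_count_table()` ships the published five-subject, eight-scheme
table as a fixture):

* **Normalized connectivity**: a scan's count divided by the subject's mean
  reference count (the three repeated DSI q5 b8000 scans). The reference
  scans' normalized values average to 1 per subject exactly.
* **Paired t-tests** on counts for every scheme pair, with Bonferroni over
  the number of pairs (28 for 8 schemes). `paired_t_test` computes
  $t = \bar d/(s_d/\sqrt n)$, $df = n-1$ explicitly; tests cross-check it
  against both `stats::t.test` and numerical integration of the
  t density.
* **Variability**: scan-rescan σ = mean over subjects of the sample (n−1)
  SD of the reference replicates — this convention reproduces the published
  σ = 229 exactly, so it is taken as the original convention. The
  "variation" figure is implemented as the maximum within-subject spread of
  mean-normalized replicate counts, which reproduces the published 5.2%.
  The published inter-subject σ = 533 is *not* reproducible from the
  printed table under any natural definition we tried (per-scan
  across-subject SDs average to ≈ 507; other readings give ≈ 553);
  `variability()` reports the mean per-scan across-subject SD for
  orientation but the package does not assert 533.
* **Fiber limitation**: subsample every scheme's fiber set to the common
  minimum $F_s$ (uniform, without replacement, seeded) before matrix
  construction, so connection counts cannot be attributed to seed-count
  differences.

## The phantom experiment

The end-to-end acceptance experiment runs three orthogonal 40 mm bundles
crossing at a common center on a $24^3$ grid of 2 mm voxels at SNR 20 —
sizes chosen so a full three-scheme comparison takes a few seconds — with
matched fiber counts via fiber limitation. Fibers routed between true
bundle-end ROI pairs satisfy DSI-q5 ≥ QBI ≥ DTI across seeds: the tensor
model collapses the triple crossing to a single average direction and
misroutes most fibers, while both high-angular-resolution reconstructions
recover essentially all of them.

The solid-angle QBI contrast is run at SNR 10 on a 30 mm variant of the
same phantom: at SNR 20 *neither* q-ball variant produces a single spurious
connection (both are perfect, so "more spurious connections" is
unobservable), whereas at SNR 10 the sharper solid-angle reconstruction
amplifies noise lobes into extra peaks and clearly increases the number of
short (< 40 mm) spurious connections relative to standard QBI. That
noise regime is a deliberate design choice to make the sensitivity
difference measurable on a desk-scale phantom.

## Limitations

* Phantom bundles are tubes with piecewise-constant tangents; fanning,
  kissing and curving-through-crossing configurations are not modeled.
* The streamline algorithm is intentionally minimal (no interpolation, no
  probabilistic variant); it is the object of study, not a recommendation.
* Absolute in vivo connection counts are out of reach by design — the
  statistics layer reproduces the published table arithmetic, and the
  phantom experiments reproduce orderings and laws, not absolute values.
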