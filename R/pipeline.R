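#' Derive a per-stage child seed from a top-level seed
#'
#' Every randomized stage (sphere-point construction, noise, seeding, fiber
#' subsampling) draws its seed from the single top-level seed via a stable
#' string hash of the stage name, so a whole pipeline run is reproducible
#' from one integer.
#'
#' @param seed top-level integer seed.
#' @param stage stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480009
  as.integer(1 + (as.numeric(seed) * 2654435 + h) %% 2147480009)
}

#' Reconstruct peak directions from a DWI dataset
#'
#' Dispatches to the reconstruction matching the method tag: `"tensor"`
#' (principal eigenvector), `"dsi"` (Fourier/radial-projection ODF),
#' `"qbi"` (Funk-Radon) or `"csa"` (solid-angle q-ball), followed by ODF
#' peak extraction for the ODF-based methods.
#'
#' @param dwi a `dwi_dataset`.
#' @param method `"tensor"`, `"dsi"`, `"qbi"` or `"csa"`.
#' @param tess a [sphere_tessellation()] (ODF methods).
#' @param rel_thresh,min_sep,max_peaks peak-extraction settings.
#' @param ... passed to the reconstruction function.
#' @return a `peak_field`.
#' @export
reconstruct_peaks <- function(dwi, method = c("tensor", "dsi", "qbi", "csa"),
                              tess = sphere_tessellation(3),
                              rel_thresh = 0.4, min_sep = 25, max_peaks = 3L,
                              ...) {
  method <- match.arg(method)
  if (method == "tensor") return(tensor_peaks(fit_tensor(dwi, ...)))
  odf <- switch(method,
                dsi = dsi_odf(dwi, tess, ...),
                qbi = qbi_odf(dwi, tess, ...),
                csa = csa_odf(dwi, tess, ...))
  extract_peaks(odf, rel_thresh = rel_thresh, min_sep = min_sep,
                max_peaks = max_peaks)
}

#' Run the phantom scheme-comparison pipeline
#'
#' For each named scheme: simulate the phantom acquisition, reconstruct
#' peaks with the scheme's method, run whole-phantom tractography, and build
#' the connection matrix. All per-stage seeds derive from the single
#' top-level `seed` via [derive_seed()].
#'
#' @param truth a [build_phantom()] result.
#' @param schemes named list of `qscheme` objects.
#' @param methods named character vector (same names) with the
#'   reconstruction per scheme: `"tensor"`, `"dsi"`, `"qbi"` or `"csa"`.
#' @param snr simulated signal-to-noise ratio on b0.
#' @param n_averages complex-averaged repeats per acquisition.
#' @param params a [tracking_params()] (its `rng_seed` is overridden by the
#'   derived per-scheme seed).
#' @param tess tessellation for the ODF methods.
#' @param seed top-level seed.
#' @param S0 b0 signal amplitude.
#' @param match_fibers apply [fiber_limitation()] across schemes before
#'   building the matrices.
#' @return An object of class `pipeline_result`: per-scheme list `runs`
#'   (each with `peaks`, `fibers`, `matrix`, `connections`), the phantom
#'   `truth`, `roi_ids` and provenance.
#' @export
run_pipeline <- function(truth, schemes, methods, snr = 20, n_averages = 1,
                         params = tracking_params(), tess = NULL, seed = 1L,
                         S0 = 100, match_fibers = FALSE) {
  stopifnot(identical(sort(names(schemes)), sort(names(methods))))
  if (is.null(tess) && any(methods != "tensor"))
    tess <- sphere_tessellation(3)
  roi_ids <- sort(setdiff(unique(as.vector(truth$roi_labels)), 0L))
  sets <- list()
  peaks_by <- list()
  for (nm in names(schemes)) {
    dwi <- simulate_dwi(truth, schemes[[nm]], S0 = S0, snr = snr,
                        n_averages = n_averages,
                        seed = derive_seed(seed, paste0("sim/", nm)))
    pf <- reconstruct_peaks(dwi, methods[[nm]], tess = tess)
    p <- params
    p$rng_seed <- derive_seed(seed, paste0("track/", nm))
    sets[[nm]] <- track_wholebrain(pf, truth$wm_mask, truth$roi_labels,
                                   p, scheme_id = nm)
    peaks_by[[nm]] <- pf
  }
  if (match_fibers)
    sets <- fiber_limitation(sets, derive_seed(seed, "fiber_limitation"))
  runs <- lapply(names(schemes), function(nm) {
    M <- build_connection_matrix(sets[[nm]], roi_ids)
    list(scheme = nm, peaks = peaks_by[[nm]], fibers = sets[[nm]],
         matrix = M, connections = count_connections(M))
  })
  names(runs) <- names(schemes)
  structure(list(runs = runs, truth = truth, roi_ids = roi_ids,
                 provenance = list(seed = seed, snr = snr,
                                   n_averages = n_averages,
                                   match_fibers = match_fibers)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Phantom scheme-comparison pipeline\n")
  for (nm in names(x$runs))
    cat(sprintf("  %-10s %6d fibers, %3d connection(s)\n", nm,
                x$runs[[nm]]$fibers$count, x$runs[[nm]]$connections))
  invisible(x)
}

#' Count fibers connecting the phantom's true ROI pairs
#'
#' @param M a `connection_matrix` whose dimnames are ROI labels.
#' @param truth the generating `phantom_truth`.
#' @return total fiber count over the true bundle-end pairs.
#' @export
true_pair_fibers <- function(M, truth) {
  ids <- as.integer(rownames(M))
  sum(apply(truth$true_pairs, 1, function(p)
    M[match(p[1], ids), match(p[2], ids)]))
}

#' Count spurious short-distance connections
#'
#' Connections (pairs with at least `n_f` fibers) that are not true bundle
#' pairs and whose geodesic connection distance is below `max_dist` —
#' the noise-dominated short-range regime.
#'
#' @param M a `connection_matrix`.
#' @param D the matching `distance_matrix`.
#' @param truth the generating `phantom_truth`.
#' @param max_dist mm threshold (default 40).
#' @param n_f minimum fiber count.
#' @return integer count of short spurious connections.
#' @export
short_spurious_connections <- function(M, D, truth, max_dist = 40, n_f = 1L) {
  ids <- as.integer(rownames(M))
  true_mask <- matrix(FALSE, nrow(M), ncol(M))
  for (r in seq_len(nrow(truth$true_pairs))) {
    a <- match(truth$true_pairs[r, 1], ids)
    b <- match(truth$true_pairs[r, 2], ids)
    true_mask[a, b] <- true_mask[b, a] <- TRUE
  }
  sel <- upper.tri(M) & M >= n_f & !true_mask & is.finite(D) & D < max_dist
  sum(sel)
}
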