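#' Save a DWI dataset as NIfTI-1 plus FSL-dialect gradient tables
#'
#' The 4-D signal goes to `nifti_path` (axis-aligned affine scaled by the
#' voxel size, origin at the volume corner); the scheme goes to
#' `bvals_path`/`bvecs_path`.
#'
#' @param dwi a `dwi_dataset`.
#' @param nifti_path,bvals_path,bvecs_path output paths.
#' @return invisibly, the NIfTI path.
#' @export
save_dwi <- function(dwi, nifti_path, bvals_path, bvecs_path) {
  img <- RNifti::asNifti(dwi$signal)
  RNifti::pixdim(img) <- c(dwi$voxel_size, 1)
  RNifti::writeNifti(img, nifti_path)
  write_bvals_bvecs(dwi$scheme, bvals_path, bvecs_path)
  invisible(nifti_path)
}

#' Load a DWI dataset from NIfTI-1 and gradient tables
#'
#' The scheme is rebuilt from the gradient table (b0 rows detected by
#' b = 0); the 4th NIfTI dimension must match the gradient count.
#'
#' @param nifti_path,bvals_path,bvecs_path input paths.
#' @param wm_mask,roi_labels optional arrays to attach.
#' @return a `dwi_dataset`.
#' @export
load_dwi <- function(nifti_path, bvals_path, bvecs_path,
                     wm_mask = NULL, roi_labels = NULL) {
  img <- RNifti::readNifti(nifti_path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4)
    stop("expected a 4-D NIfTI volume")
  scheme <- read_bvals_bvecs(bvals_path, bvecs_path)
  if (dim(arr)[4] != n_samples(scheme))
    stop(sprintf("NIfTI has %d volumes but the gradient table has %d entries",
                 dim(arr)[4], n_samples(scheme)))
  vs <- RNifti::pixdim(img)[1:3]
  new_dwi_dataset(arr, scheme, vs, wm_mask, roi_labels,
                  provenance = list(source = nifti_path))
}

#' Save an integer or logical volume as NIfTI-1
#' @param vol 3-D array.
#' @param voxel_size mm 3-vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
save_volume <- function(vol, voxel_size, path) {
  img <- RNifti::asNifti(array(as.integer(vol), dim(vol)))
  RNifti::pixdim(img) <- rep(voxel_size, length.out = 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --------------------------------------------------------------------------
# TrackVis .trk streamline format (binary, version 2, 1000-byte header).
# Points are stored in the format's voxel-mm convention (mm with the origin
# at the volume corner), which is the package's internal convention already.

#' Write streamlines as a TrackVis .trk file
#'
#' @param set a `streamline_set` (its `dim` and `voxel_size` populate the
#'   header).
#' @param path output path.
#' @return invisibly, the path.
#' @export
save_streamlines <- function(set, path) {
  if (is.null(set$voxel_size)) stop("streamline set lacks voxel-size metadata")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(as.raw(0), con)                                   # id_string pad
  writeBin(as.integer(set$dim), con, size = 2)               # dim
  writeBin(as.numeric(set$voxel_size), con, size = 4)        # voxel_size
  writeBin(numeric(3), con, size = 4)                        # origin
  writeBin(0L, con, size = 2)                                # n_scalars
  writeBin(raw(200), con)                                    # scalar names
  writeBin(0L, con, size = 2)                                # n_properties
  writeBin(raw(200), con)                                    # property names
  aff <- diag(c(set$voxel_size, 1))                          # vox_to_ras
  writeBin(as.numeric(t(aff)), con, size = 4)
  writeBin(raw(444), con)                                    # reserved
  writeChar("LPS", con, nchars = 3, eos = NULL)              # voxel_order
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                      # pad2
  writeBin(as.numeric(c(1, 0, 0, 0, 1, 0)), con, size = 4)   # image orient
  writeBin(raw(2), con)                                      # pad1
  writeBin(raw(6), con)                                      # invert/swap
  writeBin(length(set$streamlines), con, size = 4)           # n_count
  writeBin(2L, con, size = 4)                                # version
  writeBin(1000L, con, size = 4)                             # hdr_size
  for (m in set$streamlines) {
    writeBin(nrow(m), con, size = 4)
    writeBin(as.numeric(t(m)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file
#'
#' @param path input path.
#' @return a `streamline_set` (without endpoint labels).
#' @export
read_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readChar(con, 5, useBytes = TRUE)
  if (!identical(id, "TRACK")) stop("not a TrackVis .trk file")
  readBin(con, "raw", 1)
  dm <- readBin(con, "integer", 3, size = 2)
  vs <- readBin(con, "numeric", 3, size = 4)
  seek(con, 988)                                             # header tail
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000) stop("unsupported .trk header size")
  lines <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    pts <- readBin(con, "numeric", 3 * np, size = 4)
    lines[[i]] <- matrix(pts, np, 3, byrow = TRUE)
  }
  structure(list(streamlines = lines, count = n_count,
                 endpoint_labels = NULL, voxel_size = vs, dim = dm,
                 params = NULL, provenance = list(source = path)),
            class = "streamline_set")
}
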