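# Volume containers and NIfTI-1 input/output.
#
# Array convention: volumes are dense 3D arrays indexed (depth, height,
# width), 0-based half-open slicing semantics in the docs, with depth as the
# pseudo-temporal slicing axis of the network.  On disk the first (fastest)
# NIfTI axis maps to depth, so round trips are transparent and other NIfTI
# readers see the same Fortran-ordered data.
#
# The reader/writer below implements the fixed 348-byte NIfTI-1 header
# directly (no NIfTI package exists in this R installation); .nii and .nii.gz
# are both handled via gzfile(), which transparently reads plain files too.

#' Construct a volume
#'
#' @param data 3D numeric array indexed (depth, height, width).
#' @param spacing_mm voxel spacing, 3 positive reals.
#' @param modality one of "MRI_like", "TRUS_like", "unknown".
#' @return object of class `prostreg_volume`.
#' @export
volume <- function(data, spacing_mm = c(1, 1, 1), modality = "unknown") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("volume data must be finite")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals")
  modality <- match.arg(modality, c("MRI_like", "TRUS_like", "unknown"))
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 modality = modality),
            class = "prostreg_volume")
}

#' Construct a binary label mask
#'
#' @param data 3D array with values exactly 0 or 1.
#' @param spacing_mm voxel spacing.
#' @return object of class `prostreg_mask`.
#' @export
label_mask <- function(data, spacing_mm = c(1, 1, 1)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(data %in% c(0, 1))) stop("mask values must be exactly 0 or 1")
  structure(list(data = data + 0, spacing_mm = as.numeric(spacing_mm)),
            class = "prostreg_mask")
}

#' Construct a landmark set
#'
#' @param points n x 3 matrix of 0-based voxel coordinates (d, h, w order,
#'   written as x, y, z in CSV files).
#' @param ids labels, one per point.
#' @return object of class `prostreg_landmarks`.
#' @export
landmark_set <- function(points, ids = seq_len(nrow(points))) {
  points <- matrix(points, ncol = 3L)
  if (nrow(points) != length(ids)) stop("points and ids lengths differ")
  structure(list(points = points, ids = as.character(ids)),
            class = "prostreg_landmarks")
}

#' @export
print.prostreg_volume <- function(x, ...) {
  cat(sprintf("<volume %s  %s  spacing %s mm>\n", paste(dim(x$data), collapse = "x"),
              x$modality, paste(signif(x$spacing_mm, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.prostreg_mask <- function(x, ...) {
  cat(sprintf("<mask %s  |fg| = %d>\n", paste(dim(x$data), collapse = "x"),
              sum(x$data == 1)))
  invisible(x)
}

# ------------------------------------------------------------------ NIfTI ---

.nifti_write_raw <- function(data, spacing, path) {
  dm <- dim(data)
  nd <- length(dm)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(c(nd, dm, rep(1L, 7 - nd)), 2)             # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..3, intent_code
  wi(16L, 2); wi(32L, 2); wi(0L, 2)             # datatype float32, bitpix, slice_start
  wf(c(1, spacing, rep(1, 7 - length(spacing)))) # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 2L), 2)                              # qform_code 0, sform_code 2
  wf(rep(0, 6))                                 # quatern b c d, qoffset x y z
  wf(c(spacing[1], 0, 0, 0))                    # srow_x
  wf(c(0, spacing[2], 0, 0))                    # srow_y
  wf(c(0, 0, spacing[3], 0))                    # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

.nifti_read_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("malformed NIfTI file (truncated header): ", path)
  rd <- function(what, n, size, endian) readBin(hdr[seq.int(off + 1, off + n * size)],
                                                what, n = n, size = size, endian = endian)
  off <- 0
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348L) stop("malformed NIfTI file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI file (bad magic): ", path)
  off <- 40; dims <- rd("integer", 8, 2, endian)
  nd <- dims[1]
  if (nd < 3 || nd > 4) stop("unsupported NIfTI dimensionality in ", path)
  dm <- dims[2:(1 + nd)]
  off <- 70; datatype <- rd("integer", 1, 2, endian)
  off <- 76; pixdim <- rd("numeric", 8, 4, endian)
  off <- 108; vox_offset <- rd("numeric", 1, 4, endian)
  off <- 112; scl <- rd("numeric", 2, 4, endian)
  n <- prod(dm)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  data <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, 1, signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", n, 2, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n, 4, endian = endian)),
    "16" = readBin(con, "numeric", n, 4, endian = endian),
    "64" = readBin(con, "numeric", n, 8, endian = endian),
    stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(data) < n) stop("malformed NIfTI file (truncated data): ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) data <- data * scl[1] + scl[2]
  dim(data) <- dm
  list(data = data, spacing = pixdim[2:(1 + min(nd, 3))])
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @param modality modality tag to attach.
#' @return a [volume()].
#' @export
read_volume <- function(path, modality = "unknown") {
  r <- .nifti_read_raw(path)
  if (length(dim(r$data)) != 3L) stop("expected a 3D volume in ", path)
  volume(r$data, r$spacing, modality)
}

#' Write a volume (or mask) as NIfTI
#'
#' Data is stored as float32; `write_volume` then `read_volume` preserves
#' values to float32 precision and spacing to within 1e-6 mm.
#'
#' @param vol a [volume()] or [label_mask()].
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  .nifti_write_raw(vol$data, vol$spacing_mm, path)
}

#' Read a binary mask from NIfTI (values are binarized at 0.5)
#' @param path path to a .nii or .nii.gz file.
#' @return a [label_mask()].
#' @export
read_mask <- function(path) {
  r <- .nifti_read_raw(path)
  label_mask((r$data >= 0.5) + 0, r$spacing)
}

#' Read/write a deformation field as 4D NIfTI (components on the last axis)
#' @param phi deformation field (3, D, H, W).
#' @param spacing_mm voxel spacing.
#' @param path file path.
#' @export
write_field <- function(phi, path, spacing_mm = c(1, 1, 1)) {
  .check_field(phi)
  .nifti_write_raw(aperm(phi, c(2, 3, 4, 1)), spacing_mm, path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  r <- .nifti_read_raw(path)
  dm <- dim(r$data)
  if (length(dm) != 4L || dm[4] != 3L) stop("expected a (D,H,W,3) field in ", path)
  aperm(r$data, c(4, 1, 2, 3))
}

#' Read/write landmarks as CSV (columns id, x, y, z; 0-based voxel coords)
#' @param lms a [landmark_set()].
#' @param path file path.
#' @export
write_landmarks <- function(lms, path) {
  df <- data.frame(id = lms$ids, x = lms$points[, 1],
                   y = lms$points[, 2], z = lms$points[, 3])
  utils::write.csv(df, path, row.names = FALSE)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  landmark_set(as.matrix(df[, c("x", "y", "z")]), df$id)
}

# ------------------------------------------------------------ grid ops ---

#' Resample a volume or mask to a target grid
#'
#' Trilinear interpolation for images, nearest-neighbor for labels; spacing is
#' rescaled so the physical extent is preserved.
#'
#' @param vol a [volume()] or [label_mask()].
#' @param target_shape 3 integers (>= 2 each).
#' @param is_label force nearest-neighbor (defaults to TRUE for masks).
#' @return resampled object of the same class.
#' @export
resample_to_grid <- function(vol, target_shape, is_label = inherits(vol, "prostreg_mask")) {
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2L))
    stop("target_shape must be 3 integers >= 2")
  dm <- dim(vol$data)
  x <- vol$data; dim(x) <- c(1L, dm)
  out <- cpp_resample3d(as.vector(x), dim(x), target_shape, is_label)
  dim(out) <- target_shape
  sp <- vol$spacing_mm * dm / target_shape
  if (inherits(vol, "prostreg_mask")) label_mask(out, sp) else volume(out, sp, vol$modality)
}

#' Crop axial border slices along the depth axis
#'
#' Removes the first and last `n_slices` depth planes (the preprocessing step
#' that turns a 128-deep volume into a 120-deep one with the default 4).
#'
#' @param vol a [volume()] or [label_mask()].
#' @param n_slices planes to remove at each end (default 4).
#' @return cropped object of the same class.
#' @export
crop_depth <- function(vol, n_slices = 4L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 0L) stop("n_slices must be >= 0")
  D <- dim(vol$data)[1L]
  if (D <= 2L * n_slices) stop("depth ", D, " too small to crop 2 x ", n_slices, " planes")
  if (n_slices == 0L) return(vol)
  out <- vol$data[(n_slices + 1L):(D - n_slices), , , drop = FALSE]
  if (inherits(vol, "prostreg_mask")) label_mask(out, vol$spacing_mm)
  else volume(out, vol$spacing_mm, vol$modality)
}

#' Zero-pad a cropped volume back to a target depth
#'
#' Inverse (in shape) of [crop_depth()]: planes are added symmetrically, with
#' any odd remainder at the end.
#'
#' @param vol a [volume()] or [label_mask()].
#' @param target_depth desired depth (>= current depth).
#' @return padded object of the same class.
#' @export
pad_depth <- function(vol, target_depth) {
  D <- dim(vol$data)[1L]
  if (target_depth < D) stop("target_depth smaller than current depth")
  extra <- target_depth - D
  lo <- extra %/% 2L
  dm <- dim(vol$data)
  out <- array(0, c(target_depth, dm[2], dm[3]))
  out[lo + seq_len(D), , ] <- vol$data
  if (inherits(vol, "prostreg_mask")) label_mask(out, vol$spacing_mm)
  else volume(out, vol$spacing_mm, vol$modality)
}

#' Apply a region-of-interest mask to a volume (element-wise product)
#'
#' @param vol a [volume()].
#' @param mask a [label_mask()] of the same shape.
#' @return ROI-masked [volume()].
#' @export
apply_roi <- function(vol, mask) {
  if (!all(dim(vol$data) == dim(mask$data))) stop("volume and mask shapes differ")
  volume(vol$data * mask$data, vol$spacing_mm, vol$modality)
}
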