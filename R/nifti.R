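# Minimal single-file NIfTI-1 (.nii) I/O.
#
# No NIfTI-capable R package is available in the build environment, so the
# small subset of the format this package needs is implemented directly:
# uncompressed .nii, 3-D or 4-D, little- or big-endian on read (always
# little-endian float32 on write), datatypes uint8/int16/int32/float32/float64,
# sform affine. Quaternion (qform-only) files fall back to pixdim scaling.

NIFTI_DT <- list(`2`  = list(what = "integer", size = 1, signed = FALSE),
                 `4`  = list(what = "integer", size = 2, signed = TRUE),
                 `8`  = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double",  size = 4, signed = TRUE),
                 `64` = list(what = "double",  size = 8, signed = TRUE))

#' Write a 3-D or 4-D array as an uncompressed NIfTI-1 file
#'
#' @param img numeric/logical array with 3 or 4 dimensions.
#' @param path output path (`.nii`).
#' @param affine 4x4 voxel-to-mm transform, stored in the sform.
#' @param pixdim voxel sizes; defaults taken from the affine diagonal.
#' @param tr_seconds stored in `pixdim[4]` for 4-D images.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, affine = diag(4), pixdim = NULL, tr_seconds = 3) {
  nd <- length(dim(img))
  if (!nd %in% c(3, 4)) stopf("write_nifti: image must be 3-D or 4-D")
  dims <- dim(img)
  if (is.null(pixdim)) pixdim <- abs(diag(affine)[1:3])
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348)                        # sizeof_hdr
  w_raw(36)                         # data_type..dim_info (unused)
  dimv <- c(nd, dims, rep(1L, 7 - nd))
  w_i16(dimv)                       # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0)       # intent_p1..3, intent_code
  w_i16(16); w_i16(32); w_i16(0)    # datatype=float32, bitpix, slice_start
  w_f32(c(0, pixdim, if (nd == 4) tr_seconds else 0, 0, 0, 0))  # pixdim[8]
  w_f32(352)                        # vox_offset
  w_f32(1); w_f32(0)                # scl_slope, scl_inter
  w_i16(0); w_raw(2)                # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0, 0))                    # glmax, glmin
  w_raw(104)                        # descrip + aux_file
  w_i16(0); w_i16(1)                # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                  # quaternion + qoffset
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])  # srow_x/y/z
  w_raw(16)                         # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1)  # magic
  w_raw(4)                          # extension flag
  writeBin(as.numeric(img), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' @param path `.nii` path.
#' @return list with `data` (array), `affine` (4x4), `pixdim`, `tr_seconds`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("NIfTI file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
  if (sz != 348) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, 4, endian = endian)
    if (sz != 348) stopf("%s: not a NIfTI-1 file (bad sizeof_hdr)", path)
  }
  rd <- function(off, what, n, size) readBin(hdr[(off + 1):length(hdr)], what, n, size, endian = endian)
  dimv <- rd(40, "integer", 8, 2)
  nd <- dimv[1]
  if (!nd %in% c(3, 4)) stopf("%s: only 3-D/4-D images supported (dim[0]=%d)", path, nd)
  dims <- dimv[2:(1 + nd)]
  datatype <- rd(70, "integer", 1, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stopf("%s: unsupported NIfTI datatype %d", path, datatype)
  pixdim8 <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1, ] <- rd(280, "double", 4, 4)
    affine[2, ] <- rd(296, "double", 4, 4)
    affine[3, ] <- rd(312, "double", 4, 4)
  } else {
    diag(affine)[1:3] <- pixdim8[2:4]
  }
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed, endian = endian)
  if (length(vals) < n) stopf("%s: truncated data (%d of %d values)", path, length(vals), n)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims), affine = affine,
       pixdim = pixdim8[2:4], tr_seconds = if (nd == 4) pixdim8[5] else NA_real_)
}

#' Read a 4-D NIfTI volume plus named tissue masks
#'
#' Validates that every mask shares the image's spatial grid and affine.
#'
#' @param path 4-D `.nii` path.
#' @param mask_paths named character vector of 3-D mask `.nii` paths
#'   (e.g. `c(brain = "...", gray_matter = "...")`). Non-zero voxels are TRUE.
#' @param tr_seconds repetition time; if `NULL`, taken from `pixdim[4]`.
#' @return a [volume_series()].
#' @export
read_volume_series <- function(path, mask_paths = character(), tr_seconds = NULL) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 4) stopf("%s: expected a 4-D image", path)
  if (dim(img$data)[4] < 2) stopf("%s: need frames >= 2, got %d", path, dim(img$data)[4])
  sp <- dim(img$data)[1:3]
  masks <- list()
  for (nm in names(mask_paths)) {
    mk <- read_nifti(mask_paths[[nm]])
    if (length(dim(mk$data)) != 3 || !identical(dim(mk$data), sp))
      stopf("mask '%s' grid %s does not match image grid %s", nm,
            paste(dim(mk$data), collapse = "x"), paste(sp, collapse = "x"))
    if (max(abs(mk$affine - img$affine)) > 1e-4)
      stopf("mask '%s' affine does not match image affine", nm)
    masks[[nm]] <- mk$data != 0
  }
  tr <- if (!is.null(tr_seconds)) tr_seconds else img$tr_seconds
  if (!is_scalar_num(tr) || tr <= 0) tr <- 3
  volume_series(img$data, masks = masks, affine = img$affine, tr_seconds = tr)
}
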