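## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
## Only what the pipeline needs: 3D volumes, sform/qform affines, the common
## scalar datatypes, scl_slope/scl_inter scaling. No extensions, no .hdr/.img
## pairs, no resampling; orientation is preserved exactly as stored.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [cc_volume()]. The affine is taken from the sform when `sform_code > 0`,
#' else from the qform, else from `pixdim` alone. Data are returned as stored
#' (after `scl_slope`/`scl_inter` scaling); no reorientation or resampling is
#' performed.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind Optional validation: `"mask"` enforces binary values,
#'   `"labels"` enforces integer codes 0-7, `"none"` (default) skips checks.
#' @return A [cc_volume()].
#' @export
read_nifti <- function(path, kind = c("none", "mask", "labels")) {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    stop("malformed NIfTI header: file shorter than 348 bytes")
  endian <- "little"
  szh <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (szh != 348L)
      stop("malformed NIfTI header: sizeof_hdr != 348")
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian,
            signed = !(what == "integer" && size <= 2L && FALSE))
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("malformed NIfTI header: bad magic '", magic, "'")
  if (magic == "ni1")
    stop("two-file (.hdr/.img) NIfTI is not supported")
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  if (ndim < 3L || any(dims[2:4] < 1L))
    stop("expected a 3D volume, got dim = ", paste(dims, collapse = ","))
  if (ndim > 3L && any(dims[5:(1 + ndim)] > 1L))
    stop("expected a 3D volume, got a ", ndim, "D image")
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)

  if (sform_code > 0L) {
    srow <- rbind(rd(280L, "double", 4L, 4L),
                  rd(296L, "double", 4L, 4L),
                  rd(312L, "double", 4L, 4L))
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- rd(256L, "double", 1L, 4L)
    c_ <- rd(260L, "double", 1L, 4L)
    d <- rd(264L, "double", 1L, 4L)
    a2 <- 1 - b * b - c_ * c_ - d * d
    a <- sqrt(max(a2, 0))
    R <- matrix(c(a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ + a * d), 2 * (b * d - a * c_),
                  2 * (b * c_ - a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d + a * b),
                  2 * (b * d + a * c_), 2 * (c_ * d - a * b), a * a + d * d - b * b - c_ * c_),
                3, 3)
    qfac <- if (pixdim[1] < 0) -1 else 1
    R <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    off <- c(rd(268L, "double", 1L, 4L), rd(272L, "double", 1L, 4L),
             rd(276L, "double", 1L, 4L))
    affine <- rbind(cbind(R, off), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(abs(pixdim[2:4]), 1))
  }

  ## skip from byte 348 to vox_offset, then read voxels
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip < 0L) stop("malformed NIfTI header: vox_offset < 348")
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- prod(dims[2:4])
  if (dt$what == "integer" && dt$size <= 2L) {
    vals <- readBin(con, "integer", n = nvox, size = dt$size,
                    endian = endian, signed = dt$signed)
  } else {
    vals <- readBin(con, dt$what, n = nvox, size = dt$size, endian = endian)
  }
  if (length(vals) < nvox)
    stop("malformed NIfTI file: truncated voxel data")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  vol <- cc_volume(array(vals, dim = dims[2:4]), affine)
  if (kind == "mask") validate_mask(vol)
  if (kind == "labels") validate_labels(vol)
  vol
}

#' Write a NIfTI-1 volume
#'
#' Writes a [cc_volume()] as a single-file NIfTI-1 image with the affine
#' stored in the sform (`sform_code = 1`). Gzip compression is selected by a
#' `.gz` suffix.
#'
#' @param vol A [cc_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path,
                        datatype = c("float32", "uint8", "int16", "int32",
                                     "float64")) {
  datatype <- match.arg(datatype)
  code <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
            float64 = 64L)[[datatype]]
  size <- c(uint8 = 1L, int16 = 2L, int32 = 4L, float32 = 4L,
            float64 = 8L)[[datatype]]
  d <- dim(vol$data)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wd <- function(x, size) writeBin(as.double(x), con, size = size,
                                   endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)               # dim[8]
  wd(c(0, 0, 0), 4L)                             # intent_p1..p3
  wi(0L, 2L)                                     # intent_code
  wi(code, 2L)                                   # datatype
  wi(8L * size, 2L)                              # bitpix
  wi(0L, 2L)                                     # slice_start
  wd(c(1, voxel_sizes(vol$affine), 0, 0, 0, 0), 4L)  # pixdim[8], qfac = 1
  wd(352, 4L)                                    # vox_offset
  wd(1, 4L)                                      # scl_slope
  wd(0, 4L)                                      # scl_inter
  wi(0L, 2L); wi(0L, 1L); wi(0L, 1L)             # slice_end/code, xyzt_units
  wd(c(0, 0, 0), 4L)                             # cal_max/min, slice_duration
  wd(0, 4L)                                      # toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(80L + 24L), con)                  # descrip, aux_file
  wi(0L, 2L)                                     # qform_code
  wi(1L, 2L)                                     # sform_code
  wd(c(0, 0, 0, 0, 0, 0), 4L)                    # quatern b,c,d + qoffset
  wd(vol$affine[1, ], 4L)                        # srow_x
  wd(vol$affine[2, ], 4L)                        # srow_y
  wd(vol$affine[3, ], 4L)                        # srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension flag
  vals <- as.vector(vol$data)
  if (datatype %in% c("uint8", "int16", "int32")) {
    if (any(vals != round(vals)))
      stop("non-integer data cannot be written as ", datatype)
    wi(vals, size)
  } else {
    wd(vals, size)
  }
  invisible(path)
}
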