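# Minimal NIfTI-1 reader/writer (.nii / .nii.gz, single-file).  Implemented
# natively because no NIfTI package is available in the supported
# dependency set.  Covers the subset this package emits: 3D volumes,
# datatypes uint8/int16/int32/float32/float64, sform affine.  Intensity
# volumes are stored as float64 and masks as uint8 so that a write/read
# round trip is bit-exact.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

#' Write a volume to a NIfTI-1 file
#'
#' @param vol an [volume()] object.
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @param datatype `"auto"` (uint8 for masks, float64 otherwise) or one of
#'   `"uint8"`, `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "auto") {
  stopifnot(inherits(vol, "adc_volume"))
  if (datatype == "auto")
    datatype <- if (vol$role == "mask" && is_binary(vol$data)) "uint8"
                else "float64"
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$data)

  wb <- function(x, size, type = "integer")
    writeBin(switch(type, integer = as.integer(x), double = as.double(x)),
             con, size = size, endian = "little")
  wchar <- function(nbytes) writeBin(raw(nbytes), con)

  wb(348L, 4)                      # sizeof_hdr
  wchar(10 + 18)                   # data_type, db_name
  wb(0L, 4); wb(0L, 2)             # extents, session_error
  writeBin(charToRaw("r"), con); wchar(1)  # regular, dim_info
  wb(c(3L, d, 1L, 1L, 1L, 1L), 2)  # dim[8]
  wb(c(0, 0, 0), 4, "double")      # intent_p1..p3
  wb(0L, 2)                        # intent_code
  wb(dt, 2)                        # datatype
  wb(NIFTI_BITPIX[[as.character(dt)]], 2) # bitpix
  wb(0L, 2)                        # slice_start
  wb(c(1, vol$spacing, 0, 0, 0, 0), 4, "double") # pixdim[8], qfac = 1
  wb(352, 4, "double")             # vox_offset
  wb(c(1, 0), 4, "double")         # scl_slope, scl_inter
  wb(0L, 2); wchar(2)              # slice_end, slice_code, xyzt_units
  wb(c(0, 0, 0, 0), 4, "double")   # cal_max, cal_min, slice_duration, toffset
  wb(c(0L, 0L), 4)                 # glmax, glmin
  wchar(80 + 24)                   # descrip, aux_file
  wb(0L, 2)                        # qform_code
  wb(1L, 2)                        # sform_code
  wb(rep(0, 6), 4, "double")       # quatern_b..d, qoffset_x..z
  wb(vol$affine[1, ], 4, "double") # srow_x
  wb(vol$affine[2, ], 4, "double") # srow_y
  wb(vol$affine[3, ], 4, "double") # srow_z
  wchar(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  wchar(4)                         # extension flag -> offset 352

  v <- as.vector(vol$data)
  if (datatype %in% c("uint8", "int16", "int32")) {
    sz <- c(uint8 = 1L, int16 = 2L, int32 = 4L)[[datatype]]
    writeBin(as.integer(round(v)), con, size = sz, endian = "little")
  } else {
    sz <- if (datatype == "float32") 4L else 8L
    writeBin(as.double(v), con, size = sz, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param role volume role to stamp on the result (`"t2"`, `"adc"`,
#'   `"mask"`); masks read from uint8 data default to `"mask"` when left
#'   `NULL` and the data is binary.
#' @return an [volume()] object.
#' @export
read_nifti <- function(path, role = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb") # reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path)
  rd <- function(off, n, what, size, endian) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = size > 1)
  }
  endian <- "little"
  if (rd(0, 1, "integer", 4, endian) != 348L) {
    endian <- "big"
    if (rd(0, 1, "integer", 4, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  dim8 <- rd(40, 8, "integer", 2, endian)
  ndim <- dim8[1]
  if (ndim < 3 || any(dim8[2:4] < 1)) stop("expected a 3D volume: ", path)
  if (ndim > 3 && prod(dim8[5:(ndim + 1)]) != 1)
    stop("only single-frame 3D volumes are supported: ", path)
  d <- dim8[2:4]
  datatype <- rd(70, 1, "integer", 2, endian)
  pixdim <- rd(76, 8, "numeric", 4, endian)
  vox_offset <- rd(108, 1, "numeric", 4, endian)
  scl_slope <- rd(112, 1, "numeric", 4, endian)
  scl_inter <- rd(116, 1, "numeric", 4, endian)
  sform_code <- rd(254, 1, "integer", 2, endian)
  srow <- matrix(rd(280, 12, "numeric", 4, endian), 3, 4, byrow = TRUE)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  v <- switch(as.character(datatype),
    `2` = readBin(con, "integer", n, size = 1, signed = FALSE,
                  endian = endian),
    `4` = readBin(con, "integer", n, size = 2, endian = endian),
    `8` = readBin(con, "integer", n, size = 4, endian = endian),
    `16` = readBin(con, "numeric", n, size = 4, endian = endian),
    `64` = readBin(con, "numeric", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype, " in ", path))
  if (length(v) < n) stop("truncated NIfTI data: ", path)
  v <- as.double(v)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  spacing <- abs(pixdim[2:4])
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1:3, ] <- srow
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  } else {
    affine <- diag(c(spacing, 1))
  }
  if (is.null(role))
    role <- if (datatype == 2 && is_binary(v)) "mask" else "t2"
  volume(array(v, dim = d), spacing = spacing, affine = affine, role = role)
}
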