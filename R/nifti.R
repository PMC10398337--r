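#' Minimal NIfTI-1 image container
#'
#' A light in-memory representation of a NIfTI-1 volume: the voxel array
#' (3D or 4D), the 4x4 voxel-to-world affine in mm (RAS), the voxel size per
#' axis in mm and, for 4D series, the repetition time in seconds.
#'
#' @param data numeric array, 3 or 4 dimensions.
#' @param affine 4x4 voxel-to-world matrix (mm). Voxel indices are 0-based
#'   when mapped through the affine, following the NIfTI convention.
#' @param voxel_size length-3 voxel edge lengths in mm; defaults to the
#'   column norms of the affine.
#' @param tr repetition time in seconds (4D only; `NA` for 3D maps).
#' @return An object of class `nifti_image`.
#' @export
nifti_image <- function(data, affine = NULL, voxel_size = NULL, tr = NA_real_) {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("data must be a 3D or 4D array")
  if (is.null(affine)) {
    vs <- if (is.null(voxel_size)) c(1, 1, 1) else voxel_size
    affine <- diag(c(vs, 1))
  }
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (is.null(voxel_size)) {
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(data = data, affine = affine,
                 voxel_size = as.numeric(voxel_size), tr = tr),
            class = "nifti_image")
}

#' @export
print.nifti_image <- function(x, ...) {
  d <- dim(x$data)
  cat("<nifti_image> ", paste(d, collapse = " x "),
      sprintf(" | voxel %s mm", paste(signif(x$voxel_size, 3), collapse = "x")),
      if (!is.na(x$tr)) sprintf(" | TR %.3g s", x$tr), "\n", sep = "")
  invisible(x)
}

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.read_all_bytes <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  chunks <- list()
  repeat {
    b <- readBin(con, "raw", n = 2^22)
    if (length(b) == 0) break
    chunks[[length(chunks) + 1L]] <- b
  }
  do.call(c, chunks)
}

#' Read a NIfTI-1 file
#'
#' Supports single-file `.nii` / `.nii.gz`, data types uint8/int8, int16,
#' uint16, int32, float32 and float64, both endiannesses, and the
#' `scl_slope`/`scl_inter` intensity scaling. The affine is taken from the
#' sform when present, else from the qform, else from `pixdim`.
#'
#' @param path file path.
#' @return A [nifti_image].
#' @export
read_nifti <- function(path) {
  raw <- .read_all_bytes(path)
  if (length(raw) < 352) stop("not a NIfTI-1 file (too short): ", path)
  endian <- "little"
  hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
  if (hdr_size != 348L) {
    endian <- "big"
    hdr_size <- readBin(raw[1:4], "integer", size = 4, endian = endian)
    if (hdr_size != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  rb <- function(off, what, n, size) {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  dims <- rb(40, "integer", 8, 2)
  ndim <- dims[1]
  if (ndim < 3 || ndim > 4) stop("only 3D/4D NIfTI supported, got ndim=", ndim)
  shape <- dims[2:(1 + ndim)]
  datatype <- rb(70, "integer", 1, 2)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rb(76, "double", 8, 4)
  vox_offset <- rb(108, "double", 1, 4)
  scl_slope <- rb(112, "double", 1, 4)
  scl_inter <- rb(116, "double", 1, 4)
  qform_code <- rb(252, "integer", 1, 2)
  sform_code <- rb(254, "integer", 1, 2)
  n_vox <- prod(shape)
  off <- as.integer(vox_offset)
  vals <- readBin(raw[(off + 1):(off + n_vox * dt$size)], dt$what,
                  n = n_vox, size = dt$size, signed = dt$signed,
                  endian = endian)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)

  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(rb(280, "double", 4, 4), rb(296, "double", 4, 4),
                    rb(312, "double", 4, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    b <- rb(256, "double", 1, 4); c_ <- rb(260, "double", 1, 4)
    d <- rb(264, "double", 1, 4)
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
      2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2),
      3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sc <- pixdim[2:4] * c(1, 1, qfac)
    affine <- rbind(cbind(R %*% diag(sc),
                          c(rb(268, "double", 1, 4), rb(272, "double", 1, 4),
                            rb(276, "double", 1, 4))),
                    c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  tr <- if (ndim == 4) pixdim[5] else NA_real_
  nifti_image(data, affine = affine, voxel_size = abs(pixdim[2:4]), tr = tr)
}

#' Write a NIfTI-1 file
#'
#' Writes a single-file NIfTI-1 image (`.nii`, gzipped when the path ends in
#' `.gz`), with the affine stored in the sform (code 2) and qform disabled,
#' and TR (seconds) in `pixdim[4]` for 4D data.
#'
#' @param img a [nifti_image], or a bare 3D/4D array (identity affine).
#' @param path destination path.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  if (!inherits(img, "nifti_image")) img <- nifti_image(img)
  shape <- dim(img$data)
  ndim <- length(shape)
  dims <- integer(8); dims[1] <- ndim; dims[2:(1 + ndim)] <- shape
  dims[(2 + ndim):8] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- img$voxel_size
  pixdim[5] <- if (ndim == 4 && is.finite(img$tr)) img$tr else 0

  dtcode <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L
  size <- bitpix / 8L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348)                      # sizeof_hdr
  w_raw(36)                      # data_type, db_name, extents, session_error, regular, dim_info
  w_i2(dims)                     # dim[8]
  w_f4(c(0, 0, 0))               # intent_p1..p3
  w_i2(0)                        # intent_code
  w_i2(dtcode)                   # datatype
  w_i2(bitpix)                   # bitpix
  w_i2(0)                        # slice_start
  w_f4(pixdim)                   # pixdim[8]
  w_f4(352)                      # vox_offset
  w_f4(1); w_f4(0)               # scl_slope, scl_inter
  w_i2(0)                        # slice_end
  w_raw(1)                       # slice_code
  writeBin(as.raw(10L), con)     # xyzt_units: mm | sec
  w_f4(c(0, 0))                  # cal_max, cal_min
  w_f4(c(0, 0))                  # slice_duration, toffset
  w_i4(c(0, 0))                  # glmax, glmin
  desc <- charToRaw("dalff")
  w_raw0 <- function(bytes, n) writeBin(c(bytes, raw(n - length(bytes))), con)
  w_raw0(desc, 80)               # descrip
  w_raw(24)                      # aux_file
  w_i2(0)                        # qform_code
  w_i2(2)                        # sform_code
  w_f4(c(0, 0, 0))               # quatern b,c,d
  w_f4(c(0, 0, 0))               # qoffset x,y,z
  w_f4(img$affine[1, ])          # srow_x
  w_f4(img$affine[2, ])          # srow_y
  w_f4(img$affine[3, ])          # srow_z
  w_raw(16)                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4)                       # extension flag
  vals <- as.numeric(img$data)
  # write in chunks to bound memory on large 4D series
  step <- 2^22
  for (i in seq(1, length(vals), by = step)) {
    j <- min(i + step - 1, length(vals))
    writeBin(vals[i:j], con, size = size, endian = "little")
  }
  invisible(path)
}

#' Map voxel indices to world coordinates
#'
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel convention).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz1 <- cbind(ijk - 1, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}
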