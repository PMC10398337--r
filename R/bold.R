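#' BOLD 4D image with geometry, TR and brain mask
#'
#' The working container for one subject's preprocessed (or raw synthetic)
#' resting-state series: a 4D array `(x, y, z, t)`, the voxel-to-world
#' affine, the repetition time in seconds and a 3D logical brain mask of the
#' same spatial shape.
#'
#' @param data 4D numeric array (x, y, z, t), t >= 2.
#' @param affine 4x4 voxel-to-world matrix in mm.
#' @param tr repetition time, seconds, > 0.
#' @param mask 3D logical/0-1 array matching the spatial shape; default all
#'   voxels.
#' @return An object of class `bold_image`.
#' @export
bold_image <- function(data, affine = NULL, tr, mask = NULL) {
  d <- dim(data)
  if (length(d) != 4L) stop("data must be 4D (x, y, z, t)")
  if (d[4] < 2L) stop("time dimension must be >= 2")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be > 0")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(as.logical(mask), dim(mask))
  if (!all(dim(mask) == d[1:3])) stop("mask shape must match spatial shape")
  if (is.null(affine)) affine <- diag(4)
  structure(list(data = data, affine = affine, tr = tr, mask = mask),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %dx%dx%d, %d volumes, TR %.3g s, %d mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

n_volumes <- function(bold) dim(bold$data)[4]

#' Read a subject covariate table
#'
#' Expects a delimited text file with a header row and at least the columns
#' `subject_id`, `group`, `age`, `sex`, `score`. `group` must have exactly
#' two levels; subject ids must be unique.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_covariates(df)
}

#' Validate a covariate table
#'
#' @param df data.frame with columns subject_id, group, age, sex, score.
#' @return The data.frame, invisibly checked (ids unique, two group levels,
#'   numeric age, 0/1 sex).
#' @export
validate_covariates <- function(df) {
  need <- c("subject_id", "group", "age", "sex", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("covariate table missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject ids in covariate table")
  if (length(unique(df$group)) != 2L)
    stop("group must have exactly 2 levels, got: ",
         paste(unique(df$group), collapse = ", "))
  if (!is.numeric(df$age)) stop("age must be numeric")
  if (!all(df$sex %in% c(0, 1)))
    stop("sex must be coded 0/1")
  df
}

#' @export
write_covariates <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Convert between bold_image and nifti_image
#' @param bold a [bold_image].
#' @return a [nifti_image] sharing data, affine and TR.
#' @export
as_nifti <- function(bold) {
  nifti_image(bold$data, affine = bold$affine, tr = bold$tr)
}

#' @rdname as_nifti
#' @param img a 4D [nifti_image].
#' @param mask optional 3D mask.
#' @export
as_bold <- function(img, mask = NULL) {
  bold_image(img$data, affine = img$affine, tr = img$tr, mask = mask)
}
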