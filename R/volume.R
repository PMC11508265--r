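# 3D volume container: scalar array + voxel spacing + 4x4 affine + role.

#' Construct a volume
#'
#' A light container for a 3D scalar image.  Voxel indices are 0-based in
#' all geometry computations; world coordinates are
#' `affine %*% c(i, j, k, 1)`.  The third array axis is the slice
#' (through-plane) axis.
#'
#' @param data 3D numeric array; binary (0/1) for masks.
#' @param spacing voxel spacing in mm, length 3, strictly positive.
#' @param affine 4x4 orientation matrix; default is `diag(c(spacing, 1))`.
#' @param role one of `"t2"`, `"adc"`, `"mask"`.
#' @return an `adc_volume` object.
#' @export
volume <- function(data, spacing, affine = NULL,
                   role = c("t2", "adc", "mask")) {
  role <- match.arg(role)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (any(!is.finite(data))) stop("data must be finite")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  cn <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(cn - spacing) > 1e-6 * pmax(1, spacing)))
    stop("affine column norms inconsistent with spacing")
  if (role == "mask" && !all(data %in% c(0, 1)))
    stop("mask volumes must be binary (0/1)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 affine = affine, role = role),
            class = "adc_volume")
}

#' @export
print.adc_volume <- function(x, ...) {
  cat("<adc_volume role=", x$role, "> ",
      paste(dim(x$data), collapse = "x"), " voxels @ ",
      paste(signif(x$spacing, 4), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

is_binary <- function(x) all(x %in% c(0, 1))
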