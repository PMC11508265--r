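# Data pipeline: resampling to target spacing, z-score normalization,
# prostate-mask-guided cropping, axial slice extraction to network-ready
# [-1, 1] images, and the inverse placement of generated slices back into
# volume geometry.
#
# Conventions: voxel indices are 0-based; crop boxes are half-open
# [lo, hi); the slice axis is the third array axis; the order of operations
# for training data is resample -> crop -> z-score -> per-volume rescale to
# [-1, 1] during slice extraction.

# 1D linear (or nearest) interpolation along one axis of a 3D array at
# fractional 0-based positions `xi`
interp_axis <- function(arr, xi, axis, nearest = FALSE) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  n <- d[axis]
  if (nearest) {
    idx <- pmin(pmax(round(xi), 0), n - 1) + 1
    out <- m[idx, , drop = FALSE]
  } else {
    x0 <- pmin(pmax(floor(xi), 0), n - 1)
    x1 <- pmin(x0 + 1, n - 1)
    wt <- pmin(pmax(xi - x0, 0), 1)
    out <- m[x0 + 1, , drop = FALSE] * (1 - wt) +
      m[x1 + 1, , drop = FALSE] * wt
  }
  dn <- d[perm]
  dn[1] <- length(xi)
  aperm(array(out, dn), order(perm))
}

#' Resample a volume to a target voxel spacing
#'
#' Output shape is `round(shape * spacing / target)`.  Intensity volumes use
#' trilinear interpolation (applied separably per axis); masks use
#' nearest-neighbor.  Sampling is voxel-center aligned and the affine is
#' updated consistently.
#'
#' @param vol an [volume()].
#' @param target_spacing length-3 positive spacing in mm (e.g.
#'   `c(0.5, 0.5, 3)`).
#' @return resampled [volume()].
#' @export
resample <- function(vol, target_spacing) {
  stopifnot(inherits(vol, "adc_volume"))
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be 3 positive values")
  d <- dim(vol$data)
  scale <- target_spacing / vol$spacing
  nd <- as.integer(round(d * vol$spacing / target_spacing))
  if (any(nd < 1)) stop("degenerate resample: output dimension would be 0")
  out <- vol$data
  nearest <- vol$role == "mask"
  for (ax in 1:3) {
    if (nd[ax] == dim(out)[ax] && abs(scale[ax] - 1) < 1e-12) next
    xi <- (seq_len(nd[ax]) - 1 + 0.5) * scale[ax] - 0.5
    out <- interp_axis(out, xi, ax, nearest = nearest)
  }
  if (nearest) out <- round(out)
  affine <- vol$affine
  xi0 <- 0.5 * scale - 0.5
  affine[, 4] <- vol$affine[, 1:3] %*% xi0 + vol$affine[, 4]
  affine[, 1:3] <- vol$affine[, 1:3] %*% diag(scale)
  affine[4, ] <- c(0, 0, 0, 1)
  volume(out, spacing = as.numeric(target_spacing), affine = affine,
         role = vol$role)
}

#' Z-score normalize a volume
#'
#' Subtracts the volume mean and divides by the volume standard deviation
#' (whole-volume statistics, not mask-restricted).
#'
#' @param vol an [volume()] with more than one distinct value.
#' @return normalized [volume()] (mean 0, sd 1).
#' @export
zscore <- function(vol) {
  stopifnot(inherits(vol, "adc_volume"))
  v <- as.vector(vol$data)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("zscore: volume has zero variance (constant image)")
  out <- vol
  out$data <- (vol$data - mean(v)) / s
  out$role <- vol$role
  out
}

#' Crop a volume to its prostate mask
#'
#' Computes the tight bounding box of the nonzero mask, dilates it by
#' `margin_mm` (converted to voxels, clipped to the volume bounds) and
#' returns the restricted volume plus the crop box.
#'
#' @param vol volume to crop.
#' @param mask binary mask on the same grid.
#' @param margin_mm scalar (applied in-plane, 0 through-plane) or length-3
#'   margin in mm.  Default 5 mm in-plane.
#' @return list with `volume` (cropped) and `crop_box`
#'   (`list(lo, hi)`, 0-based half-open voxel bounds in the parent grid).
#' @export
crop_to_mask <- function(vol, mask, margin_mm = 5) {
  stopifnot(inherits(vol, "adc_volume"), inherits(mask, "adc_volume"))
  if (!identical(dim(vol$data), dim(mask$data)))
    stop("vol and mask grids differ")
  if (!is_binary(mask$data)) stop("mask must be binary")
  idx <- which(mask$data > 0, arr.ind = TRUE) - 1L # 0-based voxel indices
  if (nrow(idx) == 0) stop("empty mask: nothing to crop to")
  if (length(margin_mm) == 1L) margin_mm <- c(margin_mm, margin_mm, 0)
  mv <- as.integer(round(margin_mm / vol$spacing))
  lo <- pmax(apply(idx, 2, min) - mv, 0L)
  hi <- pmin(apply(idx, 2, max) + mv, dim(vol$data) - 1L) + 1L # half-open
  out <- vol
  out$data <- vol$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                       (lo[3] + 1):hi[3], drop = FALSE]
  affine <- vol$affine
  affine[, 4] <- vol$affine[, 1:3] %*% lo + vol$affine[, 4]
  out$affine <- affine
  list(volume = out, crop_box = list(lo = unname(lo), hi = unname(hi)))
}

next_multiple <- function(x, k) as.integer(ceiling(x / k) * k)

#' Extract network-ready axial slices
#'
#' Emits one sample per axial slice with nonzero mask area.  Images are
#' rescaled from the per-volume intensity range to `[-1, 1]` (the range is
#' recorded for inversion) and padded symmetrically with -1 to the next
#' multiple of `stride` (the network's total downsampling factor, 4).
#' Pairing between domains is positional when `adc` is supplied.
#'
#' @param t2 T2W volume (domain X).
#' @param adc optional co-registered ADC volume (domain Y).
#' @param mask binary prostate mask on the same grid.
#' @param subject_id provenance tag stored on each sample.
#' @param crop_box optional crop box locating these volumes inside a parent
#'   volume (as returned by [crop_to_mask()]); defaults to the full grid.
#' @param stride divisibility requirement for height/width (default 4).
#' @param target_size optional fixed `c(height, width)` to pad every slice
#'   to (must be stride-divisible and at least the crop size); use this so
#'   slices from different subjects can share one batch shape.
#' @return list of `slice_sample` objects (domain X first, then domain Y in
#'   the same slice order, when `adc` is given).  Each sample has fields
#'   `image`, `domain`, `subject_id`, `slice_index` (0-based, local to the
#'   volume), `crop_box`, `pad` and `rescale`.
#' @export
extract_slices <- function(t2, adc = NULL, mask, subject_id = "subject",
                           crop_box = NULL, stride = 4,
                           target_size = NULL) {
  stopifnot(inherits(t2, "adc_volume"), inherits(mask, "adc_volume"))
  if (!identical(dim(t2$data), dim(mask$data)))
    stop("t2 and mask grids differ")
  if (!is.null(adc) && !identical(dim(adc$data), dim(t2$data)))
    stop("t2 and adc grids differ")
  if (is.null(crop_box))
    crop_box <- list(lo = c(0L, 0L, 0L), hi = dim(t2$data))
  keep <- which(apply(mask$data, 3, sum) > 0)
  if (length(keep) == 0) stop("no slice intersects the mask")

  one_domain <- function(vol, domain) {
    rng <- range(vol$data)
    lapply(keep, function(k) {
      img <- vol$data[, , k]
      if (rng[2] > rng[1]) {
        img <- 2 * (img - rng[1]) / (rng[2] - rng[1]) - 1
      } else {
        img <- img * 0
      }
      d <- dim(img)
      target <- if (is.null(target_size)) next_multiple(d, stride)
                else as.integer(target_size)
      if (any(target < d) || any(target %% stride != 0))
        stop("target_size must be stride-divisible and >= the slice size (",
             d[1], "x", d[2], ")")
      pt <- target - d
      pad <- c(h_lo = pt[1] %/% 2, h_hi = pt[1] - pt[1] %/% 2,
               w_lo = pt[2] %/% 2, w_hi = pt[2] - pt[2] %/% 2)
      out <- matrix(-1, target[1], target[2])
      out[pad[1] + seq_len(d[1]), pad[3] + seq_len(d[2])] <- img
      structure(list(image = out, domain = domain, subject_id = subject_id,
                     slice_index = k - 1L, crop_box = crop_box, pad = pad,
                     rescale = rng),
                class = "slice_sample")
    })
  }
  samples <- one_domain(t2, "X")
  if (!is.null(adc)) samples <- c(samples, one_domain(adc, "Y"))
  samples
}

#' Reinsert slices into volume geometry
#'
#' Inverse of [extract_slices()]: removes padding, inverts the `[-1, 1]`
#' rescaling using each sample's recorded range, and writes the slice into
#' its crop box within a volume shaped like `template`.
#'
#' @param samples list of `slice_sample` objects.
#' @param template an [volume()] providing the output grid and affine.
#' @param fill background value outside the crops (default 0).
#' @return an [volume()].
#' @export
reinsert_slices <- function(samples, template, fill = 0) {
  stopifnot(inherits(template, "adc_volume"))
  d <- dim(template$data)
  out <- array(fill, d)
  for (s in samples) {
    box <- s$crop_box
    if (any(box$lo < 0) || any(box$hi > d))
      stop("crop box out of template bounds for subject ", s$subject_id,
           " slice ", s$slice_index)
    k <- box$lo[3] + s$slice_index + 1L
    if (k > box$hi[3]) stop("slice index outside crop box")
    h <- box$hi[1] - box$lo[1]
    w <- box$hi[2] - box$lo[2]
    img <- s$image[s$pad[1] + seq_len(h), s$pad[3] + seq_len(w)]
    rng <- s$rescale
    if (rng[2] > rng[1]) img <- (img + 1) / 2 * (rng[2] - rng[1]) + rng[1]
    else img <- img * 0 + rng[1]
    out[box$lo[1] + seq_len(h), box$lo[2] + seq_len(w), k] <- img
  }
  vol <- template
  vol$data <- out
  vol
}
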