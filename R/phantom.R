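# Synthetic prostate phantom: paired T2W-like and ADC-like volumes with a
# binary prostate mask, distinct transition/peripheral zones, optional
# hypointense lesions present in both domains, and artifact corruptions of
# the ADC domain (motion ghosting, distortion, aliasing, noise).  Stands in
# for clinical cohorts so every downstream stage has ground truth.
#
# Intensity model: a zone label map (0 background, 1 peripheral zone, 2
# transition zone) assigns each voxel a base T2 intensity; lesions multiply
# the local T2 intensity by `lesion_contrast` (< 1).  The clean ADC volume
# is a zone-wise affine function of the clean T2 volume,
# adc = slope[zone] * t2 + offset[zone], optionally followed by a global
# gamma, so the two domains are related by a known monotone mapping.
# Independent Gaussian noise is then added to each domain.

ARTIFACT_KINDS <- c("motion_ghost", "distortion_field", "aliasing", "noise")

default_zone_contrast <- function() {
  list(t2 = c(background = 0.35, pz = 0.75, tz = 0.50),
       adc_slope = c(background = 0.8, pz = 1.2, tz = 1.1),
       adc_offset = c(background = -0.10, pz = -0.20, tz = -0.15))
}

#' Phantom specification
#'
#' @param grid_shape voxels per axis (default 96 x 96 x 12; axis 3 is the
#'   slice axis).
#' @param spacing_mm voxel spacing (default 0.75 x 0.75 x 3 mm, so
#'   resampling to the 0.5 x 0.5 x 3 mm training target is a real
#'   operation).
#' @param prostate_axes_mm ellipsoid semi-axes of the prostate.
#' @param tz_fraction transition zone semi-axes as a fraction of the
#'   prostate semi-axes (concentric inner ellipsoid).
#' @param n_lesions number of hypointense lesions (>= 0).
#' @param lesion_radius_mm length-2 radius range.
#' @param lesion_contrast multiplicative lesion intensity factor (< 1:
#'   hypointense in both domains).
#' @param zone_contrast list with `t2` base intensities and `adc_slope` /
#'   `adc_offset` per zone (`background`, `pz`, `tz`); slopes must be
#'   positive so the T2 -> ADC mapping is monotone.
#' @param gamma optional global gamma applied to the clean ADC volume.
#' @param noise_sd additive Gaussian noise level per domain (>= 0).
#' @param artifact_menu subset of
#'   `c("motion_ghost", "distortion_field", "aliasing", "noise")` applied to
#'   the ADC volume after noise.
#' @param artifact_magnitude magnitude handed to [corrupt_adc()] for each
#'   menu entry.
#' @param seed integer seed; the whole subject is deterministic given it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 12),
                         spacing_mm = c(0.75, 0.75, 3),
                         prostate_axes_mm = c(20, 16, 10),
                         tz_fraction = 0.55,
                         n_lesions = 2,
                         lesion_radius_mm = c(3, 6),
                         lesion_contrast = 0.6,
                         zone_contrast = default_zone_contrast(),
                         gamma = 1,
                         noise_sd = 0.03,
                         artifact_menu = character(0),
                         artifact_magnitude = 0.1,
                         seed = 1L) {
  spec <- structure(
    list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
         prostate_axes_mm = prostate_axes_mm, tz_fraction = tz_fraction,
         n_lesions = as.integer(n_lesions),
         lesion_radius_mm = lesion_radius_mm,
         lesion_contrast = lesion_contrast, zone_contrast = zone_contrast,
         gamma = gamma, noise_sd = noise_sd,
         artifact_menu = artifact_menu,
         artifact_magnitude = artifact_magnitude, seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec
  if (length(s$grid_shape) != 3 || any(s$grid_shape < 4))
    stop("invalid field grid_shape: need 3 axes of at least 4 voxels")
  if (length(s$spacing_mm) != 3 || any(s$spacing_mm <= 0))
    stop("invalid field spacing_mm: spacing must be positive")
  half_extent <- s$grid_shape / 2 * s$spacing_mm
  margin <- s$prostate_axes_mm + 2 * s$spacing_mm
  if (any(margin > half_extent))
    stop("invalid field prostate_axes_mm: prostate ellipsoid does not fit ",
         "inside the grid with a 2-voxel margin")
  if (s$tz_fraction <= 0 || s$tz_fraction >= 1)
    stop("invalid field tz_fraction: must be in (0, 1)")
  if (s$n_lesions < 0) stop("invalid field n_lesions: must be >= 0")
  if (length(s$lesion_radius_mm) != 2 || any(s$lesion_radius_mm <= 0) ||
      diff(s$lesion_radius_mm) < 0)
    stop("invalid field lesion_radius_mm: need an increasing positive range")
  if (s$lesion_radius_mm[2] > min(s$prostate_axes_mm))
    stop("invalid field lesion_radius_mm: lesion larger than prostate")
  if (s$lesion_contrast <= 0 || s$lesion_contrast >= 1)
    stop("invalid field lesion_contrast: must be in (0, 1)")
  zc <- s$zone_contrast
  vals <- unlist(zc)
  if (any(!is.finite(vals)))
    stop("invalid field zone_contrast: intensities must be finite")
  if (any(zc$adc_slope <= 0))
    stop("invalid field zone_contrast: adc_slope must be positive ",
         "(monotone mapping)")
  if (s$noise_sd < 0) stop("invalid field noise_sd: must be >= 0")
  if (!all(s$artifact_menu %in% ARTIFACT_KINDS))
    stop("invalid field artifact_menu: supported kinds are ",
         paste(ARTIFACT_KINDS, collapse = ", "))
  invisible(spec)
}

# voxel-center coordinates (mm) relative to the grid center, per axis
grid_coords <- function(shape, spacing) {
  lapply(1:3, function(ax)
    ((seq_len(shape[ax]) - 1) - (shape[ax] - 1) / 2) * spacing[ax])
}

#' Generate one phantom subject
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_subject`: list with `t2`, `adc`, `mask` volumes (same
#'   grid/spacing/affine), `zone_map` (0 = background, 1 = peripheral zone,
#'   2 = transition zone), `lesion_map` (binary), `lesion_table`
#'   (data.frame of center voxel indices, radius, zone) and `spec`.
#' @export
generate_subject <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  sh <- spec$grid_shape
  co <- grid_coords(sh, spec$spacing_mm)
  ax <- spec$prostate_axes_mm
  # squared normalized ellipsoid radius at every voxel
  r2 <- outer(outer((co[[1]] / ax[1])^2, (co[[2]] / ax[2])^2, `+`),
              (co[[3]] / ax[3])^2, `+`)
  prost <- r2 <= 1
  tz <- r2 <= spec$tz_fraction^2
  zone <- array(0L, sh)
  zone[prost] <- 1L
  zone[tz] <- 2L

  lesion <- array(FALSE, sh)
  lesion_rows <- list()
  if (spec$n_lesions > 0) {
    # candidate centers: deep enough inside the prostate that the lesion
    # sphere stays within the gland
    interior <- which(r2 <= 0.6^2)
    if (length(interior) == 0) stop("prostate too small for lesions")
    centers <- sample(interior, spec$n_lesions,
                      replace = length(interior) < spec$n_lesions)
    radii <- stats::runif(spec$n_lesions, spec$lesion_radius_mm[1],
                          spec$lesion_radius_mm[2])
    for (li in seq_len(spec$n_lesions)) {
      cidx <- arrayInd(centers[li], sh)
      cmm <- vapply(1:3, function(a) co[[a]][cidx[a]], numeric(1))
      d2 <- outer(outer((co[[1]] - cmm[1])^2, (co[[2]] - cmm[2])^2, `+`),
                  (co[[3]] - cmm[3])^2, `+`)
      lesion <- lesion | (d2 <= radii[li]^2)
      lesion_rows[[li]] <- data.frame(
        i = cidx[1] - 1L, j = cidx[2] - 1L, k = cidx[3] - 1L,
        radius_mm = radii[li], zone = c("pz", "tz")[zone[centers[li]]])
    }
  }
  lesion <- lesion & prost

  zc <- spec$zone_contrast
  zi <- zone + 1L # 1 = background, 2 = pz, 3 = tz
  t2_clean <- array(zc$t2[zi], sh)
  t2_clean[lesion] <- t2_clean[lesion] * spec$lesion_contrast
  adc_clean <- array(zc$adc_slope[zi], sh) * t2_clean +
    array(zc$adc_offset[zi], sh)
  if (spec$gamma != 1) adc_clean <- pmax(adc_clean, 0)^spec$gamma

  t2 <- t2_clean
  adc <- adc_clean
  if (spec$noise_sd > 0) {
    t2 <- t2 + array(stats::rnorm(prod(sh), 0, spec$noise_sd), sh)
    adc <- adc + array(stats::rnorm(prod(sh), 0, spec$noise_sd), sh)
  }
  affine <- diag(c(spec$spacing_mm, 1))
  mask_vol <- volume(array(as.numeric(prost), sh), spec$spacing_mm, affine,
                     role = "mask")
  adc_vol <- volume(adc, spec$spacing_mm, affine, role = "adc")
  for (kind in spec$artifact_menu)
    adc_vol <- corrupt_adc(adc_vol, kind, spec$artifact_magnitude,
                           seed = spec$seed + match(kind, ARTIFACT_KINDS))
  subject <- list(
    t2 = volume(t2, spec$spacing_mm, affine, role = "t2"),
    adc = adc_vol,
    mask = mask_vol,
    zone_map = zone,
    lesion_map = array(as.numeric(lesion), sh),
    lesion_table = if (length(lesion_rows)) do.call(rbind, lesion_rows)
                   else data.frame(i = integer(), j = integer(),
                                   k = integer(), radius_mm = numeric(),
                                   zone = character()),
    spec = spec)
  class(subject) <- "phantom_subject"
  subject
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat("<phantom_subject> grid", paste(x$spec$grid_shape, collapse = "x"),
      "|", nrow(x$lesion_table), "lesion(s) |",
      sum(x$mask$data), "prostate voxels\n")
  invisible(x)
}

# smooth random 2D field in [-1, 1]-ish units: low-resolution Gaussian noise
# bilinearly upsampled to H x W
smooth_field <- function(h, w, knots = 6) {
  g <- matrix(stats::rnorm(knots * knots), knots, knots)
  xi <- (seq_len(h) - 1) / (h - 1) * (knots - 1)
  yi <- (seq_len(w) - 1) / (w - 1) * (knots - 1)
  x0 <- pmin(floor(xi), knots - 2); wx <- xi - x0
  y0 <- pmin(floor(yi), knots - 2); wy <- yi - y0
  a <- g[x0 + 1, y0 + 1] * outer(1 - wx, 1 - wy) +
    g[x0 + 2, y0 + 1] * outer(wx, 1 - wy) +
    g[x0 + 1, y0 + 2] * outer(1 - wx, wy) +
    g[x0 + 2, y0 + 2] * outer(wx, wy)
  a
}

#' Corrupt an ADC volume with an acquisition-like artifact
#'
#' Qualitative emulations of the degradations seen in clinical ADC maps:
#' `motion_ghost` adds a shifted, attenuated copy along the phase axis
#' (axis 1); `distortion_field` applies a smooth random displacement
#' concentrated at the posterior boundary; `aliasing` adds a half-field-of-
#' view wrap-around; `noise` adds Gaussian noise with sd `magnitude`.
#' Magnitude 0 returns the input unchanged; results are reproducible under
#' `seed`.  Mask volumes are warped with nearest-neighbor interpolation and
#' stay binary.
#'
#' @param vol an [volume()].
#' @param kind artifact kind (see above).
#' @param magnitude artifact strength: ghost/aliasing amplitude (fraction),
#'   displacement amplitude in voxels, or noise sd.
#' @param seed integer seed.
#' @return a new [volume()].
#' @export
corrupt_adc <- function(vol, kind, magnitude, seed = 1L) {
  stopifnot(inherits(vol, "adc_volume"))
  if (!kind %in% ARTIFACT_KINDS)
    stop("unknown artifact kind '", kind, "'; supported kinds: ",
         paste(ARTIFACT_KINDS, collapse = ", "))
  if (magnitude == 0) return(vol)
  set.seed(seed)
  d <- dim(vol$data)
  out <- vol$data
  if (kind == "noise") {
    out <- out + array(stats::rnorm(prod(d), 0, magnitude), d)
  } else if (kind == "motion_ghost") {
    shift <- max(1L, round(d[1] / 8))
    idx <- ((seq_len(d[1]) - 1 + shift) %% d[1]) + 1
    out <- out + magnitude * out[idx, , , drop = FALSE]
  } else if (kind == "aliasing") {
    shift <- d[1] %/% 2
    idx <- ((seq_len(d[1]) - 1 + shift) %% d[1]) + 1
    out <- out + magnitude * out[idx, , , drop = FALSE]
  } else if (kind == "distortion_field") {
    # posterior = high row indices; weight ramps up towards that boundary
    wgt <- exp(-((d[1] - seq_len(d[1])) / (d[1] / 4))^2)
    disp <- smooth_field(d[1], d[2]) * magnitude * wgt
    nearest <- vol$role == "mask"
    rows <- seq_len(d[1])
    for (k in seq_len(d[3])) {
      m <- vol$data[, , k]
      xi <- rows - disp # source row per target voxel
      xi <- pmin(pmax(xi, 1), d[1])
      if (nearest) {
        x0 <- round(xi)
        out[, , k] <- m[cbind(as.vector(x0), rep(seq_len(d[2]), each = d[1]))]
      } else {
        x0 <- pmin(floor(xi), d[1] - 1)
        wq <- xi - x0
        colj <- rep(seq_len(d[2]), each = d[1])
        v0 <- m[cbind(as.vector(x0), colj)]
        v1 <- m[cbind(as.vector(x0 + 1), colj)]
        out[, , k] <- v0 * (1 - as.vector(wq)) + v1 * as.vector(wq)
      }
    }
    if (nearest) out <- round(out)
  }
  res <- vol
  res$data <- out
  res
}

#' Generate and write a phantom cohort
#'
#' Writes one NIfTI triple (t2, adc, mask) per subject plus a manifest CSV
#' (`subject_id,t2_path,adc_path,mask_path`).  Per-subject seeds are derived
#' deterministically from the master seed.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param spec a [phantom_spec()]; its `seed` field is overridden per
#'   subject.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest data.frame, invisibly; also written to
#'   `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(n_subjects, spec = phantom_spec(), seed = 1L,
                            out_dir) {
  stopifnot(n_subjects >= 1)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sspec <- spec
    sspec$seed <- as.integer((as.numeric(seed) * 1009 + i * 7919) %%
                               2147483647)
    subj <- generate_subject(sspec)
    id <- sprintf("sub-%03d", i)
    paths <- file.path(out_dir, paste0(id, "_", c("t2", "adc", "mask"),
                                       ".nii.gz"))
    write_nifti(subj$t2, paths[1])
    write_nifti(subj$adc, paths[2])
    write_nifti(subj$mask, paths[3])
    rows[[i]] <- data.frame(subject_id = id, t2_path = paths[1],
                            adc_path = paths[2], mask_path = paths[3])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
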