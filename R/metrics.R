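# Evaluation metrics: PSNR, SSIM (with its luminance/contrast/structure
# decomposition), the Frechet distance between Gaussian feature moments
# (FID when the extractor is an Inception embedding; pluggable here), Dice,
# and the dataset-level evaluation harness.
#
# Metrics operate on [0, 1]-rescaled images (the inverse of the [-1, 1]
# training range); the PSNR peak defaults to the maximum of the reference
# image.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX_I^2 / MSE)` with `MSE` the mean squared pixel
#' difference.  Returns `Inf` when the images are identical.
#'
#' @param reference,generated 2D images of equal shape.
#' @param max_i peak intensity; `"auto"` (default) uses
#'   `max(reference)`.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, generated, max_i = "auto") {
  if (!identical(dim(reference), dim(generated)))
    stop("image shapes differ")
  mse <- mean((reference - generated)^2)
  if (identical(max_i, "auto")) max_i <- max(reference)
  if (!is.numeric(max_i) || max_i <= 0) stop("max_i must be positive")
  if (mse == 0) return(Inf)
  10 * log10(max_i^2 / mse)
}

gaussian_kernel1d <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# valid-mode separable filtering: band matrix of kernel rows
filter_band <- function(n, kern) {
  ks <- length(kern)
  A <- matrix(0, n - ks + 1, n)
  for (i in seq_len(n - ks + 1)) A[i, i:(i + ks - 1)] <- kern
  A
}

#' Structural similarity index
#'
#' Windowed SSIM with an 11 x 11 Gaussian window (sigma 1.5) and constants
#' `C1 = (0.01 * data_range)^2`, `C2 = (0.03 * data_range)^2`,
#' `c3 = C2 / 2`.  Returns the mean SSIM together with the per-window SSIM
#' map and the luminance/contrast/structure component maps; with
#' `c3 = C2/2` the product `l * c * s` equals the SSIM map.
#'
#' @param x,y 2D images of equal shape, at least as large as the window.
#' @param window window size (odd, default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param data_range intensity range of the images (default 1 for [0, 1]
#'   images).
#' @return list with `ssim` (mean), `map`, `l`, `c`, `s` (maps) and
#'   `l_mean`, `c_mean`, `s_mean`.
#' @export
ssim <- function(x, y, window = 11, sigma = 1.5, data_range = 1) {
  if (!identical(dim(x), dim(y))) stop("image shapes differ")
  if (data_range <= 0) stop("data_range must be positive")
  d <- dim(x)
  if (any(d < window))
    stop("image (", d[1], "x", d[2], ") smaller than the ", window,
         "x", window, " window")
  kern <- gaussian_kernel1d(window, sigma)
  A <- filter_band(d[1], kern)
  B <- filter_band(d[2], kern)
  f <- function(m) A %*% m %*% t(B)
  mx <- f(x); my <- f(y)
  sx2 <- f(x * x) - mx^2
  sy2 <- f(y * y) - my^2
  sxy <- f(x * y) - mx * my
  sx <- sqrt(pmax(sx2, 0))
  sy <- sqrt(pmax(sy2, 0))
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  c3 <- c2 / 2
  lmap <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  cmap <- (2 * sx * sy + c2) / (sx2 + sy2 + c2)
  smap <- (sxy + c3) / (sx * sy + c3)
  map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sx2 + sy2 + c2))
  list(ssim = mean(map), map = map, l = lmap, c = cmap, s = smap,
       l_mean = mean(lmap), c_mean = mean(cmap), s_mean = mean(smap))
}

#' Gaussian feature moments
#'
#' @param mu mean vector.
#' @param sigma covariance matrix (symmetric).
#' @param n_samples number of samples the moments were estimated from
#'   (>= 2).
#' @return a `gaussian_moments` object.
#' @export
gaussian_moments <- function(mu, sigma, n_samples) {
  sigma <- as.matrix(sigma)
  if (length(mu) != nrow(sigma) || nrow(sigma) != ncol(sigma))
    stop("mu/sigma dimensions disagree")
  if (max(abs(sigma - t(sigma))) > 1e-8)
    stop("sigma must be symmetric")
  if (n_samples < 2) stop("need at least 2 samples")
  structure(list(mu = as.numeric(mu), sigma = (sigma + t(sigma)) / 2,
                 n_samples = as.integer(n_samples)),
            class = "gaussian_moments")
}

sqrtm_sym <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (any(e$values < -1e-8 * max(abs(e$values), 1)))
    stop("matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Frechet distance between two Gaussians
#'
#' `|mu_r - mu_g|^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})`, with the matrix
#' square root taken via eigen-decomposition and a small diagonal
#' regularization for stability.  Non-negative; 0 at equal moments.
#'
#' @param real,gen `gaussian_moments` of equal dimension.
#' @param eps diagonal regularization (default 1e-8).
#' @return scalar distance.
#' @export
fid <- function(real, gen, eps = 1e-8) {
  stopifnot(inherits(real, "gaussian_moments"),
            inherits(gen, "gaussian_moments"))
  if (length(real$mu) != length(gen$mu))
    stop("moment dimensions differ")
  k <- length(real$mu)
  sr <- real$sigma + diag(eps, k)
  sg <- gen$sigma + diag(eps, k)
  s <- sqrtm_sym(sr)
  m <- s %*% sg %*% s
  m <- (m + t(m)) / 2
  tr_sqrt <- sum(sqrt(pmax(eigen(m, symmetric = TRUE,
                                 only.values = TRUE)$values, 0)))
  val <- sum((real$mu - gen$mu)^2) + sum(diag(sr)) + sum(diag(sg)) -
    2 * tr_sqrt
  max(val, 0)
}

resize_bilinear <- function(m, h, w) {
  a <- array(m, c(dim(m), 1L))
  xi <- (seq_len(h) - 0.5) * (dim(m)[1] / h) - 0.5
  yi <- (seq_len(w) - 0.5) * (dim(m)[2] / w) - 0.5
  a <- interp_axis(a, xi, 1)
  a <- interp_axis(a, yi, 2)
  matrix(a, h, w)
}

#' Embed an image set and compute its Gaussian moments
#'
#' Deterministic, pluggable feature extractors for the Frechet distance:
#' `raw_pool` bilinearly downsamples each image to `pool x pool` and
#' flattens; `random_projection` projects flattened pixels through a fixed
#' seeded Gaussian matrix to `dim` features (all images must share a size).
#' The Inception network used for the classic FID is an external extractor
#' and is intentionally not bundled.
#'
#' @param images list of 2D images (>= 2).
#' @param extractor `"raw_pool"` or `"random_projection"`.
#' @param pool `raw_pool` output side length (default 8).
#' @param dim `random_projection` output dimension (default 64).
#' @param seed seed for the projection matrix.
#' @return a [gaussian_moments()] with unbiased covariance.
#' @export
embed_features <- function(images, extractor = c("raw_pool",
                                                 "random_projection"),
                           pool = 8, dim = 64, seed = 1L) {
  extractor <- match.arg(extractor)
  if (length(images) < 2) stop("need at least 2 images")
  if (extractor == "raw_pool") {
    feats <- t(vapply(images, function(m)
      as.vector(resize_bilinear(m, pool, pool)), numeric(pool * pool)))
  } else {
    npix <- length(images[[1]])
    if (!all(vapply(images, length, numeric(1)) == npix))
      stop("random_projection requires equally sized images")
    set.seed(seed)
    P <- matrix(stats::rnorm(npix * dim), npix, dim) / sqrt(npix)
    feats <- t(vapply(images, function(m) as.numeric(crossprod(P, as.vector(m))),
                      numeric(dim)))
  }
  gaussian_moments(colMeans(feats), stats::cov(feats), nrow(feats))
}

#' Dice similarity coefficient
#'
#' `2 |X intersect Y| / (|X| + |Y|)`; defined as 1 when both masks are
#' empty.
#'
#' @param x_mask,y_mask binary arrays of equal shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(x_mask, y_mask) {
  if (!identical(dim(x_mask), dim(y_mask))) stop("mask shapes differ")
  if (!is_binary(x_mask) || !is_binary(y_mask))
    stop("masks must be binary (0/1)")
  nx <- sum(x_mask)
  ny <- sum(y_mask)
  if (nx + ny == 0) return(1)
  2 * sum(x_mask * y_mask) / (nx + ny)
}

slice_key <- function(s) paste0(s$subject_id, "#", s$slice_index)

slice_image01 <- function(s) {
  img <- if (inherits(s, "slice_sample")) s$image else s
  (img + 1) / 2
}

#' Evaluate generated slices against ground truth
#'
#' Pairs prediction and truth slices by subject + slice index, computes
#' per-slice PSNR and SSIM on [0, 1]-rescaled images, one Frechet distance
#' over the two slice sets, and (optionally) Dice over paired binary masks.
#'
#' @param pred_slices,truth_slices lists of `slice_sample` objects (from
#'   [extract_slices()] or [infer()]).
#' @param masks optional list with elements `pred` and `truth`: equal-length
#'   lists of binary arrays to score with [dice()].
#' @param extractor feature extractor passed to [embed_features()].
#' @return a `metric_report`: list with `per_slice` (data.frame
#'   `subject,slice,psnr,ssim`), `summary` (`metric,mean,sd`), `fid`,
#'   `dice`, `n_slices`.
#' @export
evaluate <- function(pred_slices, truth_slices, masks = NULL,
                     extractor = "raw_pool") {
  pk <- vapply(pred_slices, slice_key, character(1))
  tk <- vapply(truth_slices, slice_key, character(1))
  if (anyDuplicated(pk) || anyDuplicated(tk))
    stop("duplicate subject/slice keys: ",
         paste(unique(c(pk[duplicated(pk)], tk[duplicated(tk)])),
               collapse = ", "),
         " (filter the slice lists to one domain before evaluating)")
  missing_in_truth <- setdiff(pk, tk)
  missing_in_pred <- setdiff(tk, pk)
  if (length(missing_in_truth) || length(missing_in_pred))
    stop("unpaired slices: ",
         paste(c(missing_in_truth, missing_in_pred), collapse = ", "))
  ord <- match(pk, tk)
  rows <- vector("list", length(pred_slices))
  pred_imgs <- list()
  truth_imgs <- list()
  for (i in seq_along(pred_slices)) {
    p <- slice_image01(pred_slices[[i]])
    t0 <- slice_image01(truth_slices[[ord[i]]])
    pred_imgs[[i]] <- p
    truth_imgs[[i]] <- t0
    rows[[i]] <- data.frame(
      subject = pred_slices[[i]]$subject_id,
      slice = pred_slices[[i]]$slice_index,
      psnr = psnr(t0, p),
      ssim = ssim(t0, p, data_range = 1)$ssim)
  }
  per_slice <- do.call(rbind, rows)
  fid_val <- if (length(pred_imgs) >= 2)
    fid(embed_features(truth_imgs, extractor),
        embed_features(pred_imgs, extractor)) else NA_real_
  dice_val <- NULL
  if (!is.null(masks)) {
    stopifnot(length(masks$pred) == length(masks$truth))
    dv <- mapply(dice, masks$pred, masks$truth)
    dice_val <- c(mean = mean(dv), sd = if (length(dv) > 1) stats::sd(dv)
                  else 0)
  }
  sdv <- function(v) if (length(v) > 1) stats::sd(v) else 0
  finite_psnr <- per_slice$psnr[is.finite(per_slice$psnr)]
  summary <- data.frame(
    metric = c("psnr", "ssim"),
    mean = c(if (length(finite_psnr)) mean(finite_psnr) else Inf,
             mean(per_slice$ssim)),
    sd = c(if (length(finite_psnr)) sdv(finite_psnr) else 0,
           sdv(per_slice$ssim)))
  structure(list(per_slice = per_slice, summary = summary, fid = fid_val,
                 dice = dice_val, n_slices = nrow(per_slice)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Evaluation over", x$n_slices, "slice pair(s)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %8.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat(sprintf("  %-5s %8.4f\n", "fid", x$fid))
  if (!is.null(x$dice))
    cat(sprintf("  %-5s %8.4f +/- %.4f\n", "dice", x$dice["mean"],
                x$dice["sd"]))
  invisible(x)
}

#' Write a metric report to CSV
#'
#' Per-slice rows `subject,slice,psnr,ssim` followed by a summary block
#' `metric,mean,sd` and a `fid,<value>` line.
#'
#' @param report a `metric_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(report$per_slice, con, row.names = FALSE)
  writeLines("", con)
  writeLines("metric,mean,sd", con)
  s <- report$summary
  for (i in seq_len(nrow(s)))
    writeLines(sprintf("%s,%.6f,%.6f", s$metric[i], s$mean[i], s$sd[i]), con)
  writeLines(sprintf("fid,%.6f", report$fid), con)
  if (!is.null(report$dice))
    writeLines(sprintf("dice,%.6f,%.6f", report$dice["mean"],
                       report$dice["sd"]), con)
  invisible(path)
}
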