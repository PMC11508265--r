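# Network definitions: the ResNet-9 encoder-decoder generator with an
# integrated CBAM attention stage, the 70x70 PatchGAN discriminator, and the
# SimCLR-style projection heads used by the patch-wise contrastive loss.

#' Attention (CBAM) configuration
#'
#' @param placement encoder stage carrying the attention module: 1 = after
#'   the first 7x7 convolution (base width channels), 2/3 = after the
#'   first/second downsampling stage.
#' @param reduction_ratio channel-MLP bottleneck ratio; must divide the
#'   channel count at `placement`.
#' @param spatial_kernel odd kernel size of the spatial-attention
#'   convolution.
#' @return an `attention_config` list.
#' @export
attention_config <- function(placement = 1, reduction_ratio = 8,
                             spatial_kernel = 5) {
  stopifnot(placement %in% 1:3, reduction_ratio >= 1,
            spatial_kernel %% 2 == 1)
  structure(list(placement = placement, reduction_ratio = reduction_ratio,
                 spatial_kernel = spatial_kernel),
            class = "attention_config")
}

#' Generator configuration
#'
#' Describes the ResNet encoder-decoder generator: a 7x7 stem convolution at
#' `base_width` channels, two stride-2 downsampling convolutions,
#' `n_resblocks` residual blocks at 4x width, two transposed-convolution
#' upsampling stages and a 7x7 tanh output head, with instance normalization
#' and reflection padding throughout.  Grayscale slices are replicated to
#' three channels, matching the printed parameter budget of the standard
#' 3-channel generator.
#'
#' @param in_channels,out_channels image channels (default 3).
#' @param base_width stem width (default 64; use 16 for the CPU test scale).
#' @param n_resblocks number of residual blocks (default 9).
#' @param cbam an [attention_config()], or `NULL`/`FALSE` to disable the
#'   attention module.
#' @return a `generator_config` list.
#' @export
generator_config <- function(in_channels = 3, out_channels = 3,
                             base_width = 64, n_resblocks = 9,
                             cbam = attention_config()) {
  stopifnot(in_channels >= 1, out_channels >= 1, base_width >= 1,
            n_resblocks >= 1)
  if (isFALSE(cbam)) cbam <- NULL
  if (!is.null(cbam) && !inherits(cbam, "attention_config"))
    stop("cbam must be an attention_config(), NULL or FALSE")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 base_width = base_width, n_resblocks = n_resblocks,
                 cbam = cbam),
            class = "generator_config")
}

#' Build the generator
#'
#' Instantiates the generator with Glorot-initialized weights.  With the
#' default configuration the trainable parameter count is 11,379,254
#' (11.379M); disabling CBAM gives 11,378,179 (11.378M).
#'
#' @param config a [generator_config()].
#' @return an `adc_generator` object with elements `layers`, `params`,
#'   `taps` (encoder tap points used by PatchNCE), `n_parameters`, and
#'   `config`.
#' @export
build_generator <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop("config must be a generator_config()")
  w <- config$base_width
  layers <- list()
  taps <- integer()
  add <- function(...) for (l in list(...))
    layers[[length(layers) + 1L]] <<- l

  add(layer_conv(config$in_channels, w, 7, pad = 3, pad_mode = "reflect"),
      layer_instnorm(), layer_relu())
  taps["enc1"] <- length(layers)
  stage_ch <- c(w, 2L * w, 4L * w)
  if (!is.null(config$cbam) && config$cbam$placement == 1)
    add(layer_cbam(stage_ch[1], config$cbam$reduction_ratio,
                   config$cbam$spatial_kernel))
  add(layer_conv(w, 2 * w, 3, stride = 2, pad = 1), layer_instnorm(),
      layer_relu())
  taps["enc2"] <- length(layers)
  if (!is.null(config$cbam) && config$cbam$placement == 2)
    add(layer_cbam(stage_ch[2], config$cbam$reduction_ratio,
                   config$cbam$spatial_kernel))
  add(layer_conv(2 * w, 4 * w, 3, stride = 2, pad = 1), layer_instnorm(),
      layer_relu())
  taps["enc3"] <- length(layers)
  if (!is.null(config$cbam) && config$cbam$placement == 3)
    add(layer_cbam(stage_ch[3], config$cbam$reduction_ratio,
                   config$cbam$spatial_kernel))
  res_tap <- min(4L, config$n_resblocks)
  for (b in seq_len(config$n_resblocks)) {
    add(layer_resblock(4 * w))
    if (b == res_tap) taps["enc4"] <- length(layers)
  }
  encoder_len <- taps["enc4"]
  add(layer_convt(4 * w, 2 * w), layer_instnorm(), layer_relu())
  add(layer_convt(2 * w, w), layer_instnorm(), layer_relu())
  add(layer_conv(w, config$out_channels, 7, pad = 3, pad_mode = "reflect"),
      layer_tanh())

  params <- seq_params(layers)
  tap_channels <- c(enc0 = config$in_channels, enc1 = w, enc2 = 2L * w,
                    enc3 = 4L * w, enc4 = 4L * w)
  structure(list(layers = layers, params = params, taps = taps,
                 tap_channels = tap_channels,
                 encoder_len = unname(encoder_len),
                 n_parameters = n_params(params), config = config),
            class = "adc_generator")
}

#' @export
print.adc_generator <- function(x, ...) {
  cat("<adc_generator> base width", x$config$base_width, "|",
      x$config$n_resblocks, "residual blocks |",
      if (is.null(x$config$cbam)) "no attention" else "CBAM", "|",
      formatC(x$n_parameters, big.mark = ","), "parameters\n")
  invisible(x)
}

# forward through generator layers; `encoder_only` stops at the PatchNCE tap
# depth.  Returns output, per-layer caches and tapped encoder features.
gen_forward <- function(gen, x, encoder_only = FALSE, want_taps = FALSE) {
  upto <- if (encoder_only) gen$encoder_len else length(gen$layers)
  caches <- vector("list", upto)
  feats <- if (want_taps) list(enc0 = x) else NULL
  h <- x
  for (i in seq_len(upto)) {
    r <- gen$layers[[i]]$fwd(h)
    caches[[i]] <- r$cache
    h <- r$y
    if (want_taps) {
      hit <- names(gen$taps)[which(gen$taps == i)]
      if (length(hit)) feats[[hit]] <- h
    }
  }
  list(y = h, caches = caches, feats = feats)
}

# backward; `tap_g` carries extra gradients injected at encoder tap points
# (from the contrastive heads).  Returns the gradient w.r.t. the input.
gen_backward <- function(gen, caches, gy = NULL, tap_g = NULL,
                         encoder_only = FALSE) {
  from <- if (encoder_only) gen$encoder_len else length(gen$layers)
  g <- if (is.null(gy)) 0 else gy
  for (i in rev(seq_len(from))) {
    if (!is.null(tap_g)) {
      hit <- names(gen$taps)[which(gen$taps == i)]
      if (length(hit) && !is.null(tap_g[[hit]])) g <- g + tap_g[[hit]]
    }
    g <- gen$layers[[i]]$bwd(caches[[i]], g)
  }
  if (!is.null(tap_g) && !is.null(tap_g$enc0)) g <- g + tap_g$enc0
  g
}

#' Build the PatchGAN discriminator
#'
#' 70x70-receptive-field patch classifier: 4x4 convolutions with widths
#' 64-128-256-512 (strides 2, 2, 2, 1) and a stride-1 one-channel head.  The
#' output is an unbounded spatial map of patch scores (no sigmoid; the
#' least-squares adversarial loss operates on raw scores).
#'
#' @param in_channels input image channels.
#' @param base_width first-stage width (default 64).
#' @return an `adc_discriminator` object.
#' @export
build_discriminator <- function(in_channels = 3, base_width = 64) {
  w <- base_width
  layers <- list(
    layer_conv(in_channels, w, 4, stride = 2, pad = 1), layer_lrelu(),
    layer_conv(w, 2 * w, 4, stride = 2, pad = 1), layer_instnorm(),
    layer_lrelu(),
    layer_conv(2 * w, 4 * w, 4, stride = 2, pad = 1), layer_instnorm(),
    layer_lrelu(),
    layer_conv(4 * w, 8 * w, 4, stride = 1, pad = 1), layer_instnorm(),
    layer_lrelu(),
    layer_conv(8 * w, 1, 4, stride = 1, pad = 1)
  )
  params <- seq_params(layers)
  structure(list(layers = layers, params = params,
                 n_parameters = n_params(params),
                 in_channels = in_channels, base_width = base_width),
            class = "adc_discriminator")
}

disc_forward <- function(disc, x) seq_fwd(disc$layers, x)
disc_backward <- function(disc, caches, gy) seq_bwd(disc$layers, caches, gy)

#' Build per-layer projection heads
#'
#' One SimCLR-style MLP (linear - ReLU - linear, independent weights) per
#' tapped encoder layer, mapping `in_dims[l]`-channel patch features to
#' `out_dim`-dimensional embeddings.
#'
#' @param in_dims named or plain integer vector of per-layer input channel
#'   counts.
#' @param out_dim embedding dimension (default 256).
#' @return an `adc_projection_head` object; element `heads` holds one
#'   layer list per entry of `in_dims`.
#' @export
build_projection_head <- function(in_dims, out_dim = 256) {
  heads <- lapply(in_dims, function(d)
    list(layer_linear(d, out_dim), layer_relu(), layer_linear(out_dim, out_dim)))
  params <- list()
  for (h in heads) params <- c(params, seq_params(h))
  structure(list(heads = heads, params = params, out_dim = out_dim,
                 in_dims = in_dims, n_parameters = n_params(params)),
            class = "adc_projection_head")
}

head_forward <- function(head, l, z) seq_fwd(head$heads[[l]], z)
head_backward <- function(head, l, caches, gy) seq_bwd(head$heads[[l]], caches, gy)

# rows of z -> unit L2 norm; returns normalized rows + cache for backward
l2_normalize_rows <- function(z, eps = 1e-12) {
  nrm <- sqrt(rowSums(z^2)) + eps
  list(y = z / nrm, nrm = nrm)
}

l2_normalize_bwd <- function(cache, gy) {
  # d(u/|u|) = (g - y (y.g)) / |u|
  y <- cache$y
  (gy - y * rowSums(gy * y)) / cache$nrm
}

#' Sample patch embeddings from the generator encoder
#'
#' Runs the encoder half of the generator on `image`, taps the configured
#' feature layers, samples `n_locations` spatial positions per layer,
#' projects the feature vectors through the projection head and
#' L2-normalizes them.  To compare two images at corresponding patches, pass
#' the `locations` element of the first call as `shared_locations` to the
#' second.
#'
#' @param generator an `adc_generator`.
#' @param image a 2D slice matrix in `[-1, 1]`, or an `[H, W, C, N]` array.
#' @param layer_ids subset of `c("enc0","enc1","enc2","enc3","enc4")`
#'   (default: all five — input image, stem, the two downsamples, and the
#'   fourth residual block).
#' @param n_locations patches sampled per layer (default 256).
#' @param head an `adc_projection_head` matching `layer_ids`, or `NULL` for
#'   raw (unprojected) features.
#' @param seed integer seed for location sampling (ignored when
#'   `shared_locations` is given).
#' @param shared_locations `locations` element of a previous call.
#' @return a `feature_stack`: list with `layers`, per-layer `embeddings`
#'   (`[S, D, N]` arrays of unit-norm rows; an all-zero feature vector — a
#'   dead-ReLU location — stays zero) and `locations` (integer vectors of
#'   flat spatial indices).
#' @export
encode_patch_features <- function(generator, image,
                                  layer_ids = names(generator$tap_channels),
                                  n_locations = 256, head = NULL, seed = NULL,
                                  shared_locations = NULL) {
  x <- slice_to_tensor(image, generator$config$in_channels)
  fw <- gen_forward(generator, x, encoder_only = TRUE, want_taps = TRUE)
  embeddings <- list()
  locations <- list()
  if (!is.null(seed) && is.null(shared_locations)) set.seed(seed)
  for (li in seq_along(layer_ids)) {
    nm <- layer_ids[[li]]
    f <- fw$feats[[nm]]
    d <- dim(f)
    hw <- d[1] * d[2]
    if (n_locations > hw)
      stop("n_locations (", n_locations, ") exceeds spatial size (", hw,
           ") of layer ", nm)
    loc <- if (!is.null(shared_locations)) shared_locations[[nm]]
           else sample.int(hw, n_locations)
    fm <- array(f, c(hw, d[3], d[4]))
    D <- if (is.null(head)) d[3] else head$out_dim
    emb <- array(0, c(length(loc), D, d[4]))
    for (n in seq_len(d[4])) {
      z <- fm[loc, , n, drop = FALSE]
      dim(z) <- c(length(loc), d[3])
      if (!is.null(head)) z <- head_forward(head, li, z)$y
      emb[, , n] <- l2_normalize_rows(z)$y
    }
    embeddings[[nm]] <- emb
    locations[[nm]] <- loc
  }
  structure(list(layers = layer_ids, embeddings = embeddings,
                 locations = locations),
            class = "feature_stack")
}

# accept a 2D matrix (replicated to the channel count) or a 4D tensor
slice_to_tensor <- function(image, channels) {
  if (is.matrix(image)) {
    x <- array(image, c(nrow(image), ncol(image), 1L, 1L))
    x <- x[, , rep(1L, channels), , drop = FALSE]
    return(x)
  }
  d <- dim(image)
  if (length(d) == 4L) return(image)
  if (length(d) == 3L) return(array(image, c(d, 1L)))
  stop("image must be a 2D matrix or a [H, W, C, N] array")
}

#' Count trainable parameters
#' @param net an `adc_generator`, `adc_discriminator` or
#'   `adc_projection_head`.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) n_params(net$params)

## ---- checkpointing ----------------------------------------------------

net_weights <- function(net) lapply(net$params, function(p) p$v)

set_net_weights <- function(net, weights) {
  stopifnot(length(weights) == length(net$params))
  for (i in seq_along(weights)) {
    stopifnot(length(net$params[[i]]$v) == length(weights[[i]]))
    net$params[[i]]$v <- weights[[i]]
  }
  invisible(net)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive of named weight arrays plus the
#' configurations needed to rebuild the networks.
#'
#' @param path file path (`.rds`).
#' @param generator,discriminator,head networks to store (`discriminator`
#'   and `head` optional).
#' @param meta optional list of run metadata (training config, rescale
#'   ranges, ...).
#' @return `load_checkpoint()` returns a list with rebuilt networks and
#'   `meta`.
#' @export
save_checkpoint <- function(path, generator, discriminator = NULL,
                            head = NULL, meta = list()) {
  obj <- list(
    format = "adcgan-checkpoint-1",
    generator_config = generator$config,
    generator_weights = net_weights(generator),
    discriminator_spec = if (!is.null(discriminator))
      list(in_channels = discriminator$in_channels,
           base_width = discriminator$base_width),
    discriminator_weights = if (!is.null(discriminator))
      net_weights(discriminator),
    head_spec = if (!is.null(head))
      list(in_dims = head$in_dims, out_dim = head$out_dim),
    head_weights = if (!is.null(head)) net_weights(head),
    meta = meta
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "adcgan-checkpoint-1"))
    stop("not an adcgan checkpoint: ", path)
  gen <- build_generator(obj$generator_config)
  set_net_weights(gen, obj$generator_weights)
  disc <- NULL
  if (!is.null(obj$discriminator_spec)) {
    disc <- build_discriminator(obj$discriminator_spec$in_channels,
                                obj$discriminator_spec$base_width)
    set_net_weights(disc, obj$discriminator_weights)
  }
  head <- NULL
  if (!is.null(obj$head_spec)) {
    head <- build_projection_head(obj$head_spec$in_dims,
                                  obj$head_spec$out_dim)
    set_net_weights(head, obj$head_weights)
  }
  list(generator = gen, discriminator = disc, head = head, meta = obj$meta)
}
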