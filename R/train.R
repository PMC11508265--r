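# Unpaired adversarial training of the generator/discriminator/projection
# heads, and inference.  Each iteration performs a discriminator step
# (LSGAN) followed by a generator+head step minimizing
#   adv + lambda_SR * SR + lambda_X * PatchNCE(X) + lambda_Y * PatchNCE(Y),
# where the PatchNCE query embeddings come from re-encoding the generated
# image with the generator's own encoder, so contrastive gradients flow
# both through the encoder taps and through the full generator.

#' Training configuration
#'
#' Defaults follow the reference protocol: 5 epochs, batch size 4, Adam
#' with learning rate 0.0002 (beta1 = 0.5, beta2 = 0.999), Glorot
#' initialization, temperature 0.07.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size slices per batch.
#' @param learning_rate Adam learning rate.
#' @param beta1,beta2 Adam momentum parameters.
#' @param seed master seed covering initialization, data order and patch
#'   sampling.
#' @param loss a [loss_config()].
#' @param generator a [generator_config()]; use `base_width = 16` for the
#'   CPU test-scale profile.
#' @param disc_base_width discriminator width; defaults to the generator
#'   base width.
#' @param nce_layers encoder taps used by PatchNCE.
#' @param n_locations patches sampled per layer per iteration.
#' @param head_dim projection embedding dimension.
#' @param max_iters optional hard cap on total iterations (test profile:
#'   200).
#' @param checkpoint_every write a checkpoint every this many epochs.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 5, batch_size = 4, learning_rate = 2e-4,
                         beta1 = 0.5, beta2 = 0.999, seed = 1L,
                         loss = loss_config(),
                         generator = generator_config(),
                         disc_base_width = NULL,
                         nce_layers = c("enc0", "enc1", "enc2", "enc3",
                                        "enc4"),
                         n_locations = 256, head_dim = 256,
                         max_iters = NULL, checkpoint_every = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  if (is.null(disc_base_width)) disc_base_width <- generator$base_width
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, seed = as.integer(seed), loss = loss,
                 generator = generator, disc_base_width = disc_base_width,
                 nce_layers = nce_layers, n_locations = n_locations,
                 head_dim = head_dim, max_iters = max_iters,
                 checkpoint_every = checkpoint_every),
            class = "train_config")
}

# stack slice samples into a [H, W, C, N] tensor, replicating grayscale
stack_batch <- function(samples, channels) {
  imgs <- lapply(samples, function(s)
    if (inherits(s, "slice_sample")) s$image else s)
  d <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(m) identical(dim(m), d), logical(1))))
    stop("all slices in a batch must share the same shape")
  x <- array(unlist(imgs), c(d[1], d[2], 1L, length(imgs)))
  x[, , rep(1L, channels), , drop = FALSE]
}

# PatchNCE loss + gradients for one (query stack, key stack) pair.
# Accumulates projection-head gradients (scaled by `weight`) and returns
# gradient arrays w.r.t. the tapped feature maps.
nce_pass <- function(head, feats_q, feats_k, layer_ids, locs, tau, weight) {
  cnt <- 0
  for (nm in layer_ids)
    cnt <- cnt + length(locs[[nm]]) * dim(feats_q[[nm]])[4]
  total <- 0
  qtap <- list()
  ktap <- list()
  for (li in seq_along(layer_ids)) {
    nm <- layer_ids[li]
    fq <- feats_q[[nm]]
    fk <- feats_k[[nm]]
    d <- dim(fq)
    hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
    loc <- locs[[nm]]
    S <- length(loc)
    # gather the sampled rows of every sample into one (S*N) x C matrix so
    # the projection head runs once per stack instead of once per sample;
    # row s + S*(n-1) holds location s of sample n
    gather <- function(f) {
      a <- array(matrix(f, hw, C * N)[loc, ], c(S, C, N))
      matrix(aperm(a, c(1, 3, 2)), S * N, C)
    }
    zq <- gather(fq)
    zk <- gather(fk)
    hq <- head_forward(head, li, zq)
    hk <- head_forward(head, li, zk)
    nq <- l2_normalize_rows(hq$y)
    nk <- l2_normalize_rows(hk$y)
    D <- ncol(nq$y)
    dzq <- matrix(0, S * N, D)
    dzk <- matrix(0, S * N, D)
    scale <- weight / (cnt * tau)
    for (n in seq_len(N)) {
      rows <- (n - 1L) * S + seq_len(S)
      q <- nq$y[rows, , drop = FALSE]
      k <- nk$y[rows, , drop = FALSE]
      logits <- tcrossprod(q, k) / tau
      mx <- logits[cbind(seq_len(S), max.col(logits, ties.method = "first"))]
      ex <- exp(logits - mx)
      zs <- rowSums(ex)
      total <- total + sum(log(zs) + mx - diag(logits))
      dlog <- (ex / zs - diag(S)) * scale
      dzq[rows, ] <- dlog %*% k
      dzk[rows, ] <- crossprod(dlog, q)
    }
    gq <- head_backward(head, li, hq$caches, l2_normalize_bwd(nq, dzq))
    gk <- head_backward(head, li, hk$caches, l2_normalize_bwd(nk, dzk))
    # scatter gradients back onto the tapped feature maps
    scatter <- function(g) {
      gm <- matrix(0, hw, C * N)
      gm[loc, ] <- matrix(aperm(array(g, c(S, N, C)), c(1, 3, 2)), S, C * N)
      array(gm, d)
    }
    qtap[[nm]] <- scatter(gq)
    ktap[[nm]] <- scatter(gk)
  }
  list(loss = total / cnt, qtap = qtap, ktap = ktap)
}

sample_locations <- function(gen, layer_ids, img_dim, n_locations) {
  locs <- list()
  # spatial size per tap: enc0/enc1 full, enc2 /2, enc3 and enc4 /4
  red <- c(enc0 = 1L, enc1 = 1L, enc2 = 2L, enc3 = 4L, enc4 = 4L)
  for (nm in layer_ids) {
    hw <- (img_dim[1] %/% red[[nm]]) * (img_dim[2] %/% red[[nm]])
    if (n_locations > hw)
      stop("n_locations (", n_locations, ") exceeds spatial size (", hw,
           ") of layer ", nm)
    locs[[nm]] <- sample.int(hw, n_locations)
  }
  locs
}

check_finite_losses <- function(vals, iter) {
  bad <- names(vals)[!vapply(vals, is.finite, logical(1))]
  if (length(bad))
    stop("non-finite loss at iteration ", iter, ": ",
         paste(bad, collapse = ", "))
}

#' Train the T2W -> ADC translator
#'
#' Alternates discriminator and generator/head updates over independently
#' shuffled, unpaired batches of the two domains.  Fully seeded: two runs
#' with the same config produce identical loss logs.  Per-iteration losses
#' are appended to `out_dir/training_log.csv`
#' (`iter,d_loss,g_adv,nce_x,nce_y,sr,total`) and a checkpoint is written
#' per epoch and at the end.
#'
#' @param x_slices,y_slices lists of `slice_sample` objects (domain X = T2W
#'   and Y = ADC), preprocessed to `[-1, 1]`; all images must share one
#'   shape.
#' @param cfg a [train_config()].
#' @param out_dir output directory for the log and checkpoints.
#' @param verbose print progress every 25 iterations.
#' @param resume_from optional checkpoint path or [load_checkpoint()] result
#'   whose weights initialize the networks (optimizer state starts fresh);
#'   network shapes must match `cfg`.
#' @return invisibly, a list with `checkpoint` (path), `log` (data.frame)
#'   and the trained `generator`, `discriminator`, `head`.
#' @export
train_translator <- function(x_slices, y_slices, cfg = train_config(),
                             out_dir = tempfile("adcgan_run"),
                             verbose = FALSE, resume_from = NULL) {
  if (length(x_slices) == 0 || length(y_slices) == 0)
    stop("both domains must be nonempty")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  set.seed(cfg$seed)
  gen <- build_generator(cfg$generator)
  disc <- build_discriminator(cfg$generator$out_channels,
                              cfg$disc_base_width)
  head <- build_projection_head(gen$tap_channels[cfg$nce_layers],
                                cfg$head_dim)
  if (!is.null(resume_from)) {
    ck <- if (is.character(resume_from)) load_checkpoint(resume_from)
          else resume_from
    set_net_weights(gen, net_weights(ck$generator))
    if (!is.null(ck$discriminator))
      set_net_weights(disc, net_weights(ck$discriminator))
    if (!is.null(ck$head)) set_net_weights(head, net_weights(ck$head))
  }
  g_params <- c(gen$params, head$params)
  d_params <- disc$params
  lcfg <- cfg$loss
  chans <- cfg$generator$in_channels

  nx <- length(x_slices)
  ny <- length(y_slices)
  n_batches <- max(1L, min(nx, ny) %/% cfg$batch_size)
  max_total <- cfg$epochs * n_batches
  if (!is.null(cfg$max_iters)) max_total <- min(max_total, cfg$max_iters)
  log_cols <- c("iter", "d_loss", "g_adv", "nce_x", "nce_y", "sr", "total")
  log_mat <- matrix(NA_real_, max_total, length(log_cols),
                    dimnames = list(NULL, log_cols))
  iter <- 0L
  tg <- 0L
  td <- 0L
  y_ranges <- t(vapply(y_slices, function(s)
    if (inherits(s, "slice_sample")) s$rescale else c(0, 1), numeric(2)))
  meta <- list(train_config = cfg,
               y_range = c(stats::median(y_ranges[, 1]),
                           stats::median(y_ranges[, 2])))
  ckpt_path <- file.path(out_dir, "checkpoint.rds")
  log_path <- file.path(out_dir, "training_log.csv")
  done <- FALSE

  for (epoch in seq_len(cfg$epochs)) {
    xi <- sample(nx)
    yi <- sample(ny) # independent shuffles: no pairing leakage
    for (b in seq_len(n_batches)) {
      if (!is.null(cfg$max_iters) && iter >= cfg$max_iters) {
        done <- TRUE
        break
      }
      iter <- iter + 1L
      pos <- (b - 1) * cfg$batch_size + seq_len(cfg$batch_size)
      bx <- xi[(pos - 1) %% nx + 1]
      by <- yi[(pos - 1) %% ny + 1]
      xb <- stack_batch(x_slices[bx], chans)
      yb <- stack_batch(y_slices[by], chans)
      img_dim <- dim(xb)[1:2]
      locs <- sample_locations(gen, cfg$nce_layers, img_dim,
                               cfg$n_locations)

      ## generator forward on X (kept for both D and G steps)
      fx <- gen_forward(gen, xb, want_taps = TRUE)
      gx_img <- fx$y

      ## ---- discriminator step (generated image detached)
      zero_grads(d_params)
      dr <- disc_forward(disc, yb)
      df <- disc_forward(disc, gx_img)
      terms <- lsgan_terms(dr$y, df$y)
      d_loss <- terms$d_loss
      disc_backward(disc, dr$caches, (dr$y - 1) / length(dr$y))
      disc_backward(disc, df$caches, df$y / length(df$y))
      td <- td + 1L
      adam_step(d_params, cfg$learning_rate, td, cfg$beta1, cfg$beta2)

      ## ---- generator + head step
      zero_grads(g_params)
      df2 <- disc_forward(disc, gx_img)
      g_adv <- 0.5 * mean((df2$y - 1)^2)
      gy_img <- lcfg$adv_weight *
        disc_backward(disc, df2$caches, (df2$y - 1) / length(df2$y))

      sr <- self_regularization(xb, gx_img)
      gy_img <- gy_img + lcfg$lambda_sr * 2 * (gx_img - xb) / length(xb)

      # PatchNCE on X: keys = encoder(x), queries = encoder(G(x))
      nce_x <- 0
      if (lcfg$lambda_x > 0) {
        fe <- gen_forward(gen, gx_img, encoder_only = TRUE,
                          want_taps = TRUE)
        px <- nce_pass(head, fe$feats, fx$feats, cfg$nce_layers, locs,
                       lcfg$tau, lcfg$lambda_x)
        nce_x <- px$loss
        gy_img <- gy_img + gen_backward(gen, fe$caches, tap_g = px$qtap,
                                        encoder_only = TRUE)
        key_tap_x <- px$ktap
      } else key_tap_x <- NULL
      gen_backward(gen, fx$caches, gy = gy_img, tap_g = key_tap_x)

      # identity-pass PatchNCE on Y: keys = encoder(y),
      # queries = encoder(G(y))
      nce_y <- 0
      if (lcfg$lambda_y > 0) {
        fy <- gen_forward(gen, yb, want_taps = TRUE)
        fey <- gen_forward(gen, fy$y, encoder_only = TRUE, want_taps = TRUE)
        py <- nce_pass(head, fey$feats, fy$feats, cfg$nce_layers, locs,
                       lcfg$tau, lcfg$lambda_y)
        nce_y <- py$loss
        gyy <- gen_backward(gen, fey$caches, tap_g = py$qtap,
                            encoder_only = TRUE)
        gen_backward(gen, fy$caches, gy = gyy, tap_g = py$ktap)
      }
      tg <- tg + 1L
      adam_step(g_params, cfg$learning_rate, tg, cfg$beta1, cfg$beta2)

      total <- total_loss(g_adv, sr, nce_x, nce_y, lcfg)
      vals <- list(d_loss = d_loss, g_adv = g_adv, nce_x = nce_x,
                   nce_y = nce_y, sr = sr, total = total)
      check_finite_losses(vals, iter)
      log_mat[iter, ] <- c(iter, d_loss, g_adv, nce_x, nce_y, sr, total)
      if (verbose && iter %% 25 == 0)
        message(sprintf("iter %d  d=%.3f g_adv=%.3f nce_x=%.3f nce_y=%.3f sr=%.4f",
                        iter, d_loss, g_adv, nce_x, nce_y, sr))
    }
    if (epoch %% cfg$checkpoint_every == 0 || epoch == cfg$epochs)
      save_checkpoint(ckpt_path, gen, disc, head, meta)
    if (done) break
  }
  log <- as.data.frame(log_mat[seq_len(iter), , drop = FALSE])
  log$iter <- as.integer(log$iter)
  utils::write.csv(log, log_path, row.names = FALSE)
  save_checkpoint(ckpt_path, gen, disc, head, meta)
  invisible(list(checkpoint = ckpt_path, log = log, generator = gen,
                 discriminator = disc, head = head))
}

generate_slice <- function(gen, image) {
  x <- slice_to_tensor(image, gen$config$in_channels)
  y <- gen_forward(gen, x)$y
  # channels carry replicated grayscale; average them back to one plane
  d <- dim(y)
  out <- matrix(0, d[1], d[2])
  for (cc in seq_len(d[3])) out <- out + y[, , cc, 1]
  out / d[3]
}

#' Synthesize ADC slices or volumes from T2W input
#'
#' Deterministic inference with a trained checkpoint.  Given slice samples,
#' returns generated slice samples (domain `"Y"`); given a T2W volume plus
#' prostate mask, runs the full preprocessing chain (optional resampling to
#' the training spacing, mask cropping, z-scoring, slice extraction),
#' translates each slice and reassembles an ADC-like volume via
#' [reinsert_slices()].
#'
#' @param checkpoint path to a checkpoint file or the result of
#'   [load_checkpoint()].
#' @param input list of `slice_sample` objects, or a T2W [volume()].
#' @param mask binary prostate mask [volume()] (required for volume input).
#' @param target_spacing resampling target when `input` is a volume;
#'   default from the stored training metadata, if any.
#' @param margin_mm crop margin (see [crop_to_mask()]).
#' @return list of generated `slice_sample`s, or an ADC-like [volume()].
#' @export
infer <- function(checkpoint, input, mask = NULL, target_spacing = NULL,
                  margin_mm = 5) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint)
        else checkpoint
  gen <- ck$generator
  y_range <- ck$meta$y_range
  if (is.null(y_range)) y_range <- c(0, 1)

  if (is.list(input) && !inherits(input, "adc_volume")) {
    return(lapply(input, function(s) {
      img <- if (inherits(s, "slice_sample")) s$image else s
      out <- generate_slice(gen, img)
      if (inherits(s, "slice_sample")) {
        g <- s
        g$image <- out
        g$domain <- "Y"
        g$rescale <- y_range
        g
      } else out
    }))
  }
  stopifnot(inherits(input, "adc_volume"))
  if (is.null(mask)) stop("volume input requires a prostate mask")
  ts <- target_spacing
  if (is.null(ts)) ts <- ck$meta$target_spacing
  if (!is.null(ts) && any(abs(ts - input$spacing) > 1e-6)) {
    warning("input spacing differs from training spacing; resampling")
    input <- resample(input, ts)
    mask <- resample(mask, ts)
  }
  cr <- crop_to_mask(input, mask, margin_mm)
  crm <- crop_to_mask(mask, mask, margin_mm)
  slices <- extract_slices(zscore(cr$volume), mask = crm$volume,
                           subject_id = "infer", crop_box = cr$crop_box)
  out_slices <- infer(ck, slices)
  for (i in seq_along(out_slices)) out_slices[[i]]$rescale <- y_range
  template <- input
  template$role <- "adc"
  reinsert_slices(out_slices, template)
}
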