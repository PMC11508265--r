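# Loss terms: InfoNCE contrastive cross-entropy, its patch-wise extension
# over encoder layers (PatchNCE), pixel-level self-regularization, the
# least-squares adversarial pair, and the composite training objective.

#' Loss configuration
#'
#' @param tau contrastive temperature (default 0.07).
#' @param lambda_x,lambda_y weights of the PatchNCE terms on the source (X =
#'   T2W) and identity (Y = ADC) domains.
#' @param lambda_sr weight of the pixel-level self-regularization term.
#' @param adv_weight weight of the adversarial generator loss.
#' @return a `loss_config` list.
#' @export
loss_config <- function(tau = 0.07, lambda_x = 1, lambda_y = 1,
                        lambda_sr = 1, adv_weight = 1) {
  stopifnot(tau > 0, lambda_x >= 0, lambda_y >= 0, lambda_sr >= 0,
            adv_weight >= 0)
  structure(list(tau = tau, lambda_x = lambda_x, lambda_y = lambda_y,
                 lambda_sr = lambda_sr, adv_weight = adv_weight),
            class = "loss_config")
}

#' Contrastive batch
#'
#' Bundles one query embedding `v`, its positive `v_plus` and `M` negatives
#' `v_minus` (rows) with the temperature `tau`.
#'
#' @param v,v_plus numeric vectors of equal length.
#' @param v_minus numeric matrix, one negative per row.
#' @param tau temperature, must be positive.
#' @return a `contrastive_batch` list.
#' @export
contrastive_batch <- function(v, v_plus, v_minus, tau = 0.07) {
  if (tau <= 0) stop("tau must be positive")
  v_minus <- rbind(v_minus)
  stopifnot(length(v) == length(v_plus), ncol(v_minus) == length(v),
            nrow(v_minus) >= 1, all(is.finite(c(v, v_plus, v_minus))))
  structure(list(v = v, v_plus = v_plus, v_minus = v_minus, tau = tau),
            class = "contrastive_batch")
}

#' InfoNCE contrastive cross-entropy
#'
#' Computes
#' `-log( exp(v.v+/tau) / (exp(v.v+/tau) + sum_n exp(v.v-_n/tau)) )`,
#' stabilized by max-subtraction so large logits do not overflow.  When all
#' logits are equal with `M` negatives the loss is `log(M + 1)`.
#'
#' @param batch a [contrastive_batch()].
#' @return positive scalar loss.
#' @export
info_nce <- function(batch) {
  if (!inherits(batch, "contrastive_batch"))
    stop("batch must be a contrastive_batch()")
  lp <- sum(batch$v * batch$v_plus) / batch$tau
  ln <- as.numeric(batch$v_minus %*% batch$v) / batch$tau
  m <- max(lp, ln)
  log(sum(exp(c(lp, ln) - m))) - (lp - m)
}

#' Patch-wise NCE loss over a pair of feature stacks
#'
#' For every layer `l` and sampled location `s`, the positive pair is the
#' query embedding at `s` against the key embedding at `s`, and the
#' negatives are the key embeddings at the other `S_l - 1` locations of the
#' same image.  The returned value is the mean of the per-location
#' cross-entropies over all layers, locations and samples.
#'
#' @param feats_query,feats_key `feature_stack` objects from
#'   [encode_patch_features()] with identical layers and locations
#'   (query = generated image, key = input image).
#' @param tau temperature.
#' @return scalar loss.
#' @export
patch_nce <- function(feats_query, feats_key, tau = 0.07) {
  if (tau <= 0) stop("tau must be positive")
  if (!identical(feats_query$layers, feats_key$layers))
    stop("feature stacks tap different layers")
  total <- 0
  count <- 0
  for (nm in feats_query$layers) {
    if (!identical(feats_query$locations[[nm]], feats_key$locations[[nm]]))
      stop("feature stacks were sampled at different locations (layer ", nm,
           ")")
    eq <- feats_query$embeddings[[nm]]
    ek <- feats_key$embeddings[[nm]]
    stopifnot(identical(dim(eq), dim(ek)))
    S <- dim(eq)[1]
    for (n in seq_len(dim(eq)[3])) {
      zq <- matrix(eq[, , n], S)
      zk <- matrix(ek[, , n], S)
      logits <- tcrossprod(zq, zk) / tau
      m <- apply(logits, 1, max)
      lse <- m + log(rowSums(exp(logits - m)))
      total <- total + sum(lse - diag(logits))
      count <- count + S
    }
  }
  total / count
}

#' Pixel-level self-regularization
#'
#' Mean squared pixel deviation between the generator input and output,
#' discouraging anatomical drift in the synthesized map.
#'
#' @param x,gx arrays of identical shape (input batch and generated batch).
#' @return non-negative scalar.
#' @export
self_regularization <- function(x, gx) {
  if (!identical(dim(x), dim(gx)) || length(x) != length(gx))
    stop("x and G(x) shapes differ")
  mean((x - gx)^2)
}

#' Least-squares adversarial losses
#'
#' LSGAN objective with labels 1 for real and 0 for fake:
#' `d_loss = mean((d_real - 1)^2)/2 + mean(d_fake^2)/2`,
#' `g_loss = mean((d_fake - 1)^2)/2`.
#'
#' @param d_real,d_fake discriminator patch-score maps.
#' @return list with `d_loss` and `g_loss`.
#' @export
lsgan_terms <- function(d_real, d_fake) {
  list(d_loss = 0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2),
       g_loss = 0.5 * mean((d_fake - 1)^2))
}

#' Composite generator objective
#'
#' `L = w_adv * g_adv + lambda_SR * sr + lambda_X * nce_x +
#'  lambda_Y * nce_y`, where `nce_y` is the identity-pass PatchNCE computed
#' on domain-Y images passed through the generator.
#'
#' @param g_adv,sr,nce_x,nce_y scalar loss components.
#' @param cfg a [loss_config()].
#' @return scalar total loss.
#' @export
total_loss <- function(g_adv, sr, nce_x, nce_y, cfg = loss_config()) {
  stopifnot(is.finite(g_adv), is.finite(sr), is.finite(nce_x),
            is.finite(nce_y))
  cfg$adv_weight * g_adv + cfg$lambda_sr * sr + cfg$lambda_x * nce_x +
    cfg$lambda_y * nce_y
}
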