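# Native network engine: trainable parameters, layers with hand-derived
# backward passes, sequential containers and the Adam optimizer.  Tensors are
# plain R arrays laid out [H, W, C, N]; convolutions run in C++ (see
# src/convops.cpp).  Every layer is a list with
#   $params : named list of parameter stores (possibly empty)
#   $fwd(x) : returns list(y = output, cache = whatever bwd needs)
#   $bwd(cache, gy) : accumulates parameter gradients, returns gx
# fwd/bwd are reentrant (caches are caller-held), so the same weights can be
# used for several passes per iteration, as PatchNCE requires.

nn_par <- function(value) {
  e <- new.env(parent = emptyenv())
  e$v <- value
  e$g <- 0 # scalar zero broadcasts on first accumulation
  e$m <- 0 # Adam first moment
  e$s <- 0 # Adam second moment
  class(e) <- "nn_par"
  e
}

#' @noRd
glorot_uniform <- function(dim, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dim), -lim, lim), dim = dim)
}

zero_grads <- function(params) {
  for (p in params) p$g <- 0
  invisible(NULL)
}

#' Adam update over a flat list of parameter stores
#' @noRd
adam_step <- function(params, lr, t, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    p$m <- beta1 * p$m + (1 - beta1) * p$g
    p$s <- beta2 * p$s + (1 - beta2) * p$g^2
    mhat <- p$m / (1 - beta1^t)
    shat <- p$s / (1 - beta2^t)
    p$v <- p$v - lr * mhat / (sqrt(shat) + eps)
  }
  invisible(NULL)
}

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$v), numeric(1)))
}

## ---- layers -----------------------------------------------------------

layer_conv <- function(cin, cout, k, stride = 1, pad = 0,
                       pad_mode = c("zeros", "reflect"), bias = TRUE) {
  pad_mode <- match.arg(pad_mode)
  pm <- if (pad_mode == "reflect") 1L else 0L
  w <- nn_par(glorot_uniform(c(k, k, cin, cout), k * k * cin, k * k * cout))
  params <- list(w = w)
  if (bias) params$b <- nn_par(numeric(cout))
  fwd <- function(x) {
    b <- if (bias) params$b$v else numeric(0)
    list(y = .cpp_conv2d_fwd(x, params$w$v, b, stride, pad, pm), cache = x)
  }
  bwd <- function(cache, gy) {
    r <- .cpp_conv2d_bwd(cache, params$w$v, gy, stride, pad, pm, TRUE, bias)
    params$w$g <- params$w$g + r$gw
    if (bias) params$b$g <- params$b$g + r$gb
    r$gx
  }
  list(kind = "conv", params = params, fwd = fwd, bwd = bwd)
}

layer_convt <- function(cin, cout, k = 3, stride = 2, pad = 1, outpad = 1,
                        bias = TRUE) {
  w <- nn_par(glorot_uniform(c(k, k, cout, cin), k * k * cin, k * k * cout))
  params <- list(w = w)
  if (bias) params$b <- nn_par(numeric(cout))
  fwd <- function(x) {
    b <- if (bias) params$b$v else numeric(0)
    list(y = .cpp_convt2d_fwd(x, params$w$v, b, stride, pad, outpad),
         cache = x)
  }
  bwd <- function(cache, gy) {
    r <- .cpp_convt2d_bwd(cache, params$w$v, gy, stride, pad, bias)
    params$w$g <- params$w$g + r$gw
    if (bias) params$b$g <- params$b$g + r$gb
    r$gx
  }
  list(kind = "convt", params = params, fwd = fwd, bwd = bwd)
}

# instance normalization without affine parameters (CycleGAN convention);
# statistics per channel and per sample
layer_instnorm <- function(eps = 1e-5) {
  fwd <- function(x) {
    d <- dim(x)
    hw <- d[1] * d[2]
    xm <- matrix(x, nrow = hw)
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu^2
    sdv <- sqrt(pmax(v, 0) + eps)
    yhat <- (xm - rep(mu, each = hw)) / rep(sdv, each = hw)
    y <- array(yhat, dim = d)
    list(y = y, cache = list(yhat = yhat, sdv = sdv, d = d))
  }
  bwd <- function(cache, gy) {
    hw <- cache$d[1] * cache$d[2]
    g <- matrix(gy, nrow = hw)
    yhat <- cache$yhat
    gmu <- colMeans(g)
    gys <- colMeans(g * yhat)
    gx <- (g - rep(gmu, each = hw) - yhat * rep(gys, each = hw)) /
      rep(cache$sdv, each = hw)
    array(gx, dim = cache$d)
  }
  list(kind = "instnorm", params = list(), fwd = fwd, bwd = bwd)
}

layer_relu <- function() {
  list(kind = "relu", params = list(),
       fwd = function(x) list(y = pmax(x, 0), cache = x > 0),
       bwd = function(cache, gy) gy * cache)
}

layer_lrelu <- function(slope = 0.2) {
  list(kind = "lrelu", params = list(),
       fwd = function(x) {
         pos <- x > 0
         list(y = ifelse_arr(pos, x, slope * x), cache = pos)
       },
       bwd = function(cache, gy) ifelse_arr(cache, gy, slope * gy))
}

ifelse_arr <- function(mask, a, b) {
  out <- b
  out[mask] <- a[mask]
  out
}

layer_tanh <- function() {
  list(kind = "tanh", params = list(),
       fwd = function(x) {
         y <- tanh(x)
         list(y = y, cache = y)
       },
       bwd = function(cache, gy) gy * (1 - cache^2))
}

layer_linear <- function(din, dout, bias = TRUE) {
  w <- nn_par(glorot_uniform(c(din, dout), din, dout))
  params <- list(w = w)
  if (bias) params$b <- nn_par(numeric(dout))
  fwd <- function(x) { # x: n x din matrix
    y <- x %*% params$w$v
    if (bias) y <- y + rep(params$b$v, each = nrow(x))
    list(y = y, cache = x)
  }
  bwd <- function(cache, gy) {
    params$w$g <- params$w$g + crossprod(cache, gy)
    if (bias) params$b$g <- params$b$g + colSums(gy)
    gy %*% t(params$w$v)
  }
  list(kind = "linear", params = params, fwd = fwd, bwd = bwd)
}

## ---- containers -------------------------------------------------------

seq_params <- function(layers) {
  out <- list()
  for (l in layers) out <- c(out, l$params)
  out
}

seq_fwd <- function(layers, x, upto = length(layers)) {
  caches <- vector("list", upto)
  h <- x
  for (i in seq_len(upto)) {
    r <- layers[[i]]$fwd(h)
    caches[[i]] <- r$cache
    h <- r$y
  }
  list(y = h, caches = caches)
}

seq_bwd <- function(layers, caches, gy, from = length(layers)) {
  g <- gy
  for (i in rev(seq_len(from))) g <- layers[[i]]$bwd(caches[[i]], g)
  g
}

# residual block: x + IN(conv(relu(IN(conv(x))))), 3x3 reflection-padded convs
layer_resblock <- function(ch) {
  inner <- list(
    layer_conv(ch, ch, 3, pad = 1, pad_mode = "reflect"),
    layer_instnorm(),
    layer_relu(),
    layer_conv(ch, ch, 3, pad = 1, pad_mode = "reflect"),
    layer_instnorm()
  )
  fwd <- function(x) {
    r <- seq_fwd(inner, x)
    list(y = x + r$y, cache = r$caches)
  }
  bwd <- function(cache, gy) {
    gy + seq_bwd(inner, cache, gy)
  }
  list(kind = "resblock", params = seq_params(inner), fwd = fwd, bwd = bwd)
}
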