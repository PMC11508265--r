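# Convolutional block attention (CBAM): channel gating from pooled
# descriptors through a shared bias-free MLP, then spatial gating from
# channelwise average/max maps through a 5x5 convolution.  The refined map is
#   F'' = M_S(M_C(F) (*) F) (*) (M_C(F) (*) F)
# with (*) elementwise multiplication, M_C broadcast over space and M_S over
# channels.

sigmoid <- function(x) 1 / (1 + exp(-x))

as_hwcn <- function(f) {
  d <- dim(f)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("expected a [H, W, C] or [H, W, C, N] feature array")
  if (length(d) == 3L) {
    dim(f) <- c(d, 1L)
  }
  f
}

# full forward pass returning every intermediate needed by the backward pass
cbam_fwd <- function(f, w1, w2, conv_layer) {
  f <- as_hwcn(f)
  d <- dim(f)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (ncol(w1) != C)
    stop("channel mismatch: features have ", C, " channels, MLP expects ",
         ncol(w1))
  xm <- matrix(f, nrow = hw) # HW x (C*N), channel fastest

  # -- channel attention
  p_avg <- matrix(colMeans(xm), C, N)
  tx <- t(xm)                                  # (C*N) x HW
  amax <- max.col(tx, ties.method = "first")   # argmax location per (c, n)
  p_max <- matrix(tx[cbind(seq_len(C * N), amax)], C, N)
  h_avg <- pmax(w1 %*% p_avg, 0)
  h_max <- pmax(w1 %*% p_max, 0)
  s <- w2 %*% h_avg + w2 %*% h_max
  mc <- sigmoid(s) # C x N

  f1m <- xm * rep(as.vector(mc), each = hw)    # F' = Mc (*) F
  f1 <- array(f1m, dim = d)

  # -- spatial attention on F'
  arr <- array(f1m, c(hw, C, N))
  savg <- matrix(0, hw, N)
  smax <- matrix(-Inf, hw, N)
  camax <- matrix(1L, hw, N)
  for (n in seq_len(N)) {
    savg[, n] <- rowMeans(arr[, , n, drop = FALSE], dims = 1)
    for (cc in seq_len(C)) {
      col <- arr[, cc, n]
      upd <- col > smax[, n]
      smax[upd, n] <- col[upd]
      camax[upd, n] <- cc
    }
  }
  u <- array(0, c(d[1], d[2], 2L, N))
  u[, , 1L, ] <- savg
  u[, , 2L, ] <- smax
  cr <- conv_layer$fwd(u)
  ms <- sigmoid(cr$y) # H x W x 1 x N
  msm <- matrix(ms, hw, N)

  f2m <- matrix(0, hw, C * N)
  for (n in seq_len(N)) {
    idx <- ((n - 1) * C + 1):(n * C)
    f2m[, idx] <- f1m[, idx] * msm[, n]
  }
  list(y = array(f2m, dim = d),
       cache = list(d = d, xm = xm, mc = mc, msm = msm, f1m = f1m,
                    p_avg = p_avg, p_max = p_max, h_avg = h_avg,
                    h_max = h_max, amax = amax, camax = camax,
                    conv_cache = cr$cache))
}

cbam_bwd <- function(cache, gy, w1p, w2p, conv_layer) {
  d <- cache$d
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  g2 <- matrix(gy, hw, C * N)
  w1 <- w1p$v; w2 <- w2p$v

  # F'' = F' (*) Ms
  g1 <- matrix(0, hw, C * N)
  gms <- matrix(0, hw, N)
  for (n in seq_len(N)) {
    idx <- ((n - 1) * C + 1):(n * C)
    g1[, idx] <- g2[, idx] * cache$msm[, n]
    gms[, n] <- rowSums(g2[, idx, drop = FALSE] * cache$f1m[, idx, drop = FALSE])
  }
  # Ms = sigmoid(conv(U))
  ga <- array(gms * cache$msm * (1 - cache$msm), c(d[1], d[2], 1L, N))
  gu <- conv_layer$bwd(cache$conv_cache, ga)
  gsavg <- matrix(gu[, , 1L, ], hw, N)
  gsmax <- matrix(gu[, , 2L, ], hw, N)
  for (n in seq_len(N)) {
    idx <- ((n - 1) * C + 1):(n * C)
    g1[, idx] <- g1[, idx] + gsavg[, n] / C
    # scatter max-pool gradient to the winning channel per location
    g1m <- g1[, idx, drop = FALSE]
    g1m[cbind(seq_len(hw), cache$camax[, n])] <-
      g1m[cbind(seq_len(hw), cache$camax[, n])] + gsmax[, n]
    g1[, idx] <- g1m
  }

  # F' = F (*) Mc
  mcv <- as.vector(cache$mc)
  gx <- g1 * rep(mcv, each = hw)
  gmc <- matrix(colSums(g1 * cache$xm), C, N)

  # Mc = sigmoid(W2 relu(W1 p_avg) + W2 relu(W1 p_max))
  gs <- gmc * cache$mc * (1 - cache$mc)
  gh_avg <- crossprod(w2, gs) * (cache$h_avg > 0)
  gh_max <- crossprod(w2, gs) * (cache$h_max > 0)
  w2p$g <- w2p$g + tcrossprod(gs, cache$h_avg) + tcrossprod(gs, cache$h_max)
  w1p$g <- w1p$g + tcrossprod(gh_avg, cache$p_avg) +
    tcrossprod(gh_max, cache$p_max)
  gp_avg <- crossprod(w1, gh_avg)
  gp_max <- crossprod(w1, gh_max)

  # pooling backward: average spreads 1/HW, max goes to the argmax location
  gx <- gx + matrix(rep(as.vector(gp_avg), each = hw) / hw, hw)
  flat <- cbind(cache$amax, seq_len(C * N)) # (location, column) pairs
  gx[flat] <- gx[flat] + as.vector(gp_max)
  array(gx, dim = d)
}

layer_cbam <- function(ch, reduction_ratio = 8, spatial_kernel = 5) {
  if (ch %% reduction_ratio != 0)
    stop("reduction_ratio must divide the channel count (", ch, ")")
  if (spatial_kernel %% 2 != 1) stop("spatial_kernel must be odd")
  cr <- ch %/% reduction_ratio
  w1 <- nn_par(glorot_uniform(c(cr, ch), ch, cr))
  w2 <- nn_par(glorot_uniform(c(ch, cr), cr, ch))
  conv <- layer_conv(2, 1, spatial_kernel, pad = (spatial_kernel - 1) %/% 2,
                     bias = TRUE)
  params <- c(list(w1 = w1, w2 = w2), conv$params)
  fwd <- function(x) cbam_fwd(x, w1$v, w2$v, conv)
  bwd <- function(cache, gy) cbam_bwd(cache, gy, w1, w2, conv)
  list(kind = "cbam", params = params, fwd = fwd, bwd = bwd)
}

## ---- user-facing functional interface ---------------------------------

cbam_params_check <- function(f, params) {
  f <- as_hwcn(f)
  need <- c("w1", "w2", "conv_w", "conv_b")
  if (!all(need %in% names(params)))
    stop("params must contain ", paste(need, collapse = ", "))
  params
}

# wrap raw arrays into a conv layer sharing the given weights
conv_from_params <- function(conv_w, conv_b) {
  k <- dim(conv_w)[1]
  l <- layer_conv(2, 1, k, pad = (k - 1) %/% 2, bias = TRUE)
  l$params$w$v <- conv_w
  l$params$b$v <- as.numeric(conv_b)
  l
}

#' Channel attention weights
#'
#' Computes the channel-attention vector
#' `M_C = sigmoid(MLP(AvgPool(F)) + MLP(MaxPool(F)))`, where the bias-free
#' two-layer MLP (`w1`: C/r x C, `w2`: C x C/r) is shared between the two
#' pooled descriptors.
#'
#' @param f feature array `[H, W, C]` or `[H, W, C, N]`.
#' @param params list with `w1` and `w2` weight matrices.
#' @return numeric vector of length C (single sample) or a C x N matrix,
#'   values in (0, 1).
#' @export
channel_attention <- function(f, params) {
  f <- as_hwcn(f)
  d <- dim(f)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (ncol(params$w1) != C)
    stop("channel mismatch: features have ", C, " channels, w1 expects ",
         ncol(params$w1))
  xm <- matrix(f, nrow = hw)
  p_avg <- matrix(colMeans(xm), C, N)
  p_max <- matrix(apply(xm, 2, max), C, N)
  mlp <- function(p) params$w2 %*% pmax(params$w1 %*% p, 0)
  mc <- sigmoid(mlp(p_avg) + mlp(p_max))
  if (N == 1L) as.numeric(mc) else mc
}

#' Spatial attention map
#'
#' Average- and max-pools the feature map over the channel axis, stacks the
#' two maps and passes them through a 5x5 convolution followed by a sigmoid.
#'
#' @param f feature array `[H, W, C]` or `[H, W, C, N]`.
#' @param params list with `conv_w` (`[k, k, 2, 1]`) and `conv_b` (length 1).
#' @return H x W matrix (single sample) or `[H, W, N]` array, values in
#'   (0, 1).
#' @export
spatial_attention <- function(f, params) {
  f <- as_hwcn(f)
  d <- dim(f)
  u <- array(0, c(d[1], d[2], 2L, d[4]))
  for (n in seq_len(d[4])) {
    fs <- f[, , , n, drop = FALSE]
    dim(fs) <- d[1:3]
    u[, , 1L, n] <- apply(fs, c(1, 2), mean)
    u[, , 2L, n] <- apply(fs, c(1, 2), max)
  }
  conv <- conv_from_params(params$conv_w, params$conv_b)
  ms <- sigmoid(conv$fwd(u)$y)
  if (d[4] == 1L) matrix(ms, d[1], d[2]) else array(ms, c(d[1], d[2], d[4]))
}

#' CBAM feature refinement
#'
#' Applies channel attention followed by spatial attention:
#' `F'' = M_S(M_C(F) * F) * (M_C(F) * F)` with broadcasting of `M_C` over
#' space and `M_S` over channels.  With all parameters zero both gates equal
#' 0.5 everywhere, so `F'' = 0.25 * F`.
#'
#' @param f feature array `[H, W, C]` or `[H, W, C, N]`.
#' @param params list with `w1`, `w2`, `conv_w`, `conv_b`.
#' @return refined feature array, same shape as `f`.
#' @export
cbam_refine <- function(f, params) {
  params <- cbam_params_check(f, params)
  squeeze <- is.null(dim(f)) || length(dim(f)) == 3L
  f <- as_hwcn(f)
  conv <- conv_from_params(params$conv_w, params$conv_b)
  out <- cbam_fwd(f, params$w1, params$w2, conv)$y
  if (squeeze) {
    d <- dim(out)
    dim(out) <- d[1:3]
  }
  out
}
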