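# independent scalar oracle: direct, unstabilized softmax cross-entropy
nce_oracle <- function(v, vp, vm, tau) {
  num <- exp(sum(v * vp) / tau)
  den <- num + sum(exp(as.numeric(vm %*% v) / tau))
  -log(num / den)
}

test_that("info_nce matches closed forms and the brute-force oracle", {
  # all logits equal with M negatives -> log(M + 1)
  v <- c(1, 0)
  b <- contrastive_batch(v, c(1, 0), rbind(c(1, 0), c(1, 0), c(1, 0)))
  expect_equal(info_nce(b), log(4), tolerance = 1e-9)
  for (M in c(1, 5, 17)) {
    bM <- contrastive_batch(v, c(1, 0),
                            matrix(rep(c(1, 0), M), M, byrow = TRUE))
    expect_equal(info_nce(bM), log(M + 1), tolerance = 1e-9)
  }

  # orthogonal negative at tau = 0.07: log(1 + exp(-1/0.07)) ~ 6.1e-7
  b2 <- contrastive_batch(c(1, 0), c(1, 0), rbind(c(0, 1)), tau = 0.07)
  expect_equal(info_nce(b2), log(1 + exp(-1 / 0.07)), tolerance = 1e-12)
  expect_lt(info_nce(b2), 1e-6)

  # monotone decreasing in the positive logit; -> 0 for large logits
  ls <- vapply(c(1, 5, 20, 200), function(s) {
    info_nce(contrastive_batch(c(s, 0), c(1, 0), rbind(c(0, 1)), tau = 1))
  }, numeric(1))
  expect_true(all(diff(ls) < 0))
  expect_lt(ls[4], 1e-12)

  # stabilization: huge logits do not overflow
  bln <- contrastive_batch(c(1e4, 0), c(1, 0), rbind(c(0.99, 0)), tau = 0.07)
  expect_true(is.finite(info_nce(bln)))

  # brute-force oracle on 100 random small batches
  set.seed(10)
  for (i in 1:100) {
    d <- sample(2:6, 1)
    M <- sample(1:5, 1)
    v <- rnorm(d)
    vp <- rnorm(d)
    vm <- matrix(rnorm(M * d), M, d)
    tau <- runif(1, 0.05, 1)
    b <- contrastive_batch(v, vp, vm, tau)
    expect_equal(info_nce(b), nce_oracle(v, vp, vm, tau), tolerance = 1e-6)
  }

  expect_error(contrastive_batch(c(1, 0), c(1, 0), rbind(c(0, 1)), tau = 0),
               "tau")
})

make_stack <- function(emb_list, loc) {
  structure(list(layers = names(emb_list),
                 embeddings = lapply(emb_list, function(e)
                   array(e, c(dim(e), 1L))),
                 locations = lapply(emb_list, function(e) loc)),
            class = "feature_stack")
}

test_that("patch_nce reduces to info_nce for S = 2, L = 1", {
  set.seed(11)
  unit <- function(x) x / sqrt(sum(x^2))
  zq <- rbind(unit(rnorm(4)), unit(rnorm(4)))
  zk <- rbind(unit(rnorm(4)), unit(rnorm(4)))
  fq <- make_stack(list(l1 = zq), 1:2)
  fk <- make_stack(list(l1 = zk), 1:2)
  got <- patch_nce(fq, fk, tau = 0.07)
  want <- mean(c(
    info_nce(contrastive_batch(zq[1, ], zk[1, ], rbind(zk[2, ]), 0.07)),
    info_nce(contrastive_batch(zq[2, ], zk[2, ], rbind(zk[1, ]), 0.07))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("patch_nce matches a brute-force double loop and is order-invariant", {
  set.seed(12)
  unit_rows <- function(m) m / sqrt(rowSums(m^2))
  S <- 7
  z <- unit_rows(matrix(rnorm(S * 5), S, 5))
  fs <- make_stack(list(l1 = z), seq_len(S))
  got <- patch_nce(fs, fs, tau = 0.07)
  # brute force: for each location, positive = itself, negatives = others
  want <- mean(vapply(seq_len(S), function(s)
    nce_oracle(z[s, ], z[s, ], z[-s, , drop = FALSE], 0.07), numeric(1)))
  expect_equal(got, want, tolerance = 1e-9)
  # self-correspondence closed form: log(1 + sum exp((z_s.z_n - 1)/tau))
  want2 <- mean(vapply(seq_len(S), function(s)
    log(1 + sum(exp((z[-s, , drop = FALSE] %*% z[s, ] - 1) / 0.07))),
    numeric(1)))
  expect_equal(got, want2, tolerance = 1e-9)

  # identical permutation of both stacks leaves the loss unchanged
  pm <- sample(S)
  fsp <- make_stack(list(l1 = z[pm, ]), seq_len(S)[pm])
  expect_equal(patch_nce(fsp, fsp, tau = 0.07), got, tolerance = 1e-6)

  # mismatched locations are rejected
  fbad <- make_stack(list(l1 = z), seq_len(S) + 1L)
  expect_error(patch_nce(fs, fbad), "different locations")
})

test_that("self-regularization is a mean-squared pixel penalty", {
  set.seed(13)
  x <- array(rnorm(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  expect_equal(self_regularization(x, x), 0)
  expect_equal(self_regularization(x, x + 0.3), 0.09, tolerance = 1e-12)
  expect_gte(self_regularization(x, x - rexp(length(x))), 0)
  expect_error(self_regularization(x, array(0, c(5, 5, 3, 1))), "shapes")
})

test_that("lsgan_terms use least-squares labels 1/0", {
  expect_equal(lsgan_terms(1, 0)$d_loss, 0)
  expect_equal(lsgan_terms(0.2, 1)$g_loss, 0)
  t3 <- lsgan_terms(matrix(0.5, 2, 2), matrix(0.5, 2, 2))
  expect_equal(t3$d_loss, 0.25, tolerance = 1e-12)
  expect_equal(t3$g_loss, 0.125, tolerance = 1e-12)
})

test_that("total_loss is the lambda-weighted sum and linear in each lambda", {
  expect_equal(total_loss(3, 9, 9, 9, loss_config(lambda_x = 0,
                                                  lambda_y = 0,
                                                  lambda_sr = 0)), 3)
  expect_equal(total_loss(1, 2, 3, 4, loss_config()), 10)
  # finite-difference linearity in each weight
  base <- c(g = 0.7, sr = 1.3, x = 2.1, y = 0.4)
  for (lam in c("lambda_x", "lambda_y", "lambda_sr")) {
    f <- function(w) {
      args <- list(tau = 0.07)
      args[[lam]] <- w
      cfg <- do.call(loss_config, args)
      total_loss(base["g"], base["sr"], base["x"], base["y"], cfg)
    }
    d1 <- f(1) - f(0)
    d2 <- (f(2) - f(0)) / 2
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("every loss term sends nonzero gradients to the generator", {
  set.seed(14)
  gen <- build_generator(generator_config(base_width = 4, n_resblocks = 4,
                                          cbam = FALSE))
  layer_ids <- c("enc0", "enc1", "enc2", "enc3", "enc4")
  head <- build_projection_head(gen$tap_channels[layer_ids], 8)
  xb <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3, 1))
  locs <- lapply(c(enc0 = 1, enc1 = 1, enc2 = 1, enc3 = 1, enc4 = 1),
                 function(z) 1:4)
  grad_norm <- function() {
    sqrt(sum(vapply(gen$params, function(p) sum(p$g^2), numeric(1))))
  }
  fx <- adcgan:::gen_forward(gen, xb, want_taps = TRUE)

  adcgan:::zero_grads(gen$params)
  invisible(adcgan:::gen_backward(gen, fx$caches,
                                  gy = 2 * (fx$y - xb) / length(xb)))
  expect_gt(grad_norm(), 0) # self-regularization path

  adcgan:::zero_grads(c(gen$params, head$params))
  fe <- adcgan:::gen_forward(gen, fx$y, encoder_only = TRUE,
                             want_taps = TRUE)
  px <- adcgan:::nce_pass(head, fe$feats, fx$feats, layer_ids, locs, 0.07, 1)
  gy <- adcgan:::gen_backward(gen, fe$caches, tap_g = px$qtap,
                              encoder_only = TRUE)
  invisible(adcgan:::gen_backward(gen, fx$caches, gy = gy, tap_g = px$ktap))
  expect_gt(grad_norm(), 0) # contrastive path
  expect_gt(px$loss, 0)
})
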