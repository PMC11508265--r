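test_that("generator parameter counts match the printed architecture budget", {
  gen <- build_generator(generator_config())
  expect_equal(round(gen$n_parameters / 1e6, 3), 11.379)
  plain <- build_generator(generator_config(cbam = FALSE))
  expect_equal(round(plain$n_parameters / 1e6, 3), 11.378)
  expect_equal(gen$n_parameters - plain$n_parameters,
               64 * 8 + 8 * 64 + (5 * 5 * 2 + 1)) # CBAM budget
  expect_equal(count_parameters(gen), gen$n_parameters)
})

test_that("channel attention follows the pooled-MLP-sigmoid form", {
  set.seed(1)
  # zero MLP -> sigmoid(0) = 0.5 everywhere
  f <- array(rnorm(6 * 5 * 8), c(6, 5, 8))
  p0 <- zero_cbam_params(8, r = 4)
  expect_equal(channel_attention(f, p0), rep(0.5, 8), tolerance = 1e-12)

  # spatially constant map: AvgPool = MaxPool, so M_C = sigmoid(2 MLP(pooled))
  vals <- rnorm(8)
  fc <- array(rep(vals, each = 30), c(6, 5, 8))
  w1 <- matrix(rnorm(2 * 8), 2, 8)
  w2 <- matrix(rnorm(8 * 2), 8, 2)
  got <- channel_attention(fc, list(w1 = w1, w2 = w2))
  manual <- 1 / (1 + exp(-(2 * (w2 %*% pmax(w1 %*% vals, 0)))))
  expect_equal(got, as.numeric(manual), tolerance = 1e-9)

  # shape contract over channel counts
  for (C in c(8, 16, 64)) {
    fC <- array(rnorm(4 * 4 * C), c(4, 4, C))
    pC <- zero_cbam_params(C, r = 8)
    expect_length(channel_attention(fC, pC), C)
  }
  expect_error(channel_attention(f, list(w1 = matrix(0, 2, 4),
                                         w2 = matrix(0, 4, 2))),
               "channel mismatch")
})

test_that("spatial attention pools channels and convolves 5x5", {
  set.seed(2)
  f <- array(rnorm(7 * 6 * 3), c(7, 6, 3))
  p0 <- zero_cbam_params(8)
  ms <- spatial_attention(f, p0)
  expect_equal(dim(ms), c(7L, 6L))
  expect_equal(as.vector(ms), rep(0.5, 42), tolerance = 1e-12)

  # hand-sized oracle: brute-force 2D convolution over the pooled maps
  f2 <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  kw <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  kb <- 0.3
  got <- spatial_attention(f2, list(conv_w = kw, conv_b = kb))
  avg <- apply(f2, c(1, 2), mean)
  mx <- apply(f2, c(1, 2), max)
  # single-channel input: avg map equals max map equals the map itself
  f1 <- array(rnorm(3 * 3 * 1), c(3, 3, 1))
  expect_equal(apply(f1, c(1, 2), mean), apply(f1, c(1, 2), max))
  direct <- matrix(0, 3, 3)
  planes <- list(avg, mx)
  for (i in 1:3) for (j in 1:3) {
    acc <- kb
    for (cc in 1:2) for (u in 1:5) for (v in 1:5) {
      ii <- i + u - 3 # zero padding 2
      jj <- j + v - 3
      if (ii >= 1 && ii <= 3 && jj >= 1 && jj <= 3)
        acc <- acc + planes[[cc]][ii, jj] * kw[u, v, cc, 1]
    }
    direct[i, j] <- 1 / (1 + exp(-acc))
  }
  expect_equal(got, direct, tolerance = 1e-9)
})

test_that("cbam_refine composes the two gates (0.25 identity, zero, oracle)", {
  set.seed(3)
  f <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  p0 <- zero_cbam_params(8)
  expect_equal(cbam_refine(f, p0), 0.25 * f, tolerance = 1e-9)
  expect_equal(cbam_refine(array(0, dim(f)), p0), array(0, dim(f)))

  # composition oracle with random parameters
  p <- list(w1 = matrix(rnorm(8), 1, 8), w2 = matrix(rnorm(8), 8, 1),
            conv_w = array(rnorm(50), c(5, 5, 2, 1)), conv_b = 0.1)
  mc <- channel_attention(f, p)
  f1 <- f * rep(mc, each = 36)
  ms <- spatial_attention(f1, p)
  manual <- f1 * array(rep(as.vector(ms), 8), dim(f))
  expect_equal(cbam_refine(f, p), manual, tolerance = 1e-9)
})

test_that("generator preserves stride-4-divisible shapes and tanh range", {
  gen <- build_generator(generator_config(base_width = 8, n_resblocks = 4,
                                          cbam = attention_config(reduction_ratio = 4)))
  for (n in c(152L, 124L)) {
    set.seed(n)
    x <- array(runif(n * n * 3, -1, 1), c(n, n, 3, 1))
    y <- adcgan:::gen_forward(gen, x)$y
    expect_equal(dim(y), c(n, n, 3L, 1L))
    expect_true(all(y > -1 & y < 1)) # tanh head
  }
})

test_that("discriminator stride schedule yields the closed-form map size", {
  disc <- build_discriminator(3, 8)
  n <- 152L
  set.seed(4)
  x <- array(rnorm(n * n * 3), c(n, n, 3, 1))
  out <- adcgan:::disc_forward(disc, x)$y
  # 152 -(s2)-> 76 -(s2)-> 38 -(s2)-> 19 -(s1,k4,p1)-> 18 -(s1)-> 17
  expect_equal(dim(out), c(17L, 17L, 1L, 1L))
  expect_lt(prod(dim(out)[1:2]), n * n)

  # constant-zero weights give a constant map; raw scores are unbounded
  for (p in disc$params) p$v <- p$v * 0
  out0 <- adcgan:::disc_forward(disc, x)$y
  expect_equal(max(abs(out0 - out0[1])), 0)
  disc2 <- build_discriminator(3, 8)
  for (p in disc2$params) p$v <- p$v * 0 + 0.5
  big <- adcgan:::disc_forward(disc2, array(1, c(32, 32, 3, 1)))$y
  expect_gt(max(abs(big)), 1) # no sigmoid on the LSGAN head
})

test_that("projection heads are independent per layer and sized to out_dim", {
  head <- build_projection_head(c(a = 3, b = 8), out_dim = 16)
  za <- matrix(rnorm(10 * 3), 10, 3)
  zb <- matrix(rnorm(10 * 8), 10, 8)
  oa <- adcgan:::head_forward(head, 1, za)$y
  ob <- adcgan:::head_forward(head, 2, zb)$y
  expect_equal(ncol(oa), 16)
  expect_equal(ncol(ob), 16)

  # zero weights -> zero embeddings before normalization
  for (p in head$heads[[1]][[1]]$params) p$v <- p$v * 0
  for (p in head$heads[[1]][[3]]$params) p$v <- p$v * 0
  expect_equal(max(abs(adcgan:::head_forward(head, 1, za)$y)), 0)
  # ...and layer b is untouched by mutating layer a
  expect_equal(adcgan:::head_forward(head, 2, zb)$y, ob)
})

test_that("encode_patch_features samples shared unit-norm embeddings", {
  gen <- build_generator(generator_config(base_width = 4, n_resblocks = 4,
                                          cbam = FALSE))
  head <- build_projection_head(gen$tap_channels, out_dim = 8)
  set.seed(5)
  img <- matrix(runif(32 * 32, -1, 1), 32, 32)
  fs1 <- encode_patch_features(gen, img, n_locations = 16, head = head,
                               seed = 42)
  fs2 <- encode_patch_features(gen, img, n_locations = 16, head = head,
                               seed = 42)
  expect_identical(fs1$locations, fs2$locations)
  expect_identical(fs1$embeddings, fs2$embeddings)

  img2 <- matrix(runif(32 * 32, -1, 1), 32, 32)
  fs3 <- encode_patch_features(gen, img2, n_locations = 16, head = head,
                               shared_locations = fs1$locations)
  expect_identical(fs3$locations, fs1$locations)

  for (nm in fs1$layers) {
    nrm <- sqrt(rowSums(fs1$embeddings[[nm]][, , 1]^2))
    # unit norm except for degenerate all-zero feature vectors
    expect_true(all(abs(nrm - 1) < 1e-5 | nrm == 0))
    expect_gt(mean(abs(nrm - 1) < 1e-5), 0.5)
  }
  expect_error(encode_patch_features(gen, img, n_locations = 1e6),
               "exceeds spatial size")
})

test_that("checkpoints round-trip weights and reproduce outputs", {
  gen <- build_generator(generator_config(base_width = 4, n_resblocks = 2,
                                          cbam = FALSE))
  set.seed(6)
  x <- array(runif(16 * 16 * 3, -1, 1), c(16, 16, 3, 1))
  y0 <- adcgan:::gen_forward(gen, x)$y
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(p, gen, meta = list(tag = "test"))
  ck <- load_checkpoint(p)
  expect_equal(adcgan:::gen_forward(ck$generator, x)$y, y0,
               tolerance = 1e-6)
  expect_equal(ck$meta$tag, "test")
})
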