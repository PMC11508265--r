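test_that("psnr matches its closed forms", {
  x <- rand_img(16, seed = 20)
  expect_equal(psnr(x, x), Inf)

  # uniform squared error 0.01 at MAX_I = 1 -> 20 dB
  y <- x * 0
  x0 <- x * 0
  y[] <- 0.1
  expect_equal(psnr(x0, y, max_i = 1), 20, tolerance = 1e-12)

  # halving MAX_I at fixed MSE lowers PSNR by 20*log10(2)
  z <- rand_img(16, seed = 21)
  expect_equal(psnr(x, z, max_i = 1) - psnr(x, z, max_i = 0.5),
               20 * log10(2), tolerance = 1e-9)

  # strictly decreasing in MSE at fixed MAX_I
  p1 <- psnr(x0, x0 + 0.05, max_i = 1)
  p2 <- psnr(x0, x0 + 0.10, max_i = 1)
  expect_gt(p1, p2)

  expect_error(psnr(x, matrix(0, 2, 2)), "shapes differ")
})

test_that("ssim identities: self, constants, symmetry, l*c*s decomposition", {
  x <- rand_img(32, seed = 22)
  expect_equal(ssim(x, x)$ssim, 1, tolerance = 1e-12)

  # constant images a != b: contrast/structure neutral, luminance closed form
  a <- 0.4
  b <- 0.7
  ca <- matrix(a, 16, 16)
  cb <- matrix(b, 16, 16)
  c1 <- (0.01 * 1)^2
  expect_equal(ssim(ca, cb)$ssim, (2 * a * b + c1) / (a^2 + b^2 + c1),
               tolerance = 1e-9)

  y <- rand_img(32, seed = 23)
  expect_equal(ssim(x, y)$ssim, ssim(y, x)$ssim, tolerance = 1e-9)

  # Eq.-level decomposition: ssim map equals l * c * s when c3 = c2/2
  for (i in 1:5) {
    xi <- rand_img(20, seed = 30 + i)
    yi <- 0.5 * xi + 0.5 * rand_img(20, seed = 60 + i)
    r <- ssim(xi, yi)
    expect_equal(r$map, r$l * r$c * r$s, tolerance = 1e-9)
  }

  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "smaller than")
})

test_that("fid matches the univariate closed form and is a symmetric pseudometric", {
  m1 <- gaussian_moments(0.3, matrix(0.5), 10)
  m2 <- gaussian_moments(1.1, matrix(2.0), 10)
  want <- (0.3 - 1.1)^2 + (sqrt(0.5) - sqrt(2.0))^2
  expect_equal(fid(m1, m2), want, tolerance = 1e-6)
  expect_equal(fid(m1, m1), 0, tolerance = 1e-6)
  expect_equal(fid(m1, m2), fid(m2, m1), tolerance = 1e-6)

  # multivariate: zero at equal moments, positive otherwise, symmetric
  set.seed(24)
  A <- matrix(rnorm(25), 5)
  s1 <- crossprod(A) / 5
  B <- matrix(rnorm(25), 5)
  s2 <- crossprod(B) / 5
  g1 <- gaussian_moments(rnorm(5), s1, 20)
  g2 <- gaussian_moments(rnorm(5), s2, 20)
  expect_equal(fid(g1, g1), 0, tolerance = 1e-6)
  expect_gt(fid(g1, g2), 0)
  expect_equal(fid(g1, g2), fid(g2, g1), tolerance = 1e-6)

  expect_error(fid(g1, m1), "dimensions differ")
  expect_error(gaussian_moments(c(0, 0), matrix(c(1, 2, 3, 4), 2), 5),
               "symmetric")
})

test_that("embed_features is deterministic and degenerate-safe", {
  imgs <- lapply(1:4, function(i) matrix(0.3, 12, 12))
  m <- embed_features(imgs, "raw_pool")
  expect_equal(max(abs(m$sigma)), 0)
  expect_equal(m$mu, rep(0.3, 64), tolerance = 1e-9)

  set.seed(25)
  imgs2 <- lapply(1:5, function(i) rand_img(12, seed = i))
  m1 <- embed_features(imgs2, "raw_pool")
  mdup <- embed_features(c(imgs2, imgs2), "raw_pool")
  expect_equal(m1$mu, mdup$mu, tolerance = 1e-12)

  r1 <- embed_features(imgs2, "random_projection", dim = 16, seed = 7)
  r2 <- embed_features(imgs2, "random_projection", dim = 16, seed = 7)
  expect_identical(r1$mu, r2$mu)
  expect_identical(r1$sigma, r2$sigma)

  expect_error(embed_features(imgs2[1], "raw_pool"), "at least 2")
})

test_that("dice matches hand counts and edge conventions", {
  a <- matrix(0, 4, 4)
  b <- matrix(0, 4, 4)
  a[1:2, 1:2] <- 1 # |X| = 4
  b[2:3, 1:3] <- 1 # |Y| = 6, overlap {2,1},{2,2} ... choose overlap 3
  b[2:3, 1:3] <- 0
  b[1:2, 1] <- 1
  b[2, 2] <- 1
  b[3:5 - 1, 4] <- 1 # fill to |Y| = 6 outside X
  expect_equal(sum(a), 4)
  expect_equal(sum(b), 6)
  expect_equal(sum(a * b), 3)
  expect_equal(dice(a, b), 0.6) # 2*3 / (4+6)

  expect_equal(dice(a, a), 1)
  d0 <- matrix(0, 4, 4)
  d1 <- matrix(0, 4, 4)
  d1[4, 4] <- 1
  expect_equal(dice(a, d1), 0) # disjoint
  expect_equal(dice(d0, d0), 1) # both empty
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, b * 0.5), "binary")
})

test_that("evaluate pairs slices, aggregates, and flags offenders", {
  set.seed(26)
  truth <- list(make_slice(rand_img(32, 1) * 2 - 1, "s1", 0),
                make_slice(rand_img(32, 2) * 2 - 1, "s1", 1),
                make_slice(rand_img(32, 3) * 2 - 1, "s2", 0))
  # perfect prediction
  rep0 <- evaluate(truth, truth)
  expect_equal(rep0$n_slices, 3)
  expect_equal(rep0$summary$mean[rep0$summary$metric == "ssim"], 1)
  expect_true(all(!is.finite(rep0$per_slice$psnr))) # +Inf sentinels
  expect_lt(rep0$fid, 1e-6)

  # noisy prediction: row count, finite metrics, CSV output
  pred <- lapply(truth, function(s) {
    s$image <- pmin(pmax(s$image + rnorm(length(s$image), 0, 0.05), -1), 1)
    s
  })
  rp <- evaluate(pred, truth)
  expect_equal(nrow(rp$per_slice), 3)
  expect_true(all(is.finite(rp$per_slice$psnr)))
  expect_gt(rp$fid, 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rp, f)
  expect_true(any(grepl("^fid,", readLines(f))))

  # single pair: sd reported as 0
  r1 <- evaluate(pred[1], truth[1])
  expect_equal(r1$summary$sd, c(0, 0))

  # masks produce a Dice summary
  mk <- matrix(0, 8, 8)
  mk[2:5, 2:5] <- 1
  rm <- evaluate(pred, truth, masks = list(pred = list(mk, mk, mk),
                                           truth = list(mk, mk, mk)))
  expect_equal(unname(rm$dice["mean"]), 1)

  expect_error(evaluate(pred[1:2], truth), "unpaired")
  # mixed-domain lists with repeated subject/slice keys are rejected
  expect_error(evaluate(c(pred, pred), c(truth, truth)), "duplicate")
})
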