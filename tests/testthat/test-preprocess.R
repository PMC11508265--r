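make_vol <- function(d = c(12, 10, 6), spacing = c(1, 1, 3), seed = 1,
                     role = "t2") {
  set.seed(seed)
  volume(array(rnorm(prod(d)), d), spacing, role = role)
}

test_that("resample honors shape, identity and constant contracts", {
  # closed form: 96 voxels at 0.75 mm -> 144 voxels at 0.5 mm
  v <- make_vol(c(96, 8, 4), spacing = c(0.75, 1, 3))
  r <- resample(v, c(0.5, 1, 3))
  expect_equal(dim(r$data), c(144L, 8L, 4L))
  expect_equal(r$spacing, c(0.5, 1, 3))

  # identity resample
  r2 <- resample(v, c(0.75, 1, 3))
  expect_equal(dim(r2$data), dim(v$data))
  expect_equal(r2$data, v$data, tolerance = 1e-6)
  expect_equal(r2$affine, v$affine, tolerance = 1e-9)

  # constant volume stays constant under interpolation
  cv <- volume(array(3.7, c(10, 10, 4)), c(1, 1, 1))
  rc <- resample(cv, c(0.6, 0.6, 0.8))
  expect_equal(range(rc$data), c(3.7, 3.7), tolerance = 1e-12)

  # masks stay binary (nearest neighbor)
  m <- volume(array(round(runif(10 * 10 * 4)), c(10, 10, 4)), c(1, 1, 1),
              role = "mask")
  rm <- resample(m, c(0.7, 0.7, 1))
  expect_true(all(rm$data %in% c(0, 1)))

  expect_error(resample(v, c(1000, 1000, 1000)), "degenerate")
})

test_that("resampling to the same target twice is idempotent", {
  v <- make_vol(c(30, 28, 6), spacing = c(0.75, 0.75, 3), seed = 4)
  a <- resample(v, c(0.5, 0.5, 3))
  b <- resample(a, c(0.5, 0.5, 3))
  expect_equal(a$data, b$data, tolerance = 1e-6)
})

test_that("zscore normalizes, is affine-invariant, and rejects constants", {
  v <- make_vol(seed = 2)
  z <- zscore(v)
  expect_lt(abs(mean(z$data)), 1e-6)
  expect_lt(abs(sd(as.vector(z$data)) - 1), 1e-6)

  v2 <- v
  v2$data <- 2.5 * v$data + 7
  expect_equal(zscore(v2)$data, z$data, tolerance = 1e-6)

  cv <- volume(array(1, c(5, 5, 5)), c(1, 1, 1))
  expect_error(zscore(cv), "zero variance")
})

test_that("crop_to_mask computes dilated, clipped boxes", {
  v <- make_vol(c(20, 20, 6), seed = 3)
  full <- volume(array(1, dim(v$data)), v$spacing, role = "mask")
  cr <- crop_to_mask(v, full, margin_mm = 0)
  expect_identical(cr$volume$data, v$data)
  expect_equal(cr$crop_box$lo, c(0, 0, 0))
  expect_equal(cr$crop_box$hi, dim(v$data))

  single <- volume(array(0, dim(v$data)), v$spacing, role = "mask")
  single$data[5, 7, 3] <- 1
  cs <- crop_to_mask(v, single, margin_mm = 0)
  expect_equal(dim(cs$volume$data), c(1L, 1L, 1L))
  expect_equal(cs$crop_box$lo, c(4, 6, 2))
  expect_equal(cs$volume$data[1, 1, 1], v$data[5, 7, 3])

  # 5 mm margin at 0.5 mm spacing dilates by 10 voxels in-plane, clipped
  v5 <- make_vol(c(40, 40, 6), spacing = c(0.5, 0.5, 3), seed = 5)
  mk <- volume(array(0, dim(v5$data)), v5$spacing, role = "mask")
  mk$data[16:25, 5:30, 2:5] <- 1
  c5 <- crop_to_mask(v5, mk, margin_mm = 5)
  expect_equal(c5$crop_box$lo, c(15 - 10, 0, 1)) # j clipped at 0
  expect_equal(c5$crop_box$hi, c(25 + 10, 40, 5))

  # every nonzero mask voxel is inside the box
  idx <- which(mk$data > 0, arr.ind = TRUE) - 1
  expect_true(all(t(idx) >= c5$crop_box$lo) &&
              all(t(t(idx) < c5$crop_box$hi)))

  empty <- volume(array(0, dim(v$data)), v$spacing, role = "mask")
  expect_error(crop_to_mask(v, empty), "empty mask")
})

test_that("extract_slices counts, pads and rescales correctly", {
  d <- c(150, 150, 9)
  set.seed(6)
  v <- volume(array(rnorm(prod(d)), d), c(0.5, 0.5, 3))
  a <- volume(array(rnorm(prod(d)), d), c(0.5, 0.5, 3), role = "adc")
  m <- volume(array(0, d), c(0.5, 0.5, 3), role = "mask")
  m$data[40:80, 40:80, 4:8] <- 1 # mask nonzero only on slices 3..7 (0-based)
  s <- extract_slices(v, a, m)
  expect_length(s, 10) # 5 per domain
  expect_equal(sum(vapply(s, function(x) x$domain == "X", logical(1))), 5)
  expect_equal(vapply(s[1:5], function(x) x$slice_index, integer(1)), 3:7)

  # 150x150 pads to 152x152; all values within [-1, 1]
  expect_true(all(vapply(s, function(x)
    identical(dim(x$image), c(152L, 152L)), logical(1))))
  rng <- range(vapply(s, function(x) range(x$image), numeric(2)))
  expect_gte(rng[1], -1)
  expect_lte(rng[2], 1)

  nomask <- volume(array(0, d), c(0.5, 0.5, 3), role = "mask")
  expect_error(extract_slices(v, mask = nomask), "no slice")

  expect_error(extract_slices(v, mask = m, target_size = c(100, 100)),
               "target_size")
})

test_that("extract/reinsert round-trips the cropped region", {
  subj <- generate_subject(tiny_spec(noise_sd = 0.01))
  cr <- crop_to_mask(subj$t2, subj$mask, 3)
  crm <- crop_to_mask(subj$mask, subj$mask, 3)
  s <- extract_slices(cr$volume, mask = crm$volume, crop_box = cr$crop_box)
  back <- reinsert_slices(s, subj$t2, fill = NA)
  lo <- cr$crop_box$lo
  hi <- cr$crop_box$hi
  ks <- vapply(s, function(x) lo[3] + x$slice_index + 1L, integer(1))
  for (i in seq_along(s)) {
    got <- back[["data"]][(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], ks[i]]
    want <- subj$t2$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2], ks[i]]
    expect_equal(got, want, tolerance = 1e-5)
  }
  # voxels outside crops keep the fill value
  expect_true(is.na(back$data[1, 1, 1]))

  # disjoint writes / bounds checks
  bad <- s[[1]]
  bad$crop_box$hi <- dim(subj$t2$data) + 5L
  expect_error(reinsert_slices(list(bad), subj$t2), "out of template bounds")
})
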