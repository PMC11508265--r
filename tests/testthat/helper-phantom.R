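# shared fixture builders (everything generated in code at test time)

# small, fast phantom spec used across tests (overrides win over defaults)
tiny_spec <- function(...) {
  args <- list(grid_shape = c(48, 48, 8), spacing_mm = c(1, 1, 3),
               prostate_axes_mm = c(14, 12, 5), n_lesions = 1,
               lesion_radius_mm = c(2, 4), noise_sd = 0, seed = 11L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(phantom_spec, args)
}

# preprocessed [-1, 1] slice sets for a small cohort; slices share one shape
make_cohort_slices <- function(n_subjects, seed, target_size = c(64, 64),
                               noise_sd = 0.02) {
  xs <- list()
  ys <- list()
  for (i in seq_len(n_subjects)) {
    spec <- phantom_spec(prostate_axes_mm = c(16, 13, 9), n_lesions = 1,
                         noise_sd = noise_sd, seed = seed + i)
    subj <- generate_subject(spec)
    crt <- crop_to_mask(subj$t2, subj$mask, 5)
    cra <- crop_to_mask(subj$adc, subj$mask, 5)
    crm <- crop_to_mask(subj$mask, subj$mask, 5)
    id <- sprintf("sub%03d", i)
    xs <- c(xs, extract_slices(zscore(crt$volume), mask = crm$volume,
                               subject_id = id, target_size = target_size))
    ys <- c(ys, extract_slices(zscore(cra$volume), mask = crm$volume,
                               subject_id = id, target_size = target_size))
  }
  list(x = xs, y = ys)
}

# hand-made slice_sample for metric tests
make_slice <- function(img, subject = "s1", k = 0L) {
  structure(list(image = img, domain = "Y", subject_id = subject,
                 slice_index = as.integer(k),
                 crop_box = list(lo = c(0L, 0L, 0L),
                                 hi = c(dim(img), k + 1L)),
                 pad = c(h_lo = 0L, h_hi = 0L, w_lo = 0L, w_hi = 0L),
                 rescale = c(0, 1)),
            class = "slice_sample")
}

rand_img <- function(n = 32, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n), n, n)
}

# zeroed CBAM parameter set for a C-channel feature map
zero_cbam_params <- function(C, r = 8, k = 5) {
  list(w1 = matrix(0, C %/% r, C), w2 = matrix(0, C, C %/% r),
       conv_w = array(0, c(k, k, 2, 1)), conv_b = 0)
}

# small 32x32 slice sets for fast trainer tests
make_tiny_slices <- function(n_subjects, seed) {
  xs <- list()
  ys <- list()
  for (i in seq_len(n_subjects)) {
    spec <- tiny_spec(noise_sd = 0.02)
    spec$seed <- seed + i
    subj <- generate_subject(spec)
    crt <- crop_to_mask(subj$t2, subj$mask, 1)
    cra <- crop_to_mask(subj$adc, subj$mask, 1)
    crm <- crop_to_mask(subj$mask, subj$mask, 1)
    id <- sprintf("t%02d", i)
    xs <- c(xs, extract_slices(zscore(crt$volume), mask = crm$volume,
                               subject_id = id, target_size = c(32, 32)))
    ys <- c(ys, extract_slices(zscore(cra$volume), mask = crm$volume,
                               subject_id = id, target_size = c(32, 32)))
  }
  list(x = xs, y = ys)
}

tiny_cfg <- function(max_iters, seed = 5L) {
  train_config(epochs = 50, batch_size = 2, max_iters = max_iters,
               seed = seed,
               generator = generator_config(base_width = 8,
                                            cbam = attention_config(reduction_ratio = 4)),
               n_locations = 32, head_dim = 32)
}
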