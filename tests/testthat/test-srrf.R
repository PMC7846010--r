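test_that("radiality maps score gradient convergence", {
  # flat field: no gradients, radiality identically zero
  flat <- matrix(5, 15, 15)
  expect_true(all(compute_radiality_map(flat, 0.5, 4, 8)$values == 0))
  # single Gaussian spot: global maximum within one magnified pixel of the
  # centre, and a much sharper peak than the PSF itself
  fr <- gaussian_image(21, cbind(10, 10), sigma = 1.3)
  rm <- compute_radiality_map(fr, 0.5, 10, 8)
  ij <- which(rm$values == max(rm$values), arr.ind = TRUE)
  centre_idx <- (10 + 0.5) * 10 + 0.5 # magnified index of source coord 10
  expect_true(all(abs(ij - centre_idx) <= 1))
  prof <- rm$values[round(centre_idx), ]
  fwhm_rad <- sum(prof > max(prof) / 2) / 10 # in source pixels
  expect_lt(fwhm_rad, 2.355 * 1.3 / 3)
  # input validation
  expect_error(compute_radiality_map(matrix(1, 2, 40), 1, 2, 8), "smaller")
  expect_error(compute_radiality_map(fr, 0.5, 10, 7), "even")
  expect_error(compute_radiality_map(fr, -1, 10, 8), "positive")
})

test_that("TRAC2 keeps fluctuations and floors negative cumulants", {
  # temporally constant stack -> identically zero
  cm <- replicate(6, matrix(2, 5, 5), simplify = FALSE)
  expect_true(all(trac2(cm)$values == 0))
  # alternating +a/-a around the mean: lag-1 product -a^2, floored to 0
  alt <- lapply(1:6, function(t) matrix(3 + (-1)^t, 4, 4))
  expect_true(all(trac2(alt)$values == 0))
  # positively correlated blinking survives
  set.seed(1)
  state <- rep(c(1, 1, 0, 0), 5)
  blink <- lapply(state, function(s) matrix(s, 3, 3))
  expect_true(all(trac2(blink)$values > 0))
  expect_error(trac2(list(matrix(1, 2, 2), matrix(1, 3, 3))), "mismatched")
})

test_that("reconstruction localizes a blinking emitter and suppresses static background", {
  # one blinking emitter plus one always-on (static) emitter
  blink <- emitter_field(rbind(c(500, 700)), brightness = 1000,
                         on_probability = 0.3, window_nm = c(1800, 1400))
  static <- emitter_field(rbind(c(1300, 700)), brightness = 1000,
                          on_probability = 1, window_nm = c(1800, 1400))
  stb <- simulate_blinking_stack(blink, n_frames = 60, psf_sigma = 120,
                                 pixel_size = 100, read_noise_sd = 1,
                                 seed = 21)
  sts <- simulate_blinking_stack(static, n_frames = 60, psf_sigma = 120,
                                 pixel_size = 100, shot_noise = FALSE,
                                 read_noise_sd = 0, seed = 22)
  mixed <- image_stack(mapply(`+`, stb$frames, sts$frames, SIMPLIFY = FALSE),
                       pixel_size = 100)
  sr <- srrf_reconstruct(mixed, ring_radius = 0.5, magnification = 5,
                         axes_in_ring = 8)
  mean_img <- temporal_mean(mixed)$values
  # positions on the magnified and source grids
  at <- function(img, x_nm, y_nm, px) {
    img[round(y_nm / px), round(x_nm / px)]
  }
  patch_max <- function(img, x_nm, y_nm, px, half = 2) {
    i <- round(y_nm / px); j <- round(x_nm / px)
    max(img[(i - half):(i + half), (j - half):(j + half)])
  }
  contrast_sr <- patch_max(sr$values, 500, 700, 20) /
    max(patch_max(sr$values, 1300, 700, 20), 1e-12)
  contrast_mean <- patch_max(mean_img, 500, 700, 100, 1) /
    patch_max(mean_img, 1300, 700, 100, 1)
  # blinking-to-static contrast improves at least tenfold
  expect_gt(contrast_sr / contrast_mean, 10)
  # localization: reconstructed peak within one source pixel of ground truth
  pk <- which(sr$values == max(sr$values), arr.ind = TRUE)
  expect_lt(abs(pk[1, 2] * 20 - 500), 100)
  expect_lt(abs(pk[1, 1] * 20 - 700), 100)
  # magnification 1 keeps the source shape
  sr1 <- srrf_reconstruct(mixed, ring_radius = 0.5, magnification = 1,
                          axes_in_ring = 8)
  expect_identical(dim(sr1$values), dim(mixed$frames[[1]]))
  expect_true(all(sr$values >= 0))
})

test_that("blinking pair at 0.6 x FWHM is resolved by SRRF but not by the temporal mean", {
  psf <- 120; px <- 100
  sep <- 0.6 * 2.355 * psf
  cx <- 1200; cy <- 1200
  ef <- emitter_field(rbind(c(cx - sep / 2, cy), c(cx + sep / 2, cy)),
                      brightness = 1000, on_probability = 0.3,
                      window_nm = c(2400, 2400))
  st <- simulate_blinking_stack(ef, n_frames = 100, psf_sigma = psf,
                                pixel_size = px, read_noise_sd = 1, seed = 5)
  sr <- srrf_reconstruct(st, ring_radius = 0.5, magnification = 5,
                         axes_in_ring = 8)
  mag_px <- px / 5
  row <- sr$values[round(cy / mag_px), ]
  # restrict to the neighbourhood of the pair
  j1 <- round((cx - sep) / mag_px); j2 <- round((cx + sep) / mag_px)
  seg <- row[j1:j2]
  peaks <- local_maxima(seg, floor_frac = 0.25)
  expect_gte(length(peaks), 2)
  top2 <- sort(peaks[order(seg[peaks], decreasing = TRUE)][1:2])
  saddle <- min(seg[top2[1]:top2[2]])
  expect_gte(1 - saddle / min(seg[top2]), 0.20)
  # recovered positions within one source pixel of the true emitters
  pos_nm <- (j1 - 1 + top2) * mag_px
  expect_lt(abs(pos_nm[1] - (cx - sep / 2)), 100)
  expect_lt(abs(pos_nm[2] - (cx + sep / 2)), 100)
  # the diffraction-limited temporal mean shows no 20% dip between the peaks
  m <- temporal_mean(st)$values
  mrow <- m[round(cy / px), ]
  i1 <- round((cx - sep / 2) / px); i2 <- round((cx + sep / 2) / px)
  dip_mean <- 1 - min(mrow[i1:i2]) / min(mrow[i1], mrow[i2])
  expect_lt(dip_mean, 0.2)
})

test_that("reconstruction is translation-equivariant in the interior", {
  # the same blinking noise realization, rolled by one source pixel in x,
  # must reconstruct at a position shifted by exactly the magnification
  ef <- emitter_field(cbind(700, 800), brightness = 1000,
                      on_probability = 0.4, window_nm = c(1600, 1600))
  st <- simulate_blinking_stack(ef, n_frames = 40, psf_sigma = 120,
                                pixel_size = 100, read_noise_sd = 1,
                                seed = 33)
  n <- ncol(st$frames[[1]])
  rolled <- image_stack(lapply(st$frames, function(f) f[, c(n, 1:(n - 1))]),
                        pixel_size = 100)
  mag <- 5
  a <- srrf_reconstruct(st, 0.5, mag, 8)$values
  b <- srrf_reconstruct(rolled, 0.5, mag, 8)$values
  pa <- which(a == max(a), arr.ind = TRUE)[1, ]
  pb <- which(b == max(b), arr.ind = TRUE)[1, ]
  expect_lte(abs(pb[1] - pa[1]), 1)
  expect_lte(abs((pb[2] - pa[2]) - mag), 1)
  expect_true(all(a >= 0))
})
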