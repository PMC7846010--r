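test_that("carpet extraction preserves geometry", {
  # identity: rotation 0 at 25 nm pixels returns the ROI column-for-column
  set.seed(2)
  img <- super_res_image(matrix(runif(200 * 160), 200, 160), pixel_size = 25)
  cp <- extract_carpet(img, column_width_nm = 25)
  expect_equal(cp$columns, unname(img$values))
  expect_equal(ncol(cp$columns), 160)
  # a vertical stripe rotated by 90 degrees gives one peak per column at a
  # common y
  stripe <- matrix(0, 81, 81); stripe[, 38:44] <- 5
  rs <- extract_carpet(super_res_image(stripe, 25), angle_deg = 90,
                       roi_um = c(0.5, 0.5, 1, 1))
  peaks <- apply(rs$columns, 2, which.max)
  expect_lte(diff(range(peaks)), 1)
  # rotating the ROI out of the image is a geometry error
  expect_error(extract_carpet(super_res_image(stripe, 25), angle_deg = 45),
               "outside")
  # column profiles track the membrane apex
  model <- membrane_model(length_um = 4, height_um = 2,
                          deformation_amplitude_nm = 150,
                          layer_offsets_nm = c(0, 0),
                          layer_thickness_nm = 0,
                          emitter_density_per_um = 400)
  pair <- simulate_membrane_pair(model, shot_noise = FALSE, seed = 6)
  gt <- attr(pair$ref, "ground_truth")
  cp2 <- extract_carpet(pair$ref)
  apex <- apply(cp2$columns, 2, which.max) * 25 - 12.5
  ok <- abs(apex - gt$centerline_nm) <= 50
  expect_gt(mean(ok), 0.9)
})

test_that("paired correlation functions obey their closed-form cases", {
  y <- seq(12.5, 5000, 25)
  p <- gaussian_profile(y, 2500)
  # autocorrelation peaks at zero lag
  pc <- pcf(p, p, max_lag = 20)
  expect_equal(attr(pc, "lags")[which.max(pc)], 0)
  # exact integer translations: features moved toward larger y give a
  # positive argmax, toward smaller y a negative one
  p_up <- c(rep(1, 3), p[1:(length(p) - 3)]) # features shifted +3 bins
  pc2 <- pcf(p, p_up, max_lag = 20)
  expect_equal(attr(pc2, "lags")[which.max(pc2)], 3)
  p_dn <- c(p[-(1:3)], rep(1, 3))            # features shifted -3 bins
  pc3 <- pcf(p, p_dn, max_lag = 20)
  expect_equal(attr(pc3, "lags")[which.max(pc3)], -3)
  # constant profile: pCF identically zero
  expect_true(all(abs(pcf(rep(4, 200), p, max_lag = 10)) < 1e-12))
  # zero-mean profile is an error
  expect_error(pcf(rep(0, 200), p, max_lag = 5), "zero-mean")
})

test_that("pCCF recovers signed sub-bin inter-layer distances", {
  y <- seq(12.5, 5000, 25)
  f1 <- gaussian_profile(y, 2500)
  f2 <- gaussian_profile(y, 2500 - 26)
  pc <- pccf(f1, f2, max_lag = 20)
  d <- nanolayers:::refine_argmax(pc, attr(pc, "lags")) * 25
  expect_lt(abs(d - (-26)), 3)
  # identical profiles: zero distance
  pc0 <- pccf(f1, f1, max_lag = 20)
  expect_equal(abs(nanolayers:::refine_argmax(pc0, attr(pc0, "lags"))), 0)
  # sign convention: a shift toward the cytoplasm end (smaller y) is negative
  expect_lt(d, 0)
  f2b <- gaussian_profile(y, 2500 + 26)
  pcb <- pccf(f1, f2b, max_lag = 20)
  expect_gt(nanolayers:::refine_argmax(pcb, attr(pcb, "lags")), 0)
  # antisymmetry under channel swap
  pr <- pccf(f2, f1, max_lag = 20)
  dr <- nanolayers:::refine_argmax(pr, attr(pr, "lags")) * 25
  expect_lt(abs(d + dr), 2)
})

test_that("sub-bin shifts are recovered within 0.2 bins at shot-noise SNR 10", {
  y <- seq(12.5, 5000, 25)
  # noiseless: quadratic refinement bias well below 0.1 bins
  for (true_shift in c(0.4, -0.7)) {
    shifted <- gaussian_profile(y, 2500 + true_shift * 25, amp = 100)
    pc <- pcf(gaussian_profile(y, 2500, amp = 100), shifted, max_lag = 20)
    expect_lt(abs(nanolayers:::refine_argmax(pc, attr(pc, "lags")) -
                  true_shift), 0.1)
  }
  # Poisson noise at peak SNR 10: mean recovery error below 0.2 bins
  set.seed(9)
  miss <- vapply(1:40, function(i) {
    tr <- runif(1, -1, 1)
    a <- rpois(length(y), gaussian_profile(y, 2500, amp = 100))
    b <- rpois(length(y), gaussian_profile(y, 2500 + tr * 25, amp = 100))
    pc <- pcf(a, b, max_lag = 20)
    abs(nanolayers:::refine_argmax(pc, attr(pc, "lags")) - tr)
  }, numeric(1))
  expect_lt(mean(miss), 0.2)
})

test_that("alignment straightens a deformed membrane carpet", {
  model <- membrane_model(length_um = 4, height_um = 2.5,
                          deformation_amplitude_nm = 200,
                          layer_offsets_nm = c(0, -26),
                          layer_thickness_nm = 10,
                          emitter_density_per_um = 400,
                          brightness = 800)
  pair <- simulate_membrane_pair(model, shot_noise = TRUE, seed = 13)
  cp <- extract_carpet(pair$ref)
  al <- align_carpet(cp, max_lag_nm = 800)
  gt <- attr(pair$ref, "ground_truth")
  disp <- gt$centerline_nm - gt$centerline_nm[1]
  kept <- al$kept
  # recovered shifts match the known apex displacement within one bin
  expect_gt(mean(abs(al$shifts_nm[kept] - disp[kept]) <= 25), 0.9)
  # alignment collapses the spread of per-column peak positions
  sd_before <- sd(apply(cp$columns, 2, which.max))
  sd_after <- sd(apply(al$carpet$columns, 2, which.max))
  expect_gte(sd_before / sd_after, 5)
  # undeformed membrane: all shifts essentially zero
  flatm <- membrane_model(length_um = 2, height_um = 1.5,
                          deformation_amplitude_nm = 0,
                          layer_thickness_nm = 0,
                          emitter_density_per_um = 400)
  fp <- simulate_membrane_pair(flatm, shot_noise = FALSE, seed = 2)
  fal <- align_carpet(extract_carpet(fp$ref))
  expect_lt(max(abs(fal$shifts_nm), na.rm = TRUE), 13)
})

test_that("aligned profiles average at the replicate level", {
  cols <- matrix(rep(c(1, 3, 9, 3, 1), 4), ncol = 4)
  c1 <- make_carpet(cols, replicate_id = "cellA")
  c2 <- make_carpet(cols, replicate_id = "cellB")
  avg <- average_aligned_profile(list(c1, c2))
  expect_equal(avg$sem, rep(0, 5))
  expect_equal(avg$mean, c(1, 3, 9, 3, 1))
  # n = 2 closed form at one y
  c3 <- make_carpet(cols * 2, replicate_id = "cellB")
  avg2 <- average_aligned_profile(list(c1, c3))
  expect_equal(avg2$mean[3], (9 + 18) / 2)
  expect_equal(avg2$sem[3], abs(9 - 18) / 2)
  expect_warning(average_aligned_profile(list(c1)), "single replicate")
})

test_that("distance distributions summarize signed distances and modes", {
  set.seed(21)
  y <- seq(12.5, 3000, 25)
  ref_cols <- replicate(30, gaussian_profile(y, 1500))
  down <- replicate(30, gaussian_profile(y, 1500 - 26))
  rc <- make_carpet(ref_cols, replicate_id = "c1")
  tc <- make_carpet(down, replicate_id = "c1")
  rc2 <- make_carpet(ref_cols, replicate_id = "c2")
  tc2 <- make_carpet(down, replicate_id = "c2")
  dd <- distance_distribution(list(rc, rc2), list(tc, tc2), max_lag_nm = 500)
  expect_lt(abs(dd$mean_nm + 26), 3)
  expect_equal(dd$sem_nm, 0)
  expect_equal(nrow(dd$modes), 1)
  # bimodal mixture: half the columns displaced -26 nm, half +26 nm
  up <- replicate(30, gaussian_profile(y, 1500 + 26))
  mixed <- cbind(down[, 1:15], up[, 1:15])
  noise <- function(m) m + abs(matrix(rnorm(length(m), 0, 3), nrow(m)))
  dmix <- distance_distribution(
    list(make_carpet(noise(ref_cols), replicate_id = "c1"),
         make_carpet(noise(ref_cols), replicate_id = "c2")),
    list(make_carpet(noise(mixed), replicate_id = "c1"),
         make_carpet(noise(mixed), replicate_id = "c2")),
    max_lag_nm = 500)
  expect_gte(nrow(dmix$modes), 2)
  expect_lt(min(dmix$modes$location_nm), 0)
  expect_gt(max(dmix$modes$location_nm), 0)
  expect_lt(abs(dmix$mean_nm), 10)
  # replicate guard
  expect_warning(distance_distribution(list(rc), list(tc), max_lag_nm = 500),
                 "replicates")
})

test_that("wild-type-like and mutant-like distances separate decisively", {
  wt <- layer_distance_experiment(n_carpets = 4, offset_nm = -26, seed = 15)
  mut <- layer_distance_experiment(n_carpets = 4, offset_nm = 26, seed = 16)
  kw <- kruskal.test(list(wt$distances_nm, mut$distances_nm))
  expect_lt(kw$p.value, 1e-4)
  expect_lt(wt$mean_nm, 0)
  expect_gt(mut$mean_nm, 0)
  # broad but honest: individual columns span both signs
  expect_gt(max(wt$distances_nm), 0)
  expect_lt(min(wt$distances_nm), 0)
})
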