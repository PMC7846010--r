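test_that("convolution K equals the brute-force pair sum", {
  set.seed(11)
  for (n in c(16, 32)) {
    w <- matrix(sample(0:255, n * n, TRUE), n, n)
    f <- intensity_field(w, pixel_size = 25, quantize_8bit = FALSE)
    g <- radius_grid(25, 25 * floor(n / 2 - 1))
    k_fast <- intensity_k_raw(f, g)
    k_ref <- nanolayers:::k_brute_force(f, g)
    expect_lt(max(abs(k_fast - k_ref) / pmax(abs(k_ref), 1e-12)), 1e-6)
    # and with the edge correction off
    expect_lt(max(abs(intensity_k_raw(f, g, edge_correction = FALSE) -
                      nanolayers:::k_brute_force(f, g, FALSE)) /
                  pmax(k_ref, 1e-12)), 1e-6)
  }
})

test_that("K follows the CSR closed form on a uniform field", {
  f <- intensity_field(matrix(7, 200, 200), pixel_size = 25,
                       quantize_8bit = FALSE)
  g <- radius_grid(25, 600)
  k <- intensity_k_raw(f, g)
  # interior-dominated radii: within 2% of pi r^2 (below ~8 px the lattice
  # disc counts themselves deviate from pi r^2 by more than that)
  sel <- g$radii_nm >= 200
  rel <- (k[sel] - pi * g$radii_nm[sel]^2) / (pi * g$radii_nm[sel]^2)
  expect_lt(max(abs(rel)), 0.02)
  # radii below the pixel spacing contain no pairs at all
  g0 <- radius_grid(10, 10)
  expect_identical(intensity_k_raw(f, g0), 0)
  # grid exceeding half the window errors
  expect_error(intensity_k_raw(f, radius_grid(25, 3000)), "half")
})

test_that("Besag weights reproduce half-plane geometry and mask handling", {
  e <- besag_edge_weights(matrix(TRUE, 41, 41), 4)
  expect_equal(e[21, 21], 1.0)
  expect_equal(e[21, 1], 2.0, tolerance = 1e-12)
  expect_equal(e[1, 1], 4.0, tolerance = 1e-12)
  expect_true(all(e >= 1))
  # general mask: count-ratio weights, NA off-mask
  mask <- matrix(TRUE, 9, 9); mask[1:3, 1:3] <- FALSE
  em <- besag_edge_weights(mask, 2)
  expect_true(is.na(em[2, 2]))
  expect_true(all(em[!is.na(em)] >= 1))
})

test_that("the permutation null is seeded, calibrated and guarded", {
  set.seed(4)
  w <- matrix(rpois(80 * 80, 3), 80, 80)
  f <- intensity_field(w, pixel_size = 25, quantize_8bit = FALSE)
  g <- radius_grid(25, 500)
  n1 <- build_csr_null(f, g, n_sim = 100, seed = 5)
  n2 <- build_csr_null(f, g, n_sim = 100, seed = 5)
  expect_identical(n1$q_low, n2$q_low)
  expect_identical(n1$q_high, n2$q_high)
  # exact closed form for the permutation expectation:
  # E[K_perm] = K_uniform * N (SW^2 - sum w^2) / (SW^2 (N - 1))
  k_unif <- intensity_k_raw(intensity_field(matrix(1, 80, 80), 25,
                                            quantize_8bit = FALSE), g)
  N <- 80 * 80; SW <- sum(w); SW2 <- sum(w^2)
  e_exact <- k_unif * N * (SW^2 - SW2) / (SW^2 * (N - 1))
  mc_err <- 4 * n1$sd / sqrt(n1$n_sim)
  expect_true(all(abs(n1$mean - e_exact) < mc_err + 1e-9 * e_exact))
  # and the coarse CSR reading: close to pi r^2 away from lattice scales
  sel <- g$radii_nm >= 250
  expect_true(all(abs(n1$mean[sel] / (pi * g$radii_nm[sel]^2) - 1) < 0.03))
  expect_true(all(n1$q_low < n1$q_high))
  # degenerate field: all weight in one pixel
  w1 <- matrix(0, 20, 20); w1[7, 9] <- 5
  expect_error(build_csr_null(intensity_field(w1, 25, quantize_8bit = FALSE),
                              radius_grid(25, 100), n_sim = 100, seed = 1),
               "degenerate")
  expect_error(build_csr_null(f, g, n_sim = 50, seed = 1))
  expect_error(build_csr_null(f, g, n_sim = 100), "seed")
})

test_that("normalization centres the curve and flags zero-SD radii", {
  null <- structure(list(radii_nm = c(25, 50), mean = c(10, 20),
                         sd = c(2, 4), q_low = c(5, 10), q_high = c(15, 30),
                         n_sim = 100, quantiles = c(0.01, 0.99), seed = 1),
                    class = "csr_null")
  expect_equal(normalize_k(c(10, 20), null), c(0, 0))
  expect_equal(normalize_k(c(14, 12), null), c(2, -2))
  null$sd <- c(2, 0)
  expect_error(normalize_k(c(1, 2), null), "50 nm")
})

test_that("K-tilde flags clustering at the generative scale of a Thomas field", {
  spec <- point_process_spec("thomas", window_um = c(2.5, 2.5), intensity = 2,
                             cluster_sigma_nm = 100, offspring_mean = 20)
  img <- simulate_point_field(spec, psf_sigma = 40, pixel_size = 25, seed = 2)
  curve <- ripley_analyze(intensity_field(img), radius_grid(25, 1000),
                          n_sim = 100, seed = 8)
  sel <- curve$radii_nm >= 100 & curve$radii_nm <= 200
  expect_true(all(curve$classification[sel] == "clustered"))
  # the exceedance spans a contiguous radius range covering 2 cluster sigma
  runs <- rle(curve$classification == "clustered")
  expect_gte(max(runs$lengths[runs$values]) * 25, 200)
})

test_that("argmax summary breaks ties toward the smaller radius", {
  curve <- structure(list(radii_nm = c(25, 50, 75, 100),
                          k_tilde = c(1, 5, 5, 2),
                          classification = rep("random", 4)),
                     class = "k_curve")
  s <- summarize_k(curve)
  expect_equal(s$argmax_radius, 50)
  expect_equal(s$argmax_value, 5)
})

test_that("group comparisons of argmax values match hand-computed ranks", {
  r <- compare_argmax_groups(list(a = c(1, 2, 3), b = c(10, 11, 12),
                                  c = c(20, 21, 22)))
  expect_equal(r$H, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  # identical groups: H = 0, p = 1 path without error
  same <- compare_argmax_groups(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_argmax_groups(list(a = 1:2, b = 1:3)), "at least 3")
  # clustered simulations separate from CSR ones
  set.seed(31)
  am <- function(kind, s) {
    spec <- if (kind == "thomas")
      point_process_spec("thomas", window_um = c(1.6, 1.6), intensity = 2,
                         cluster_sigma_nm = 100, offspring_mean = 20)
    else point_process_spec("csr", window_um = c(1.6, 1.6), intensity = 40)
    img <- simulate_point_field(spec, psf_sigma = 0, pixel_size = 25, seed = s)
    ripley_analyze(intensity_field(img, quantize_8bit = FALSE),
                   radius_grid(25, 400), n_sim = 100,
                   seed = split_seed(s, 3))$argmax_value
  }
  g1 <- vapply(1:7, am, numeric(1), kind = "thomas")
  g2 <- vapply(1:7, am, numeric(1), kind = "csr")
  expect_lt(compare_argmax_groups(list(clustered = g1, csr = g2))$p_value,
            0.05)
})

test_that("Besag correction reduces the edge bias of K under CSR", {
  # raw-K bias against the analytic CSR value at the largest radius
  bias_c <- bias_u <- numeric(12)
  for (s in 1:12) {
    img <- simulate_point_field(point_process_spec("csr",
             window_um = c(1.6, 1.6), intensity = 100), psf_sigma = 0,
             pixel_size = 25, seed = 300 + s)
    f <- intensity_field(img, quantize_8bit = FALSE)
    g <- radius_grid(25, 400)
    bias_c[s] <- intensity_k_raw(f, g)[16] - pi * 400^2
    bias_u[s] <- intensity_k_raw(f, g, edge_correction = FALSE)[16] -
      pi * 400^2
  }
  expect_lt(abs(mean(bias_c)), abs(mean(bias_u)))
})
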