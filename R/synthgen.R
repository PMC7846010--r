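#' Blinking emitter field
#'
#' Describes a set of point emitters with per-frame Bernoulli on-switching,
#' the raw material for simulated fluctuation stacks.
#'
#' @param positions_nm two-column matrix of emitter coordinates in nm.
#' @param brightness expected photons per frame emitted by an "on" emitter.
#' @param on_probability per-frame probability that an emitter is on.
#' @param window_nm c(width, height) of the imaged window in nm.
#' @return an object of class `emitter_field`.
#' @export
emitter_field <- function(positions_nm, brightness = 500, on_probability = 1,
                          window_nm = c(2000, 2000)) {
  positions_nm <- matrix(as.numeric(positions_nm), ncol = 2)
  stopifnot(brightness > 0, on_probability >= 0, on_probability <= 1,
            length(window_nm) == 2, all(window_nm > 0))
  if (nrow(positions_nm) > 0 &&
      (any(positions_nm < 0) || any(positions_nm[, 1] > window_nm[1]) ||
       any(positions_nm[, 2] > window_nm[2])))
    stop("emitter positions must lie inside the window")
  structure(list(positions_nm = positions_nm, brightness = brightness,
                 on_probability = on_probability, window_nm = window_nm),
            class = "emitter_field")
}

# Integrated Gaussian PSF rendering: each emitter deposits `amp` photons with
# exact per-pixel integrals (separable erf), so total photons are conserved
# whenever the PSF lies fully inside the window.
render_gaussians <- function(pos_nm, amps, psf_sigma, pixel_size, dim_px) {
  img <- matrix(0, nrow = dim_px[2], ncol = dim_px[1]) # rows = y
  if (length(amps) == 1) amps <- rep(amps, nrow(pos_nm))
  if (nrow(pos_nm) == 0) return(img)
  if (psf_sigma == 0) { # point-mass rasterization: histogram of positions
    ix <- pmin(pmax(floor(pos_nm[, 1] / pixel_size), 0), dim_px[1] - 1) + 1
    iy <- pmin(pmax(floor(pos_nm[, 2] / pixel_size), 0), dim_px[2] - 1) + 1
    for (i in seq_along(ix)) img[iy[i], ix[i]] <- img[iy[i], ix[i]] + amps[i]
    return(img)
  }
  half <- ceiling(4 * psf_sigma / pixel_size) + 1
  for (i in seq_len(nrow(pos_nm))) {
    cx <- pos_nm[i, 1] / pixel_size - 0.5 # pixel-centre coordinates, 0-based
    cy <- pos_nm[i, 2] / pixel_size - 0.5
    x0 <- max(0, floor(cx) - half); x1 <- min(dim_px[1] - 1, ceiling(cx) + half)
    y0 <- max(0, floor(cy) - half); y1 <- min(dim_px[2] - 1, ceiling(cy) + half)
    if (x1 < x0 || y1 < y0) next
    xs <- x0:x1; ys <- y0:y1
    s <- psf_sigma / pixel_size
    fx <- pnorm(xs + 0.5, cx, s) - pnorm(xs - 0.5, cx, s)
    fy <- pnorm(ys + 0.5, cy, s) - pnorm(ys - 0.5, cy, s)
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amps[i] * (fy %o% fx)
  }
  img
}

#' Simulate a temporal stack of a blinking emitter field
#'
#' Renders `n_frames` diffraction-limited frames of the field: each frame is
#' the sum of integrated Gaussian PSFs of the emitters that are on in that
#' frame, plus Poisson shot noise and additive Gaussian read noise.
#'
#' @param field an [emitter_field()].
#' @param n_frames number of frames (>= 2).
#' @param psf_sigma PSF standard deviation in nm (>= pixel_size / 2).
#' @param pixel_size pixel size in nm.
#' @param shot_noise logical; apply Poisson shot noise.
#' @param read_noise_sd Gaussian read noise SD in counts (0 disables).
#' @param bleach_rate optional per-frame exponential decay rate of the
#'   on-probability (0 = no bleaching).
#' @param on_correlation lag-1 autocorrelation of the on/off state (two-state
#'   Markov switching with the stationary on-probability of the field);
#'   0 gives frame-independent switching. Fluorophore on-times spanning
#'   several frames are what a lag-1 temporal cumulant detects.
#' @param seed integer seed; identical seeds give identical stacks.
#' @return an `image_stack` (list of frames plus pixel size metadata).
#' @export
simulate_blinking_stack <- function(field, n_frames = 100, psf_sigma = 120,
                                    pixel_size = 100, shot_noise = TRUE,
                                    read_noise_sd = 1, bleach_rate = 0,
                                    on_correlation = 0.5, seed = 1) {
  stopifnot(inherits(field, "emitter_field"), n_frames >= 2)
  if (psf_sigma <= 0 || pixel_size <= 0)
    stop("psf_sigma and pixel_size must be positive")
  if (psf_sigma < pixel_size / 2)
    stop("psf_sigma must be at least half the pixel size")
  stopifnot(on_correlation >= 0, on_correlation < 1)
  set.seed(seed)
  dim_px <- ceiling(field$window_nm / pixel_size)
  n_em <- nrow(field$positions_nm)
  frames <- vector("list", n_frames)
  state <- if (n_em) runif(n_em) < field$on_probability else logical(0)
  for (t in seq_len(n_frames)) {
    p_on <- field$on_probability * exp(-bleach_rate * (t - 1))
    if (t > 1 && n_em) {
      # Markov switching: stay-on / turn-on probabilities chosen so the
      # stationary on-probability is p_on and the lag-1 autocorrelation is
      # on_correlation
      q_on <- p_on + (1 - p_on) * on_correlation
      q_off <- p_on * (1 - on_correlation)
      u <- runif(n_em)
      state <- ifelse(state, u < q_on, u < q_off)
    }
    on <- state
    img <- render_gaussians(field$positions_nm[on, , drop = FALSE],
                            field$brightness, psf_sigma, pixel_size, dim_px)
    if (shot_noise) img[] <- rpois(length(img), img)
    if (read_noise_sd > 0) img <- img + rnorm(length(img), 0, read_noise_sd)
    frames[[t]] <- img
  }
  image_stack(frames, pixel_size = pixel_size,
              provenance = list(seed = seed, psf_sigma = psf_sigma,
                                field = field, bleach_rate = bleach_rate))
}

#' Membrane model for two-layer simulations
#'
#' A smooth membrane centerline running along x, displaced by a stationary
#' Gaussian-process deformation (squared-exponential kernel) to emulate the
#' stretching and folding seen in apical-membrane images, with two
#' fluorescent layers at signed normal offsets from the centerline
#' (negative = toward the cytoplasm, i.e. smaller y).
#'
#' @param length_um membrane-axis extent (x) in um.
#' @param height_um perpendicular extent (y) in um.
#' @param layer_offsets_nm length-2 signed normal offsets in nm; the first
#'   layer is the reference layer.
#' @param deformation_amplitude_nm SD of the centerline displacement in nm.
#' @param deformation_corr_length_nm correlation length of the displacement.
#' @param emitter_density_per_um emitters per um of membrane per layer.
#' @param brightness photons per emitter.
#' @param layer_thickness_nm SD of emitter scatter along the membrane normal
#'   about each layer line: finite layer thickness plus the localization
#'   scatter of a super-resolved reconstruction.
#' @return an object of class `membrane_model`.
#' @export
membrane_model <- function(length_um = 10, height_um = 5,
                           layer_offsets_nm = c(0, -26),
                           deformation_amplitude_nm = 200,
                           deformation_corr_length_nm = 1000,
                           emitter_density_per_um = 150,
                           brightness = 300,
                           layer_thickness_nm = 25) {
  stopifnot(length(layer_offsets_nm) == 2,
            deformation_corr_length_nm > 0,
            deformation_amplitude_nm >= 0,
            emitter_density_per_um > 0, brightness > 0)
  structure(list(length_um = length_um, height_um = height_um,
                 layer_offsets_nm = layer_offsets_nm,
                 deformation_amplitude_nm = deformation_amplitude_nm,
                 deformation_corr_length_nm = deformation_corr_length_nm,
                 emitter_density_per_um = emitter_density_per_um,
                 brightness = brightness,
                 layer_thickness_nm = layer_thickness_nm),
            class = "membrane_model")
}

# Sample a squared-exponential Gaussian process on grid x (nm).
gp_sample <- function(x, amplitude, corr_length) {
  if (amplitude == 0) return(numeric(length(x)))
  K <- amplitude^2 * exp(-0.5 * (outer(x, x, "-") / corr_length)^2)
  L <- chol(K + diag(1e-8 * amplitude^2, length(x)))
  as.numeric(crossprod(L, rnorm(length(x))))
}

#' Simulate a two-layer membrane image pair
#'
#' Places emitters on a deformed membrane centerline at two signed normal
#' offsets and renders one image per layer (channel) on a shared pixel grid.
#' Image rows are ordered cytoplasm (low y) to lumen (high y); the ground
#' truth (centerline, offsets, parameters) travels in the `ground_truth`
#' attribute of each image.
#'
#' @param model a [membrane_model()].
#' @param psf_sigma rendering PSF sigma in nm.
#' @param pixel_size pixel size in nm.
#' @param shot_noise logical; apply Poisson noise to the rendered channels.
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param shared_emitters use the same emitter positions (along the membrane
#'   and in normal scatter) for both layers, so equal offsets give pixelwise
#'   identical noiseless channels; by default each layer is labeled
#'   independently.
#' @param seed integer seed.
#' @return list with `ref` and `test` super-resolved images
#'   ([super_res_image]) sharing geometry.
#' @export
simulate_membrane_pair <- function(model, psf_sigma = 40, pixel_size = 25,
                                   shot_noise = TRUE, read_noise_sd = 0,
                                   shared_emitters = FALSE, seed = 1) {
  stopifnot(inherits(model, "membrane_model"))
  if (psf_sigma <= 0 || pixel_size <= 0)
    stop("psf_sigma and pixel_size must be positive")
  set.seed(seed)
  Wnm <- model$length_um * 1000; Hnm <- model$height_um * 1000
  dim_px <- c(ceiling(Wnm / pixel_size), ceiling(Hnm / pixel_size))
  xs <- (seq_len(dim_px[1]) - 0.5) * pixel_size
  centerline <- Hnm / 2 + gp_sample(xs, model$deformation_amplitude_nm,
                                    model$deformation_corr_length_nm)
  margin <- max(abs(model$layer_offsets_nm)) + 4 * psf_sigma +
    4 * model$layer_thickness_nm
  if (any(centerline < margin) || any(centerline > Hnm - margin))
    stop("window too small to contain the deformed membrane")
  slope <- c(diff(centerline[1:2]), diff(centerline)) / pixel_size
  out <- vector("list", 2)
  n_shared <- rpois(1, model$emitter_density_per_um * model$length_um)
  ex_shared <- runif(n_shared, 0, Wnm)
  scatter_shared <- rnorm(n_shared, 0, model$layer_thickness_nm)
  for (l in 1:2) {
    if (shared_emitters) {
      n_em <- n_shared; ex <- ex_shared; scatter <- scatter_shared
    } else {
      n_em <- rpois(1, model$emitter_density_per_um * model$length_um)
      ex <- runif(n_em, 0, Wnm)
      scatter <- rnorm(n_em, 0, model$layer_thickness_nm)
    }
    ey <- approx(xs, centerline, xout = ex, rule = 2)$y
    sl <- approx(xs, slope, xout = ex, rule = 2)$y
    nrm <- 1 / sqrt(1 + sl^2)
    off <- model$layer_offsets_nm[l] + scatter
    pos <- cbind(ex - off * sl * nrm, ey + off * nrm)
    img <- render_gaussians(pos, model$brightness, psf_sigma, pixel_size, dim_px)
    if (shot_noise) img[] <- rpois(length(img), img)
    if (read_noise_sd > 0) img <- img + rnorm(length(img), 0, read_noise_sd)
    out[[l]] <- super_res_image(img, pixel_size = pixel_size,
                                channel = c("ref", "test")[l],
                                provenance = list(seed = seed, layer = l,
                                                  psf_sigma = psf_sigma))
    attr(out[[l]], "ground_truth") <- list(
      centerline_nm = centerline, x_nm = xs,
      layer_offsets_nm = model$layer_offsets_nm, model = model)
  }
  names(out) <- c("ref", "test")
  out
}

#' Spatial point-process specification
#'
#' @param kind one of `"csr"`, `"thomas"`, `"hardcore"`.
#' @param window_um c(width, height) of the window in um.
#' @param intensity points per um^2 (for `"thomas"`: parent cluster density).
#' @param cluster_sigma_nm Gaussian offspring scatter (thomas only).
#' @param offspring_mean mean offspring per parent (thomas only).
#' @param inhibition_radius_nm hard-core distance (hardcore only).
#' @return an object of class `point_process_spec`.
#' @export
point_process_spec <- function(kind = c("csr", "thomas", "hardcore"),
                               window_um = c(10, 10), intensity = 10,
                               cluster_sigma_nm = 100, offspring_mean = 20,
                               inhibition_radius_nm = 200) {
  kind <- match.arg(kind)
  stopifnot(intensity > 0, all(window_um > 0))
  if (kind == "thomas") stopifnot(cluster_sigma_nm > 0, offspring_mean > 0)
  if (kind == "hardcore") stopifnot(inhibition_radius_nm > 0)
  structure(list(kind = kind, window_um = window_um, intensity = intensity,
                 cluster_sigma_nm = cluster_sigma_nm,
                 offspring_mean = offspring_mean,
                 inhibition_radius_nm = inhibition_radius_nm),
            class = "point_process_spec")
}

# Realize the point pattern of a spec (positions in nm). Thomas parents are
# drawn on a window extended by 4 cluster sigmas to avoid cluster-edge bias;
# hardcore uses Matern-II thinning (uniform marks, keep if no smaller-marked
# point within the inhibition radius).
sample_points <- function(spec) {
  Wnm <- spec$window_um[1] * 1000; Hnm <- spec$window_um[2] * 1000
  A_um2 <- prod(spec$window_um)
  if (spec$kind == "csr") {
    n <- rpois(1, spec$intensity * A_um2)
    return(cbind(runif(n, 0, Wnm), runif(n, 0, Hnm)))
  }
  if (spec$kind == "thomas") {
    ext <- 4 * spec$cluster_sigma_nm
    A_ext <- (Wnm + 2 * ext) * (Hnm + 2 * ext) / 1e6
    n_par <- rpois(1, spec$intensity * A_ext)
    px <- runif(n_par, -ext, Wnm + ext); py <- runif(n_par, -ext, Hnm + ext)
    n_off <- rpois(n_par, spec$offspring_mean)
    x <- rep(px, n_off) + rnorm(sum(n_off), 0, spec$cluster_sigma_nm)
    y <- rep(py, n_off) + rnorm(sum(n_off), 0, spec$cluster_sigma_nm)
    keep <- x >= 0 & x <= Wnm & y >= 0 & y <= Hnm
    return(cbind(x[keep], y[keep]))
  }
  # hardcore (Matern II)
  n <- rpois(1, spec$intensity * A_um2)
  x <- runif(n, 0, Wnm); y <- runif(n, 0, Hnm); mark <- runif(n)
  keep <- rep(TRUE, n)
  if (n > 1) {
    d <- as.matrix(dist(cbind(x, y)))
    for (i in seq_len(n)) {
      rival <- d[i, ] < spec$inhibition_radius_nm & mark < mark[i]
      rival[i] <- FALSE
      if (any(rival)) keep[i] <- FALSE
    }
  }
  cbind(x[keep], y[keep])
}

#' Simulate a rasterized point-field intensity image
#'
#' Realizes the point pattern of `spec` and renders a Gaussian spot per point
#' on a pixel grid. The realized point list is kept as ground truth in the
#' `ground_truth` attribute.
#'
#' @param spec a [point_process_spec()].
#' @param psf_sigma spot sigma in nm; 0 rasterizes each point as a
#'   single-pixel mass (pure point-pattern histogram).
#' @param pixel_size pixel size in nm.
#' @param amplitude photons per point.
#' @param seed integer seed.
#' @return a [super_res_image].
#' @export
simulate_point_field <- function(spec, psf_sigma = 40, pixel_size = 25,
                                 amplitude = 100, seed = 1) {
  stopifnot(inherits(spec, "point_process_spec"))
  if (psf_sigma < 0 || pixel_size <= 0)
    stop("psf_sigma must be nonnegative and pixel_size positive")
  set.seed(seed)
  expected <- spec$intensity * prod(spec$window_um) *
    (if (spec$kind == "thomas") spec$offspring_mean else 1)
  if (expected < 10)
    warning("expected point count below 10; spatial statistics unreliable")
  pts <- sample_points(spec)
  dim_px <- ceiling(spec$window_um * 1000 / pixel_size)
  img <- render_gaussians(pts, amplitude, psf_sigma, pixel_size, dim_px)
  out <- super_res_image(img, pixel_size = pixel_size, channel = spec$kind,
                         provenance = list(seed = seed, spec = spec,
                                           psf_sigma = psf_sigma))
  attr(out, "ground_truth") <- list(points_nm = pts, spec = spec)
  out
}
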