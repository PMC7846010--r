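#' Intensity field for spatial statistics
#'
#' Wraps a nonnegative weight image (typically an 8-bit grayscale export of
#' one super-resolved channel) with its pixel size and an optional binary
#' analysis mask. Pixel intensities are used as weights directly -- no spot
#' detection -- which keeps overlapping events at high densities countable.
#'
#' @param x a [super_res_image] or numeric matrix of weights.
#' @param pixel_size pixel size in nm (taken from `x` if an image).
#' @param mask optional logical matrix; default all `TRUE`.
#' @param quantize_8bit scale to integer 0..255 by the image maximum, as in
#'   8-bit TIFF export of the analysis ROIs.
#' @return an object of class `intensity_field`.
#' @export
intensity_field <- function(x, pixel_size = NULL, mask = NULL,
                            quantize_8bit = TRUE) {
  if (inherits(x, "super_res_image")) {
    if (is.null(pixel_size)) pixel_size <- x$pixel_size
    x <- x$values
  }
  stopifnot(is.matrix(x), !is.null(pixel_size), pixel_size > 0)
  if (any(x < 0)) stop("intensity weights must be nonnegative")
  if (quantize_8bit) {
    mx <- max(x)
    x <- if (mx > 0) round(x / mx * 255) else x
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  stopifnot(identical(dim(mask), dim(x)))
  if (sum(x[mask]) <= 0) stop("total masked weight must be positive")
  structure(list(values = x, pixel_size = pixel_size, mask = mask,
                 full_rect = all(mask)),
            class = "intensity_field")
}

#' Radius grid for K curves
#'
#' Uniform radii `step, 2*step, ..., rmax` in nm (default 25 nm steps up to
#' 2.5 um).
#'
#' @param step_nm radius step in nm.
#' @param rmax_nm largest radius in nm.
#' @return an object of class `radius_grid`.
#' @export
radius_grid <- function(step_nm = 25, rmax_nm = 2500) {
  stopifnot(step_nm > 0, rmax_nm >= step_nm)
  radii <- seq(step_nm, rmax_nm, by = step_nm)
  structure(list(radii_nm = radii, step_nm = step_nm), class = "radius_grid")
}

check_grid <- function(field, grid) {
  short <- min(dim(field$values)) * field$pixel_size
  if (max(grid$radii_nm) > short / 2)
    stop("max radius exceeds half the shorter window side")
}

#' Besag edge-correction weights
#'
#' Per-pixel correction factor (area of the full disc over the area of the
#' disc clipped to the analysis window) at one radius: 1 for interior
#' pixels, 2 on a straight edge, 4 at a corner. For a full rectangular mask
#' the overlap is computed exactly on the continuous pixel-centre hull; for
#' general masks a discrete pixel-count ratio is used, and masked-out pixels
#' get `NA`.
#'
#' @param mask logical matrix defining the analysis window.
#' @param radius_px radius in pixel units.
#' @return numeric matrix of weights (>= 1), `NA` outside the mask.
#' @export
besag_edge_weights <- function(mask, radius_px) {
  stopifnot(is.matrix(mask), radius_px > 0)
  if (all(mask))
    return(besag_weights_rect_cpp(ncol(mask), nrow(mask), radius_px))
  idx <- which(mask, arr.ind = TRUE)
  r2 <- radius_px^2
  R <- floor(radius_px)
  offs <- expand.grid(dy = -R:R, dx = -R:R)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r2, ]
  n_full <- nrow(offs)
  w <- matrix(NA_real_, nrow(mask), ncol(mask))
  H <- nrow(mask); W <- ncol(mask)
  for (k in seq_len(nrow(idx))) {
    y <- idx[k, 1]; x <- idx[k, 2]
    yy <- y + offs$dy; xx <- x + offs$dx
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    inside <- sum(mask[cbind(yy[ok], xx[ok])])
    w[y, x] <- n_full / inside
  }
  w
}

# O(n^2) reference implementation: explicit pair sum over masked pixels.
# Kept deliberately independent of the FFT engine; used as the test oracle
# and as the fallback for non-rectangular masks.
k_brute_force <- function(field, grid, edge_correction = TRUE) {
  check_grid(field, grid)
  px <- field$pixel_size
  idx <- which(field$mask, arr.ind = TRUE)
  w <- field$values[idx]
  pos <- (idx - 0.5) * px # pixel centres in nm; cols: y, x
  d <- as.matrix(dist(pos))
  A <- sum(field$mask) * px^2
  SW <- sum(w)
  vapply(grid$radii_nm, function(r) {
    ew <- if (edge_correction) besag_edge_weights(field$mask, r / px)[idx]
          else rep(1, length(w))
    within <- d <= r
    diag(within) <- FALSE
    # sum_i w_i e_i sum_{j != i, d_ij <= r} w_j
    A * sum(w * ew * (within %*% w)) / SW^2
  }, numeric(1))
}

#' Intensity-weighted Ripley K curve
#'
#' Computes, for each radius r,
#' `K(r) = A * sum_{i != j} w_i w_j e_i(r) 1(d_ij <= r) / (sum w)^2`,
#' where the `w` are pixel intensities, `A` is the masked window area,
#' distances run between pixel centres, self-pairs are excluded, and
#' `e_i(r)` is the Besag edge weight ([besag_edge_weights()]). Under
#' complete spatial randomness K(r) is close to `pi r^2`. Full rectangular
#' windows use an exact FFT + edge-band engine; general masks fall back to
#' the explicit pair sum.
#'
#' @param field an [intensity_field()].
#' @param grid a [radius_grid()].
#' @param edge_correction apply Besag edge weights (default); `FALSE` leaves
#'   the raw biased estimator (useful for quantifying the edge bias).
#' @return numeric vector of K values in nm^2, one per radius.
#' @export
intensity_k_raw <- function(field, grid, edge_correction = TRUE) {
  stopifnot(inherits(field, "intensity_field"), inherits(grid, "radius_grid"))
  check_grid(field, grid)
  if (!field$full_rect) return(k_brute_force(field, grid, edge_correction))
  px <- field$pixel_size
  as.numeric(k_perm_engine(field$values, grid$radii_nm / px, 0L,
                           edge_correction)) * px^2
}

#' Permutation null for complete spatial randomness
#'
#' Randomly permutes the pixel intensities within the mask (preserving the
#' intensity histogram, destroying all spatial structure), recomputes the K
#' curve per permutation, and stores the per-radius null mean, SD and the
#' requested quantiles.
#'
#' @inheritParams intensity_k_raw
#' @param n_sim number of permutations (>= 100).
#' @param quantiles lower/upper envelope probabilities (default 1st/99th).
#' @param seed integer seed (mandatory for reproducible envelopes).
#' @return an object of class `csr_null` with per-radius `mean`, `sd`,
#'   `q_low`, `q_high` (raw K scale, nm^2).
#' @export
build_csr_null <- function(field, grid, n_sim = 200,
                           quantiles = c(0.01, 0.99), seed,
                           edge_correction = TRUE) {
  stopifnot(inherits(field, "intensity_field"), n_sim >= 100,
            length(quantiles) == 2, quantiles[1] > 0,
            quantiles[1] < quantiles[2], quantiles[2] < 1)
  if (missing(seed)) stop("a seed is required for the permutation null")
  check_grid(field, grid)
  if (sum(field$values[field$mask] > 0) < 2)
    stop("degenerate field: all weight concentrated in one pixel")
  set.seed(seed)
  px <- field$pixel_size
  if (field$full_rect) {
    km <- k_perm_engine(field$values, grid$radii_nm / px, as.integer(n_sim),
                        edge_correction) * px^2
    null_k <- km[-1, , drop = FALSE]
    obs <- km[1, ]
  } else {
    null_k <- matrix(0, n_sim, length(grid$radii_nm))
    f <- field
    for (s in seq_len(n_sim)) {
      f$values[f$mask] <- sample(field$values[field$mask])
      null_k[s, ] <- k_brute_force(f, grid, edge_correction)
    }
    obs <- k_brute_force(field, grid, edge_correction)
  }
  structure(list(radii_nm = grid$radii_nm,
                 mean = colMeans(null_k),
                 sd = apply(null_k, 2, sd),
                 q_low = apply(null_k, 2, quantile, probs = quantiles[1]),
                 q_high = apply(null_k, 2, quantile, probs = quantiles[2]),
                 n_sim = n_sim, quantiles = quantiles, seed = seed,
                 observed_k = obs),
            class = "csr_null")
}

#' Normalize a K curve against its CSR null
#'
#' `K~(r) = (K(r) - null mean(r)) / null SD(r)`: density-normalized and of
#' approximately unit variance under complete spatial randomness.
#'
#' @param k_raw K values in nm^2 (from [intensity_k_raw()]).
#' @param null a `csr_null` built on the same field and grid.
#' @return numeric vector of dimensionless K-tilde values.
#' @export
normalize_k <- function(k_raw, null) {
  stopifnot(inherits(null, "csr_null"), length(k_raw) == length(null$mean))
  bad <- which(null$sd == 0)
  if (length(bad))
    stop("null SD is zero at radius ", null$radii_nm[bad[1]], " nm")
  (k_raw - null$mean) / null$sd
}

#' Full K-tilde analysis of an intensity field
#'
#' Convenience wrapper: observed K, permutation null, normalization,
#' envelope classification and the argmax summary in one call (the null and
#' observed curves share one pass through the engine).
#'
#' @inheritParams build_csr_null
#' @return a `k_curve`: radii, raw K, K-tilde, normalized envelopes,
#'   per-radius classification (`clustered` / `random` / `dispersed`),
#'   argmax radius and value, and the underlying null.
#' @export
ripley_analyze <- function(field, grid = radius_grid(), n_sim = 200,
                           quantiles = c(0.01, 0.99), seed) {
  null <- build_csr_null(field, grid, n_sim = n_sim, quantiles = quantiles,
                         seed = seed)
  k_raw <- null$observed_k
  k_tilde <- normalize_k(k_raw, null)
  env_low <- (null$q_low - null$mean) / null$sd
  env_high <- (null$q_high - null$mean) / null$sd
  cls <- ifelse(k_tilde > env_high, "clustered",
                ifelse(k_tilde < env_low, "dispersed", "random"))
  am <- which.max(k_tilde) # ties break toward the smaller radius
  structure(list(radii_nm = grid$radii_nm, k_raw = k_raw, k_tilde = k_tilde,
                 env_low = env_low, env_high = env_high,
                 classification = cls,
                 argmax_radius = grid$radii_nm[am],
                 argmax_value = k_tilde[am],
                 null = null),
            class = "k_curve")
}

#' Summary statistics of a K curve
#'
#' @param curve a `k_curve` from [ripley_analyze()].
#' @return list with `argmax_radius` (nm), `argmax_value` and the per-radius
#'   `classification`.
#' @export
summarize_k <- function(curve) {
  stopifnot(inherits(curve, "k_curve"))
  am <- which.max(curve$k_tilde)
  list(argmax_radius = curve$radii_nm[am],
       argmax_value = curve$k_tilde[am],
       classification = curve$classification)
}

#' Compare argmax(K~) values across groups
#'
#' Kruskal-Wallis omnibus test (tie-corrected H) over labeled collections of
#' argmax values, followed by Dunn pairwise comparisons with Holm
#' adjustment.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @return list with `H`, `df`, `p_value` and a data frame of pairwise
#'   adjusted p values.
#' @export
compare_argmax_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("each group needs at least 3 values")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  if (length(unique(x)) == 1) {
    pairs <- t(combn(levels(g), 2))
    return(list(H = 0, df = nlevels(g) - 1, p_value = 1,
                pairwise = data.frame(group1 = pairs[, 1],
                                      group2 = pairs[, 2],
                                      p_adj = 1)))
  }
  kw <- kruskal.test(x, g)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value, pairwise = dunn_posthoc(x, g))
}
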