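#' Pipeline configuration
#'
#' Bundles the stage parameters of the full analysis with a single master
#' seed. Child seeds for the stochastic stages are derived with
#' [split_seed()] so stages are independently rerunnable.
#'
#' @param seed master integer seed.
#' @param pixel_size_nm super-resolved pixel size.
#' @param srrf list of reconstruction settings (ring radius 0.5,
#'   magnification 10, 8 axes, 100 frames).
#' @param ripley list of K-curve settings (25 nm steps, permutation count,
#'   envelope quantiles).
#' @param carpet list of carpet settings (ROI size in um, 25 nm columns,
#'   lag range, alignment peak floor, injected |offset| in nm).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, pixel_size_nm = 25,
                            srrf = list(ring_radius = 0.5, magnification = 10,
                                        axes_in_ring = 8, n_frames = 100),
                            ripley = list(dr_nm = 25, rmax_nm = 2500,
                                          n_sim = 200,
                                          quantiles = c(0.01, 0.99)),
                            carpet = list(roi_um = c(10, 5), dr_nm = 25,
                                          max_lag_nm = 1000,
                                          peak_floor = 0.05,
                                          offset_nm = 26)) {
  structure(list(seed = as.integer(seed), pixel_size_nm = pixel_size_nm,
                 srrf = srrf, ripley = ripley, carpet = carpet),
            class = "pipeline_config")
}

#' Derive a child seed for a pipeline stage
#'
#' Deterministic splitting rule `(seed * 1000003 + stage) mod (2^31 - 1)`
#' so each stochastic stage gets an independent, reproducible stream.
#'
#' @param seed master integer seed.
#' @param stage integer stage index.
#' @return integer child seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stage)) %% 2147483647 + 1)
}

#' Simulated inter-layer distance experiment
#'
#' Generates `n_carpets` two-channel membrane images whose test layer sits
#' at a known signed normal offset from the reference layer, extracts the
#' intensity carpets, aligns columns with the reference-channel pCF, and
#' collects the per-column pCCF distances into a [distance_distribution()].
#' Each carpet is one cellular replicate.
#'
#' @param n_carpets number of simulated ROIs/cells.
#' @param offset_nm injected signed normal offset of the test layer
#'   (negative = cytoplasm side).
#' @param model a [membrane_model()] template; its offsets are replaced by
#'   `c(0, offset_nm)`.
#' @param psf_sigma,pixel_size rendering settings in nm.
#' @param max_lag_nm pCF/pCCF search range.
#' @param seed master seed (one child seed per carpet).
#' @return a `distance_distribution`.
#' @export
layer_distance_experiment <- function(n_carpets = 30, offset_nm = -26,
                                      model = membrane_model(),
                                      psf_sigma = 40, pixel_size = 25,
                                      max_lag_nm = 500, seed = 1) {
  model$layer_offsets_nm <- c(0, offset_nm)
  refs <- vector("list", n_carpets)
  tests <- vector("list", n_carpets)
  for (i in seq_len(n_carpets)) {
    pair <- simulate_membrane_pair(model, psf_sigma = psf_sigma,
                                   pixel_size = pixel_size,
                                   seed = split_seed(seed, i))
    rid <- sprintf("cell%02d", i)
    rc <- extract_carpet(pair$ref, replicate_id = rid)
    tc <- extract_carpet(pair$test, replicate_id = rid)
    al <- align_carpet(rc, max_lag_nm = max_lag_nm)
    refs[[i]] <- al$carpet
    tests[[i]] <- apply_alignment(tc, al)
  }
  distance_distribution(refs, tests, max_lag_nm = max_lag_nm)
}

#' Simulated cluster-scale recovery experiment
#'
#' Generates seeded clustered (Thomas) intensity fields, runs the full
#' K-tilde analysis per field and returns the argmax radius and
#' classification summary of each replicate.
#'
#' @param n_fields number of seeded replicates.
#' @param spec a [point_process_spec()] (default: Thomas parents at
#'   2 per um^2, mean 20 offspring, 100 nm cluster sigma in a 10 x 10 um
#'   window).
#' @param psf_sigma,pixel_size rendering settings in nm.
#' @param grid a [radius_grid()].
#' @param n_sim permutation count for each null.
#' @param seed master seed.
#' @return data frame with one row per field: `argmax_nm`, `argmax_value`,
#'   and the fraction of radii classified clustered.
#' @export
cluster_argmax_experiment <- function(n_fields = 50,
                                      spec = point_process_spec(
                                        "thomas", window_um = c(10, 10),
                                        intensity = 2, cluster_sigma_nm = 100,
                                        offspring_mean = 20),
                                      psf_sigma = 40, pixel_size = 25,
                                      grid = radius_grid(25, 1000),
                                      n_sim = 200, seed = 1) {
  out <- data.frame(field = seq_len(n_fields), argmax_nm = NA_real_,
                    argmax_value = NA_real_, frac_clustered = NA_real_)
  for (i in seq_len(n_fields)) {
    s <- split_seed(seed, i)
    img <- simulate_point_field(spec, psf_sigma = psf_sigma,
                                pixel_size = pixel_size, seed = s)
    field <- intensity_field(img)
    curve <- ripley_analyze(field, grid, n_sim = n_sim,
                            seed = split_seed(s, 1))
    out$argmax_nm[i] <- curve$argmax_radius
    out$argmax_value[i] <- curve$argmax_value
    out$frac_clustered[i] <- mean(curve$classification == "clustered")
  }
  out
}

#' End-to-end synthetic demonstration of the layered-toxin analysis
#'
#' Simulates a wild-type-like condition (test layer on the cytoplasm side of
#' the reference layer) and a mutant-like condition (offset inverted), runs
#' carpet alignment and distance estimation on both, and analyzes a
#' clustered versus a random point field with the K-tilde statistic. The
#' report reproduces the qualitative contrasts of the layered-toxin study:
#' sign inversion of the mean inter-layer distance and clustered versus
#' random classification.
#'
#' @param config a [pipeline_config()].
#' @param n_carpets carpets per condition.
#' @param out_dir optional directory for artifacts (channel TIFFs, distance
#'   CSVs, K-curve CSV, JSON report).
#' @return list with both `distance_distribution`s, both `k_curve`s and a
#'   `summary` list.
#' @export
run_demo_synergy_layers <- function(config = pipeline_config(),
                                    n_carpets = 8, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  off <- abs(config$carpet$offset_nm)
  wt <- layer_distance_experiment(n_carpets, offset_nm = -off,
                                  pixel_size = config$pixel_size_nm,
                                  max_lag_nm = config$carpet$max_lag_nm,
                                  seed = split_seed(config$seed, 101))
  mut <- layer_distance_experiment(n_carpets, offset_nm = off,
                                   pixel_size = config$pixel_size_nm,
                                   max_lag_nm = config$carpet$max_lag_nm,
                                   seed = split_seed(config$seed, 202))
  small_win <- c(2.5, 2.5)
  grid <- radius_grid(config$ripley$dr_nm,
                      min(config$ripley$rmax_nm,
                          small_win[1] * 1000 / 2 - config$ripley$dr_nm))
  # point fields are rasterized as single-pixel masses so the CSR condition
  # sits inside the permutation null's hypothesis class (pixel-exchangeable)
  thom <- simulate_point_field(
    point_process_spec("thomas", window_um = small_win, intensity = 2,
                       cluster_sigma_nm = 100, offspring_mean = 20),
    psf_sigma = 0,
    pixel_size = config$pixel_size_nm, seed = split_seed(config$seed, 303))
  csr <- simulate_point_field(
    point_process_spec("csr", window_um = small_win, intensity = 40),
    psf_sigma = 0,
    pixel_size = config$pixel_size_nm, seed = split_seed(config$seed, 404))
  k_thom <- ripley_analyze(intensity_field(thom, quantize_8bit = FALSE), grid,
                           n_sim = config$ripley$n_sim,
                           quantiles = config$ripley$quantiles,
                           seed = split_seed(config$seed, 505))
  k_csr <- ripley_analyze(intensity_field(csr, quantize_8bit = FALSE), grid,
                          n_sim = config$ripley$n_sim,
                          quantiles = config$ripley$quantiles,
                          seed = split_seed(config$seed, 606))
  summary <- list(
    wt_mean_nm = wt$mean_nm, wt_sem_nm = wt$sem_nm,
    mut_mean_nm = mut$mean_nm, mut_sem_nm = mut$sem_nm,
    sign_inverted = sign(wt$mean_nm) == -sign(mut$mean_nm),
    thomas_argmax_nm = k_thom$argmax_radius,
    thomas_frac_clustered = mean(k_thom$classification == "clustered"),
    csr_frac_random = mean(k_csr$classification == "random"),
    seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_image(thom, file.path(out_dir, "thomas_field.tif"), bits = 8)
    write_k_curve(k_thom, file.path(out_dir, "k_thomas.csv"))
    write_k_curve(k_csr, file.path(out_dir, "k_csr.csv"))
    write_distances(wt, file.path(out_dir, "distances_wt.csv"),
                    file.path(out_dir, "distances_wt.json"))
    write_distances(mut, file.path(out_dir, "distances_mut.csv"),
                    file.path(out_dir, "distances_mut.json"))
    jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(wt = wt, mutant = mut, k_thomas = k_thom, k_csr = k_csr,
       summary = summary)
}
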