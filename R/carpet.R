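#' Extract an intensity carpet from a membrane ROI
#'
#' Rotates the image (bicubic interpolation) so the membrane axis is
#' horizontal, crops the ROI, and bins the x axis into columns of
#' `column_width_nm` (averaging pixels within a bin). Each column is a
#' membrane-perpendicular line profile; rows run cytoplasm (low y) to lumen
#' (high y).
#'
#' @param image a [super_res_image].
#' @param angle_deg rotation applied before extraction (degrees,
#'   counter-clockwise).
#' @param roi_um optional c(x, y, width, height) ROI in um after rotation;
#'   default uses the full image.
#' @param column_width_nm lateral bin width (default 25 nm).
#' @param replicate_id cell/replicate identifier carried through to distance
#'   summaries.
#' @return an `intensity_carpet`: `columns` matrix (profile samples x
#'   columns), `y_step_nm`, `column_width_nm`, `reference_index`, labels.
#' @export
extract_carpet <- function(image, angle_deg = 0, roi_um = NULL,
                           column_width_nm = 25, replicate_id = "r1") {
  stopifnot(inherits(image, "super_res_image"), column_width_nm > 0)
  vals <- image$values
  px <- image$pixel_size
  if (angle_deg != 0) vals <- rotate_bicubic_cpp(vals, angle_deg)
  if (!is.null(roi_um)) {
    stopifnot(length(roi_um) == 4)
    x0 <- floor(roi_um[1] * 1000 / px) + 1
    y0 <- floor(roi_um[2] * 1000 / px) + 1
    nx <- round(roi_um[3] * 1000 / px)
    ny <- round(roi_um[4] * 1000 / px)
    if (x0 < 1 || y0 < 1 || x0 + nx - 1 > ncol(vals) ||
        y0 + ny - 1 > nrow(vals))
      stop("ROI falls outside the image")
    vals <- vals[y0:(y0 + ny - 1), x0:(x0 + nx - 1)]
  }
  if (anyNA(vals))
    stop("rotation placed part of the ROI outside the image")
  bin <- max(1L, round(column_width_nm / px))
  ncols <- floor(ncol(vals) / bin)
  if (ncols < 1) stop("ROI too narrow for the requested column width")
  cols <- vapply(seq_len(ncols), function(j) {
    rowMeans(vals[, ((j - 1) * bin + 1):(j * bin), drop = FALSE])
  }, numeric(nrow(vals)))
  structure(list(columns = cols, y_step_nm = px,
                 column_width_nm = bin * px, reference_index = 1L,
                 channel = image$channel, replicate_id = replicate_id,
                 angle_deg = angle_deg),
            class = "intensity_carpet")
}

# quadratic sub-bin refinement of a discrete argmax
refine_argmax <- function(vals, lags) {
  i <- which.max(vals)
  if (i == 1 || i == length(vals)) return(lags[i])
  y0 <- vals[i - 1]; y1 <- vals[i]; y2 <- vals[i + 1]
  den <- y0 - 2 * y1 + y2
  if (den >= 0) return(lags[i]) # flat or degenerate peak
  lags[i] + 0.5 * (y0 - y2) / den * (lags[2] - lags[1])
}

pair_correlation <- function(f1, f2, max_lag) {
  n <- length(f1)
  if (length(f2) != n) stop("profiles must have equal length")
  if (mean(f1) == 0 || mean(f2) == 0)
    stop("pair correlation undefined for a zero-mean profile")
  max_lag <- min(max_lag, n - 2)
  lags <- -max_lag:max_lag
  vals <- vapply(lags, function(k) {
    if (k >= 0) { a <- f1[1:(n - k)]; b <- f2[(1 + k):n] }
    else        { a <- f1[(1 - k):n]; b <- f2[1:(n + k)] }
    m1 <- mean(a); m2 <- mean(b)
    if (m1 == 0 || m2 == 0) return(NA_real_)
    mean(a * b) / (m1 * m2) - 1
  }, numeric(1))
  structure(vals, lags = lags)
}

#' Paired correlation function of two line profiles
#'
#' `pCF(dy) = <F1(y) F2(y + dy)> / (<F1> <F2>) - 1`, averaged over the
#' overlapping samples only (no wrap-around), over a symmetric lag range.
#' The argmax over dy identifies the shift between the local maxima of the
#' two profiles; a constant profile gives pCF identically 0.
#'
#' @param profile_ref,profile_other equal-length line profiles with nonzero
#'   mean.
#' @param max_lag largest |lag| in samples.
#' @return numeric vector of correlation values with a `lags` attribute.
#' @export
pcf <- function(profile_ref, profile_other, max_lag = 40) {
  pair_correlation(profile_ref, profile_other, max_lag)
}

#' Paired cross-correlation function between two channels
#'
#' Same estimator as [pcf()] applied across channels of one aligned column:
#' `pCCF(dy) = <F1(y,0) F2(y+dy)> / (<F1><F2>) - 1`. The (sub-bin refined)
#' argmax is the signed inter-layer distance: negative lags point toward
#' the cytoplasm end of the profile.
#'
#' @param profile_1 reference-channel profile.
#' @param profile_2 second-channel profile from the same column.
#' @param max_lag largest |lag| in samples.
#' @return numeric vector of correlation values with a `lags` attribute.
#' @export
pccf <- function(profile_1, profile_2, max_lag = 40) {
  pair_correlation(profile_1, profile_2, max_lag)
}

#' Align carpet columns by the paired correlation function
#'
#' For every column, the shift relative to the reference column is the
#' sub-bin refined argmax of its pCF with the reference; each column is then
#' translated by minus that shift (linear interpolation, mean padding).
#' Columns whose pCF maximum falls below `peak_floor` are flagged
#' unalignable and excluded.
#'
#' @param carpet an `intensity_carpet`.
#' @param max_lag_nm largest shift searched (default 1000 nm).
#' @param peak_floor minimum pCF peak height for a column to count as
#'   alignable.
#' @return list with `shifts_nm` (NA for excluded columns), the aligned
#'   `carpet` (excluded columns dropped), `kept` (column indices) and
#'   `n_excluded`.
#' @export
align_carpet <- function(carpet, max_lag_nm = 1000, peak_floor = 0.05) {
  stopifnot(inherits(carpet, "intensity_carpet"))
  ref <- carpet$columns[, carpet$reference_index]
  max_lag <- max(1L, round(max_lag_nm / carpet$y_step_nm))
  nc <- ncol(carpet$columns)
  shifts <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    pc <- pair_correlation(ref, carpet$columns[, j], max_lag)
    if (all(is.na(pc)) || max(pc, na.rm = TRUE) < peak_floor) next
    shifts[j] <- refine_argmax(ifelse(is.na(pc), -Inf, pc), attr(pc, "lags"))
  }
  shifts[carpet$reference_index] <- 0
  kept <- which(!is.na(shifts))
  aligned <- carpet
  aligned$columns <- vapply(kept, function(j) {
    shift_profile(carpet$columns[, j], shifts[j])
  }, numeric(nrow(carpet$columns)))
  aligned$kept <- kept
  list(shifts_nm = shifts * carpet$y_step_nm, carpet = aligned,
       kept = kept, n_excluded = nc - length(kept))
}

# translate a profile by -shift samples (sample at y + shift), mean padding
shift_profile <- function(f, shift) {
  n <- length(f)
  out <- approx(seq_len(n), f, xout = seq_len(n) + shift, rule = 1)$y
  out[is.na(out)] <- mean(f)
  out
}

#' Apply reference-channel alignment shifts to a second-channel carpet
#'
#' @param carpet an `intensity_carpet` sharing geometry with the carpet the
#'   shifts were estimated from.
#' @param alignment result of [align_carpet()] on the reference channel.
#' @return the shifted carpet restricted to the alignable columns.
#' @export
apply_alignment <- function(carpet, alignment) {
  stopifnot(inherits(carpet, "intensity_carpet"))
  shifts <- alignment$shifts_nm / carpet$y_step_nm
  out <- carpet
  out$columns <- vapply(alignment$kept, function(j) {
    shift_profile(carpet$columns[, j], shifts[j])
  }, numeric(nrow(carpet$columns)))
  out$kept <- alignment$kept
  out
}

#' Average aligned profile across cellular replicates
#'
#' Pools all columns within each replicate into a per-replicate mean
#' profile, then returns the across-replicate mean and SEM per sample: the
#' SEM is estimated at the level of cellular replicates, not columns.
#'
#' @param carpets list of aligned `intensity_carpet`s (one or more per
#'   replicate; `replicate_id` labels the replicate).
#' @return list with `y_nm`, `mean`, `sem` (NA with a warning if only one
#'   replicate) and `n_replicates`.
#' @export
average_aligned_profile <- function(carpets) {
  stopifnot(length(carpets) >= 1)
  reps <- vapply(carpets, function(cc) cc$replicate_id, character(1))
  per_rep <- lapply(split(carpets, reps), function(group) {
    rowMeans(do.call(cbind, lapply(group, function(cc) rowMeans(cc$columns))))
  })
  m <- do.call(cbind, per_rep)
  nrep <- ncol(m)
  sem <- if (nrep >= 2) apply(m, 1, sd) / sqrt(nrep) else {
    warning("single replicate: SEM undefined")
    rep(NA_real_, nrow(m))
  }
  list(y_nm = (seq_len(nrow(m)) - 0.5) * carpets[[1]]$y_step_nm,
       mean = rowMeans(m), sem = sem, n_replicates = nrep)
}

# density-mode detection: local maxima with prominence >= 10% of the peak
find_modes <- function(x, prominence_frac = 0.1) {
  if (length(unique(x)) < 2)
    return(data.frame(location_nm = unique(x), weight = 1))
  d <- density(x, bw = "nrd0")
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1
  if (!length(locmax)) locmax <- which.max(y)
  keep <- logical(length(locmax))
  for (k in seq_along(locmax)) {
    i <- locmax[k]
    higher <- locmax[y[locmax] > y[i]]
    # prominence: drop to the deepest saddle separating this peak from
    # higher ground (global peak has full prominence)
    if (!length(higher)) { keep[k] <- TRUE; next }
    saddle <- max(vapply(higher, function(j) {
      rng <- if (j < i) j:i else i:j
      min(y[rng])
    }, numeric(1)))
    keep[k] <- (y[i] - saddle) >= prominence_frac * max(y)
  }
  locmax <- locmax[keep]
  data.frame(location_nm = d$x[locmax],
             weight = y[locmax] / sum(y[locmax]))
}

#' Signed inter-layer distance distribution
#'
#' For every aligned column, the signed distance between the second-channel
#' and reference-channel layer maxima is the sub-bin refined argmax of their
#' paired cross-correlation. Negative distances place the second channel on
#' the cytoplasm side of the reference. The summary mean and SEM are
#' computed at the cellular-replicate level; modes of the pooled
#' distribution are detected by kernel density (Silverman bandwidth,
#' prominence at least 10% of the global maximum).
#'
#' @param ref_carpets,test_carpets lists of aligned carpets (same length and
#'   column structure, e.g. from [align_carpet()] / [apply_alignment()]).
#' @param max_lag_nm largest |distance| searched.
#' @return a `distance_distribution`: per-column `distances_nm` and
#'   `replicate`, replicate-level `mean_nm` and `sem_nm`, and detected
#'   `modes`.
#' @export
distance_distribution <- function(ref_carpets, test_carpets,
                                  max_lag_nm = 1000) {
  stopifnot(length(ref_carpets) == length(test_carpets),
            length(ref_carpets) >= 1)
  dist_nm <- numeric(0)
  rep_id <- character(0)
  for (i in seq_along(ref_carpets)) {
    rc <- ref_carpets[[i]]; tc <- test_carpets[[i]]
    stopifnot(identical(dim(rc$columns), dim(tc$columns)))
    max_lag <- max(1L, round(max_lag_nm / rc$y_step_nm))
    for (j in seq_len(ncol(rc$columns))) {
      pc <- pair_correlation(rc$columns[, j], tc$columns[, j], max_lag)
      if (all(is.na(pc))) next
      d <- refine_argmax(ifelse(is.na(pc), -Inf, pc), attr(pc, "lags"))
      dist_nm <- c(dist_nm, d * rc$y_step_nm)
      rep_id <- c(rep_id, rc$replicate_id)
    }
  }
  if (length(dist_nm) < 24)
    warning("fewer than 24 columns: distance summary unreliable")
  rep_means <- tapply(dist_nm, rep_id, mean)
  nrep <- length(rep_means)
  sem <- if (nrep >= 2) sd(rep_means) / sqrt(nrep) else NA_real_
  if (nrep < 2) warning("fewer than 2 replicates: summary flagged unreliable")
  structure(list(distances_nm = dist_nm, replicate = rep_id,
                 mean_nm = mean(rep_means), sem_nm = sem,
                 replicate_means_nm = rep_means,
                 modes = find_modes(dist_nm)),
            class = "distance_distribution")
}
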