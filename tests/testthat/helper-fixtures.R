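# analytic image fixtures used across test files

# sum of Gaussians sampled at pixel centres (0-based integer coordinates)
gaussian_image <- function(n, centers, sigma, amp = 1) {
  xy <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
  v <- 0
  for (k in seq_len(nrow(centers))) {
    v <- v + amp * exp(-((xy$x - centers[k, 1])^2 +
                         (xy$y - centers[k, 2])^2) / (2 * sigma^2))
  }
  matrix(v, n, n)
}

# noiseless Gaussian line profile on a y grid (nm)
gaussian_profile <- function(y_nm, mu_nm, sigma_nm = 60, amp = 100, base = 1) {
  base + amp * exp(-(y_nm - mu_nm)^2 / (2 * sigma_nm^2))
}

# build an intensity_carpet by hand from a matrix of columns
make_carpet <- function(cols, y_step_nm = 25, replicate_id = "r1",
                        channel = "test") {
  structure(list(columns = cols, y_step_nm = y_step_nm,
                 column_width_nm = y_step_nm, reference_index = 1L,
                 channel = channel, replicate_id = replicate_id,
                 angle_deg = 0),
            class = "intensity_carpet")
}

# interior local maxima of a vector above a height floor; a plateau counts
# as a single maximum at its centre
local_maxima <- function(v, floor_frac = 0) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  i <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1 || j == k) next
    if (r$values[j] > r$values[j - 1] && r$values[j] > r$values[j + 1])
      i <- c(i, (starts[j] + ends[j]) %/% 2)
  }
  i[v[i] >= floor_frac * max(v)]
}
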