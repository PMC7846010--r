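#' Temporal image stack
#'
#' Time-ordered frames of one imaging plane and channel. Frames are numeric
#' matrices with rows = y, columns = x; all frames share a shape.
#'
#' @param frames list of 2-D numeric matrices.
#' @param pixel_size pixel size in nm.
#' @param channel optional channel label.
#' @param provenance free-form list of generating parameters.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, channel = "", provenance = list()) {
  stopifnot(is.list(frames), length(frames) >= 2, pixel_size > 0)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must share the same shape")
  structure(list(frames = frames, pixel_size = pixel_size, channel = channel,
                 provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.4g nm/px)\n",
              length(x$frames), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Super-resolved (or rendered) intensity image
#'
#' @param values nonnegative numeric matrix (rows = y).
#' @param pixel_size pixel size in nm.
#' @param channel channel label.
#' @param provenance list of generating/reconstruction parameters.
#' @return an object of class `super_res_image`.
#' @export
super_res_image <- function(values, pixel_size, channel = "",
                            provenance = list()) {
  stopifnot(is.matrix(values), pixel_size > 0)
  if (any(values < 0)) values[values < 0] <- 0
  structure(list(values = values, pixel_size = pixel_size, channel = channel,
                 provenance = provenance),
            class = "super_res_image")
}

#' @export
print.super_res_image <- function(x, ...) {
  cat(sprintf("<super_res_image> %d x %d px (%.4g nm/px) channel '%s'\n",
              nrow(x$values), ncol(x$values), x$pixel_size, x$channel))
  invisible(x)
}

#' @export
print.k_curve <- function(x, ...) {
  cat(sprintf(
    "<k_curve> %d radii (%.0f-%.0f nm), argmax K~ = %.2f at %.0f nm\n",
    length(x$radii_nm), min(x$radii_nm), max(x$radii_nm),
    x$argmax_value, x$argmax_radius))
  tab <- table(factor(x$classification,
                      levels = c("clustered", "random", "dispersed")))
  cat("  classification: ", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
print.intensity_carpet <- function(x, ...) {
  cat(sprintf(
    "<intensity_carpet> %d columns x %d samples (column width %g nm) channel '%s'\n",
    ncol(x$columns), nrow(x$columns), x$column_width_nm, x$channel))
  invisible(x)
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "<distance_distribution> %d distances, %d replicates: mean %.1f nm (SEM %.2f)\n",
    length(x$distances_nm), length(unique(x$replicate)), x$mean_nm, x$sem_nm))
  if (nrow(x$modes)) {
    cat("  modes at:", paste(sprintf("%.1f nm", x$modes$location_nm),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
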