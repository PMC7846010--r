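# Minimal uncompressed little-endian IEEE-float grayscale TIFF writer
# (single or multi frame). The tiff package reads float TIFFs natively but
# only writes 32-bit scaled-integer samples, which breaks lossless
# round-tripping of float imagery; this writer emits SampleFormat = 3
# (IEEE float) strips that readTIFF, Fiji and libtiff all understand.
write_float_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  pos <- 8L
  writeBin(pos, con, size = 4, endian = "little") # offset of first IFD
  for (k in seq_along(frames)) {
    m <- frames[[k]]
    H <- nrow(m); W <- ncol(m)
    data_off <- pos + ifd_size
    next_ifd <- if (k < length(frames)) data_off + 4L * W * H else 0L
    tags <- list(c(256L, 3L, 1L, W),          # ImageWidth
                 c(257L, 3L, 1L, H),          # ImageLength
                 c(258L, 3L, 1L, 32L),        # BitsPerSample
                 c(259L, 3L, 1L, 1L),         # Compression: none
                 c(262L, 3L, 1L, 1L),         # Photometric: black is zero
                 c(273L, 4L, 1L, data_off),   # StripOffsets
                 c(277L, 3L, 1L, 1L),         # SamplesPerPixel
                 c(278L, 3L, 1L, H),          # RowsPerStrip
                 c(279L, 4L, 1L, 4L * W * H), # StripByteCounts
                 c(339L, 3L, 1L, 3L))         # SampleFormat: IEEE float
    writeBin(n_tags, con, size = 2, endian = "little")
    for (tg in tags) {
      writeBin(tg[1], con, size = 2, endian = "little")
      writeBin(tg[2], con, size = 2, endian = "little")
      writeBin(tg[3], con, size = 4, endian = "little")
      if (tg[2] == 3L) { # SHORT value padded in its 4-byte slot
        writeBin(tg[4], con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(tg[4], con, size = 4, endian = "little")
      }
    }
    writeBin(next_ifd, con, size = 4, endian = "little")
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    pos <- next_ifd
  }
  invisible(path)
}

read_sidecar <- function(path) {
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
}

decode_frame <- function(f) {
  if (is.array(f) && length(dim(f)) == 3) f <- f[, , 1]
  fmt <- attr(f, "sample.format")
  bps <- attr(f, "bits.per.sample")
  v <- if (!is.null(fmt) && identical(fmt, "float")) {
    f # float samples come back on their native scale
  } else if (!is.null(bps) && bps %in% c(8, 16)) {
    f * (2^bps - 1) # integer grayscale on its native 0..(2^b - 1) scale
  } else {
    f
  }
  matrix(as.numeric(v), nrow(f), ncol(f))
}

#' Write a single-frame TIFF image
#'
#' Writes either 32-bit IEEE-float (values stored as-is, lossless for
#' float-representable data) or 8-bit grayscale: data already on the 0..255
#' integer scale is stored natively (lossless), anything else is min-max
#' scaled onto 0..255 with the range recorded in the sidecar. A JSON
#' sidecar `<path>.json`
#' stores the pixel size and any provenance so ground truth travels with
#' the data.
#'
#' @param image a [super_res_image] or numeric matrix.
#' @param path output file path (`.tif`).
#' @param bits 32 (float) or 8.
#' @param pixel_size pixel size in nm for the sidecar (from the image if
#'   available).
#' @export
write_image <- function(image, path, bits = 32, pixel_size = NULL) {
  prov <- list()
  if (inherits(image, "super_res_image")) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    prov <- image$provenance
    image <- image$values
  }
  stopifnot(is.matrix(image), bits %in% c(8, 32))
  side <- list(pixel_size_nm = pixel_size, bits = bits, provenance = prov)
  if (bits == 8) {
    if (all(image == round(image)) && min(image) >= 0 && max(image) <= 255) {
      # already 8-bit-valued: store on the native 0..255 scale (lossless)
      tiff::writeTIFF(image / 255, path, bits.per.sample = 8L)
      side$scale_min <- 0; side$scale_max <- 255
    } else {
      rng <- range(image)
      scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
      tiff::writeTIFF(scaled, path, bits.per.sample = 8L)
      side$scale_min <- rng[1]; side$scale_max <- rng[2]
    }
  } else {
    write_float_tiff(image, path)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Read a single-frame TIFF image (with optional sidecar metadata)
#'
#' @param path TIFF file path.
#' @param pixel_size pixel size in nm; taken from the JSON sidecar when
#'   present.
#' @return a [super_res_image] (integer grayscale data returned on its
#'   native 0..255 / 0..65535 scale, float data as stored).
#' @export
read_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such image file: ", path)
  side <- read_sidecar(path)
  if (is.null(pixel_size)) pixel_size <- side$pixel_size_nm
  if (is.null(pixel_size))
    stop("pixel size missing for ", path, ": supply pixel_size or a sidecar")
  m <- decode_frame(tiff::readTIFF(path, info = TRUE))
  super_res_image(m, pixel_size = as.numeric(pixel_size))
}

#' Write / read a multi-frame grayscale TIFF stack
#'
#' Stacks are stored as multi-page 32-bit float TIFF (lossless); the JSON
#' sidecar records the pixel size.
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  write_float_tiff(stack$frames, path)
  jsonlite::write_json(list(pixel_size_nm = stack$pixel_size,
                            n_frames = length(stack$frames)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @param pixel_size pixel size in nm (sidecar value used when present).
#' @export
read_image_stack <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("no such stack file: ", path)
  side <- read_sidecar(path)
  if (is.null(pixel_size)) pixel_size <- side$pixel_size_nm
  if (is.null(pixel_size)) stop("pixel size missing for ", path)
  frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  image_stack(lapply(frames, decode_frame),
              pixel_size = as.numeric(pixel_size))
}

#' Read an ROI table
#'
#' CSV with columns `x_um, y_um, width_um, height_um, angle_deg,
#' replicate_id`; malformed rows are reported by row number.
#'
#' @param path CSV file path.
#' @return data frame of validated ROIs.
#' @export
read_roi_table <- function(path) {
  if (!file.exists(path)) stop("no such ROI table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "width_um", "height_um", "angle_deg",
            "replicate_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ROI table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  for (col in setdiff(need, "replicate_id")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("ROI table ", path, ", row ", bad[1],
           ": non-numeric value in column '", col, "'")
    tab[[col]] <- v
  }
  if (any(tab$width_um <= 0) || any(tab$height_um <= 0)) {
    bad <- which(tab$width_um <= 0 | tab$height_um <= 0)[1]
    stop("ROI table ", path, ", row ", bad, ": non-positive ROI size")
  }
  tab
}

#' Export a K curve as CSV
#'
#' Columns: `radius_nm, k_raw, k_tilde, env_low, env_high, classification`.
#'
#' @param curve a `k_curve` from [ripley_analyze()].
#' @param path output CSV path.
#' @export
write_k_curve <- function(curve, path) {
  stopifnot(inherits(curve, "k_curve"))
  utils::write.csv(data.frame(radius_nm = curve$radii_nm,
                              k_raw = curve$k_raw, k_tilde = curve$k_tilde,
                              env_low = curve$env_low,
                              env_high = curve$env_high,
                              classification = curve$classification),
                   path, row.names = FALSE)
  invisible(path)
}

#' Export a distance distribution (CSV + JSON summary)
#'
#' @param dd a `distance_distribution`.
#' @param csv_path per-column distances CSV.
#' @param json_path summary JSON (mean, SEM, modes).
#' @export
write_distances <- function(dd, csv_path, json_path = NULL) {
  stopifnot(inherits(dd, "distance_distribution"))
  utils::write.csv(data.frame(replicate = dd$replicate,
                              distance_nm = dd$distances_nm),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(mean_nm = dd$mean_nm, sem_nm = dd$sem_nm,
                              n_replicates = length(dd$replicate_means_nm),
                              modes = dd$modes),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
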