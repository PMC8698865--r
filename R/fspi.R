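#' Pixel-scale calibration
#'
#' Converts a known physical width and its extent in pixels into an
#' effective resolution in micrometres per pixel. Merging four aquarium
#' sides of 12 cm internal width into a 5396-px-wide composite gives the
#' reference resolution of 88.9 um/px.
#'
#' @param width_cm Physical width in centimetres.
#' @param width_px Same width in pixels.
#' @return Resolution in micrometres per pixel (`width_cm * 1e4 / width_px`).
#' @examples
#' pixel_scale(48, 5396)
#' @export
pixel_scale <- function(width_cm, width_px) {
  if (!is.numeric(width_cm) || !is.numeric(width_px) ||
      any(width_cm <= 0) || any(width_px <= 0)) {
    stop("`width_cm` and `width_px` must be positive", call. = FALSE)
  }
  width_cm * 1e4 / width_px
}

#' Merge aquarium side photographs into one composite image
#'
#' Horizontally concatenates the four side views of an aquarium (each
#' cropped to the internal width) so that depth profiles from all sides are
#' analysed as one image. The side order is configurable and recorded as an
#' attribute; reworking depth metrics are invariant to it.
#'
#' @param images List of RGB arrays (`height x width x 3`, values in 0..1).
#' @param side_order Integer permutation giving the concatenation order.
#' @return A single RGB array with attribute `side_order`.
#' @examples
#' side <- array(0.2, dim = c(10, 8, 3))
#' dim(merge_sides(list(side, side, side, side)))
#' @export
merge_sides <- function(images, side_order = seq_along(images)) {
  if (!is.list(images) || length(images) == 0L || any(vapply(images, is.null, logical(1)))) {
    stop("`images` must be a non-empty list of RGB arrays (no missing sides)", call. = FALSE)
  }
  dims <- vapply(images, function(x) dim(x)[1:2], numeric(2))
  if (length(unique(dims[1, ])) != 1L) {
    stop("all side images must have the same height", call. = FALSE)
  }
  if (any(vapply(images, function(x) length(dim(x)) != 3L || dim(x)[3] != 3L, logical(1)))) {
    stop("side images must be RGB arrays with 3 channels", call. = FALSE)
  }
  if (!setequal(side_order, seq_along(images))) {
    stop("`side_order` must be a permutation of the side indices", call. = FALSE)
  }
  ordered <- images[side_order]
  h <- dims[1, 1]
  merged <- vapply(1:3, function(ch) {
    do.call(cbind, lapply(ordered, function(img) img[, , ch]))
  }, matrix(0, h, sum(dims[2, ])))
  structure(merged, side_order = side_order)
}

#' Segment luminophore pixels by HSV colour thresholding
#'
#' Classifies every pixel as luminophore (1) or background (0) by testing
#' whether its hue falls inside an orange band and its saturation and value
#' exceed minima. The result is the binary occurrence matrix on which all
#' reworking depth metrics are computed.
#'
#' @param image RGB array (`height x width x 3`, values in 0..1).
#' @param hue_band Length-2 numeric, hue window in degrees (0..360). A band
#'   with `hue_band[1] > hue_band[2]` wraps around 0/360.
#' @param saturation_min,value_min Minimum HSV saturation and value (0..1).
#' @return An integer 0/1 matrix of class `lumi_matrix` (origin top-left,
#'   rows increase downward).
#' @export
segment_luminophores <- function(image, hue_band = c(15, 55),
                                 saturation_min = 0.4, value_min = 0.4) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L || prod(dim(image)[1:2]) == 0L) {
    stop("`image` must be a non-empty RGB array", call. = FALSE)
  }
  if (length(hue_band) != 2L || any(hue_band < 0 | hue_band > 360)) {
    stop("`hue_band` must be two hue angles in [0, 360]", call. = FALSE)
  }
  if (saturation_min < 0 || saturation_min > 1 || value_min < 0 || value_min > 1) {
    stop("saturation and value thresholds must lie in [0, 1]", call. = FALSE)
  }
  d <- dim(image)
  hsv <- grDevices::rgb2hsv(r = as.vector(image[, , 1]),
                            g = as.vector(image[, , 2]),
                            b = as.vector(image[, , 3]),
                            maxColorValue = 1)
  h <- hsv[1, ] * 360
  in_band <- if (hue_band[1] <= hue_band[2]) {
    h >= hue_band[1] & h <= hue_band[2]
  } else {
    h >= hue_band[1] | h <= hue_band[2]
  }
  hit <- in_band & hsv[2, ] >= saturation_min & hsv[3, ] >= value_min
  m <- matrix(as.integer(hit), nrow = d[1], ncol = d[2])
  class(m) <- c("lumi_matrix", class(m))
  m
}

#' Trace the sediment-water interface
#'
#' For each image column, finds the topmost row at which the sediment
#' begins, defined as the first run of at least `min_run` consecutive
#' pixels on the sediment side of a luminance threshold; requiring a run
#' rejects isolated speckle. The per-column elevations are then smoothed
#' with a running median. Columns in which no sediment is found are flagged
#' and excluded from surface-roughness calculations.
#'
#' @param image RGB array, or a luminance matrix.
#' @param luminance_threshold Rec.709 luminance cut separating water from
#'   sediment.
#' @param smoothing_window Odd window width (columns) of the running
#'   median; 1 disables smoothing.
#' @param sediment Whether sediment is `"bright"` (default; dark water
#'   column above a pale sediment under UV) or `"dark"` relative to water.
#' @param min_run Minimum consecutive sediment rows that establish the
#'   surface.
#' @return An `interface_profile`: list with `elevation_row` (one row index
#'   per column, `NA` where excluded), `excluded_columns`,
#'   `smoothing_window`.
#' @export
detect_interface <- function(image, luminance_threshold = 0.15,
                             smoothing_window = 11, sediment = c("bright", "dark"),
                             min_run = 5L) {
  sediment <- match.arg(sediment)
  lum <- if (length(dim(image)) == 3L) {
    0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  } else {
    image
  }
  if (smoothing_window < 1 || smoothing_window %% 2 == 0) {
    stop("`smoothing_window` must be a positive odd integer", call. = FALSE)
  }
  sed <- if (sediment == "bright") lum >= luminance_threshold else lum <= luminance_threshold
  n_col <- ncol(sed)
  n_row <- nrow(sed)
  min_run <- min(min_run, n_row)
  elevation <- vapply(seq_len(n_col), function(j) {
    r <- rle(sed[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= min_run
    if (any(ok)) starts[which(ok)[1]] else NA_real_
  }, numeric(1))

  excluded <- which(is.na(elevation))
  if (length(excluded) == n_col) {
    stop("no sediment found in any column; check `luminance_threshold`", call. = FALSE)
  }
  if (length(excluded) > 0L) {
    message(sprintf("detect_interface: %d column(s) without sediment excluded", length(excluded)))
  }
  smoothed <- elevation
  if (smoothing_window > 1 && n_col >= 2) {
    filled <- elevation
    if (length(excluded) > 0L) {
      good <- which(!is.na(elevation))
      filled[excluded] <- stats::approx(good, elevation[good], xout = excluded, rule = 2)$y
    }
    k <- min(smoothing_window, if (n_col %% 2 == 1) n_col else n_col - 1)
    smoothed <- as.numeric(stats::runmed(filled, k = k, endrule = "median"))
    smoothed[excluded] <- NA_real_
  }
  structure(list(elevation_row = smoothed,
                 excluded_columns = excluded,
                 smoothing_window = smoothing_window,
                 luminance_threshold = luminance_threshold),
            class = "interface_profile")
}

#' Particle reworking depth metrics
#'
#' Computes, from a binary luminophore matrix and an interface profile, the
#' mean, median and maximum mixed depths of tracer particles and the
#' surface boundary roughness. The depth of a luminophore pixel is measured
#' vertically from the sediment surface of its own column (per-column
#' reference), and pixels lying above the interface are floored to depth 0:
#' negative depths are optical artefacts, not reworking. SBR is the range
#' (highest minus lowest elevation) of the traced interface.
#'
#' @param matrix A `lumi_matrix` (or plain 0/1 matrix).
#' @param interface An `interface_profile` from [detect_interface()], or a
#'   numeric vector of per-column surface row indices.
#' @param pixel_scale Resolution in micrometres per pixel.
#' @return A one-row tibble: `n_pixels`, `L_mean`, `L_median`, `L_max`,
#'   `SBR` (all depths in cm). With zero luminophore pixels the depth
#'   metrics are `NA` (explicit null result) and `SBR` is still reported.
#' @export
depth_metrics <- function(matrix, interface, pixel_scale) {
  if (pixel_scale <= 0) stop("`pixel_scale` must be positive", call. = FALSE)
  elev <- if (inherits(interface, "interface_profile")) interface$elevation_row else as.numeric(interface)
  if (length(elev) != ncol(matrix)) {
    stop("interface must provide one elevation per matrix column", call. = FALSE)
  }
  px_cm <- pixel_scale / 1e4
  idx <- which(matrix == 1L, arr.ind = TRUE)
  if (nrow(idx) > 0L && anyNA(elev[idx[, 2]])) {
    warning("luminophore pixels in columns without a traced interface were dropped")
    idx <- idx[!is.na(elev[idx[, 2]]), , drop = FALSE]
  }
  sbr <- (max(elev, na.rm = TRUE) - min(elev, na.rm = TRUE)) * px_cm
  if (nrow(idx) == 0L) {
    return(tibble::tibble(n_pixels = 0L, L_mean = NA_real_, L_median = NA_real_,
                          L_max = NA_real_, SBR = sbr))
  }
  depth_cm <- pmax(idx[, 1] - elev[idx[, 2]], 0) * px_cm
  tibble::tibble(
    n_pixels = nrow(idx),
    L_mean = mean(depth_cm),
    L_median = stats::median(depth_cm),
    L_max = max(depth_cm),
    SBR = sbr
  )
}

#' Average per-side surface boundary roughness to the aquarium level
#'
#' @param sbr_values Numeric vector of per-side SBR values (cm).
#' @return Their arithmetic mean.
#' @examples
#' aggregate_sbr(c(0, 0, 0, 2))
#' @export
aggregate_sbr <- function(sbr_values) {
  if (length(sbr_values) == 0L || all(is.na(sbr_values))) {
    stop("at least one SBR value is required", call. = FALSE)
  }
  mean(sbr_values, na.rm = TRUE)
}

#' One-call f-SPI analysis of a profile image
#'
#' Runs segmentation, interface tracing and depth metrics on a (merged)
#' profile image and returns the reworking metrics as a tibble row.
#'
#' @param image RGB array.
#' @param pixel_scale Micrometres per pixel.
#' @param hue_band,saturation_min,value_min Passed to
#'   [segment_luminophores()].
#' @param luminance_threshold,smoothing_window,sediment Passed to
#'   [detect_interface()].
#' @return A one-row tibble as from [depth_metrics()] plus
#'   `n_excluded_columns`.
#' @export
analyze_profile <- function(image, pixel_scale,
                            hue_band = c(15, 55), saturation_min = 0.4,
                            value_min = 0.4, luminance_threshold = 0.15,
                            smoothing_window = 11, sediment = "bright") {
  mask <- segment_luminophores(image, hue_band, saturation_min, value_min)
  interface <- detect_interface(image, luminance_threshold, smoothing_window,
                                sediment = sediment)
  depth_metrics(mask, interface, pixel_scale) |>
    dplyr::mutate(n_excluded_columns = length(interface$excluded_columns))
}

#' QC overlay of segmentation and interface trace
#'
#' Returns a copy of the image with the traced interface drawn as a red
#' line and segmented luminophore pixels tinted green, for visual quality
#' control of an f-SPI analysis.
#'
#' @param image RGB array.
#' @param mask `lumi_matrix` for the same image.
#' @param interface `interface_profile` for the same image.
#' @return An RGB array of the same dimensions.
#' @export
overlay_qc <- function(image, mask, interface) {
  out <- image
  idx <- which(mask == 1L, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    out[cbind(idx, 2L)] <- 1
    out[cbind(idx, 1L)] <- 0
    out[cbind(idx, 3L)] <- 0.2
  }
  elev <- round(interface$elevation_row)
  cols <- which(!is.na(elev))
  rows <- pmin(pmax(elev[cols], 1), nrow(image))
  out[cbind(rows, cols, 1L)] <- 1
  out[cbind(rows, cols, 2L)] <- 0
  out[cbind(rows, cols, 3L)] <- 0
  out
}
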