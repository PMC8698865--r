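#' Depth laws for synthetic luminophore placement
#'
#' Constructs the probability law from which luminophore burial depths
#' (cm below the sediment-water interface) are drawn by
#' [render_fspi_image()]. Available laws: `"surface"` (all particles at the
#' interface, the unreworked starting state), `"uniform"` on `(0, max_cm)`,
#' `"exponential"` with mean `mean_cm` (typical of diffusive biodiffuser
#' profiles), and `"point"` (all particles at exactly `depth_cm`; useful
#' for exact oracle tests).
#'
#' @param type One of `"surface"`, `"uniform"`, `"exponential"`, `"point"`.
#' @param max_cm Upper bound of the uniform law.
#' @param mean_cm Mean of the (untruncated) exponential law.
#' @param truncate_cm Optional upper truncation of the exponential law at
#'   the sediment-column depth (particles cannot be mixed below the
#'   aquarium floor); default `Inf` (no truncation).
#' @param depth_cm Depth of the point law.
#' @return A `depth_law` object.
#' @examples
#' depth_law("uniform", max_cm = 2)
#' @export
depth_law <- function(type = c("surface", "uniform", "exponential", "point"),
                      max_cm = 2, mean_cm = 1, truncate_cm = Inf, depth_cm = 1) {
  type <- match.arg(type)
  params <- switch(type,
    surface = list(),
    uniform = {
      if (max_cm <= 0) stop("`max_cm` must be positive", call. = FALSE)
      list(max_cm = max_cm)
    },
    exponential = {
      if (mean_cm <= 0) stop("`mean_cm` must be positive", call. = FALSE)
      if (truncate_cm <= 0) stop("`truncate_cm` must be positive", call. = FALSE)
      list(mean_cm = mean_cm, truncate_cm = truncate_cm)
    },
    point = {
      if (depth_cm < 0) stop("`depth_cm` must be non-negative", call. = FALSE)
      list(depth_cm = depth_cm)
    }
  )
  structure(c(list(type = type), params), class = "depth_law")
}

draw_depths <- function(law, n) {
  switch(law$type,
    surface = rep(0, n),
    uniform = stats::runif(n, 0, law$max_cm),
    exponential = {
      # inverse-CDF sampling on the (possibly truncated) support
      p_max <- stats::pexp(law$truncate_cm, rate = 1 / law$mean_cm)
      stats::qexp(stats::runif(n, 0, p_max), rate = 1 / law$mean_cm)
    },
    point = rep(law$depth_cm, n)
  )
}

#' Analytic moments of a depth law
#'
#' Closed-form mean, median and supremum depth of a [depth_law()], used as
#' ground truth when checking that image analysis recovers the law that
#' generated an image.
#'
#' @param law A `depth_law`.
#' @return A tibble with `mean_cm`, `median_cm`, `max_cm` (`Inf` for the
#'   unbounded exponential).
#' @export
depth_law_moments <- function(law) {
  stopifnot(inherits(law, "depth_law"))
  switch(law$type,
    surface = tibble::tibble(mean_cm = 0, median_cm = 0, max_cm = 0),
    uniform = tibble::tibble(mean_cm = law$max_cm / 2, median_cm = law$max_cm / 2,
                             max_cm = law$max_cm),
    exponential = {
      m <- law$mean_cm
      t <- law$truncate_cm
      if (is.finite(t)) {
        p_max <- stats::pexp(t, rate = 1 / m)
        tibble::tibble(
          mean_cm = m - t * exp(-t / m) / p_max,
          median_cm = stats::qexp(p_max / 2, rate = 1 / m),
          max_cm = t
        )
      } else {
        tibble::tibble(mean_cm = m, median_cm = log(2) * m, max_cm = Inf)
      }
    },
    point = tibble::tibble(mean_cm = law$depth_cm, median_cm = law$depth_cm,
                           max_cm = law$depth_cm)
  )
}

#' Interface shapes for synthetic profiles
#'
#' Describes the sediment-water interface of a synthetic profile as an
#' elevation offset (cm, positive = deeper) per column relative to the
#' nominal surface: `"flat"`, `"step"` (left half at `h1_cm`, right half at
#' `h2_cm`, so the surface roughness is exactly `|h1_cm - h2_cm|`), or
#' `"sinusoid"` with amplitude and period in cm. Optional per-column
#' uniform jitter (in pixels) roughens any shape.
#'
#' @param type `"flat"`, `"step"` or `"sinusoid"`.
#' @param h_cm Offset of the flat interface.
#' @param h1_cm,h2_cm Offsets of the two step halves.
#' @param amplitude_cm,period_cm Sinusoid parameters.
#' @param jitter_px Half-width of integer jitter added per column.
#' @return An `interface_law` object.
#' @export
interface_law <- function(type = c("flat", "step", "sinusoid"), h_cm = 0,
                          h1_cm = 0, h2_cm = 0.5, amplitude_cm = 0.25,
                          period_cm = 4, jitter_px = 0) {
  type <- match.arg(type)
  structure(list(type = type, h_cm = h_cm, h1_cm = h1_cm, h2_cm = h2_cm,
                 amplitude_cm = amplitude_cm, period_cm = period_cm,
                 jitter_px = jitter_px),
            class = "interface_law")
}

interface_offsets_px <- function(law, width_px, pixel_scale) {
  px_per_cm <- 1e4 / pixel_scale
  x_cm <- (seq_len(width_px) - 0.5) / px_per_cm
  base <- switch(law$type,
    flat = rep(law$h_cm, width_px),
    step = ifelse(seq_len(width_px) <= width_px / 2, law$h1_cm, law$h2_cm),
    sinusoid = law$amplitude_cm * sin(2 * pi * x_cm / law$period_cm)
  )
  off <- round(base * px_per_cm)
  if (law$jitter_px > 0) {
    off <- off + sample(seq(-law$jitter_px, law$jitter_px), width_px, replace = TRUE)
  }
  off
}

#' Render a synthetic f-SPI profile image with known ground truth
#'
#' Draws an RGB sediment-profile photograph as seen under UV: a dark water
#' column above a grey-blue sediment body, with `n_luminophore_px` orange
#' luminophore pixels placed at depths drawn from `depth_law` below the
#' per-column interface given by `interface`. The returned object carries
#' the exact per-pixel label mask and interface elevations, so image
#' analysis can be scored against truth.
#'
#' @param width_px,height_px Image size in pixels.
#' @param pixel_scale Micrometres per pixel (default 100, i.e. 1 cm =
#'   100 px).
#' @param depth_law A [depth_law()].
#' @param interface An [interface_law()].
#' @param n_luminophore_px Number of luminophore placements (overlapping
#'   draws collapse onto one pixel in the mask).
#' @param interface_depth_cm Nominal depth of the sediment surface below
#'   the image top (water-column height).
#' @param noise List with `salt_pepper` (per-pixel probability of a
#'   white/black speckle) and `gauss_sd` (SD of additive luminance jitter);
#'   both default to 0 (off).
#' @param seed Optional integer seed for exact reproducibility.
#' @param luminophore_rgb,sediment_rgb,water_rgb Colours as length-3 RGB
#'   vectors in 0..1.
#' @return An `fspi_truth` object: list with `image`, `label_mask`
#'   (`lumi_matrix`), `interface_row` (true elevation per column),
#'   `pixel_scale`, `depth_law`, `interface_law`.
#' @examples
#' truth <- render_fspi_image(width_px = 120, height_px = 320,
#'                            depth_law = depth_law("point", depth_cm = 1),
#'                            n_luminophore_px = 50, seed = 1)
#' truth_metrics(truth)
#' @export
render_fspi_image <- function(width_px = 400, height_px = 600, pixel_scale = 100,
                              depth_law = lumibr::depth_law("uniform", max_cm = 2),
                              interface = interface_law("flat"),
                              n_luminophore_px = 2000,
                              interface_depth_cm = 2,
                              noise = list(salt_pepper = 0, gauss_sd = 0),
                              seed = NULL,
                              luminophore_rgb = c(1.0, 0.55, 0.10),
                              sediment_rgb = c(0.30, 0.32, 0.38),
                              water_rgb = c(0.02, 0.02, 0.05)) {
  stopifnot(inherits(depth_law, "depth_law"), inherits(interface, "interface_law"))
  if (!is.null(seed)) set.seed(seed)
  px_per_cm <- 1e4 / pixel_scale

  base_row <- round(interface_depth_cm * px_per_cm)
  elev <- base_row + interface_offsets_px(interface, width_px, pixel_scale)
  if (any(elev < 1) || any(elev > height_px)) {
    stop("interface elevations fall outside the image; enlarge the image or ",
         "reduce `interface_depth_cm`", call. = FALSE)
  }

  img <- array(0, dim = c(height_px, width_px, 3))
  rows <- matrix(seq_len(height_px), height_px, width_px)
  below <- rows >= matrix(elev, height_px, width_px, byrow = TRUE)
  for (ch in 1:3) {
    plane <- matrix(water_rgb[ch], height_px, width_px)
    plane[below] <- sediment_rgb[ch]
    img[, , ch] <- plane
  }

  mask <- matrix(0L, height_px, width_px)
  if (n_luminophore_px > 0) {
    cols <- sample.int(width_px, n_luminophore_px, replace = TRUE)
    depths_cm <- draw_depths(depth_law, n_luminophore_px)
    rows_lp <- elev[cols] + round(depths_cm * px_per_cm)
    if (any(rows_lp > height_px)) {
      stop("drawn luminophore depth exceeds the image height below the ",
           "interface; enlarge `height_px` or shallow the depth law", call. = FALSE)
    }
    mask[cbind(rows_lp, cols)] <- 1L
    idx <- which(mask == 1L, arr.ind = TRUE)
    for (ch in 1:3) img[cbind(idx, ch)] <- luminophore_rgb[ch]
  }

  if (isTRUE(noise$gauss_sd > 0)) {
    img <- img + array(stats::rnorm(length(img), 0, noise$gauss_sd), dim = dim(img))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  if (isTRUE(noise$salt_pepper > 0)) {
    n_px <- height_px * width_px
    hit <- which(stats::runif(n_px) < noise$salt_pepper)
    if (length(hit) > 0L) {
      val <- stats::rbinom(length(hit), 1L, 0.5)
      for (ch in 1:3) img[hit + (ch - 1L) * n_px] <- val
    }
  }

  class(mask) <- c("lumi_matrix", class(mask))
  structure(list(image = img, label_mask = mask, interface_row = elev,
                 pixel_scale = pixel_scale, depth_law = depth_law,
                 interface_law = interface,
                 n_luminophore_px = n_luminophore_px),
            class = "fspi_truth")
}

#' Ground-truth reworking metrics of a synthetic profile
#'
#' Computes [depth_metrics()] directly from the generator's label mask and
#' true interface elevations, bypassing segmentation. Used as the oracle
#' against which the image-analysis pipeline is scored.
#'
#' @param truth An `fspi_truth` from [render_fspi_image()].
#' @return A one-row tibble as from [depth_metrics()].
#' @export
truth_metrics <- function(truth) {
  stopifnot(inherits(truth, "fspi_truth"))
  depth_metrics(truth$label_mask, truth$interface_row, truth$pixel_scale)
}

#' Write a synthetic profile image to PNG
#'
#' @param truth An `fspi_truth`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_fspi_png <- function(truth, path) {
  stopifnot(inherits(truth, "fspi_truth"))
  png::writePNG(truth$image, target = path)
  invisible(path)
}
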