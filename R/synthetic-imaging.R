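#' Synthetic fluoroscopy-like frame with known aerated area
#'
#' Builds a grayscale frame (values in [0, 1], 0 = black/radiolucent)
#' containing a lung-shaped region (two ellipses) in which an exact number
#' of pixels — `round(aerated_fraction * region area)` — are dark (aerated)
#' and the rest bright (non-aerated tissue), plus Gaussian speckle noise.
#' The intensity separation is large relative to the noise so threshold
#' segmentation can recover the count.
#'
#' @param aerated_fraction Fraction of the lung region that is aerated,
#'   in [0, 1].
#' @param size `c(rows, cols)` of the frame.
#' @param seed Integer seed; `NULL` leaves RNG state alone.
#' @param noise_sd Speckle noise standard deviation (intensity units).
#' @param levels `c(aerated, tissue, background)` base intensities.
#' @return List: `image` (matrix), `region_mask` (logical matrix),
#'   `aerated_truth` (pixel count), `region_pixels`.
#' @export
generate_fluoro_frame <- function(aerated_fraction, size = c(128, 128),
                                  seed = NULL, noise_sd = 0.04,
                                  levels = c(0.2, 0.65, 0.9)) {
  if (aerated_fraction < 0 || aerated_fraction > 1)
    pv_stop("aerated_fraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  nr <- size[1]; nc <- size[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # two "lung fields": left and right ellipses
  e1 <- ((row - 0.55 * nr) / (0.38 * nr))^2 +
    ((col - 0.32 * nc) / (0.2 * nc))^2 <= 1
  e2 <- ((row - 0.55 * nr) / (0.38 * nr))^2 +
    ((col - 0.68 * nc) / (0.2 * nc))^2 <= 1
  region <- e1 | e2
  n_region <- sum(region)
  k <- as.integer(round(aerated_fraction * n_region))

  img <- matrix(levels[3], nr, nc)
  img[region] <- levels[2]
  idx <- which(region)
  if (k > 0) img[sample(idx, k)] <- levels[1]
  img <- img + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
  img <- pmin(pmax(img, 0), 1)   # argument order preserves matrix shape
  list(image = img, region_mask = region, aerated_truth = k,
       region_pixels = n_region)
}

#' Synthetic binary airspace image with known mean chord length
#'
#' Phantoms for mean-linear-intercept validation. `pattern = "stripes"`
#' draws alternating vertical air/tissue bands with air-band width equal to
#' `chord_length`, so test lines perpendicular to the bands see air chords
#' of exactly that length. `pattern = "circles"` scatters non-overlapping
#' air discs of diameter `chord_length`; the mean chord of a disc across
#' uniformly placed lines is (pi/4) * diameter, which is returned as the
#' expected MLI.
#'
#' @param chord_length Air chord (stripes) or disc diameter (circles), um.
#' @param pixel_size Image calibration (um/px).
#' @param pattern "stripes" or "circles".
#' @param size `c(rows, cols)` in pixels.
#' @param tissue_width Tissue-band width for stripes (um); default equals
#'   `chord_length`.
#' @param n_circles Number of discs attempted for the circle phantom.
#' @param seed Integer seed for disc placement.
#' @return List: `airspace_mask` (logical, TRUE = air), `exclusion_mask`
#'   (logical, all FALSE), `expected_mli` (um), `pixel_size`.
#' @export
generate_airspace_image <- function(chord_length, pixel_size = 1,
                                    pattern = c("stripes", "circles"),
                                    size = c(512, 512), tissue_width = NULL,
                                    n_circles = 60, seed = NULL) {
  pattern <- match.arg(pattern)
  if (pixel_size <= 0) pv_stop("pixel_size must be > 0")
  if (chord_length < 2 * pixel_size)
    pv_stop("chord_length below image resolution (need >= 2 pixels)",
            "pvvent_argument_error")
  if (!is.null(seed)) set.seed(seed)
  nr <- size[1]; nc <- size[2]
  mask <- matrix(FALSE, nr, nc)

  if (pattern == "stripes") {
    w_air <- round(chord_length / pixel_size)
    w_tis <- round((tissue_width %||% chord_length) / pixel_size)
    period <- w_air + w_tis
    phase <- ((seq_len(nc) - 1) %% period)
    air_cols <- phase < w_air
    mask[, air_cols] <- TRUE
    expected <- w_air * pixel_size
  } else {
    r <- chord_length / pixel_size / 2
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    while (nrow(centers) < n_circles && tries < 50 * n_circles) {
      tries <- tries + 1
      cand <- c(runif(1, r + 2, nr - r - 2), runif(1, r + 2, nc - r - 2))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) > 2 * r + 2)) {
        centers <- rbind(centers, cand)
      }
    }
    row <- matrix(seq_len(nr), nr, nc)
    col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (i in seq_len(nrow(centers))) {
      mask <- mask | ((row - centers[i, 1])^2 + (col - centers[i, 2])^2 <= r^2)
    }
    expected <- (pi / 4) * chord_length
  }

  list(airspace_mask = mask,
       exclusion_mask = matrix(FALSE, nr, nc),
       expected_mli = expected, pixel_size = pixel_size)
}
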