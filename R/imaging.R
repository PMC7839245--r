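#' Segment aerated lung on a grayscale frame
#'
#' Threshold segmentation standing in for manual radiodensity-based pixel
#' counting: within the lung region, pixels darker (more radiolucent) than
#' the threshold count as aerated. The threshold is either a fixed
#' intensity or chosen automatically by Otsu's method on the region
#' histogram; the strategy and value used are recorded in the output, and
#' the operation is deterministic for fixed inputs.
#'
#' @param frame Numeric matrix, intensities in [0, 1] (0 = black).
#' @param region_mask Logical matrix delimiting the lung; `NULL` uses the
#'   whole frame.
#' @param threshold Numeric cut in [0, 1], or `"otsu"`.
#' @return List of class `lung_segmentation`: `mask` (logical, aerated),
#'   `aerated_pixels`, `region_pixels`, `threshold_used`, `strategy`.
#' @export
segment_lung <- function(frame, region_mask = NULL, threshold = "otsu") {
  if (!is.matrix(frame)) pv_stop("frame must be a single-channel matrix")
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(frame),
                                                  ncol(frame))
  if (!any(region_mask)) pv_stop("empty lung region", "pvvent_argument_error")
  vals <- frame[region_mask]
  if (identical(threshold, "otsu")) {
    thr <- EBImage::otsu(EBImage::Image(matrix(vals, ncol = 1)),
                         range = c(0, 1))
    strategy <- "otsu"
  } else {
    thr <- as.numeric(threshold)
    strategy <- "fixed"
  }
  mask <- region_mask & (frame < thr)
  structure(
    list(mask = mask, aerated_pixels = sum(mask),
         region_pixels = sum(region_mask), threshold_used = thr,
         strategy = strategy),
    class = "lung_segmentation"
  )
}

#' Aeration result for one timepoint
#'
#' @param timepoint Label ("H0" ... "H6").
#' @param aerated_pixels,region_pixels Pixel counts,
#'   `aerated_pixels <= region_pixels`.
#' @return data.frame row of class `aeration_result`.
#' @export
aeration_result <- function(timepoint, aerated_pixels, region_pixels) {
  if (aerated_pixels > region_pixels)
    pv_stop("aerated_pixels cannot exceed region_pixels")
  df <- data.frame(timepoint = timepoint, aerated_pixels = aerated_pixels,
                   region_pixels = region_pixels)
  class(df) <- c("aeration_result", "data.frame")
  df
}

#' Percent change in aerated area versus baseline
#'
#' change_t = 100 * (aerated_t - aerated_H0) / aerated_H0, with the first
#' row of the ordered series as the H0 reference (its change is 0 by
#' construction).
#'
#' @param series data.frame with columns `timepoint` and `aerated_pixels`,
#'   ordered H0 first (e.g. rbind of [aeration_result()] rows), or a
#'   numeric vector of counts.
#' @return The input with an added `pct_change_vs_h0` column (or a numeric
#'   vector if the input was numeric).
#' @export
#' @examples
#' aeration_change(c(1000, 821))  # 0, -17.9
aeration_change <- function(series) {
  counts <- if (is.data.frame(series)) series$aerated_pixels else series
  if (length(counts) < 1 || counts[1] == 0)
    pv_stop("baseline (H0) aerated area missing or zero",
            "pvvent_argument_error")
  pct <- 100 * (counts - counts[1]) / counts[1]
  if (is.data.frame(series)) {
    series$pct_change_vs_h0 <- pct
    series
  } else pct
}

#' Mean linear intercept (MLI) of an airspace mask
#'
#' Automated airspace-size morphometry: evenly spaced test lines are laid
#' across the binary airspace image; on each line, maximal runs of air
#' pixels (chords) are measured, excluding chords that touch the image
#' edge (truncation bias) or an excluded region (vessels/airways). The MLI
#' is the total air-chord length divided by the number of complete air
#' chords, in micrometers. The alternative denominator — the number of
#' air-tissue intercept crossings — is available via
#' `denominator = "intercepts"`.
#'
#' @param airspace_mask Logical matrix, TRUE = air.
#' @param exclusion_mask Logical matrix of regions to avoid (big vessels
#'   and airways); `NULL` for none.
#' @param pixel_size Calibration (um/px), > 0.
#' @param spacing Line spacing (px).
#' @param orientation "horizontal", "vertical" or "both".
#' @param denominator "chords" (default) or "intercepts".
#' @return List of class `morphometry_result`: `mli` (um), `n_lines`,
#'   `n_chords`, `n_intercepts`, `pixel_size`, `orientation`.
#' @export
mean_linear_intercept <- function(airspace_mask, exclusion_mask = NULL,
                                  pixel_size = 1, spacing = 20,
                                  orientation = c("horizontal", "vertical",
                                                  "both"),
                                  denominator = c("chords", "intercepts")) {
  orientation <- match.arg(orientation)
  denominator <- match.arg(denominator)
  if (pixel_size <= 0) pv_stop("pixel_size must be > 0")
  if (!is.null(exclusion_mask) &&
      !identical(dim(airspace_mask), dim(exclusion_mask)))
    pv_stop("masks must have the same shape")
  if (is.null(exclusion_mask))
    exclusion_mask <- matrix(FALSE, nrow(airspace_mask), ncol(airspace_mask))

  lines <- list()
  if (orientation %in% c("horizontal", "both")) {
    for (r in seq(ceiling(spacing / 2), nrow(airspace_mask), by = spacing))
      lines[[length(lines) + 1L]] <- list(air = airspace_mask[r, ],
                                          excl = exclusion_mask[r, ])
  }
  if (orientation %in% c("vertical", "both")) {
    for (cc in seq(ceiling(spacing / 2), ncol(airspace_mask), by = spacing))
      lines[[length(lines) + 1L]] <- list(air = airspace_mask[, cc],
                                          excl = exclusion_mask[, cc])
  }

  total_air <- 0; n_chords <- 0L; n_intercepts <- 0L; any_tissue <- FALSE
  for (ln in lines) {
    air <- ln$air; excl <- ln$excl
    n <- length(air)
    r <- rle(air)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    n_intercepts <- n_intercepts + sum(r$values) * 2L
    if (any(!air)) any_tissue <- TRUE
    for (j in which(r$values)) {
      if (starts[j] == 1L || ends[j] == n) next          # edge-touching
      if (any(excl[starts[j]:ends[j]])) next             # excluded region
      if (excl[starts[j] - 1L] || excl[ends[j] + 1L]) next
      total_air <- total_air + r$lengths[j]
      n_chords <- n_chords + 1L
    }
  }
  if (!any_tissue)
    pv_stop("degenerate field: no tissue intercepted by any test line",
            "pvvent_domain_error")
  if (n_chords == 0)
    pv_stop("no complete air chords on any test line", "pvvent_domain_error")
  denom <- if (denominator == "chords") n_chords else n_intercepts / 2
  structure(
    list(mli = total_air / denom * pixel_size, n_lines = length(lines),
         n_chords = n_chords, n_intercepts = n_intercepts,
         pixel_size = pixel_size, orientation = orientation,
         denominator = denominator),
    class = "morphometry_result"
  )
}

#' Average MLI over microscopy fields
#'
#' The study convention averages the per-field MLI over all fields of a
#' subject (18 fields at 10x in the protocol).
#'
#' @param results List of [mean_linear_intercept()] results.
#' @return List: `mli` (um, mean over fields), `fields_used`, `per_field`.
#' @export
average_mli <- function(results) {
  if (length(results) == 0) pv_stop("no fields supplied")
  per <- vapply(results, function(r) r$mli, numeric(1))
  list(mli = mean(per), fields_used = length(results), per_field = per)
}

#' Write a grayscale image or binary mask as PNG
#'
#' @param image Numeric matrix in [0, 1] or logical matrix.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  m <- if (is.logical(image)) image * 1 else pmin(pmax(image, 0), 1)
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_image_png
#' @param as_mask Logical: threshold at 0.5 and return a logical matrix.
#' @export
read_image_png <- function(path, as_mask = FALSE) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  if (as_mask) img > 0.5 else img
}
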