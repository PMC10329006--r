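#' Measure raw fluorescence intensity in a region of interest
#'
#' Mirrors ROI quantification on live-imaging data: in `single_plane` mode
#' the mean pixel value over the ROI of one plane; in `sum_z` mode the
#' image is first summed pixel-wise over Z, then averaged (or, with
#' `integrate = TRUE`, summed) over the ROI. Integrated sums are the right
#' choice for total-amount readouts (e.g. total tubulin around
#' chromosomes); means for concentration-like readouts.
#'
#' @param img 2D matrix (X, Y) or 3D array (X, Y, Z).
#' @param roi either a list with `x` and `y` (each length-2 inclusive pixel
#'   ranges, 1-based) or a logical mask matching the XY dimensions.
#' @param mode "single_plane" or "sum_z".
#' @param plane plane index for `single_plane` on a 3D input.
#' @param integrate with `sum_z`: sum over the ROI instead of averaging.
#' @return scalar intensity (arbitrary units).
#' @export
measure_roi <- function(img, roi, mode = c("single_plane", "sum_z"),
                        plane = NULL, integrate = FALSE) {
  mode <- match.arg(mode)
  if (mode == "single_plane") {
    if (length(dim(img)) == 3) {
      if (is.null(plane)) stop("single_plane mode on a 3D stack needs `plane`")
      img <- img[, , plane]
    }
  } else {
    if (length(dim(img)) != 3) stop("sum_z mode needs a 3D stack")
    img <- apply(img, c(1, 2), sum)
  }
  mask <- roi_mask(roi, dim(img))
  vals <- img[mask]
  if (length(vals) == 0) stop("empty ROI")
  if (mode == "sum_z" && integrate) sum(vals) else mean(vals)
}

roi_mask <- function(roi, dm) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == dm)) stop("ROI mask does not match image dimensions")
    return(roi)
  }
  if (!all(c("x", "y") %in% names(roi))) {
    stop("ROI must be a logical mask or a list with x and y ranges")
  }
  if (roi$x[1] < 1 || roi$x[2] > dm[1] || roi$y[1] < 1 || roi$y[2] > dm[2] ||
      roi$x[1] > roi$x[2] || roi$y[1] > roi$y[2]) {
    stop("ROI outside image bounds")
  }
  m <- matrix(FALSE, dm[1], dm[2])
  m[roi$x[1]:roi$x[2], roi$y[1]:roi$y[2]] <- TRUE
  m
}

#' Intensity profile along a line (linescan)
#'
#' Samples the image at pixel pitch along the segment from `p0` to `p1`,
#' averaging across `width_px` one-pixel-spaced offsets perpendicular to
#' the line, with bilinear interpolation. This is the 15-pixel-wide (or
#' one-pixel) linescan used for profiles along chromosomes.
#'
#' @param plane 2D matrix (X, Y).
#' @param p0,p1 line endpoints in pixel coordinates (length 2; pixel
#'   centres at integer coordinates).
#' @param width_px odd integer line width in pixels (default 1).
#' @return data.frame with `distance_px` along the line and `intensity`.
#' @export
linescan <- function(plane, p0, p1, width_px = 1) {
  if (width_px < 1 || width_px %% 2 != 1) {
    stop("width_px must be an odd positive integer")
  }
  d <- c(p1[1] - p0[1], p1[2] - p0[2])
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length line")
  u <- d / len
  n_perp <- c(-u[2], u[1])
  ts <- seq(0, len, by = 1)
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)
  prof <- vapply(ts, function(t) {
    pt <- c(p0[1], p0[2]) + t * u
    mean(vapply(offs, function(o) {
      bilinear(plane, pt[1] + o * n_perp[1], pt[2] + o * n_perp[2])
    }, numeric(1)))
  }, numeric(1))
  data.frame(distance_px = ts, intensity = prof)
}

bilinear <- function(img, x, y) {
  dm <- dim(img)
  x <- min(max(x, 1), dm[1])
  y <- min(max(y, 1), dm[2])
  x0 <- floor(x); y0 <- floor(y)
  x1 <- min(x0 + 1, dm[1]); y1 <- min(y0 + 1, dm[2])
  fx <- x - x0; fy <- y - y0
  img[x0, y0] * (1 - fx) * (1 - fy) + img[x1, y0] * fx * (1 - fy) +
    img[x0, y1] * (1 - fx) * fy + img[x1, y1] * fx * fy
}

#' Background-normalize an intensity series and scale to a control maximum
#'
#' Each raw value is background-subtracted and divided by the mean
#' cytoplasmic background, `(raw - background) / background`, making the
#' result invariant to global multiplicative gain. The background-normalized
#' series is then divided by the maximum background-normalized value of the
#' control series, so the control series itself peaks at exactly 1.
#'
#' @param raw numeric vector of raw intensities (a.u.).
#' @param background_mean mean cytoplasmic background of this series (> 0).
#' @param control raw control series; defaults to `raw` (self-normalization).
#' @param control_background background of the control series (defaults to
#'   `background_mean`).
#' @return numeric vector of normalized intensities.
#' @export
normalize_series <- function(raw, background_mean, control = raw,
                             control_background = background_mean) {
  if (background_mean <= 0 || control_background <= 0) {
    stop("background means must be positive")
  }
  bn <- (raw - background_mean) / background_mean
  ctrl_bn <- (control - control_background) / control_background
  cmax <- max(ctrl_bn)
  if (cmax <= 0) stop("control series has no signal above background")
  bn / cmax
}
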