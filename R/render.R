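#' Render a two-channel image stack from one oocyte's tracks
#'
#' Produces a synthetic acquisition: each homolog centroid becomes an
#' anisotropic Gaussian intensity blob in the chromatin channel; the
#' tubulin channel holds the two pole blobs plus a spindle-shaped
#' (pole-to-pole elongated Gaussian) background. Poisson shot noise plus
#' Gaussian read noise is scaled so that the blob peak amplitude over the
#' noise standard deviation at the peak equals `snr`; `snr = Inf` renders
#' noiselessly. Physical coordinates map to voxels with centres at
#' `origin + (index + 0.5) * spacing` (0-based indices).
#'
#' @param tracks tracks data.frame for a single oocyte.
#' @param geometry an [acquisition_geometry()]; frames rendered are the
#'   times present in `tracks`.
#' @param psf_sigma length-3 Gaussian blob sigma (x, y, z), um.
#' @param snr peak signal-to-noise ratio (> 0, may be `Inf`).
#' @param origin length-3 physical position (um) of the volume corner; by
#'   default chosen to cover the tracks with a margin.
#' @param fov_xy length-2 field of view (x, y extent, um) used with
#'   `origin`; tracks outside the volume are an error reporting the
#'   offending frame.
#' @param background mean background photon count.
#' @param seed RNG seed for the noise.
#' @return an `img_stack`: 5-D array with dim (X, Y, Z, channel, T) and
#'   attributes `origin`, `spacing` (x, y, z um), `times` (s), `channels`,
#'   `onset_index`.
#' @export
render_stack <- function(tracks, geometry = acquisition_geometry(),
                         psf_sigma = c(0.2, 0.2, 0.3), snr = 10,
                         origin = NULL, fov_xy = NULL, background = 20,
                         seed = 1) {
  validate_tracks(tracks)
  stopifnot(all(psf_sigma > 0), snr > 0)
  if (length(unique(tracks$oocyte_id)) != 1) {
    stop("render_stack takes tracks of a single oocyte")
  }
  obj <- tracks[tracks$object_class %in% c("pole", "homolog"), ]
  times <- sort(unique(obj$time_s))
  nt <- length(times)
  sp <- c(geometry$dxy, geometry$dxy, geometry$dz)
  nz <- geometry$n_z
  if (is.null(origin)) {
    rx <- range(obj$x_um); ry <- range(obj$y_um); rz <- range(obj$z_um)
    margin <- 1.5
    zmid <- mean(rz)
    origin <- c(rx[1] - margin, ry[1] - margin, zmid - nz * sp[3] / 2)
    nx <- ceiling((diff(rx) + 2 * margin) / sp[1])
    ny <- ceiling((diff(ry) + 2 * margin) / sp[2])
  } else {
    stopifnot(length(fov_xy) == 2)
    nx <- ceiling(fov_xy[1] / sp[1])
    ny <- ceiling(fov_xy[2] / sp[2])
  }
  hi <- origin + c(nx, ny, nz) * sp
  out_x <- obj$x_um < origin[1] | obj$x_um > hi[1]
  out_y <- obj$y_um < origin[2] | obj$y_um > hi[2]
  out_z <- obj$z_um < origin[3] | obj$z_um > hi[3]
  if (any(out_x | out_y | out_z)) {
    bad <- obj$time_s[which(out_x | out_y | out_z)[1]]
    stop("tracks extend outside the rendered volume at time ", bad, " s")
  }

  amp <- if (is.infinite(snr)) 1000 else {
    (snr^2 + snr * sqrt(snr^2 + 4 * background)) / 2
  }
  # voxel-centre coordinate vectors
  xs <- origin[1] + (seq_len(nx) - 0.5) * sp[1]
  ys <- origin[2] + (seq_len(ny) - 0.5) * sp[2]
  zs <- origin[3] + (seq_len(nz) - 0.5) * sp[3]

  img <- array(background, c(nx, ny, nz, 2, nt))
  for (k in seq_len(nt)) {
    fr <- obj[obj$time_s == times[k], ]
    homs <- fr[fr$object_class == "homolog", ]
    chrom <- array(0, c(nx, ny, nz))
    for (i in seq_len(nrow(homs))) {
      chrom <- add_blob(chrom, xs, ys, zs,
                        c(homs$x_um[i], homs$y_um[i], homs$z_um[i]),
                        psf_sigma, amp)
    }
    poles <- fr[fr$object_class == "pole", ]
    tub <- array(0, c(nx, ny, nz))
    for (i in seq_len(nrow(poles))) {
      tub <- add_blob(tub, xs, ys, zs,
                      c(poles$x_um[i], poles$y_um[i], poles$z_um[i]),
                      psf_sigma, amp)
    }
    if (nrow(poles) == 2) {
      pa <- as.numeric(poles[poles$pole_id == "A", c("x_um", "y_um", "z_um")])
      pb <- as.numeric(poles[poles$pole_id == "B", c("x_um", "y_um", "z_um")])
      tub <- tub + spindle_cloud(xs, ys, zs, pa, pb, 0.35 * amp)
    }
    img[, , , 1, k] <- img[, , , 1, k] + chrom
    img[, , , 2, k] <- img[, , , 2, k] + tub
  }
  if (!is.infinite(snr)) {
    img <- with_seed(seed, {
      array(stats::rpois(length(img), img) + stats::rnorm(length(img), 0, 1),
            dim(img))
    })
  }
  structure(img, origin = origin, spacing = sp, times = times,
            channels = geometry$channels,
            onset_index = geometry$t_onset_index, class = "img_stack")
}

# add an axis-aligned anisotropic Gaussian blob, evaluated on a +/- 4 sigma
# window
add_blob <- function(arr, xs, ys, zs, center, sigma, amp) {
  ix <- which(abs(xs - center[1]) <= 4 * sigma[1])
  iy <- which(abs(ys - center[2]) <= 4 * sigma[2])
  iz <- which(abs(zs - center[3]) <= 4 * sigma[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(arr)
  gx <- exp(-(xs[ix] - center[1])^2 / (2 * sigma[1]^2))
  gy <- exp(-(ys[iy] - center[2])^2 / (2 * sigma[2]^2))
  gz <- exp(-(zs[iz] - center[3])^2 / (2 * sigma[3]^2))
  arr[ix, iy, iz] <- arr[ix, iy, iz] + amp * (gx %o% gy %o% gz)
  arr
}

# elongated Gaussian between the poles (the bulk tubulin signal)
spindle_cloud <- function(xs, ys, zs, pole_a, pole_b, amp,
                          sigma_perp = 0.6) {
  m <- (pole_a + pole_b) / 2
  d <- pole_b - pole_a
  L <- sqrt(sum(d^2))
  u <- d / L
  sigma_ax <- L / 4
  gx <- outer(xs - m[1], ys - m[2], function(a, b) a * u[1] + b * u[2])
  along <- outer(gx, (zs - m[3]) * u[3], `+`)
  r2 <- outer(outer((xs - m[1])^2, (ys - m[2])^2, `+`), (zs - m[3])^2, `+`)
  perp2 <- pmax(r2 - along^2, 0)
  amp * exp(-along^2 / (2 * sigma_ax^2) - perp2 / (2 * sigma_perp^2))
}

#' Write an image stack as multi-page TIFF plus a YAML sidecar
#'
#' Pages are written in T, C, Z order (Z fastest), each page a Y-by-X
#' matrix. Intensities are scaled to [0, 1] by the stack maximum; the scale
#' factor and all physical metadata (spacings, frame interval, times,
#' channel roles, onset index, origin) go to the sidecar.
#'
#' @param stack an `img_stack` from [render_stack()].
#' @param path TIFF output path.
#' @param sidecar YAML output path (default `path` with .yaml).
#' @param dt frame interval recorded in the sidecar, s.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = NULL, dt = 10) {
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".yaml", path)
  d <- dim(stack)
  scale <- max(stack, 1e-12)
  pages <- list()
  for (k in seq_len(d[5])) for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    pages[[length(pages) + 1]] <- t(pmax(stack[, , z, ch, k], 0)) / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    axes = "TCZYX", n_x = d[1], n_y = d[2], n_z = d[3],
    n_channels = d[4], n_t = d[5],
    spacing_um = as.numeric(attr(stack, "spacing")),
    origin_um = as.numeric(attr(stack, "origin")),
    dt_s = dt, times_s = as.numeric(attr(stack, "times")),
    channels = as.character(attr(stack, "channels")),
    onset_index = attr(stack, "onset_index"),
    intensity_scale = scale
  )
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param sidecar YAML sidecar path (default derived from `path`).
#' @return an `img_stack` (intensities rescaled to the original values).
#' @export
read_stack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.tiff?$", ".yaml", path)
  meta <- yaml::read_yaml(sidecar)
  pages <- tiff::readTIFF(path, all = TRUE)
  img <- array(0, c(meta$n_x, meta$n_y, meta$n_z, meta$n_channels, meta$n_t))
  i <- 0
  for (k in seq_len(meta$n_t)) {
    for (ch in seq_len(meta$n_channels)) {
      for (z in seq_len(meta$n_z)) {
        i <- i + 1
        img[, , z, ch, k] <- t(pages[[i]]) * meta$intensity_scale
      }
    }
  }
  structure(img, origin = meta$origin_um, spacing = meta$spacing_um,
            times = meta$times_s, channels = meta$channels,
            onset_index = meta$onset_index, class = "img_stack")
}
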