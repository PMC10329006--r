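#' Build the per-timepoint spindle reference frame
#'
#' The spindle frame is defined by the two pole positions: the unit long-axis
#' vector points from pole A to pole B, and the equator is the plane through
#' the pole-pole midpoint perpendicular to that axis. All chromosome metrics
#' (orientation angle, congression distance, axial-compaction distance) are
#' expressed in this frame, which is re-derived at every frame because the
#' spindle rotates and shortens over time.
#'
#' @param pole_a,pole_b numeric length-3 positions in micrometres.
#' @param t time in seconds (relative to anaphase onset), carried through for
#'   bookkeeping.
#' @return An object of class `spindle_frame`: a list with `pole_a`, `pole_b`,
#'   `u` (unit axis A to B), `m` (equator centre), `length` (pole-pole
#'   distance, um) and `t`.
#' @examples
#' sf <- spindle_frame(c(0, 0, 0), c(10, 0, 0))
#' sf$u      # c(1, 0, 0)
#' sf$length # 10
#' @export
spindle_frame <- function(pole_a, pole_b, t = NA_real_) {
  pole_a <- as.numeric(pole_a)
  pole_b <- as.numeric(pole_b)
  stopifnot(length(pole_a) == 3, length(pole_b) == 3)
  d <- pole_b - pole_a
  L <- sqrt(sum(d^2))
  if (!is.finite(L) || L == 0) {
    stop("degenerate spindle: coincident poles")
  }
  structure(
    list(pole_a = pole_a, pole_b = pole_b, u = d / L,
         m = (pole_a + pole_b) / 2, length = L, t = t),
    class = "spindle_frame"
  )
}

#' @export
print.spindle_frame <- function(x, ...) {
  cat(sprintf("<spindle_frame> t = %s s, L = %.3f um, u = (%.3f, %.3f, %.3f)\n",
              format(x$t), x$length, x$u[1], x$u[2], x$u[3]))
  invisible(x)
}

#' Bivalent orientation angle relative to the spindle long axis
#'
#' The bivalent axis is the vector from homolog 1 to homolog 2 (centroids).
#' `theta_labeled` is the angle between that vector and the pole-A-to-pole-B
#' axis, in degrees within [0, 180]; it depends on the homolog labelling and
#' is the quantity used to detect orientation reversions (crossings of 90
#' degrees, i.e. the homologs swapping pole-facing identity). `theta_folded`
#' = min(theta, 180 - theta) is label-free, lives in [0, 90], and is the
#' quantity compared against the orientation threshold.
#'
#' @param homolog1,homolog2 numeric length-3 homolog centroid positions (um).
#' @param frame a [spindle_frame()].
#' @return list with `theta_labeled` and `theta_folded`, both in degrees;
#'   both `NA` (undefined angle) if the homolog centroids coincide.
#' @export
orientation_angle <- function(homolog1, homolog2, frame) {
  v <- as.numeric(homolog2) - as.numeric(homolog1)
  nv <- sqrt(sum(v^2))
  if (is.na(nv) || nv == 0) {
    return(list(theta_labeled = NA_real_, theta_folded = NA_real_))
  }
  ct <- sum(v * frame$u) / nv
  ct <- min(1, max(-1, ct))
  th <- acos(ct) * 180 / pi
  list(theta_labeled = th, theta_folded = min(th, 180 - th))
}

#' Distance from the spindle equator plane
#'
#' Absolute distance of a point (typically the bivalent centroid, the mean of
#' the two homolog centroids) from the plane through the spindle midpoint
#' perpendicular to the long axis. This is the congression metric.
#'
#' @param centroid numeric length-3 position (um).
#' @param frame a [spindle_frame()].
#' @return distance in micrometres.
#' @export
equator_distance <- function(centroid, frame) {
  abs(sum((as.numeric(centroid) - frame$m) * frame$u))
}

#' Distance from the spindle long axis
#'
#' Perpendicular distance of a point from the line through the two poles;
#' the axial-compaction metric.
#'
#' @inheritParams equator_distance
#' @return distance in micrometres.
#' @export
axis_distance <- function(centroid, frame) {
  d <- as.numeric(centroid) - frame$m
  p <- sum(d * frame$u)
  sqrt(max(sum(d^2) - p^2, 0))
}

#' Signed coordinate along the spindle axis
#'
#' Projection of (position - equator centre) onto the long-axis unit vector;
#' negative values lie on the pole-A side. Used by the anaphase fate
#' classifier to decide which spindle half a homolog ends up in.
#'
#' @inheritParams equator_distance
#' @param position numeric length-3 position (um).
#' @return signed distance in micrometres.
#' @export
equator_coordinate <- function(position, frame) {
  sum((as.numeric(position) - frame$m) * frame$u)
}

#' Chromosome oscillation series
#'
#' Oscillation is quantified by subtracting the distance of the bivalent
#' centre from the spindle equator from the same distance one frame interval
#' later and taking absolute values. A series of n distances yields n - 1
#' oscillation values, aligned with the first frame of each pair.
#'
#' @param d_eq numeric vector of equator distances (um) sampled every `dt` s.
#' @param dt frame interval in seconds (bookkeeping only; the lag is one
#'   sample).
#' @return numeric vector of length `length(d_eq) - 1` (empty for a
#'   single-frame series).
#' @export
oscillation <- function(d_eq, dt = 10) {
  if (length(d_eq) < 2) return(numeric(0))
  abs(diff(d_eq))
}

#' Bivalent stretching metrics
#'
#' From the four endpoint markers of a bivalent (two per homolog) computes
#' the homolog lengths (endpoint-to-endpoint within a homolog), the
#' inter-homolog distance (between homolog endpoint midpoints) and the
#' bivalent length, defined as the maximum pairwise distance among the four
#' endpoints, i.e. the outermost end-to-end extent of the bivalent.
#'
#' @param hom1_ends,hom2_ends 2 x 3 matrices of endpoint positions (um), one
#'   row per endpoint.
#' @return list with `L_hom1`, `L_hom2`, `d_IH`, `L_biv` in micrometres; all
#'   `NA` if any endpoint is missing.
#' @export
stretch_metrics <- function(hom1_ends, hom2_ends) {
  if (anyNA(hom1_ends) || anyNA(hom2_ends) ||
      nrow(hom1_ends) != 2 || nrow(hom2_ends) != 2) {
    return(list(L_hom1 = NA_real_, L_hom2 = NA_real_,
                d_IH = NA_real_, L_biv = NA_real_))
  }
  dist3 <- function(a, b) sqrt(sum((a - b)^2))
  c1 <- colMeans(hom1_ends)
  c2 <- colMeans(hom2_ends)
  pts <- rbind(hom1_ends, hom2_ends)
  list(
    L_hom1 = dist3(hom1_ends[1, ], hom1_ends[2, ]),
    L_hom2 = dist3(hom2_ends[1, ], hom2_ends[2, ]),
    d_IH = dist3(c1, c2),
    L_biv = max(stats::dist(pts))
  )
}

#' Detect orientation reversion events
#'
#' A reversion is a crossing of the labeled orientation angle from below 90
#' degrees to above 90 degrees that persists for at least `persistence`
#' consecutive frames -- the signature of the two homologs swapping
#' pole-facing identity. Transient single-frame spikes are not counted.
#' Frames with undefined angles break any candidate run.
#'
#' @param theta_labeled numeric vector of labeled angles (degrees, [0, 180])
#'   with fixed homolog/pole identities.
#' @param persistence minimum number of consecutive frames above 90 degrees
#'   (default 3).
#' @return list with `events` (integer indices of the first frame of each
#'   persistent crossing) and `n_events`.
#' @export
detect_reversion <- function(theta_labeled, persistence = 3) {
  above <- theta_labeled > 90
  above[is.na(above)] <- FALSE
  events <- integer(0)
  n <- length(above)
  i <- 1
  while (i <= n) {
    if (above[i] && (i == 1 || !above[i - 1])) {
      run <- i
      while (run < n && above[run + 1]) run <- run + 1
      run_len <- run - i + 1
      # only count crossings from below, not series that start reverted
      if (run_len >= persistence && i > 1) events <- c(events, i)
      i <- run + 1
    } else {
      i <- i + 1
    }
  }
  list(events = events, n_events = length(events))
}

#' Compute the full per-bivalent metric table from point tracks
#'
#' For every oocyte and frame, rebuilds the spindle frame from the two pole
#' positions and computes, per bivalent: the labeled and folded orientation
#' angles, distance to the spindle equator, distance to the spindle long
#' axis, the oscillation series, signed equator coordinates of both
#' homologs, and (when endpoint markers are present) the stretching metrics.
#' Homolog labels are fixed so that homolog 1 is the homolog nearer pole A
#' at the first frame where both homologs are tracked.
#'
#' @param tracks a tracks data.frame in the package schema (see
#'   [read_tracks()]): columns `oocyte_id`, `condition`, `time_s`,
#'   `object_class` in pole/homolog/endpoint, `pole_id`, `bivalent_id`,
#'   `homolog_id`, `endpoint_id`, `x_um`, `y_um`, `z_um`.
#' @return a data.frame with one row per oocyte x bivalent x frame and
#'   columns `oocyte_id`, `condition`, `bivalent_id`, `time_s`,
#'   `theta_labeled`, `theta_folded`, `d_eq`, `d_ax`, `osc`, `s_hom1`,
#'   `s_hom2`, `L_hom1`, `L_hom2`, `d_IH`, `L_biv`. `osc` is `NA` at each
#'   bivalent's last frame; stretching columns are `NA` without endpoints.
#' @export
compute_metrics <- function(tracks) {
  validate_tracks(tracks)
  out <- lapply(split(tracks, tracks$oocyte_id), compute_metrics_one)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

compute_metrics_one <- function(tr) {
  times <- sort(unique(tr$time_s))
  nt <- length(times)
  pos_series <- function(sub) {
    m <- matrix(NA_real_, nt, 3)
    idx <- match(sub$time_s, times)
    m[idx, ] <- as.matrix(sub[, c("x_um", "y_um", "z_um")])
    m
  }
  poles <- tr[tr$object_class == "pole", ]
  if (!all(c("A", "B") %in% poles$pole_id)) {
    stop("oocyte ", tr$oocyte_id[1], ": need pole tracks labelled A and B")
  }
  pA <- pos_series(poles[poles$pole_id == "A", ])
  pB <- pos_series(poles[poles$pole_id == "B", ])
  axis <- pB - pA
  L <- sqrt(rowSums(axis^2))
  u <- axis / L
  m <- (pA + pB) / 2

  homs <- tr[tr$object_class == "homolog", ]
  ends <- tr[tr$object_class == "endpoint", ]
  res <- list()
  for (bid in sort(unique(homs$bivalent_id))) {
    h1 <- pos_series(homs[homs$bivalent_id == bid & homs$homolog_id == 1, ])
    h2 <- pos_series(homs[homs$bivalent_id == bid & homs$homolog_id == 2, ])
    ok <- stats::complete.cases(h1) & stats::complete.cases(h2) &
      stats::complete.cases(u)
    if (!any(ok)) next
    # fix labels: homolog 1 is nearer pole A at the first tracked frame
    f0 <- which(ok)[1]
    if (sum((h1[f0, ] - pA[f0, ])^2) > sum((h2[f0, ] - pA[f0, ])^2)) {
      tmp <- h1; h1 <- h2; h2 <- tmp
    }
    v <- h2 - h1
    nv <- sqrt(rowSums(v^2))
    ct <- rowSums(v * u) / nv
    ct <- pmin(1, pmax(-1, ct))
    th <- acos(ct) * 180 / pi
    th[!is.finite(nv) | nv == 0] <- NA_real_
    cen <- (h1 + h2) / 2
    d <- cen - m
    proj <- rowSums(d * u)
    d_eq <- abs(proj)
    d_ax <- sqrt(pmax(rowSums(d^2) - proj^2, 0))
    s1 <- rowSums((h1 - m) * u)
    s2 <- rowSums((h2 - m) * u)
    osc <- c(abs(diff(d_eq)), NA_real_)

    # d_IH is the homolog-centroid distance and needs no endpoint markers;
    # homolog and bivalent lengths do.
    st <- matrix(NA_real_, nt, 3,
                 dimnames = list(NULL, c("L_hom1", "L_hom2", "L_biv")))
    eb <- ends[ends$bivalent_id == bid, ]
    if (nrow(eb) > 0) {
      ep <- lapply(1:2, function(h) lapply(1:2, function(e) {
        pos_series(eb[eb$homolog_id == h & eb$endpoint_id == e, ])
      }))
      for (ti in seq_len(nt)) {
        e11 <- ep[[1]][[1]][ti, ]; e12 <- ep[[1]][[2]][ti, ]
        e21 <- ep[[2]][[1]][ti, ]; e22 <- ep[[2]][[2]][ti, ]
        sm <- stretch_metrics(rbind(e11, e12), rbind(e21, e22))
        st[ti, ] <- c(sm$L_hom1, sm$L_hom2, sm$L_biv)
      }
    }
    keep <- ok # frames with undefined angles stay, flagged NA
    res[[length(res) + 1]] <- data.frame(
      oocyte_id = tr$oocyte_id[1], condition = tr$condition[1],
      bivalent_id = bid, time_s = times,
      theta_labeled = th, theta_folded = pmin(th, 180 - th),
      d_eq = d_eq, d_ax = d_ax, osc = osc, s_hom1 = s1, s_hom2 = s2,
      L_hom1 = st[, 1], L_hom2 = st[, 2], d_IH = nv, L_biv = st[, 3]
    )[keep, ]
  }
  do.call(rbind, res)
}
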