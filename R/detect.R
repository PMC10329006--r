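# ---- separable 3D filtering -------------------------------------------------

# convolve a 3D array along dimension `d` with a symmetric kernel,
# replicate-padding the edges
conv_dim <- function(a, k, d) {
  dm <- dim(a)
  ord <- c(d, setdiff(1:3, d))
  m <- matrix(aperm(a, ord), dm[d])
  kl <- (length(k) - 1) / 2
  mp <- rbind(m[rep(1, kl), , drop = FALSE], m,
              m[rep(nrow(m), kl), , drop = FALSE])
  out <- stats::filter(mp, k, sides = 2)
  out <- out[(kl + 1):(kl + nrow(m)), , drop = FALSE]
  aperm(array(out, dm[ord]), order(ord))
}

gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- stats::dnorm(-r:r, sd = max(sigma_vox, 1e-6))
  k / sum(k)
}

gauss_smooth3 <- function(a, sigma_vox) {
  for (d in 1:3) a <- conv_dim(a, gauss_kernel(sigma_vox[d]), d)
  a
}

# physical-units Laplacian by central second differences
laplacian3 <- function(a, spacing) {
  out <- conv_dim(a, c(1, -2, 1), 1) / spacing[1]^2
  out <- out + conv_dim(a, c(1, -2, 1), 2) / spacing[2]^2
  out + conv_dim(a, c(1, -2, 1), 3) / spacing[3]^2
}

# 3x3x3 neighbourhood maximum by sequential axis dilation
maxfilter3 <- function(a) {
  dil <- function(a, d) {
    dm <- dim(a)
    idx_lo <- c(1, seq_len(dm[d] - 1))
    idx_hi <- c(seq_len(dm[d] - 1) + 1, dm[d])
    sl <- function(i) switch(d, a[i, , , drop = FALSE],
                             a[, i, , drop = FALSE], a[, , i, drop = FALSE])
    pmax(a, sl(idx_lo), sl(idx_hi))
  }
  for (d in 1:3) a <- dil(a, d)
  a
}

# ---- spot detection ---------------------------------------------------------

#' Detect chromosome spots in one 3D frame by Laplacian-of-Gaussian filtering
#'
#' Scale-normalized LoG blob detection on anisotropic voxels: the frame is
#' smoothed with Gaussians whose physical sigma spans a small scale range
#' starting at `min_diameter / (2 * sqrt(3))` (the sigma at which a 3D blob
#' of that diameter responds maximally), the negative scale-normalized
#' Laplacian is computed in physical units, and local maxima across space
#' and scale with normalized response at or above `intensity_threshold` are
#' kept, with non-maximum suppression at half the detected diameter.
#' Positions are refined to sub-voxel precision by the intensity-weighted
#' centroid of the background-subtracted neighbourhood one diameter wide,
#' and returned in physical micrometres.
#'
#' @param frame 3D numeric array (X, Y, Z voxel order).
#' @param spacing length-3 voxel size (x, y, z), um; `spacing[3]` (the Z
#'   step) must be known for anisotropy to be accounted for.
#' @param min_diameter detection threshold diameter, um (default 0.8, the
#'   value used for chromosome spotting); must be at least 2 XY pixels.
#' @param intensity_threshold relative response cutoff in (0, 1), as a
#'   fraction of the strongest response in the frame.
#' @param origin physical position of the volume corner, um.
#' @param n_scales number of LoG scales.
#' @return data.frame with `x_um`, `y_um`, `z_um`, `intensity` (LoG
#'   response), `diameter_um`; zero rows for a blank frame.
#' @export
detect_spots <- function(frame, spacing, min_diameter = 0.8,
                         intensity_threshold = 0.1, origin = c(0, 0, 0),
                         n_scales = 3) {
  stopifnot(length(dim(frame)) == 3, length(spacing) == 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacings (including dz) must be known and positive")
  }
  if (min_diameter < 2 * spacing[1]) {
    stop("min_diameter must be at least 2 XY pixels")
  }
  sigma0 <- min_diameter / (2 * sqrt(3))
  sigmas <- sigma0 * 1.35^(seq_len(n_scales) - 1)
  peaks <- list()
  noise_floor <- 0
  for (s in sigmas) {
    # never smooth below 0.8 voxel: coarsely sampled axes (typically Z)
    # would otherwise pass shot noise straight into the Laplacian
    sm <- gauss_smooth3(frame, pmax(s / spacing, 0.8))
    resp <- -s^2 * laplacian3(sm, spacing)
    noise_floor <- max(noise_floor, 10 * stats::mad(resp))
    mx <- maxfilter3(resp)
    idx <- which(resp >= mx & resp > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      # drop maxima inside the filter support of the volume boundary, where
      # the padded convolution inflates the response
      dm <- dim(frame)
      rb <- pmax(ceiling(2 * pmax(s / spacing, 0.8)), 1)
      inside <- idx[, 1] > rb[1] & idx[, 1] <= dm[1] - rb[1] &
        idx[, 2] > rb[2] & idx[, 2] <= dm[2] - rb[2] &
        idx[, 3] > rb[3] & idx[, 3] <= dm[3] - rb[3]
      idx <- idx[inside, , drop = FALSE]
    }
    if (nrow(idx) > 0) {
      peaks[[length(peaks) + 1]] <- data.frame(
        i = idx[, 1], j = idx[, 2], k = idx[, 3],
        resp = resp[idx], sigma = s
      )
    }
  }
  if (length(peaks) == 0) return(empty_spotset())
  pk <- do.call(rbind, peaks)
  pk <- pk[pk$resp >= max(intensity_threshold * max(pk$resp), noise_floor), ]
  if (nrow(pk) == 0) return(empty_spotset())
  # physical coordinates of the voxel centres
  pk$x <- origin[1] + (pk$i - 0.5) * spacing[1]
  pk$y <- origin[2] + (pk$j - 0.5) * spacing[2]
  pk$z <- origin[3] + (pk$k - 0.5) * spacing[3]
  # non-maximum suppression across scales and neighbours; the radius uses
  # the larger of the two candidate diameters, so a weak large-scale
  # "bridge" response between two resolved blobs is absorbed by them
  pk <- pk[order(-pk$resp), ]
  keep <- rep(TRUE, nrow(pk))
  diam <- 2 * pk$sigma * sqrt(3)
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      later <- (i + 1):nrow(pk)
      d2 <- (pk$x[later] - pk$x[i])^2 + (pk$y[later] - pk$y[i])^2 +
        (pk$z[later] - pk$z[i])^2
      rad <- pmax(diam[later], diam[i]) / 2
      keep[later][d2 < rad^2] <- FALSE
    }
  }
  pk <- pk[keep, ]
  # sub-voxel refinement by intensity-weighted centroid
  dm <- dim(frame)
  ref <- t(vapply(seq_len(nrow(pk)), function(r) {
    rad <- pmax(1, ceiling(pk$sigma[r] * sqrt(3) / spacing))
    ii <- max(1, pk$i[r] - rad[1]):min(dm[1], pk$i[r] + rad[1])
    jj <- max(1, pk$j[r] - rad[2]):min(dm[2], pk$j[r] + rad[2])
    kk <- max(1, pk$k[r] - rad[3]):min(dm[3], pk$k[r] + rad[3])
    w <- frame[ii, jj, kk] - min(frame[ii, jj, kk])
    tw <- sum(w)
    if (tw == 0) {
      return(c(pk$x[r], pk$y[r], pk$z[r]))
    }
    cx <- sum(apply(w, 1, sum) * (origin[1] + (ii - 0.5) * spacing[1])) / tw
    cy <- sum(apply(w, 2, sum) * (origin[2] + (jj - 0.5) * spacing[2])) / tw
    cz <- sum(apply(w, 3, sum) * (origin[3] + (kk - 0.5) * spacing[3])) / tw
    c(cx, cy, cz)
  }, numeric(3)))
  data.frame(x_um = ref[, 1], y_um = ref[, 2], z_um = ref[, 3],
             intensity = pk$resp, diameter_um = 2 * pk$sigma * sqrt(3))
}

empty_spotset <- function() {
  data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             intensity = numeric(0), diameter_um = numeric(0))
}

#' Locate the two spindle poles
#'
#' If explicit coordinates are supplied they are passed through unchanged,
#' except that A/B labels are kept consistent across frames by
#' nearest-previous-position matching. Otherwise the poles are estimated
#' from the tubulin intensity distribution: intensity-weighted principal
#' component analysis defines the spindle long axis, and the poles are
#' placed at the 2nd and 98th intensity-weighted percentiles of the voxel
#' positions projected on that axis.
#'
#' @param frame 3D tubulin array, or `NULL` when `points` is given.
#' @param spacing,origin voxel geometry (um), as in [detect_spots()].
#' @param points optional 2 x 3 matrix of user-supplied pole positions
#'   (rows A, B).
#' @param prev optional 2 x 3 matrix of the previous frame's labelled poles,
#'   used to keep labels consistent.
#' @return 2 x 3 matrix with rownames A, B.
#' @export
identify_poles <- function(frame = NULL, spacing = NULL, origin = c(0, 0, 0),
                           points = NULL, prev = NULL) {
  if (!is.null(points)) {
    stopifnot(nrow(points) == 2)
    est <- as.matrix(points)
  } else {
    stopifnot(!is.null(frame), !is.null(spacing))
    dm <- dim(frame)
    # denoise before weighting so shot noise cannot flatten the PCA
    sm <- gauss_smooth3(frame, c(2, 2, 1))
    thr <- stats::median(sm) + 3 * stats::mad(sm)
    w <- pmax(sm - thr, 0)
    if (sum(w) == 0) stop("no spindle axis: empty tubulin frame")
    xs <- origin[1] + (seq_len(dm[1]) - 0.5) * spacing[1]
    ys <- origin[2] + (seq_len(dm[2]) - 0.5) * spacing[2]
    zs <- origin[3] + (seq_len(dm[3]) - 0.5) * spacing[3]
    wx <- apply(w, 1, sum); wy <- apply(w, 2, sum); wz <- apply(w, 3, sum)
    mu <- c(sum(wx * xs), sum(wy * ys), sum(wz * zs)) / sum(w)
    # weighted covariance from the marginals plus cross terms
    idx <- which(w > 0, arr.ind = TRUE)
    ww <- w[idx]
    P <- cbind(xs[idx[, 1]], ys[idx[, 2]], zs[idx[, 3]])
    Pc <- sweep(P, 2, mu)
    cv <- crossprod(Pc * ww, Pc) / sum(ww)
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[1] < 2 * ev$values[2]) {
      stop("no spindle axis: tubulin intensity distribution is isotropic")
    }
    ax <- ev$vectors[, 1]
    proj <- drop(Pc %*% ax)
    o <- order(proj)
    cw <- cumsum(ww[o]) / sum(ww)
    q <- c(proj[o][which(cw >= 0.02)[1]], proj[o][which(cw >= 0.98)[1]])
    est <- rbind(mu + q[1] * ax, mu + q[2] * ax)
    # refine each pole onto the local intensity maximum (the percentile
    # along the axis underestimates the pole-pole extent by a fraction of
    # the spindle-body width)
    for (r in 1:2) {
      d2 <- rowSums(sweep(P, 2, est[r, ])^2)
      near <- d2 < 1.0^2
      if (any(near)) {
        est[r, ] <- colSums(P[near, , drop = FALSE] * ww[near]) /
          sum(ww[near])
      }
    }
  }
  if (!is.null(prev)) {
    d_keep <- sum((est[1, ] - prev[1, ])^2) + sum((est[2, ] - prev[2, ])^2)
    d_swap <- sum((est[1, ] - prev[2, ])^2) + sum((est[2, ] - prev[1, ])^2)
    if (d_swap < d_keep) est <- est[2:1, ]
  }
  rownames(est) <- c("A", "B")
  colnames(est) <- c("x_um", "y_um", "z_um")
  est
}

# ---- linking ----------------------------------------------------------------

#' Link per-frame spot sets into tracks
#'
#' Greedy mutual-nearest-neighbour linking: at each frame the closest
#' (active track, spot) pairs are joined in order of increasing distance,
#' subject to a displacement budget of `max_disp` um per elapsed frame.
#' Tracks missing a spot survive up to `max_gap` frames, with linear
#' position prediction across the gap; unlinked spots start new tracks.
#' Fragments are legal output, and no spot is ever assigned to two tracks
#' in the same frame.
#'
#' @param spots data.frame with `frame` (integer) and `x_um`, `y_um`,
#'   `z_um`; at least two frames.
#' @param max_disp maximum displacement per frame, um.
#' @param max_gap maximum number of consecutive missing frames.
#' @return data.frame with `track_id`, `frame`, `x_um`, `y_um`, `z_um`,
#'   `gap` (TRUE when the preceding frames of this track were closed over).
#' @export
link_tracks <- function(spots, max_disp = 1.0, max_gap = 2) {
  frames <- sort(unique(spots$frame))
  if (length(frames) < 2) stop("need at least 2 frames to link")
  cols <- c("x_um", "y_um", "z_um")
  active <- list() # each: id, pos, vel, last_frame
  done <- list()
  rows <- list()
  next_id <- 1L
  for (f in frames) {
    sp <- as.matrix(spots[spots$frame == f, cols, drop = FALSE])
    n_sp <- nrow(sp)
    assigned_track <- integer(0)
    assigned_spot <- integer(0)
    if (length(active) > 0 && n_sp > 0) {
      pred <- t(vapply(active, function(a) {
        a$pos + a$vel * (f - a$last_frame)
      }, numeric(3)))
      dmat <- outer(seq_len(nrow(pred)), seq_len(n_sp),
                    Vectorize(function(i, j) sqrt(sum((pred[i, ] - sp[j, ])^2))))
      budget <- vapply(active, function(a) max_disp * (f - a$last_frame),
                       numeric(1))
      repeat {
        dmin <- min(dmat)
        if (!is.finite(dmin)) break
        ij <- which(dmat == dmin, arr.ind = TRUE)[1, ]
        if (dmin > budget[ij[1]]) {
          dmat[ij[1], ] <- Inf
          next
        }
        assigned_track <- c(assigned_track, ij[1])
        assigned_spot <- c(assigned_spot, ij[2])
        dmat[ij[1], ] <- Inf
        dmat[, ij[2]] <- Inf
      }
    }
    new_active <- list()
    for (t_i in seq_along(active)) {
      a <- active[[t_i]]
      hit <- match(t_i, assigned_track)
      if (!is.na(hit)) {
        s_i <- assigned_spot[hit]
        gap <- (f - a$last_frame) > 1
        rows[[length(rows) + 1]] <- data.frame(
          track_id = a$id, frame = f, x_um = sp[s_i, 1], y_um = sp[s_i, 2],
          z_um = sp[s_i, 3], gap = gap)
        a$vel <- (sp[s_i, ] - a$pos) / (f - a$last_frame)
        a$pos <- sp[s_i, ]
        a$last_frame <- f
        new_active[[length(new_active) + 1]] <- a
      } else if (f - a$last_frame <= max_gap) {
        new_active[[length(new_active) + 1]] <- a
      } else {
        done[[length(done) + 1]] <- a
      }
    }
    if (n_sp > 0) {
      for (s_i in setdiff(seq_len(n_sp), assigned_spot)) {
        rows[[length(rows) + 1]] <- data.frame(
          track_id = next_id, frame = f, x_um = sp[s_i, 1],
          y_um = sp[s_i, 2], z_um = sp[s_i, 3], gap = FALSE)
        new_active[[length(new_active) + 1]] <- list(
          id = next_id, pos = sp[s_i, ], vel = c(0, 0, 0), last_frame = f)
        next_id <- next_id + 1L
      }
    }
    active <- new_active
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$track_id, out$frame), ]
}

# ---- homolog pairing --------------------------------------------------------

#' Pair homolog tracks into bivalents
#'
#' At `pairing_time` (a pre-onset frame where all 12 homologs are tracked),
#' finds the perfect matching of the 12 homolog positions minimizing the
#' total intra-pair distance (exact branch-and-bound enumeration), and
#' labels the pairs bivalent 1..6 ordered by distance of the pair centroid
#' to pole A.
#'
#' @param tracks linked homolog tracks from [link_tracks()].
#' @param pole_a pole A position at `pairing_time` (length 3, um).
#' @param pairing_time frame (integer, matching `tracks$frame`) at which to
#'   pair.
#' @return data.frame with `track_id`, `bivalent_id`, `homolog_id`
#'   (homolog 1 is the member nearer pole A).
#' @export
pair_homologs <- function(tracks, pole_a, pairing_time) {
  at <- tracks[tracks$frame == pairing_time, ]
  if (nrow(at) != 12) {
    cnt <- table(tracks$frame)
    stop("need exactly 12 homolog tracks alive at the pairing frame; got ",
         nrow(at), " (tracks per frame: ",
         paste(names(cnt), as.integer(cnt), sep = ":", collapse = " "), ")")
  }
  P <- as.matrix(at[, c("x_um", "y_um", "z_um")])
  D <- as.matrix(stats::dist(P))
  pairs <- min_weight_matching(D)
  cen_d <- vapply(pairs, function(pr) {
    sqrt(sum((colMeans(P[pr, ]) - pole_a)^2))
  }, numeric(1))
  pairs <- pairs[order(cen_d)]
  out <- do.call(rbind, lapply(seq_along(pairs), function(b) {
    pr <- pairs[[b]]
    dA <- c(sqrt(sum((P[pr[1], ] - pole_a)^2)),
            sqrt(sum((P[pr[2], ] - pole_a)^2)))
    if (dA[2] < dA[1]) pr <- rev(pr)
    data.frame(track_id = at$track_id[pr], bivalent_id = b, homolog_id = 1:2)
  }))
  rownames(out) <- NULL
  out
}

# exact minimum-weight perfect matching on a small even point set
min_weight_matching <- function(D) {
  n <- nrow(D)
  stopifnot(n %% 2 == 0)
  best <- list(cost = Inf, pairs = NULL)
  rec <- function(remaining, cost, pairs) {
    if (cost >= best$cost) return()
    if (length(remaining) == 0) {
      best <<- list(cost = cost, pairs = pairs)
      return()
    }
    i <- remaining[1]
    for (j in remaining[-1]) {
      rec(setdiff(remaining, c(i, j)), cost + D[i, j],
          c(pairs, list(c(i, j))))
    }
  }
  rec(seq_len(n), 0, list())
  best$pairs
}

# ---- full image-to-tracks pipeline -----------------------------------------

#' Recover point tracks from a rendered two-channel stack
#'
#' Runs spot detection on every chromatin frame, pole identification on
#' every tubulin frame, links the chromosome spots over time, pairs
#' homologs into bivalents at a pre-onset frame, and returns a tracks
#' data.frame in the package schema, directly comparable to simulator
#' ground truth.
#'
#' @param stack an `img_stack`.
#' @param oocyte_id,condition identifiers for the output table.
#' @param min_diameter,intensity_threshold see [detect_spots()].
#' @param max_disp,max_gap see [link_tracks()].
#' @param pairing_frame 1-based frame index at which to pair homologs
#'   (default: 5 frames before onset, clipped to the first frame).
#' @param edits optional data.frame of manual corrections applied after
#'   linking: columns `track_id`, `frame` (NA for all frames), `action`
#'   ("delete" drops the observation, "remap" with `new_track_id`
#'   relabels).
#' @return a tracks data.frame (`pole` and `homolog` rows).
#' @export
track_stack <- function(stack, oocyte_id = "oo001", condition = "unknown",
                        min_diameter = 0.8, intensity_threshold = 0.1,
                        max_disp = 1.0, max_gap = 2, pairing_frame = NULL,
                        edits = NULL) {
  sp <- attr(stack, "spacing")
  org <- attr(stack, "origin")
  times <- attr(stack, "times")
  chan <- attr(stack, "channels")
  ci <- match("chromatin", chan)
  ti <- match("tubulin", chan)
  nt <- dim(stack)[5]
  spots <- list()
  poles <- list()
  prev <- NULL
  for (k in seq_len(nt)) {
    s <- detect_spots(stack[, , , ci, k], sp, min_diameter,
                      intensity_threshold, org)
    if (nrow(s) > 0) s$frame <- k
    spots[[k]] <- s
    prev <- identify_poles(stack[, , , ti, k], sp, org, prev = prev)
    poles[[k]] <- prev
  }
  spots <- do.call(rbind, spots)
  tr <- link_tracks(spots, max_disp, max_gap)
  tr <- apply_edits(tr, edits)
  onset_1b <- attr(stack, "onset_index") %||% (nt - 1)
  if (is.null(pairing_frame)) {
    # earliest frame where all 12 homologs were observed: before
    # congression the bivalents are far apart, so intra-bivalent distances
    # are unambiguously the smallest and the matching is safe
    counts <- table(tr$frame)
    ok <- as.integer(names(counts))[counts == 12]
    ok <- ok[ok <= max(1, onset_1b + 1 - 2)]
    if (length(ok) == 0) {
      stop("no pre-onset frame with 12 homolog observations; ",
           "supply pairing_frame")
    }
    pairing_frame <- min(ok)
  }
  pairing <- pair_homologs(tr, poles[[pairing_frame]]["A", ], pairing_frame)
  tr <- merge(tr, pairing, by = "track_id")
  hom_rows <- data.frame(
    oocyte_id = oocyte_id, condition = condition, time_s = times[tr$frame],
    object_class = "homolog", pole_id = NA_character_,
    bivalent_id = tr$bivalent_id, homolog_id = tr$homolog_id,
    endpoint_id = NA_integer_, x_um = tr$x_um, y_um = tr$y_um,
    z_um = tr$z_um)
  pole_rows <- do.call(rbind, lapply(seq_len(nt), function(k) {
    data.frame(oocyte_id = oocyte_id, condition = condition,
               time_s = times[k], object_class = "pole",
               pole_id = c("A", "B"), bivalent_id = NA_integer_,
               homolog_id = NA_integer_, endpoint_id = NA_integer_,
               x_um = poles[[k]][, 1], y_um = poles[[k]][, 2],
               z_um = poles[[k]][, 3])
  }))
  out <- rbind(pole_rows, hom_rows)
  out <- out[order(out$object_class, out$bivalent_id, out$homolog_id,
                   out$pole_id, out$time_s), ]
  rownames(out) <- NULL
  out
}

# manual-correction hook standing in for interactive curation
apply_edits <- function(tr, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(tr)
  for (r in seq_len(nrow(edits))) {
    e <- edits[r, ]
    sel <- tr$track_id == e$track_id &
      (is.na(e$frame) | tr$frame == e$frame)
    if (identical(e$action, "delete")) {
      tr <- tr[!sel, ]
    } else if (identical(e$action, "remap")) {
      tr$track_id[sel] <- e$new_track_id
    } else {
      stop("unknown edit action: ", e$action)
    }
  }
  tr
}

# ---- evaluation against ground truth ---------------------------------------

#' Spot and track recovery scores against simulator ground truth
#'
#' Matches detected spots to true homolog positions frame by frame
#' (greedy nearest neighbour within `tol`), giving recall and precision,
#' and scores track identity agreement: the fraction of frame-to-frame
#' links whose two endpoints match the same true object.
#'
#' @param tracks linked tracks from [link_tracks()] (`track_id`, `frame`,
#'   positions).
#' @param truth data.frame of true positions: `frame`, `object` (identity
#'   label), `x_um`, `y_um`, `z_um`.
#' @param tol matching tolerance, um.
#' @return list with `recall`, `precision`, `identity_agreement`.
#' @export
evaluate_tracking <- function(tracks, truth, tol = 0.5) {
  n_true <- 0; n_det <- 0; n_match <- 0
  tracks$obj <- NA_character_
  for (f in unique(truth$frame)) {
    tt <- truth[truth$frame == f, ]
    dd_i <- which(tracks$frame == f)
    dd <- tracks[dd_i, ]
    n_true <- n_true + nrow(tt)
    n_det <- n_det + nrow(dd)
    if (nrow(dd) == 0) next
    D <- outer(seq_len(nrow(dd)), seq_len(nrow(tt)), Vectorize(function(i, j) {
      sqrt((dd$x_um[i] - tt$x_um[j])^2 + (dd$y_um[i] - tt$y_um[j])^2 +
             (dd$z_um[i] - tt$z_um[j])^2)
    }))
    repeat {
      dmin <- min(D)
      if (!is.finite(dmin) || dmin > tol) break
      ij <- which(D == dmin, arr.ind = TRUE)[1, ]
      n_match <- n_match + 1
      tracks$obj[dd_i[ij[1]]] <- tt$object[ij[2]]
      D[ij[1], ] <- Inf
      D[, ij[2]] <- Inf
    }
  }
  n_links <- 0; n_agree <- 0
  for (tid in unique(tracks$track_id)) {
    tk <- tracks[tracks$track_id == tid, ]
    tk <- tk[order(tk$frame), ]
    if (nrow(tk) < 2) next
    o <- tk$obj
    n_links <- n_links + nrow(tk) - 1
    n_agree <- n_agree + sum(!is.na(o[-1]) & !is.na(o[-length(o)]) &
                               o[-1] == o[-length(o)])
  }
  list(recall = n_match / n_true, precision = n_match / n_det,
       identity_agreement = if (n_links > 0) n_agree / n_links else NA_real_)
}
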