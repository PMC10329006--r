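#' Classification thresholds and fate-calling parameters
#'
#' Defaults carry the study's printed constants: chromosomes are properly
#' oriented below a 22.5 degree bivalent-spindle angle, properly congressed
#' below 0.5 um from the spindle equator, and properly compacted below
#' 1.6 um from the spindle long axis. Threshold comparisons are inclusive
#' (<=). The anaphase fate parameters (checkpoint and call times, the
#' segregated and lagging distance bands) parameterize the fate classifier.
#'
#' @param theta_max orientation threshold, degrees.
#' @param d_eq_max congression threshold, um.
#' @param d_ax_max axial-compaction threshold, um.
#' @param t_fate_check mid-anaphase checkpoint, s after onset.
#' @param t_fate_end fate-call time, s after onset.
#' @param d_seg distance from the equator beyond which a homolog counts as
#'   segregated, um.
#' @param d_lag half-width of the equatorial lagging band, um.
#' @param metaphase_window window (s, relative to onset) over which the
#'   congression/compaction calibration maxima are taken.
#' @return a `classification_config` list.
#' @export
classification_config <- function(theta_max = 22.5, d_eq_max = 0.5,
                                  d_ax_max = 1.6, t_fate_check = 60,
                                  t_fate_end = 120, d_seg = 2.0, d_lag = 1.0,
                                  metaphase_window = c(-100, 0)) {
  stopifnot(theta_max > 0, d_eq_max > 0, d_ax_max > 0, d_seg > 0, d_lag > 0,
            t_fate_check < t_fate_end)
  structure(list(theta_max = theta_max, d_eq_max = d_eq_max,
                 d_ax_max = d_ax_max, t_fate_check = t_fate_check,
                 t_fate_end = t_fate_end, d_seg = d_seg, d_lag = d_lag,
                 metaphase_window = metaphase_window),
            class = "classification_config")
}

#' Calibrate classification thresholds on a control cohort
#'
#' The orientation threshold is the mean over control oocytes of the
#' per-oocyte maximum folded angle at the anaphase-onset frame; the
#' congression and compaction thresholds are the means of the per-oocyte
#' maxima of the equator and long-axis distances over the metaphase window.
#' This mirrors how the reference thresholds (22.5 degrees, 0.5 um, 1.6 um)
#' were derived from control recordings. All other configuration fields
#' keep their defaults.
#'
#' @param metrics a metrics data.frame from [compute_metrics()] for the
#'   control cohort, with `time_s` zeroed on anaphase onset.
#' @param onset_time onset time in the metrics' clock (default 0 s).
#' @param config a [classification_config()] supplying the non-calibrated
#'   fields and the metaphase window.
#' @return a `classification_config` with calibrated `theta_max`,
#'   `d_eq_max`, `d_ax_max`.
#' @export
calibrate_thresholds <- function(metrics, onset_time = 0,
                                 config = classification_config()) {
  by_oocyte <- split(metrics, metrics$oocyte_id)
  tms <- sort(unique(metrics$time_s))
  dt_min <- if (length(tms) > 1) min(diff(tms)) else 1e-6
  per_max <- vapply(by_oocyte, function(m) {
    at_onset <- m[abs(m$time_s - onset_time) < dt_min / 2, ]
    if (nrow(at_onset) == 0 || all(is.na(at_onset$theta_folded))) {
      stop("missing onset annotation: no metrics at the onset frame for ",
           m$oocyte_id[1])
    }
    w <- m[m$time_s >= config$metaphase_window[1] + onset_time &
           m$time_s <= config$metaphase_window[2] + onset_time, ]
    c(theta = max(at_onset$theta_folded, na.rm = TRUE),
      d_eq = max(w$d_eq, na.rm = TRUE),
      d_ax = max(w$d_ax, na.rm = TRUE))
  }, numeric(3))
  config$theta_max <- mean(per_max["theta", ])
  config$d_eq_max <- mean(per_max["d_eq", ])
  config$d_ax_max <- mean(per_max["d_ax", ])
  config
}

#' Per-timepoint orientation/congression/compaction state
#'
#' Flags every bivalent at every frame as oriented (folded angle <=
#' `theta_max`), congressed (`d_eq` <= `d_eq_max`) and compacted (`d_ax` <=
#' `d_ax_max`), and computes cohort proportions per time bin with counts.
#' Frames with undefined angles are excluded from the orientation
#' denominator.
#'
#' @param metrics a metrics data.frame from [compute_metrics()].
#' @param config a [classification_config()].
#' @return list with `flags` (metrics plus logical columns `oriented`,
#'   `congressed`, `compacted`) and `proportions` (`time_s`, `metric`,
#'   `n_defined`, `n_below`, `proportion`).
#' @export
classify_timepoints <- function(metrics, config = classification_config()) {
  flags <- metrics
  flags$oriented <- metrics$theta_folded <= config$theta_max
  flags$congressed <- metrics$d_eq <= config$d_eq_max
  flags$compacted <- metrics$d_ax <= config$d_ax_max
  prop_of <- function(col, name) {
    agg <- lapply(split(flags[[col]], flags$time_s), function(x) {
      c(n_defined = sum(!is.na(x)), n_below = sum(x, na.rm = TRUE))
    })
    tm <- as.numeric(names(agg))
    m <- do.call(rbind, agg)
    data.frame(time_s = tm, metric = name, n_defined = m[, 1],
               n_below = m[, 2], proportion = m[, 2] / m[, 1])
  }
  props <- rbind(prop_of("oriented", "oriented"),
                 prop_of("congressed", "congressed"),
                 prop_of("compacted", "compacted"))
  rownames(props) <- NULL
  props <- props[order(props$metric, props$time_s), ]
  list(flags = flags, proportions = props)
}

#' Call anaphase segregation fates and oocyte ploidy
#'
#' Works on signed equator coordinates s(t) of each homolog (projection on
#' the pole-A-to-pole-B axis, negative on the A side). At the fate-call
#' time: a bivalent whose homologs sit on the same side with both
#' |s| >= `d_seg` is co-segregating; opposite sides with both |s| >= `d_seg`
#' is normal, unless a homolog lagged, in which case the bivalent is a
#' laggard that resolved correctly. A homolog counts as lagging when
#' |s| < `d_lag` at the mid-anaphase checkpoint while at least half of all
#' homologs in the oocyte have already cleared `d_seg`. Lagging homologs
#' that end on the partner's side, or never leave the lagging band, make the
#' bivalent a mis-segregating laggard. Bivalents whose tracks end before the
#' call time, or whose final geometry matches none of the rules, are
#' "uncallable" and excluded from ploidy with a warning. An oocyte is
#' euploid iff no bivalent is co-segregating or a mis-segregating laggard.
#'
#' @param tracks a tracks data.frame (poles + homologs required).
#' @param config a [classification_config()].
#' @param onset anaphase-onset time in the tracks' clock, s (default 0).
#' @return list with `fates` (oocyte_id, bivalent_id, category,
#'   theta_onset_deg), `oocytes` (oocyte_id, ploidy) and `config`.
#' @export
classify_fates <- function(tracks, config = classification_config(),
                           onset = 0) {
  validate_tracks(tracks)
  out <- lapply(split(tracks, tracks$oocyte_id), classify_fates_one,
                config = config, onset = onset)
  fates <- do.call(rbind, lapply(out, `[[`, "fates"))
  oocytes <- do.call(rbind, lapply(out, `[[`, "oocytes"))
  rownames(fates) <- rownames(oocytes) <- NULL
  if (any(fates$category == "uncallable")) {
    warning(sum(fates$category == "uncallable"),
            " bivalent(s) uncallable; excluded from ploidy")
  }
  list(fates = fates, oocytes = oocytes, config = config)
}

classify_fates_one <- function(tr, config, onset) {
  times <- sort(unique(tr$time_s))
  nearest <- function(t0) times[which.min(abs(times - t0))]
  dt_min <- if (length(times) > 1) min(diff(times)) else 1
  t_on <- nearest(onset)
  t_chk <- nearest(onset + config$t_fate_check)
  t_end <- nearest(onset + config$t_fate_end)
  covered <- abs(t_end - (onset + config$t_fate_end)) < dt_min / 2

  # nearest observation within 1.5 frames, so a single closed-over gap at a
  # checkpoint frame does not void the call
  pos_at <- function(sub, t0) {
    if (nrow(sub) == 0) return(rep(NA_real_, 3))
    d <- abs(sub$time_s - t0)
    i <- which.min(d)
    if (d[i] <= 1.5 * dt_min) {
      as.numeric(sub[i, c("x_um", "y_um", "z_um")])
    } else {
      rep(NA_real_, 3)
    }
  }
  poles <- tr[tr$object_class == "pole", ]
  frame_at <- function(t0) {
    spindle_frame(pos_at(poles[poles$pole_id == "A", ], t0),
                  pos_at(poles[poles$pole_id == "B", ], t0), t0)
  }
  f_on <- frame_at(t_on); f_chk <- frame_at(t_chk); f_end <- frame_at(t_end)

  homs <- tr[tr$object_class == "homolog", ]
  bids <- sort(unique(homs$bivalent_id))
  nb <- length(bids)
  s_chk <- s_end <- matrix(NA_real_, nb, 2)
  theta_on <- rep(NA_real_, nb)
  for (i in seq_len(nb)) {
    h <- lapply(1:2, function(j) {
      homs[homs$bivalent_id == bids[i] & homs$homolog_id == j, ]
    })
    p_on <- lapply(h, pos_at, t0 = t_on)
    theta_on[i] <- orientation_angle(p_on[[1]], p_on[[2]], f_on)$theta_folded
    for (j in 1:2) {
      s_chk[i, j] <- equator_coordinate(pos_at(h[[j]], t_chk), f_chk)
      s_end[i, j] <- equator_coordinate(pos_at(h[[j]], t_end), f_end)
    }
  }

  seg_frac <- mean(abs(s_chk) >= config$d_seg, na.rm = TRUE)
  lagging <- (abs(s_chk) < config$d_lag) & (seg_frac >= 0.5)
  category <- character(nb)
  for (i in seq_len(nb)) {
    s <- s_end[i, ]
    if (!covered || anyNA(s)) {
      category[i] <- "uncallable"
      next
    }
    both_seg <- all(abs(s) >= config$d_seg)
    same_side <- prod(sign(s)) > 0
    was_lagging <- any(lagging[i, ], na.rm = TRUE)
    in_band <- any(abs(s) < config$d_lag)
    category[i] <-
      if (was_lagging) {
        if (both_seg && !same_side) "lagging_correct"
        else if (same_side || in_band) "lagging_missegregated"
        else "uncallable"
      } else {
        if (both_seg && same_side) "co_segregating"
        else if (both_seg && !same_side) "normal"
        else "uncallable"
      }
  }
  callable <- category != "uncallable"
  ploidy <- if (any(category[callable] %in%
                    c("co_segregating", "lagging_missegregated"))) {
    "aneuploid"
  } else {
    "euploid"
  }
  list(fates = data.frame(oocyte_id = tr$oocyte_id[1], bivalent_id = bids,
                          category = category, theta_onset_deg = theta_on),
       oocytes = data.frame(oocyte_id = tr$oocyte_id[1], ploidy = ploidy))
}

#' Detect anaphase onset from the inter-homolog distance jump
#'
#' Cohesion release at anaphase onset produces an abrupt jump in the
#' inter-homolog distance. Per oocyte, the per-frame median of `d_IH` over
#' bivalents is differenced; onset is the first frame whose increment
#' exceeds the median plus `k` times the MAD of the pre-jump increments
#' (threshold refined once using only increments before the first
#' candidate).
#'
#' @param metrics a metrics data.frame with a `d_IH` column.
#' @param k MAD multiplier (default 5).
#' @return data.frame with `oocyte_id`, `onset_time_s` (time of the first
#'   elevated frame, in the metrics' clock) and `onset_index` (0-based frame
#'   index within the oocyte's frame list).
#' @export
onset_detect <- function(metrics, k = 5) {
  if (all(is.na(metrics$d_IH))) {
    stop("onset not detected; d_IH unavailable - supply onset explicitly")
  }
  res <- lapply(split(metrics, metrics$oocyte_id), function(m) {
    med <- vapply(split(m$d_IH, m$time_s),
                  function(x) stats::median(x, na.rm = TRUE), numeric(1))
    tm <- as.numeric(names(med))
    o <- order(tm)
    tm <- tm[o]; med <- med[o]
    inc <- diff(med)
    if (length(inc) < 3) stop("onset not detected; series too short")
    find <- function(base) {
      thr <- stats::median(base, na.rm = TRUE) +
        k * stats::mad(base, na.rm = TRUE)
      which(inc > thr)[1]
    }
    cand <- find(inc)
    if (!is.na(cand) && cand > 2) cand <- find(inc[seq_len(cand - 1)])
    if (is.na(cand)) {
      stop("onset not detected in ", m$oocyte_id[1], "; supply --onset")
    }
    data.frame(oocyte_id = m$oocyte_id[1], onset_time_s = tm[cand + 1],
               onset_index = cand) # 0-based index of the first elevated frame
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Angle-at-onset versus mis-segregation association
#'
#' Regresses the binary mis-segregation indicator (co-segregating or
#' mis-segregating laggard) on the folded orientation angle at anaphase
#' onset by logistic maximum likelihood, and assesses significance with a
#' seeded label-permutation test on |slope| (robust at cohort-scale n,
#' unlike the Wald test). When `metrics` is supplied, also returns the mean
#' +/- SEM folded angle over time per fate category.
#'
#' @param fates the `fates` data.frame from [classify_fates()] (columns
#'   `category`, `theta_onset_deg`; "uncallable" rows are dropped).
#' @param metrics optional metrics data.frame for the per-category angle
#'   time courses.
#' @param n_perm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return list with `defined` (FALSE when fewer than two fate categories
#'   are present, association undefined), `slope` (per degree), `intercept`,
#'   `p_perm`, `separation` (TRUE on complete separation: the reported
#'   slope is then a finite surrogate of an infinite estimate), `n`, and
#'   `time_courses` (or NULL).
#' @export
angle_fate_association <- function(fates, metrics = NULL, n_perm = 10000,
                                   seed = 1) {
  f <- fates[fates$category != "uncallable" & !is.na(fates$theta_onset_deg), ]
  mis <- as.integer(f$category %in% c("co_segregating",
                                      "lagging_missegregated"))
  tc <- NULL
  if (!is.null(metrics)) {
    mm <- merge(metrics, f[, c("oocyte_id", "bivalent_id", "category")],
                by = c("oocyte_id", "bivalent_id"))
    mm <- mm[!is.na(mm$theta_folded), ]
    tc <- stats::aggregate(theta_folded ~ category + time_s, mm,
                           function(x) c(mean = mean(x),
                                         sem = stats::sd(x) / sqrt(length(x)),
                                         n = length(x)))
    tc <- cbind(tc[c("category", "time_s")],
                as.data.frame(tc$theta_folded))
    names(tc) <- c("category", "time_s", "mean_theta", "sem_theta", "n")
  }
  if (length(unique(mis)) < 2) {
    return(list(defined = FALSE, slope = NA_real_, intercept = NA_real_,
                p_perm = NA_real_, separation = FALSE, n = nrow(f),
                time_courses = tc))
  }
  X <- cbind(1, f$theta_onset_deg)
  fit_slope <- function(y) {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial(),
                     control = list(maxit = 100))
    )
    fit$coefficients
  }
  co <- fit_slope(mis)
  eta <- X %*% co
  separation <- all((eta > 0) == (mis == 1)) && all(abs(eta) > 8)
  obs <- abs(co[2])
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      abs(fit_slope(sample(mis))[2]) >= obs
    }, logical(1)))
  })
  list(defined = TRUE, slope = unname(co[2]), intercept = unname(co[1]),
       p_perm = (1 + exceed) / (n_perm + 1), separation = separation,
       n = nrow(f), time_courses = tc)
}
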