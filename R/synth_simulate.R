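#' Simulate a ground-truthed cohort of meiosis I oocytes
#'
#' Generates point trajectories for 2 spindle poles and `n_bivalents`
#' bivalents (2 homolog centroids plus 2 endpoint markers per homolog) per
#' oocyte, at every frame of the acquisition geometry, together with the
#' ground truth the analysis pipeline is meant to recover.
#'
#' The kinematics are deliberately phenomenological (no force balance):
#' * Before onset, the bivalent orientation angle relaxes toward the spindle
#'   axis by first-order (discrete Ornstein-Uhlenbeck) decay at `k_orient`,
#'   starting at the oocyte's spindle bipolarization time (drawn from
#'   `t_bipolar_mean`/`t_bipolar_sd`); a fraction `f_persistent_misorient`
#'   of bivalents never relax. The equator distance relaxes at `k_congress`
#'   toward a per-bivalent plate offset with additive noise `sigma_pos` and
#'   no imposed oscillation; the lateral (short-axis) position relaxes
#'   toward a progressively compacting anchor.
#' * Bivalent length grows by `dL` across the `stretch_ramp` window, split
#'   between the inter-homolog distance and the homolog lengths.
#' * At anaphase onset cohesion releases: homolog separation proceeds at
#'   `v_push + v_pull` toward the facing poles (saturating 3.5 um from the
#'   equator), and each bivalent's fate is drawn with
#'   P(mis-segregate) = plogis(beta0 + beta1 * theta_onset), mis-segregation
#'   splitting into co-segregation and mis-segregating laggards; a further
#'   fraction of correctly segregating bivalents lag before resolving.
#'
#' @param config a [cohort_config()].
#' @return list with `tracks` (data.frame in the package tracks schema, one
#'   row per object per frame) and `truth`: `bivalents` (oocyte_id,
#'   bivalent_id, fate, theta_onset_deg, persistent_misorient), `oocytes`
#'   (oocyte_id, ploidy, t_bipolar_s), `onset_time_s` (0) and `onset_index`
#'   (0-based frame of onset).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    per <- lapply(seq_len(config$n_oocytes), function(i) {
      simulate_oocyte(sprintf("oo%03d", i), config)
    })
  })
  tracks <- do.call(rbind, lapply(per, `[[`, "tracks"))
  biv <- do.call(rbind, lapply(per, `[[`, "truth_biv"))
  ooc <- do.call(rbind, lapply(per, `[[`, "truth_oocyte"))
  rownames(tracks) <- rownames(biv) <- rownames(ooc) <- NULL
  list(tracks = tracks,
       truth = list(bivalents = biv, oocytes = ooc, onset_time_s = 0,
                    onset_index = config$geometry$t_onset_index))
}

simulate_oocyte <- function(oid, config) {
  p <- config$preset
  g <- config$geometry
  nb <- config$n_bivalents
  nt <- g$n_t
  dt <- g$dt
  io <- g$t_onset_index + 1 # 1-based onset frame
  times <- frame_times(g)
  # anaphase travel saturates at a per-homolog depth: chromosomes arrive at
  # slightly different distances from the pole and stay resolvable there
  s_max <- matrix(stats::runif(nb * 2, 2.8, 3.8), nb, 2)
  sigma_meas <- 0.5 * p$sigma_pos

  t_bipolar <- stats::rnorm(1, p$t_bipolar_mean, p$t_bipolar_sd)
  persistent <- stats::runif(nb) < p$f_persistent_misorient

  # initial per-bivalent state
  theta <- ifelse(persistent,
                  stats::runif(nb, 30, 90),
                  stats::runif(nb, 0, 60)) * pi / 180
  phi <- stats::runif(nb, 0, 2 * pi)
  side <- sample(c(-1, 1), nb, replace = TRUE)
  eq_anchor <- abs(stats::rnorm(nb, 0, p$sigma_eq_ss))
  deq <- abs(stats::rnorm(nb, 0, max(p$sigma_eq_ss, 0.3))) + 0.3
  # lateral anchors on a jittered rosette (one central bivalent, the rest
  # on a ring), the arrangement metaphase plates actually adopt; bivalents
  # keep exclusive territories, so homologs of different bivalents stay
  # optically resolvable
  rho_anchor0 <- rosette_anchors(nb, r_max = p$r_ax0, min_sep = 1.8)
  rho <- rho_anchor0

  ramp <- function(t) {
    sr <- p$stretch_ramp
    pmin(1, pmax(0, (t - sr[["t_start"]]) / (sr[["t_end"]] - sr[["t_start"]])))
  }

  hom_pos <- array(NA_real_, c(nt, nb, 2, 3))
  end_pos <- array(NA_real_, c(nt, nb, 2, 2, 3))
  pole_pos <- array(NA_real_, c(nt, 2, 3))
  theta_onset <- rep(NA_real_, nb)
  a_or <- exp(-p$k_orient * dt)
  a_c <- exp(-p$k_congress * dt)

  meas_noise <- function(n) {
    if (sigma_meas == 0) 0 else stats::rnorm(n, 0, sigma_meas)
  }

  # ---- pre-onset frames (including the onset frame itself) ----
  for (k in seq_len(io)) {
    tk <- times[k]
    # split the programmed bivalent-length increase between the
    # inter-homolog distance and the homolog lengths so the end-to-end
    # extent (d_IH + mean homolog length, collinear geometry) grows by dL
    d_ih <- p$d_ih0 + ramp(tk) * p$stretch_ramp[["dL"]] / 2
    l_hom <- p$l_hom0 + ramp(tk) * p$stretch_ramp[["dL"]] / 2
    v <- cbind(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
    cen <- cbind(side * deq, rho)
    h1 <- cen - (d_ih / 2) * v
    h2 <- cen + (d_ih / 2) * v
    hom_pos[k, , 1, ] <- h1 + meas_noise(3 * nb)
    hom_pos[k, , 2, ] <- h2 + meas_noise(3 * nb)
    for (h in 1:2) {
      hc <- if (h == 1) h1 else h2
      end_pos[k, , h, 1, ] <- hc - (l_hom / 2) * v + meas_noise(3 * nb)
      end_pos[k, , h, 2, ] <- hc + (l_hom / 2) * v + meas_noise(3 * nb)
    }
    Lsp <- p$L_spindle0 +
      (p$L_spindle1 - p$L_spindle0) * (k - 1) / max(io - 1, 1)
    pole_pos[k, 1, ] <- c(-Lsp / 2, 0, 0) + 0.3 * meas_noise(3)
    pole_pos[k, 2, ] <- c(Lsp / 2, 0, 0) + 0.3 * meas_noise(3)

    if (k == io) {
      theta_onset <- fold_angle(theta * 180 / pi)
      v_frozen <- v
      l_hom_onset <- l_hom
      s_on <- cbind(h1[, 1], h2[, 1])
      lat_on <- array(NA_real_, c(nb, 2, 2)) # [bivalent, homolog, y/z]
      lat_on[, 1, ] <- h1[, 2:3]
      lat_on[, 2, ] <- h2[, 2:3]
      break
    }
    # state update to frame k + 1
    relax <- (tk >= t_bipolar) & !persistent
    theta <- ifelse(relax, theta * a_or, theta)
    sig_ang <- if (p$sigma_pos == 0) 0 else sqrt(2) * p$sigma_pos / (d_ih / 2)
    theta <- theta + stats::rnorm(nb, 0, sig_ang)
    theta <- abs(theta)
    theta <- ifelse(theta > pi, 2 * pi - theta, theta)
    phi <- phi + stats::rnorm(nb, 0, 0.15)
    deq <- eq_anchor + (deq - eq_anchor) * a_c +
      stats::rnorm(nb, 0, p$sigma_pos)
    deq <- abs(deq)
    shrink <- 1 - (1 - p$ax_shrink) * k / max(io - 1, 1)
    tgt <- rho_anchor0 * shrink
    rho <- tgt + (rho - tgt) * a_c +
      matrix(stats::rnorm(2 * nb, 0, p$sigma_pos), nb, 2)
  }

  # ---- fate draws at onset ----
  p_mis <- stats::plogis(p$beta0 + p$beta1 * theta_onset)
  mis <- stats::runif(nb) < p_mis
  coseg <- mis & (stats::runif(nb) < p$f_coseg_given_mis)
  lag_ok <- !mis & (stats::runif(nb) < p$f_lagging_correct)
  fate <- ifelse(coseg, "co_segregating",
          ifelse(mis, "lagging_missegregated",
          ifelse(lag_ok, "lagging_correct", "normal")))

  # facing pole of each homolog: the one with the smaller axis coordinate
  # faces pole A (dir -1)
  dir_face <- t(apply(s_on, 1, function(s) if (s[1] <= s[2]) c(-1, 1) else c(1, -1)))
  lagger <- sample(1:2, nb, replace = TRUE)
  stay <- stats::runif(nb) < 0.5 # mis-segregating laggards that never leave
  v_seg <- p$v_push + p$v_pull

  # per-homolog anaphase trajectory mode and direction
  mode <- matrix("segregate", nb, 2)
  dirs <- dir_face
  for (b in seq_len(nb)) {
    if (fate[b] == "co_segregating") {
      sd_ <- sign(s_on[b, 1] + s_on[b, 2])
      if (sd_ == 0) sd_ <- 1
      dirs[b, ] <- c(sd_, sd_)
    } else if (fate[b] == "lagging_correct") {
      lg <- lagger[b]
      mode[b, lg] <- "lag"
      dirs[b, lg] <- dir_face[b, lg]
    } else if (fate[b] == "lagging_missegregated") {
      lg <- lagger[b]
      mode[b, lg] <- if (stay[b]) "stay" else "lag"
      dirs[b, lg] <- dir_face[b, 3 - lg] # wrong side: partner's pole
    }
  }

  # ---- post-onset frames ----
  if (io < nt) {
    for (k in (io + 1):nt) {
      tau <- times[k]
      for (h in 1:2) {
        s0 <- s_on[, h]
        sm <- s_max[, h]
        s_lag <- s0 * exp(-0.02 * tau)
        s_go <- pmin(sm, pmax(-sm, s0 + dirs[, h] * v_seg * tau))
        s_rel <- s0 * exp(-0.02 * p$t_lag_release)
        s_resume <- pmin(sm, pmax(-sm,
          s_rel + dirs[, h] * p$v_lag * (tau - p$t_lag_release)))
        s <- ifelse(mode[, h] == "segregate", s_go,
             ifelse(mode[, h] == "stay", s_lag,
                    ifelse(tau <= p$t_lag_release, s_lag, s_resume)))
        hp <- cbind(s, lat_on[, h, 1], lat_on[, h, 2])
        hom_pos[k, , h, ] <- hp + meas_noise(3 * nb)
        end_pos[k, , h, 1, ] <- hp - (l_hom_onset / 2) * v_frozen +
          meas_noise(3 * nb)
        end_pos[k, , h, 2, ] <- hp + (l_hom_onset / 2) * v_frozen +
          meas_noise(3 * nb)
      }
      pole_pos[k, 1, ] <- c(-p$L_spindle1 / 2, 0, 0) + 0.3 * meas_noise(3)
      pole_pos[k, 2, ] <- c(p$L_spindle1 / 2, 0, 0) + 0.3 * meas_noise(3)
    }
  }

  tracks <- assemble_tracks(oid, p$name, times, pole_pos, hom_pos, end_pos)
  ploidy <- if (any(fate %in% c("co_segregating", "lagging_missegregated"))) {
    "aneuploid"
  } else {
    "euploid"
  }
  list(
    tracks = tracks,
    truth_biv = data.frame(oocyte_id = oid, bivalent_id = seq_len(nb),
                           fate = fate, theta_onset_deg = theta_onset,
                           persistent_misorient = persistent),
    truth_oocyte = data.frame(oocyte_id = oid, ploidy = ploidy,
                              t_bipolar_s = t_bipolar)
  )
}

rosette_anchors <- function(nb, r_max = 2.2, min_sep = 1.8) {
  if (nb == 1) return(matrix(stats::rnorm(2, 0, 0.1), 1, 2))
  ring_n <- nb - 1
  r_ring <- min(max(min_sep, min_sep / (2 * sin(pi / ring_n))), r_max)
  ang <- 2 * pi * seq_len(ring_n) / ring_n + stats::runif(1, 0, 2 * pi) +
    stats::rnorm(ring_n, 0, 0.08)
  rad <- r_ring * (1 + stats::rnorm(ring_n, 0, 0.04))
  rbind(stats::rnorm(2, 0, 0.1),
        cbind(rad * cos(ang), rad * sin(ang)))
}

assemble_tracks <- function(oid, condition, times, pole_pos, hom_pos, end_pos) {
  nt <- length(times)
  nb <- dim(hom_pos)[2]
  row_block <- function(n, object_class, pole_id, bivalent_id, homolog_id,
                        endpoint_id, xyz, time_s) {
    data.frame(oocyte_id = oid, condition = condition, time_s = time_s,
               object_class = object_class, pole_id = pole_id,
               bivalent_id = bivalent_id, homolog_id = homolog_id,
               endpoint_id = endpoint_id,
               x_um = xyz[, 1], y_um = xyz[, 2], z_um = xyz[, 3])
  }
  poles <- row_block(2 * nt, "pole", rep(c("A", "B"), each = nt),
                     NA_integer_, NA_integer_, NA_integer_,
                     rbind(pole_pos[, 1, ], pole_pos[, 2, ]),
                     rep(times, 2))
  gh <- expand.grid(t = seq_len(nt), b = seq_len(nb), h = 1:2)
  homs <- row_block(nrow(gh), "homolog", NA_character_, gh$b, gh$h,
                    NA_integer_,
                    cbind(as.vector(hom_pos[, , , 1]),
                          as.vector(hom_pos[, , , 2]),
                          as.vector(hom_pos[, , , 3])),
                    times[gh$t])
  ge <- expand.grid(t = seq_len(nt), b = seq_len(nb), h = 1:2, e = 1:2)
  ends <- row_block(nrow(ge), "endpoint", NA_character_, ge$b, ge$h, ge$e,
                    cbind(as.vector(end_pos[, , , , 1]),
                          as.vector(end_pos[, , , , 2]),
                          as.vector(end_pos[, , , , 3])),
                    times[ge$t])
  rbind(poles, homs, ends)
}
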