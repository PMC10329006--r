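test_that("a noiseless render places the argmax voxel at the object and the
           blob centroid within half a pixel", {
  g <- acquisition_geometry(n_z = 12, dz = 0.4, dxy = 0.2, n_t = 16,
                            t_onset_index = 15)
  # single homolog exactly at a voxel centre of a known volume
  org <- c(-2, -2, -2.4)
  pos <- org + c(10.5 * 0.2, 9.5 * 0.2, 5.5 * 0.4)
  tr <- data.frame(oocyte_id = "o", condition = "c", time_s = 0,
                   object_class = c("homolog", "pole", "pole"),
                   pole_id = c(NA, "A", "B"), bivalent_id = c(1, NA, NA),
                   homolog_id = c(1, NA, NA), endpoint_id = NA_integer_,
                   x_um = c(pos[1], -1.6, 1.6), y_um = c(pos[2], 0, 0),
                   z_um = c(pos[3], 0, 0))
  st <- render_stack(tr, g, snr = Inf, origin = org, fov_xy = c(4, 4))
  fr <- st[, , , 1, 1]
  am <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  expect_equal(unname(am), c(11, 10, 6))
  # intensity-weighted centroid of the noiseless blob recovers the position
  w <- fr - min(fr)
  xs <- org[1] + (seq_len(dim(fr)[1]) - 0.5) * 0.2
  ys <- org[2] + (seq_len(dim(fr)[2]) - 0.5) * 0.2
  zs <- org[3] + (seq_len(dim(fr)[3]) - 0.5) * 0.4
  cen <- c(sum(apply(w, 1, sum) * xs), sum(apply(w, 2, sum) * ys),
           sum(apply(w, 3, sum) * zs)) / sum(w)
  expect_lt(abs(cen[1] - pos[1]), 0.1)
  expect_lt(abs(cen[2] - pos[2]), 0.1)
  expect_lt(abs(cen[3] - pos[3]), 0.2)
  # rendering is seed-deterministic
  st1 <- render_stack(tr, g, snr = 5, origin = org, fov_xy = c(4, 4),
                      seed = 3)
  st2 <- render_stack(tr, g, snr = 5, origin = org, fov_xy = c(4, 4),
                      seed = 3)
  expect_identical(as.numeric(st1), as.numeric(st2))
  # out-of-volume tracks are rejected with the offending frame
  expect_error(render_stack(tr, g, origin = org + 5, fov_xy = c(1, 1)),
               "outside the rendered volume at time 0")
})

test_that("detection finds isolated blobs within a voxel and nothing in a
           blank frame", {
  g <- acquisition_geometry(n_z = 12, dz = 0.4, dxy = 0.2, n_t = 16,
                            t_onset_index = 15)
  expect_equal(nrow(detect_spots(array(7, c(30, 30, 12)),
                                 c(0.2, 0.2, 0.4))), 0)
  set.seed(5)
  # 12 well-separated blobs on a grid, diameter ~1.5 um
  centers <- as.matrix(expand.grid(x = c(1, 3, 5, 7), y = c(1.2, 3.6, 6)))
  centers <- cbind(centers, z = rep(c(1.6, 2.8), 6))
  tr <- data.frame(oocyte_id = "o", condition = "c", time_s = 0,
                   object_class = "homolog", pole_id = NA_character_,
                   bivalent_id = rep(1:6, each = 2),
                   homolog_id = rep(1:2, 6), endpoint_id = NA_integer_,
                   x_um = centers[, 1], y_um = centers[, 2],
                   z_um = centers[, 3])
  st <- render_stack(tr, g, psf_sigma = c(0.44, 0.44, 0.44), snr = Inf,
                     origin = c(-1, -1, 0), fov_xy = c(10, 8.5))
  sp <- detect_spots(st[, , , 1, 1], attr(st, "spacing"),
                     min_diameter = 0.8, origin = attr(st, "origin"))
  expect_equal(nrow(sp), 12)
  for (i in seq_len(12)) {
    d <- sqrt((sp$x_um - centers[i, 1])^2 + (sp$y_um - centers[i, 2])^2 +
                (sp$z_um - centers[i, 3])^2)
    expect_lt(min(d), 0.25)
  }
  expect_true(all(sp$diameter_um >= 0.8))
})

test_that("detection is equivariant to whole-voxel translations", {
  g <- acquisition_geometry(n_z = 12, dz = 0.4, dxy = 0.2, n_t = 16,
                            t_onset_index = 15)
  tr <- data.frame(oocyte_id = "o", condition = "c", time_s = 0,
                   object_class = "homolog", pole_id = NA_character_,
                   bivalent_id = 1, homolog_id = 1, endpoint_id = NA,
                   x_um = 2.03, y_um = 1.87, z_um = 2.2)
  st <- render_stack(tr, g, snr = Inf, origin = c(0, 0, 0),
                     fov_xy = c(6, 6))
  fr <- st[, , , 1, 1]
  sp0 <- detect_spots(fr, attr(st, "spacing"), origin = c(0, 0, 0))
  # shift by 3 voxels in x, 2 in y (content moved, same volume)
  shifted <- array(min(fr), dim(fr))
  shifted[4:dim(fr)[1], 3:dim(fr)[2], ] <-
    fr[1:(dim(fr)[1] - 3), 1:(dim(fr)[2] - 2), ]
  sp1 <- detect_spots(shifted, attr(st, "spacing"), origin = c(0, 0, 0))
  expect_equal(nrow(sp0), 1)
  expect_equal(nrow(sp1), 1)
  expect_equal(sp1$x_um - sp0$x_um, 3 * 0.2, tolerance = 1e-6)
  expect_equal(sp1$y_um - sp0$y_um, 2 * 0.2, tolerance = 1e-6)
  expect_equal(sp1$z_um, sp0$z_um, tolerance = 1e-6)
})

test_that("pole identification passes points through, relabels by
           continuity, and recovers rendered poles", {
  pts <- rbind(c(-2, 0, 0), c(2, 0, 0))
  out <- identify_poles(points = pts)
  expect_equal(unname(out), pts)
  # swapped input order is relabelled so A stays A
  out2 <- identify_poles(points = pts[2:1, ], prev = out)
  expect_equal(unname(out2["A", ]), pts[1, ])
  expect_equal(unname(out2["B", ]), pts[2, ])

  g <- acquisition_geometry(n_z = 16, dz = 0.4, dxy = 0.2, n_t = 16,
                            t_onset_index = 15)
  tr <- data.frame(oocyte_id = "o", condition = "c", time_s = 0,
                   object_class = "pole", pole_id = c("A", "B"),
                   bivalent_id = NA, homolog_id = NA, endpoint_id = NA,
                   x_um = c(-2, 2), y_um = 0, z_um = 0)
  st <- render_stack(tr, g, snr = Inf, origin = c(-4, -3, -3.2),
                     fov_xy = c(8, 6))
  est <- identify_poles(st[, , , 2, 1], attr(st, "spacing"),
                        attr(st, "origin"))
  errA <- min(sqrt(sum((est["A", ] - c(-2, 0, 0))^2)),
              sqrt(sum((est["A", ] - c(2, 0, 0))^2)))
  errB <- min(sqrt(sum((est["B", ] - c(-2, 0, 0))^2)),
              sqrt(sum((est["B", ] - c(2, 0, 0))^2)))
  expect_lt(errA, 0.5)
  expect_lt(errB, 0.5)
  # an isotropic blob has no spindle axis
  iso <- array(0, c(20, 20, 10))
  iso[10, 10, 5] <- 100
  expect_error(identify_poles(gauss_blur <- iso, c(0.2, 0.2, 0.4)),
               "no spindle axis")
})

test_that("linking keeps stationary spots, closes gaps, and never reuses a
           spot", {
  sp <- do.call(rbind, lapply(1:10, function(f) {
    data.frame(frame = f, x_um = c(0, 3), y_um = 0, z_um = 0)
  }))
  tr <- link_tracks(sp, max_disp = 1)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_equal(as.numeric(table(tr$track_id)), c(10, 10))
  expect_false(any(tr$gap))
  # one observation missing mid-track: single track with one gap flag
  sp2 <- sp[!(sp$frame == 5 & sp$x_um == 0), ]
  tr2 <- link_tracks(sp2, max_disp = 1, max_gap = 1)
  t0 <- tr2[tr2$x_um == 0, ]
  expect_equal(length(unique(t0$track_id)), 1)
  expect_equal(sum(t0$gap), 1)
  expect_equal(t0$frame[t0$gap], 6)
  # no spot assigned twice within a frame
  dup <- stats::aggregate(track_id ~ frame, tr2, function(x) anyDuplicated(x))
  expect_true(all(dup$track_id == 0))
})

test_that("linking recovers simulated control identities perfectly when
           displacements stay under the budget", {
  sim <- simulate_cohort(cohort_config(1, genotype_preset("control"),
                                       geom_metaphase(), seed = 14))
  homs <- sim$tracks[sim$tracks$object_class == "homolog", ]
  times <- sort(unique(homs$time_s))
  spots <- data.frame(frame = match(homs$time_s, times), x_um = homs$x_um,
                      y_um = homs$y_um, z_um = homs$z_um)
  lt <- link_tracks(spots, max_disp = 1)
  truth <- data.frame(frame = match(homs$time_s, times),
                      object = paste(homs$bivalent_id, homs$homolog_id),
                      x_um = homs$x_um, y_um = homs$y_um, z_um = homs$z_um)
  ev <- evaluate_tracking(lt, truth, tol = 0.1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$identity_agreement, 1)
})

test_that("homolog pairing matches ground truth on simulated oocytes and
           rejects incomplete track sets", {
  sim <- simulate_cohort(cohort_config(2, genotype_preset("control"),
                                       geom_metaphase(), seed = 17))
  for (oid in unique(sim$tracks$oocyte_id)) {
    homs <- sim$tracks[sim$tracks$object_class == "homolog" &
                         sim$tracks$oocyte_id == oid, ]
    times <- sort(unique(homs$time_s))
    first <- homs[homs$time_s == times[1], ]
    tracks <- data.frame(track_id = seq_len(12), frame = 1,
                         x_um = first$x_um, y_um = first$y_um,
                         z_um = first$z_um)
    poleA <- sim$tracks[sim$tracks$object_class == "pole" &
                          sim$tracks$oocyte_id == oid &
                          sim$tracks$pole_id == "A" &
                          sim$tracks$time_s == times[1], ]
    pr <- pair_homologs(tracks, c(poleA$x_um, poleA$y_um, poleA$z_um), 1)
    # every detected pair is a true bivalent
    for (b in 1:6) {
      ids <- pr$track_id[pr$bivalent_id == b]
      expect_equal(first$bivalent_id[ids[1]], first$bivalent_id[ids[2]])
    }
    expect_error(pair_homologs(tracks[-1, ], c(0, 0, 0), 1), "exactly 12")
  }
})

test_that("six tight pairs far apart pair by plain nearest neighbours", {
  set.seed(23)
  centers <- cbind(seq(0, 25, by = 5), 0, 0)
  pts <- do.call(rbind, lapply(seq_len(6), function(i) {
    rbind(centers[i, ] + c(-0.25, 0, 0), centers[i, ] + c(0.25, 0, 0))
  }))
  tracks <- data.frame(track_id = 1:12, frame = 1, x_um = pts[, 1],
                       y_um = pts[, 2], z_um = pts[, 3])
  pr <- pair_homologs(tracks, c(-5, 0, 0), 1)
  for (b in 1:6) {
    ids <- sort(pr$track_id[pr$bivalent_id == b])
    expect_equal(ids[2] - ids[1], 1) # consecutive points are the true pairs
  }
  # bivalents ordered by distance to pole A
  expect_equal(pr$bivalent_id[order(pr$track_id)], rep(1:6, each = 2))
})
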