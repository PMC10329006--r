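make_calib_metrics <- function(max_angles, max_deq, max_dax) {
  # two frames per oocyte: one mid-metaphase, one at onset
  do.call(rbind, lapply(seq_along(max_angles), function(i) {
    data.frame(oocyte_id = sprintf("o%d", i), condition = "ctrl",
               bivalent_id = c(1, 2, 1, 2), time_s = c(-50, -50, 0, 0),
               theta_folded = c(5, 6, max_angles[i], max_angles[i] - 3),
               theta_labeled = 10, osc = NA,
               d_eq = c(max_deq[i], max_deq[i] / 2, 0.1, 0.1),
               d_ax = c(max_dax[i], max_dax[i] / 2, 0.3, 0.2),
               s_hom1 = 0, s_hom2 = 0, L_hom1 = NA, L_hom2 = NA,
               d_IH = 1, L_biv = NA)
  }))
}

test_that("calibration is the mean of per-oocyte maxima and is
           permutation-invariant", {
  met <- make_calib_metrics(c(20, 25), c(0.4, 0.6), c(1.5, 1.7))
  cal <- calibrate_thresholds(met)
  expect_equal(cal$theta_max, 22.5)
  expect_equal(cal$d_eq_max, 0.5)
  expect_equal(cal$d_ax_max, 1.6)
  # single-oocyte cohort calibrates to its own maximum
  one <- calibrate_thresholds(met[met$oocyte_id == "o1", ])
  expect_equal(one$theta_max, 20)
  # permuting rows changes nothing
  set.seed(2)
  cal2 <- calibrate_thresholds(met[sample(nrow(met)), ])
  expect_equal(cal2$theta_max, cal$theta_max)
  expect_equal(cal2$d_eq_max, cal$d_eq_max)
  # no metrics at the onset frame is an error
  expect_error(calibrate_thresholds(met[met$time_s != 0, ]), "onset")
})

test_that("calibration equals an independent brute-force oracle on
           simulated cohorts", {
  sim <- simulate_cohort(cohort_config(5, genotype_preset("control"),
                                       seed = 31))
  met <- compute_metrics(sim$tracks)
  cal <- calibrate_thresholds(met)
  # oracle: explicit loop over oocytes
  oids <- unique(met$oocyte_id)
  mx_th <- mx_eq <- mx_ax <- numeric(0)
  for (o in oids) {
    m <- met[met$oocyte_id == o, ]
    mx_th <- c(mx_th, max(m$theta_folded[m$time_s == 0], na.rm = TRUE))
    w <- m[m$time_s >= -100 & m$time_s <= 0, ]
    mx_eq <- c(mx_eq, max(w$d_eq))
    mx_ax <- c(mx_ax, max(w$d_ax))
  }
  expect_equal(cal$theta_max, mean(mx_th), tolerance = 1e-12)
  expect_equal(cal$d_eq_max, mean(mx_eq), tolerance = 1e-12)
  expect_equal(cal$d_ax_max, mean(mx_ax), tolerance = 1e-12)
})

test_that("per-timepoint flags use inclusive thresholds and exact
           proportions", {
  met <- data.frame(oocyte_id = "o1", condition = "x", bivalent_id = 1:10,
                    time_s = 0, theta_labeled = 10,
                    theta_folded = c(22.5, rep(5, 9)), osc = NA,
                    d_eq = c(rep(1, 4), rep(0.2, 6)), d_ax = 0.5,
                    s_hom1 = 0, s_hom2 = 0, L_hom1 = NA, L_hom2 = NA,
                    d_IH = 1, L_biv = NA)
  cls <- classify_timepoints(met, classification_config())
  expect_true(all(cls$flags$oriented)) # 22.5 == threshold counts as oriented
  pr <- cls$proportions
  expect_equal(pr$proportion[pr$metric == "congressed"], 0.6)
  expect_equal(pr$n_defined[pr$metric == "congressed"], 10)
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1))
  # undefined angles leave the denominator
  met$theta_folded[1:2] <- NA
  cls2 <- classify_timepoints(met, classification_config())
  expect_equal(cls2$proportions$n_defined[
    cls2$proportions$metric == "oriented"], 8)
})

test_that("fate rules resolve hand-built anaphase geometries", {
  cfg <- classification_config()
  # normal: opposite sides, fully segregated throughout
  tr <- make_fate_tracks(list(
    function(t) if (t <= 0) c(-0.4, 0.4) else c(-3, 3),      # normal
    function(t) if (t <= 0) c(0.2, 0.8) else c(3, 3.4),      # co-segregating
    function(t) {                                            # lagging, correct
      if (t <= 0) c(-0.3, 0.3)
      else if (t <= 70) c(-3, 0.1)
      else c(-3, min(0.1 + 0.06 * (t - 70), 3))
    },
    function(t) {                                            # lagging, wrong
      if (t <= 0) c(-0.3, 0.3)
      else if (t <= 70) c(-3, 0.1)
      else c(-3, max(0.1 - 0.06 * (t - 70), -3))
    }))
  fc <- classify_fates(tr, cfg)
  expect_equal(fc$fates$category,
               c("normal", "co_segregating", "lagging_correct",
                 "lagging_missegregated"))
  expect_equal(fc$oocytes$ploidy, "aneuploid")
  # all-normal oocyte is euploid
  tr2 <- make_fate_tracks(list(function(t) if (t <= 0) c(-0.4, 0.4)
                               else c(-3, 3)))
  expect_equal(classify_fates(tr2, cfg)$oocytes$ploidy, "euploid")
  # tracks ending before the call time are uncallable, with a warning
  tr3 <- tr2[tr2$time_s <= 60, ]
  expect_warning(fc3 <- classify_fates(tr3, cfg), "uncallable")
  expect_equal(fc3$fates$category, "uncallable")
})

test_that("fate calls are invariant to swapping the pole labels", {
  sim <- simulate_cohort(cohort_config(4, genotype_preset("knl1_null"),
                                       geom_anaphase(), seed = 12))
  tr <- sim$tracks
  fc1 <- suppressWarnings(classify_fates(tr))
  swapped <- tr
  swapped$pole_id[tr$object_class == "pole"] <-
    c(A = "B", B = "A")[tr$pole_id[tr$object_class == "pole"]]
  fc2 <- suppressWarnings(classify_fates(swapped))
  expect_equal(fc1$fates$category, fc2$fates$category)
  expect_equal(fc1$oocytes$ploidy, fc2$oocytes$ploidy)
})

test_that("fate classifier recovers simulator ground truth on a
           kinetochore-null cohort", {
  sim <- simulate_cohort(cohort_config(10, genotype_preset("knl1_null"),
                                       geom_anaphase(), seed = 5))
  fc <- suppressWarnings(classify_fates(sim$tracks))
  acc <- mean(fc$fates$category == sim$truth$bivalents$fate)
  expect_gte(acc, 0.9)
})

test_that("onset detection finds a step, rejects a smooth ramp, and lands
           within a frame of simulated truth", {
  met_step <- data.frame(oocyte_id = "o1", bivalent_id = 1,
                         time_s = (0:39) * 10,
                         d_IH = c(rep(1, 20), rep(3, 20)))
  od <- onset_detect(met_step)
  expect_equal(od$onset_index, 20)       # 0-based first elevated frame
  expect_equal(od$onset_time_s, 200)
  met_ramp <- data.frame(oocyte_id = "o1", bivalent_id = 1,
                         time_s = (0:39) * 10, d_IH = seq(1, 3, length = 40))
  expect_error(onset_detect(met_ramp), "onset not detected")

  sim <- simulate_cohort(cohort_config(12, genotype_preset("control"),
                                       geom_anaphase(), seed = 19))
  met <- compute_metrics(sim$tracks)
  od <- onset_detect(met)
  hit <- abs(od$onset_index - sim$truth$onset_index) <= 1
  expect_gte(mean(hit), 0.95)
})

test_that("association is undefined with a single fate category and
           recovers a positive slope under a programmed angle link", {
  fates0 <- data.frame(oocyte_id = "o", bivalent_id = 1:10,
                       category = "normal", theta_onset_deg = runif(10, 0, 40))
  a0 <- angle_fate_association(fates0, n_perm = 10)
  expect_false(a0$defined)

  sim <- simulate_cohort(cohort_config(8, genotype_preset("knl1_null"),
                                       geom_metaphase(), seed = 44))
  tb <- sim$truth$bivalents
  fates <- data.frame(oocyte_id = tb$oocyte_id, bivalent_id = tb$bivalent_id,
                      category = tb$fate,
                      theta_onset_deg = tb$theta_onset_deg)
  a <- angle_fate_association(fates, n_perm = 199, seed = 3)
  expect_true(a$defined)
  expect_gt(a$slope, 0)
  expect_lt(a$p_perm, 0.05)
  # time courses come back when metrics are supplied
  met <- compute_metrics(sim$tracks)
  a2 <- angle_fate_association(fates, metrics = met, n_perm = 19)
  expect_true(!is.null(a2$time_courses))
  expect_true(all(c("category", "time_s", "mean_theta", "sem_theta", "n")
                  %in% names(a2$time_courses)))
})
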