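#' Acquisition geometry for simulated and real stacks
#'
#' Describes the 3D+t sampling of a two-channel acquisition. Defaults follow
#' routine live imaging of meiosis I oocytes: 30 Z-planes separated by
#' 0.3 um acquired every 10 s, with an XY pixel of 0.11 um (typical
#' spinning-disk 40-60x sampling). Frames run from roughly 500 s before to
#' 120 s after anaphase onset.
#'
#' @param n_z number of Z planes.
#' @param dz Z spacing, um.
#' @param dxy XY pixel size, um.
#' @param dt frame interval, s.
#' @param n_t number of frames.
#' @param t_onset_index 0-based frame index of anaphase onset.
#' @param channels ordered channel roles.
#' @return an `acquisition_geometry` list.
#' @export
acquisition_geometry <- function(n_z = 30, dz = 0.3, dxy = 0.11, dt = 10,
                                 n_t = 63, t_onset_index = 50,
                                 channels = c("chromatin", "tubulin")) {
  stopifnot(n_z >= 1, dz > 0, dxy > 0, dt > 0, n_t >= 1)
  if (t_onset_index < 0 || t_onset_index >= n_t) {
    stop("t_onset_index must lie within 0..(n_t - 1)")
  }
  structure(list(n_z = n_z, dz = dz, dxy = dxy, dt = dt, n_t = n_t,
                 t_onset_index = t_onset_index, channels = channels),
            class = "acquisition_geometry")
}

#' Frame times relative to anaphase onset
#'
#' @param geometry an [acquisition_geometry()].
#' @return numeric vector of length `n_t`, seconds, negative before onset.
#' @export
frame_times <- function(geometry) {
  (seq_len(geometry$n_t) - 1 - geometry$t_onset_index) * geometry$dt
}

#' Genotype presets for the cohort simulator
#'
#' Each preset is a bag of kinematic parameters for the first-order
#' (discrete Ornstein-Uhlenbeck) relaxation model of bivalent orientation
#' and congression, the pre-anaphase stretching ramp, anaphase separation
#' speeds, and the logistic link between the orientation angle at anaphase
#' onset and the probability of mis-segregation. Shipped presets emulate the
#' qualitative phenotypes of the corresponding perturbations:
#'
#' * `control` - fast orientation/congression relaxation, stretch ramp from
#'   -150 s to -50 s, essentially no mis-segregation.
#' * `knl1_null` - kinetochore-null-like: a fraction of bivalents never
#'   relax their orientation, congression is loose, and mis-segregation
#'   probability rises steeply with the angle at onset.
#' * `lateral_loss` - loss of lateral (motor-driven) interactions: delayed
#'   orientation/congression that recovers before onset; accurate
#'   segregation.
#' * `endon_loss` - loss of end-on attachments: no stretch ramp, widened
#'   metaphase plate, no pulling (`v_pull = 0`), but accurate segregation.
#' * `combined_loss` - end-on plus pushing loss: homologs fail to separate
#'   and mis-segregation is angle-linked.
#'
#' Rates are per second, lengths in micrometres, times in seconds relative
#' to anaphase onset. `beta0`/`beta1` are the logistic intercept and
#' per-degree slope; `f_persistent_misorient` is the fraction of bivalents
#' whose orientation relaxation is disabled.
#'
#' @param name one of the shipped preset names.
#' @param ... named overrides of individual fields.
#' @return a `genotype_preset` list.
#' @export
genotype_preset <- function(name = c("control", "knl1_null", "lateral_loss",
                                     "endon_loss", "combined_loss"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    k_orient = 0.02, k_congress = 0.015, sigma_pos = 0.05,
    f_persistent_misorient = 0,
    stretch_ramp = c(t_start = -150, t_end = -50, dL = 0.4),
    v_push = 0.02, v_pull = 0.02,
    beta0 = -6.5, beta1 = 0.06,
    t_bipolar_mean = -350, t_bipolar_sd = 40,
    # phenomenology not named in the headline parameters:
    sigma_eq_ss = 0.2,      # per-bivalent metaphase-plate offset SD, um
    r_ax0 = 2.2,            # initial lateral (short-axis) spread radius, um
    ax_shrink = 0.6,        # lateral anchor shrink factor reached at onset
    f_lagging_correct = 0.02,  # lagging-but-correct fraction of normal draws
    f_coseg_given_mis = 0.5,   # co-segregation share of mis-segregations
    d_ih0 = 1.0, l_hom0 = 2.0, # resting inter-homolog distance, homolog length
    L_spindle0 = 5.2, L_spindle1 = 4.0, # pole-pole distance start -> onset
    v_lag = 0.06,           # post-release speed of resolved laggards, um/s
    t_lag_release = 70      # s after onset when laggards resolve
  )
  tweaks <- switch(name,
    control = list(),
    knl1_null = list(f_persistent_misorient = 0.35, beta0 = -3.2,
                     sigma_eq_ss = 0.6, f_lagging_correct = 0.12),
    lateral_loss = list(t_bipolar_mean = -120, t_bipolar_sd = 20,
                        sigma_eq_ss = 0.35),
    endon_loss = list(stretch_ramp = c(t_start = -150, t_end = -50, dL = 0),
                      sigma_eq_ss = 0.9, k_congress = 0.005, v_pull = 0,
                      beta1 = 0, f_lagging_correct = 0.3),
    combined_loss = list(stretch_ramp = c(t_start = -150, t_end = -50, dL = 0),
                         sigma_eq_ss = 0.9, k_congress = 0.005, v_pull = 0,
                         v_push = 0, beta0 = -2.5, beta1 = 0.06,
                         f_persistent_misorient = 0.35)
  )
  p <- utils::modifyList(base, tweaks)
  p <- utils::modifyList(p, list(...))
  validate_preset(p)
  structure(p, class = "genotype_preset")
}

validate_preset <- function(p) {
  if (p$k_orient < 0 || p$k_congress < 0 || p$v_push < 0 || p$v_pull < 0) {
    stop("rates and speeds must be non-negative")
  }
  if (p$sigma_pos < 0) stop("sigma_pos must be non-negative")
  if (p$f_persistent_misorient < 0 || p$f_persistent_misorient > 1) {
    stop("f_persistent_misorient must lie in [0, 1]")
  }
  sr <- p$stretch_ramp
  if (sr[["t_start"]] > sr[["t_end"]] || sr[["t_end"]] > 0) {
    stop("stretch window must be ordered and precede anaphase onset")
  }
  invisible(p)
}

#' Cohort configuration for the simulator
#'
#' @param n_oocytes number of oocytes to simulate.
#' @param preset a [genotype_preset()] (or a preset name).
#' @param geometry an [acquisition_geometry()].
#' @param n_bivalents bivalents per oocyte (6 in *C. elegans* meiosis I).
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_oocytes, preset = genotype_preset("control"),
                          geometry = acquisition_geometry(),
                          n_bivalents = 6, seed = 1) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  stopifnot(inherits(preset, "genotype_preset"),
            inherits(geometry, "acquisition_geometry"),
            n_oocytes >= 1, n_bivalents >= 1)
  times <- (seq_len(geometry$n_t) - 1 - geometry$t_onset_index) * geometry$dt
  if (preset$stretch_ramp[["t_start"]] < times[1]) {
    stop("movie too short: stretch window starts before the first frame")
  }
  structure(list(n_oocytes = n_oocytes, n_bivalents = n_bivalents,
                 preset = preset, geometry = geometry, seed = seed),
            class = "cohort_config")
}
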