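# Compact acquisition geometries used throughout the tests: coarser voxels
# and shorter movies than the defaults, chosen to keep run times small
# while containing the stretch window and (where needed) anaphase.

geom_metaphase <- function() {
  acquisition_geometry(n_z = 18, dz = 0.4, dxy = 0.15, dt = 10,
                       n_t = 16, t_onset_index = 15)
}

geom_anaphase <- function() {
  acquisition_geometry(n_z = 18, dz = 0.4, dxy = 0.15, dt = 10,
                       n_t = 28, t_onset_index = 15)
}

# minimal two-pole + n-bivalent synthetic track table built by hand, with
# poles on the x axis at +/- L/2 and homologs at stated signed equator
# coordinates; used to exercise the fate classifier on known geometry
make_fate_tracks <- function(s_hom, times = seq(-20, 120, by = 10),
                             L_spindle = 4, oocyte_id = "fx1") {
  # s_hom: list per bivalent of function(t) -> c(s1, s2)
  rows <- list()
  for (t in times) {
    rows[[length(rows) + 1]] <- data.frame(
      oocyte_id = oocyte_id, condition = "fixture", time_s = t,
      object_class = "pole", pole_id = c("A", "B"),
      bivalent_id = NA_integer_, homolog_id = NA_integer_,
      endpoint_id = NA_integer_,
      x_um = c(-L_spindle / 2, L_spindle / 2), y_um = 0, z_um = 0)
    for (b in seq_along(s_hom)) {
      s <- s_hom[[b]](t)
      rows[[length(rows) + 1]] <- data.frame(
        oocyte_id = oocyte_id, condition = "fixture", time_s = t,
        object_class = "homolog", pole_id = NA_character_,
        bivalent_id = b, homolog_id = 1:2, endpoint_id = NA_integer_,
        x_um = s, y_um = 0.3 * b, z_um = -0.2 * b)
    }
  }
  do.call(rbind, rows)
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

# independent brute-force oracles for the spindle-frame distances
oracle_plane_dist <- function(p, m, u) {
  abs(sum(u * (p - m))) / sqrt(sum(u^2))
}

oracle_line_dist <- function(p, a, b) {
  d <- b - a
  w <- p - a
  cr <- c(w[2] * d[3] - w[3] * d[2],
          w[3] * d[1] - w[1] * d[3],
          w[1] * d[2] - w[2] * d[1])
  sqrt(sum(cr^2)) / sqrt(sum(d^2))
}
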