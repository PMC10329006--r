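track_columns <- c("oocyte_id", "condition", "time_s", "object_class",
                   "pole_id", "bivalent_id", "homolog_id", "endpoint_id",
                   "x_um", "y_um", "z_um")

#' Validate a tracks table
#'
#' Checks the presence of all required columns, legal object classes, and
#' per-object strictly increasing time. Used internally by every consumer of
#' the tracks schema.
#'
#' @param tracks a data.frame.
#' @return the tracks data.frame, invisibly.
#' @export
validate_tracks <- function(tracks) {
  missing <- setdiff(track_columns, names(tracks))
  if (length(missing) > 0) {
    stop("missing column ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(tracks$object_class), c("pole", "homolog", "endpoint"))
  if (length(bad) > 0) {
    stop("unknown object_class: ", paste(bad, collapse = ", "))
  }
  key <- paste(tracks$oocyte_id, tracks$object_class, tracks$pole_id,
               tracks$bivalent_id, tracks$homolog_id, tracks$endpoint_id)
  for (sub in split(tracks$time_s, key)) {
    if (any(diff(sort(sub)) == 0) || is.unsorted(sub)) {
      stop("non-monotone time within an object track")
    }
  }
  invisible(tracks)
}

#' Read point tracks from CSV
#'
#' Reads a tracks table in the package schema: one row per object per frame,
#' columns `oocyte_id, condition, time_s, object_class, pole_id,
#' bivalent_id, homolog_id, endpoint_id, x_um, y_um, z_um`. Time is in
#' seconds relative to anaphase onset, positions in micrometres. Unknown
#' extra columns are preserved.
#'
#' @param path CSV file path.
#' @return validated tracks data.frame.
#' @export
read_tracks <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tracks(tr)
  tr
}

#' Write point tracks to CSV
#'
#' @param tracks a tracks data.frame (validated before writing).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  validate_tracks(tracks)
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
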