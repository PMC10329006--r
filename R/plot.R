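#' Color-coded per-bivalent metric plot
#'
#' Scatter of an individual-bivalent metric against time, each dot colored
#' by the cohort proportion of bivalents below the threshold in that time
#' bin, with the threshold drawn as a horizontal line -- the standard
#' orientation/congression/compaction presentation for chromosome dynamics
#' cohorts. Output is deterministic given the input tables.
#'
#' @param flags the `flags` data.frame from [classify_timepoints()].
#' @param proportions the `proportions` data.frame from the same call.
#' @param metric one of "theta_folded", "d_eq", "d_ax".
#' @param threshold threshold value to draw (and used for the color scale
#'   label).
#' @param path optional file path; when given the figure is written there
#'   (format from the extension).
#' @return the ggplot object, invisibly when written to `path`.
#' @export
plot_colorcoded <- function(flags, proportions, metric = "theta_folded",
                            threshold, path = NULL) {
  if (nrow(flags) == 0) stop("empty input")
  flag_col <- switch(metric, theta_folded = "oriented", d_eq = "congressed",
                     d_ax = "compacted",
                     stop("unknown metric: ", metric))
  pr <- proportions[proportions$metric == flag_col, c("time_s", "proportion")]
  df <- merge(flags[, c("time_s", metric)], pr, by = "time_s")
  names(df)[2] <- "value"
  ylab <- switch(metric, theta_folded = "angle to spindle axis (deg)",
                 d_eq = "distance to equator (um)",
                 d_ax = "distance to long axis (um)")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                        color = .data$proportion)) +
    ggplot2::geom_point(size = 1, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_color_gradient(low = "#d73027", high = "#1a9850",
                                  limits = c(0, 1),
                                  name = "proportion\nbelow threshold") +
    ggplot2::labs(x = "time relative to anaphase onset (s)", y = ylab) +
    ggplot2::theme_classic()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Reproducibility record for a pipeline run
#'
#' @param config any configuration object (hashed after JSON serialization).
#' @param seed the seed used.
#' @return list with package and R versions, the config hash and the seed.
#' @export
run_info <- function(config = NULL, seed = NA) {
  hash <- NA_character_
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE), tf)
    hash <- unname(tools::md5sum(tf))
  }
  list(package = as.character(utils::packageVersion("meiotrack")),
       r_version = R.version.string, config_hash = hash, seed = seed)
}
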