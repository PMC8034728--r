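# ggplot2 views of the run artifacts: rate and survival kinetics, the
# potential-of-death series, and the spatial death map colored by time.

#' Plot apoptosis-rate kinetics
#'
#' @param kinetics Tibble from [apoptosis_rate()].
#' @return A ggplot.
#' @export
plot_apoptosis_rate <- function(kinetics) {
  df <- kinetics[!is.na(kinetics$apoptosis_rate_pct), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$hours, .data$apoptosis_rate_pct)) +
    ggplot2::labs(x = "time (h)", y = "apoptosis rate (%)") +
    ggplot2::theme_minimal()
  if (nrow(df) == 0L)
    return(p + ggplot2::annotate("text", x = 0, y = 0, label = "no kinetics"))
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::expand_limits(y = 0)
}

#' Plot overall-survival kinetics
#'
#' @param survival Tibble from [overall_survival()].
#' @return A ggplot.
#' @export
plot_survival <- function(survival) {
  ggplot2::ggplot(survival, ggplot2::aes(.data$hours, .data$survival_pct)) +
    ggplot2::geom_line() +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(x = "time (h)", y = "overall survival (%)") +
    ggplot2::theme_minimal()
}

#' Plot the potential-of-death series
#'
#' @param pdeath Tibble from [windowed_pdeath()].
#' @return A ggplot.
#' @export
plot_pdeath <- function(pdeath) {
  ggplot2::ggplot(pdeath, ggplot2::aes(.data$hours, .data$pdeath)) +
    ggplot2::geom_line() +
    ggplot2::expand_limits(y = 0) +
    ggplot2::labs(x = "time (h)", y = "potential of death induction") +
    ggplot2::theme_minimal()
}

#' Spatial map of death events colored by death time
#'
#' @param events Event tibble.
#' @param dims Optional `c(D1, D2)` fixing the panel extent.
#' @param cal A [calibration()] for the hour scale.
#' @return A ggplot (y axis reversed to match image row order).
#' @export
plot_death_map <- function(events, dims = NULL, cal = calibration()) {
  df <- events[!is.na(events$death_frame), , drop = FALSE]
  df$hours <- frames_to_hours(df$death_frame, cal)
  p <- ggplot2::ggplot(df,
                       ggplot2::aes(.data$x, .data$y, size = .data$radius,
                                    color = .data$hours)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_size_identity() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "death time (h)") +
    ggplot2::theme_minimal()
  if (!is.null(dims))
    p <- p + ggplot2::expand_limits(x = c(1, dims[2]), y = c(1, dims[1]))
  p
}

#' Autoplot an apoptomap run
#'
#' @param object An `apoptomap_run`.
#' @param which One of `"rate"`, `"survival"`, `"pdeath"`, `"map"`.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot apoptomap_run
#' @export
autoplot.apoptomap_run <- function(object,
                                   which = c("rate", "survival", "pdeath", "map"),
                                   ...) {
  switch(match.arg(which),
         rate = plot_apoptosis_rate(object$kinetics),
         survival = plot_survival(object$survival),
         pdeath = plot_pdeath(object$pdeath),
         map = plot_death_map(object$events, object$dims,
                              object$cfg$calibration))
}

#' Write the standard figure set for a finished run
#'
#' @param run An `apoptomap_run`.
#' @param dir Output directory.
#' @return Paths of the written figures, invisibly.
#' @export
plot_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  figs <- list(rate = plot_apoptosis_rate(run$kinetics),
               survival = plot_survival(run$survival),
               pdeath = plot_pdeath(run$pdeath),
               death_map = plot_death_map(run$events, run$dims,
                                          run$cfg$calibration))
  paths <- character()
  for (nm in names(figs)) {
    p <- file.path(dir, paste0(nm, ".png"))
    ggplot2::ggsave(p, figs[[nm]], width = 6, height = 4, dpi = 150)
    paths <- c(paths, p)
  }
  invisible(paths)
}
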