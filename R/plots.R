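#' Scatter-and-histogram view of an event table
#'
#' Landing-event contrast against time next to the marginal contrast
#' histogram with its KDE overlay -- the standard first look at a mass
#' photometry acquisition.
#'
#' @param events Event tibble with `time_s` and `contrast`.
#' @param bandwidth KDE bandwidth (contrast units).
#' @param bin_width Histogram bin width.
#' @return A ggplot object (faceted scatter + histogram).
#' @export
plot_contrast_events <- function(events, bandwidth = 2.1e-4,
                                 bin_width = 1e-4) {
  if (nrow(events) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no data") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(events, ggplot2::aes(x = .data$time_s, y = .data$contrast)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.5) +
    ggplot2::labs(x = "time after sample addition (s)",
                  y = "contrast magnitude") +
    ggplot2::theme_minimal()
}

#' @rdname plot_contrast_events
#' @export
plot_contrast_histogram <- function(events, bandwidth = 2.1e-4,
                                    bin_width = 1e-4) {
  if (nrow(events) < 2) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no data") +
             ggplot2::theme_void())
  }
  dens <- contrast_kde(events$contrast, bandwidth = bandwidth)
  scale <- nrow(events) * bin_width
  ggplot2::ggplot(events, ggplot2::aes(x = .data$contrast)) +
    ggplot2::geom_histogram(binwidth = bin_width, fill = "grey70") +
    ggplot2::geom_line(
      data = dens$curve,
      ggplot2::aes(x = .data$contrast, y = .data$density * scale),
      colour = "red"
    ) +
    ggplot2::labs(x = "contrast magnitude", y = "events per bin") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mp_density <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$contrast, y = .data$density)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "contrast magnitude", y = "density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mp_peaks <- function(object, ...) {
  grid <- tibble(contrast = seq(min(object$mu - 4 * object$sigma),
                                max(object$mu + 4 * object$sigma),
                                length.out = 512))
  curves <- purrr::pmap_dfr(
    object[, c("peak", "A", "mu", "sigma")],
    function(peak, A, mu, sigma) {
      tibble(peak = factor(peak), contrast = grid$contrast,
             count = A * exp(-(grid$contrast - mu)^2 / (2 * sigma^2)))
    }
  )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$contrast, y = .data$count,
                                       colour = .data$peak)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "contrast magnitude", y = "fitted counts per bin",
                  colour = "component") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mp_calibration <- function(object, ...) {
  d <- augment(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$mu)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$included), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 8)) +
    ggplot2::labs(x = "nominal length (bp or nt)",
                  y = "peak mean contrast", shape = "in fit") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mp_abundance <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  uncorrected = .data$raw_area / sum(.data$raw_area),
                  corrected = .data$mole_fraction),
    c("uncorrected", "corrected"),
    names_to = "stage", values_to = "fraction"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$length),
                                  y = .data$fraction,
                                  colour = .data$stage, group = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "length (bp or nt)", y = "mole fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Render the standard report figures
#'
#' Writes up to four figures from a pipeline report: the event scatter, the
#' contrast histogram + KDE overlay across replicates, mole fractions before
#' and after the diffusion correction, and the calibration line with
#' residuals. Figures whose stage output is missing are skipped with a
#' warning; an empty run yields placeholder "no data" figures.
#'
#' @param report An `mp_run_report` from [run_pipeline()].
#' @param out_dir Directory for the figure files.
#' @param format `"pdf"` or `"png"`.
#' @return Invisibly, the written file paths.
#' @export
make_figures <- function(report, out_dir, format = c("pdf", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "mp_run_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  save_fig <- function(plot, name) {
    p <- file.path(out_dir, paste0(name, ".", format))
    ggplot2::ggsave(p, plot, width = 6, height = 4, dpi = 150)
    written <<- c(written, p)
  }

  ev1 <- report$replicates[[1]]$events
  if (!is.null(ev1)) {
    save_fig(plot_contrast_events(ev1), "events_scatter")
    save_fig(plot_contrast_histogram(
      ev1, bandwidth = report$config$bandwidth,
      bin_width = report$config$bin_width), "contrast_histogram")
  } else {
    warn("no event table in report; scatter/histogram figures skipped")
  }

  calib <- report$replicates[[1]]$calibration
  if (!is.null(calib)) save_fig(autoplot(calib), "calibration_line")
  else warn("no calibration in report; calibration figure skipped")

  ab <- report$replicates[[1]]$abundance
  if (!is.null(ab)) save_fig(autoplot(ab), "mole_fractions")
  else warn("no abundance stage in report; mole-fraction figure skipped")

  invisible(written)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
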