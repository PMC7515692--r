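#' Calibrate contrast against DNA length
#'
#' Ordinary least-squares line of fitted peak-mean contrast versus nominal
#' length in base pairs (dsDNA) or nucleotides (ssDNA). Species approaching
#' the diffraction limit can be excluded by label (the conventional choice
#' for a 2000 bp fragment); exclusion is always explicit, never automatic.
#'
#' @param peaks Data frame with one row per species: a peak-mean contrast
#'   column (`mu`) and a nominal length column (`length`); a `label` column
#'   is used for exclusions. [peaks_with_lengths()] builds this from an
#'   `mp_peaks` fit.
#' @param exclude Character vector of species labels excluded from the fit
#'   (still reported, never silently dropped).
#' @param through_origin If `TRUE`, force the line through zero contrast at
#'   zero length (direct proportionality); default is a free intercept.
#'
#' @return An object of class `mp_calibration`: list with `slope` (contrast
#'   per bp/nt), `intercept`, `r_squared` (`NA` with a flag when fewer than 3
#'   points), `n_points`, `excluded_labels`, `data`, and the underlying `lm`
#'   fit.
#' @export
#' @examples
#' pk <- tibble::tibble(label = c("100bp", "400bp", "800bp"),
#'                      length = c(100, 400, 800),
#'                      mu = 1.22e-5 * c(100, 400, 800))
#' fit <- fit_contrast_vs_length(pk)
#' glance(fit)
fit_contrast_vs_length <- function(peaks, exclude = character(),
                                   through_origin = FALSE) {
  stopifnot(all(c("mu", "length") %in% names(peaks)))
  if (!"label" %in% names(peaks)) peaks$label <- as.character(peaks$length)
  unknown <- setdiff(exclude, peaks$label)
  if (length(unknown) > 0) {
    warn(paste0("exclude labels not present: ", paste(unknown, collapse = ", ")))
  }
  included <- !(peaks$label %in% exclude)
  if (sum(included) < 2) abort("need at least 2 included points for a line.")
  d <- peaks[included, ]
  fit <- if (through_origin) lm(mu ~ 0 + length, data = d)
         else lm(mu ~ length, data = d)
  cf <- coef(fit)
  slope <- unname(cf[["length"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  n <- nrow(d)
  r2 <- if (n >= 3) summary(fit)$r.squared else NA_real_
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         r_squared_defined = n >= 3, n_points = n,
         excluded_labels = exclude, through_origin = through_origin,
         data = as_tibble(peaks[, c("label", "length", "mu")]),
         included = included, lm = fit),
    class = "mp_calibration"
  )
}

#' @export
print.mp_calibration <- function(x, ...) {
  cat("<mp_calibration>\n")
  cat(sprintf("  slope: %.4g contrast per bp/nt, intercept: %.4g\n",
              x$slope, x$intercept))
  cat(sprintf("  R^2: %s over %d points%s\n",
              if (x$r_squared_defined) sprintf("%.6f", x$r_squared)
              else "undefined (2 points)",
              x$n_points,
              if (length(x$excluded_labels))
                paste0(" (excluded: ",
                       paste(x$excluded_labels, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' @method tidy mp_calibration
#' @export
tidy.mp_calibration <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @method glance mp_calibration
#' @export
glance.mp_calibration <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept, r.squared = x$r_squared,
    n_points = x$n_points, n_excluded = length(x$excluded_labels),
    through_origin = x$through_origin
  )
}

#' @method augment mp_calibration
#' @export
augment.mp_calibration <- function(x, ...) {
  d <- x$data
  d$included <- x$included
  d$fitted <- x$intercept + x$slope * d$length
  d$residual <- d$mu - d$fitted
  d
}

#' Convert contrast to a length estimate
#'
#' Inverts the calibration line: `length = (contrast - intercept) / slope`.
#' Contrasts below the intercept give negative estimates, returned as-is with
#' a warning rather than clamped.
#'
#' @param fit An `mp_calibration` (or any list with `slope`, `intercept`).
#' @param contrast Numeric vector of contrasts.
#' @return Estimated lengths in bp or nt (same unit as the calibration).
#' @export
length_from_contrast <- function(fit, contrast) {
  if (fit$slope <= 0) abort("calibration slope must be > 0.")
  est <- (contrast - fit$intercept) / fit$slope
  if (any(est < 0)) warn("contrast below the calibration intercept: negative length estimate(s)")
  est
}

#' Summarize length-recovery error
#'
#' Deviations `estimated - nominal` per species, with the mean and sample
#' standard deviation (denominator n - 1) across all supplied values.
#'
#' @param estimates Estimated lengths (bp or nt).
#' @param nominals Nominal lengths, paired with `estimates`.
#' @param labels Optional species labels.
#' @return A list of class `mp_length_error`: tibble `per_species` (`label`,
#'   `nominal`, `estimated`, `deviation`), `mean_error`, `sd_error` (`NA`
#'   with `sd_defined = FALSE` for a single value), and `sd_denominator`
#'   (`"n-1"`).
#' @export
#' @examples
#' length_error_summary(c(102, 198), c(100, 200))
length_error_summary <- function(estimates, nominals, labels = NULL) {
  if (length(estimates) != length(nominals)) {
    abort("`estimates` and `nominals` must have equal length.")
  }
  if (is.null(labels)) labels <- as.character(nominals)
  dev <- estimates - nominals
  structure(
    list(
      per_species = tibble(label = labels, nominal = nominals,
                           estimated = estimates, deviation = dev),
      mean_error = mean(dev),
      sd_error = if (length(dev) >= 2) sd(dev) else NA_real_,
      sd_defined = length(dev) >= 2,
      sd_denominator = "n-1"
    ),
    class = "mp_length_error"
  )
}

#' @export
print.mp_length_error <- function(x, ...) {
  cat(sprintf("<mp_length_error> mean %.3g +/- %s (n = %d, sd denominator %s)\n",
              x$mean_error,
              if (x$sd_defined) sprintf("%.3g", x$sd_error) else "NA",
              nrow(x$per_species), x$sd_denominator))
  invisible(x)
}

#' @method tidy mp_length_error
#' @export
tidy.mp_length_error <- function(x, ...) x$per_species

#' @method glance mp_length_error
#' @export
glance.mp_length_error <- function(x, ...) {
  tibble(mean_error = x$mean_error, sd_error = x$sd_error,
         n = nrow(x$per_species))
}

#' Mass-domain contrast ratio
#'
#' Converts a contrast-per-length slope into contrast per kDa, for comparison
#' with protein mass photometry. For ssDNA measured per nucleotide, double
#' the per-nt slope first (`nt_to_bp = TRUE`) so the ratio is per base-pair
#' equivalent.
#'
#' @param fit An `mp_calibration` (or any list with `slope`).
#' @param mass_per_unit kDa per bp (default 0.649 for dsDNA) or per nt.
#' @param nt_to_bp If `TRUE`, multiply the slope by 2 to convert a per-nt
#'   ssDNA slope to a per-bp-equivalent before dividing.
#' @return Contrast per kDa.
#' @export
#' @examples
#' mass_contrast_ratio(list(slope = 1.22e-5), mass_per_unit = 0.649)
mass_contrast_ratio <- function(fit, mass_per_unit = 0.649, nt_to_bp = FALSE) {
  if (mass_per_unit <= 0) abort("`mass_per_unit` must be > 0.")
  slope <- fit$slope
  if (nt_to_bp) slope <- 2 * slope
  slope / mass_per_unit
}

#' Attach nominal lengths to fitted peaks
#'
#' Assigns fitted mixture components to nominal species by rank: ascending
#' peak contrast is matched to ascending nominal length (the standard
#' assignment-by-inspection for a ladder).
#'
#' @param peaks An `mp_peaks` tibble from [fit_gaussian_mixture()].
#' @param lengths Nominal lengths, one per component.
#' @param labels Optional labels; defaults to `<length>bp`.
#' @param unit Label suffix used when `labels` is `NULL`.
#' @return The peaks tibble with `label` and `length` columns added.
#' @export
peaks_with_lengths <- function(peaks, lengths, labels = NULL, unit = "bp") {
  if (nrow(peaks) != length(lengths)) {
    abort("number of fitted components must equal number of nominal lengths.")
  }
  lengths <- sort(lengths)
  if (is.null(labels)) labels <- paste0(lengths, unit)
  out <- peaks[order(peaks$mu), ]
  out$label <- labels
  out$length <- lengths
  out
}
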