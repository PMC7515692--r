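#' Fit the average binding rate from landing times
#'
#' Landing events observed in the window `[t0, t_final]` are modelled as
#' arrival times of an exponential depletion process measured from sample
#' addition, truncated to the window. The default estimator is the maximum
#' likelihood rate of the truncated exponential density
#' `k * exp(-k t) / (exp(-k t0) - exp(-k t_final))`; a binned least-squares
#' fit of an exponential to the event rate versus time is available as an
#' alternative (`method = "binned"`).
#'
#' When the observed times are indistinguishable from uniform (no depletion
#' within the window), the likelihood is maximized at `k -> 0`; the estimate
#' is then flagged with `depletion_detected = FALSE`.
#'
#' @param event_times Event times in seconds from sample addition (>= 50).
#' @param window An [acquisition_window()].
#' @param method `"mle"` (default) or `"binned"`.
#' @param n_bins Bins for the `"binned"` method.
#' @return A list of class `mp_rate_fit`: `k` (s^-1), `se`, `n_events`,
#'   `depletion_detected`, `method`, `window`.
#' @export
fit_binding_rate <- function(event_times, window = acquisition_window(),
                             method = c("mle", "binned"), n_bins = 24L) {
  method <- match.arg(method)
  event_times <- event_times[is.finite(event_times)]
  n <- length(event_times)
  if (n < 50) abort("need at least 50 events for a stable rate fit.")
  if (any(event_times < window$t0 - 1e-9 | event_times > window$t_final + 1e-9)) {
    abort("all event times must lie within the acquisition window.")
  }
  if (diff(range(event_times)) == 0) abort("all event times are equal.")
  t0 <- window$t0; tf <- window$t_final

  if (method == "mle") {
    nll <- function(logk) {
      k <- exp(logk)
      -(n * log(k) - k * sum(event_times) - n * log(exp(-k * t0) - exp(-k * tf)))
    }
    lo <- log(1e-6); hi <- log(10 / (tf - t0) * 100)
    opt <- optimize(nll, c(lo, hi))
    k_hat <- exp(opt$minimum)
    # observed information on the k scale by central differences
    h <- k_hat * 1e-4
    d2 <- (nll(log(k_hat + h)) - 2 * nll(log(k_hat)) + nll(log(k_hat - h)))
    # second derivative wrt log k; transform to k: I_k = I_logk / k^2
    info_logk <- d2 / (log(k_hat + h) - log(k_hat))^2
    se <- if (is.finite(info_logk) && info_logk > 0) {
      k_hat / sqrt(info_logk)
    } else NA_real_
    depletion <- opt$minimum > lo + 1e-3 && k_hat * (tf - t0) > 1e-3
  } else {
    breaks <- seq(t0, tf, length.out = n_bins + 1L)
    counts <- graphics::hist(event_times, breaks = breaks, plot = FALSE)$counts
    mids <- (breaks[-1] + head(breaks, -1)) / 2
    d <- data.frame(t = mids, y = counts)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c0 * exp(-k * t), data = d,
                        start = list(c0 = max(counts), k = 1 / (tf - t0))),
      error = function(e) NULL
    )
    if (is.null(fit)) abort("binned exponential fit failed to converge.")
    cf <- coef(fit)
    k_hat <- unname(cf[["k"]])
    se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
    depletion <- k_hat * (tf - t0) > 1e-3
  }
  structure(
    list(k = k_hat, se = se, n_events = n, depletion_detected = depletion,
         method = method, window = window),
    class = "mp_rate_fit"
  )
}

#' @export
print.mp_rate_fit <- function(x, ...) {
  cat(sprintf("<mp_rate_fit> k = %.4g +/- %.2g s^-1 (%s, %d events)%s\n",
              x$k, x$se, x$method, x$n_events,
              if (!x$depletion_detected) " [no depletion detected]" else ""))
  invisible(x)
}

#' @method glance mp_rate_fit
#' @export
glance.mp_rate_fit <- function(x, ...) {
  tibble(k = x$k, se = x$se, n_events = x$n_events,
         depletion_detected = x$depletion_detected, method = x$method)
}

#' Abundance-weighted mean length
#'
#' Default (`mode = "weighted"`): `sum(length_i * a_i) / sum(a_i)`, the
#' abundance-weighted mean length of the components in solution. A literal
#' mode dividing by the number of species, `sum(length_i * a_i) / N`, is kept
#' for strict fidelity to the conventional printed formula; with fractional
#' abundances it equals the weighted mean divided by N and is dimensionally a
#' mean only when the `a_i` sum to N, so it is flagged in the result
#' attribute.
#'
#' @param lengths Species lengths (bp or nt).
#' @param abundances Non-negative abundances (peak areas or counts), paired
#'   with `lengths`.
#' @param mode `"weighted"` (default) or `"literal"`.
#' @return The mean length, with attribute `mode`.
#' @export
#' @examples
#' mean_length(c(100, 300), c(1, 1))  # 200
#' mean_length(c(100, 300), c(3, 1))  # 150
mean_length <- function(lengths, abundances, mode = c("weighted", "literal")) {
  mode <- match.arg(mode)
  if (length(lengths) != length(abundances)) {
    abort("`lengths` and `abundances` must have equal length.")
  }
  if (any(abundances < 0)) abort("abundances must be >= 0.")
  if (sum(abundances) == 0) abort("abundances must not all be zero.")
  v <- if (mode == "weighted") {
    sum(lengths * abundances) / sum(abundances)
  } else {
    sum(lengths * abundances) / length(lengths)
  }
  structure(v, mode = mode)
}

#' Diffusion scaling factor
#'
#' `alpha = k / mean_length^beta`: converts the fitted average binding rate
#' into the scaling factor of the power law `k_i = alpha * length^beta`,
#' assumed constant across all DNA components.
#'
#' @param k Average binding rate (s^-1, > 0).
#' @param mean_length Mean length of the components in solution (> 0).
#' @param beta Diffusion exponent, default -0.72.
#' @return The scaling factor `alpha`.
#' @export
#' @examples
#' scaling_alpha(0.02, 200)  # 0.02 * 200^0.72
scaling_alpha <- function(k, mean_length, beta = -0.72) {
  if (k <= 0 || mean_length <= 0) abort("`k` and `mean_length` must be > 0.")
  k / mean_length^beta
}

#' Per-species binding rate
#'
#' `k_i = alpha * length^beta`, the diffusion-limited binding rate of a
#' species of the given length.
#'
#' @param alpha Scaling factor (> 0).
#' @param length Species length in bp or nt (>= 1).
#' @param beta Diffusion exponent, default -0.72.
#' @return Binding rate(s) in s^-1.
#' @export
species_rate <- function(alpha, length, beta = -0.72) {
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (any(length < 1)) abort("`length` must be >= 1.")
  alpha * length^beta
}

#' Finite-window diffusion correction
#'
#' Rescales an observed abundance to the abundance that would have been
#' observed over all time: `a' = a * exp(k_i * t0) / (1 - exp(-k_i *
#' (t_final - t0)))`. The numerator restores molecules bound before
#' acquisition started; the denominator restores those still in solution at
#' `t_final`. The factor is always >= 1.
#'
#' @param raw_area Observed abundance `a` (peak area or count, >= 0).
#' @param k_i Species binding rate (s^-1, > 0); vectorized with `raw_area`.
#' @param window An [acquisition_window()].
#' @return Corrected abundance(s) `a'`.
#' @export
#' @examples
#' diffusion_correction(100, 0.01, acquisition_window(15, 135))
diffusion_correction <- function(raw_area, k_i, window = acquisition_window()) {
  if (any(k_i <= 0)) abort("`k_i` must be > 0.")
  if (any(raw_area < 0)) abort("`raw_area` must be >= 0.")
  raw_area * exp(k_i * window$t0) / (1 - exp(-k_i * (window$t_final - window$t0)))
}

#' Renormalize corrected abundances to mole fractions
#'
#' @param corrected_areas Non-negative corrected abundances with positive sum.
#' @return Fractions summing to 1.
#' @export
mole_fractions <- function(corrected_areas) {
  if (length(corrected_areas) < 1) abort("need at least one species.")
  s <- sum(corrected_areas)
  if (s <= 0) abort("total corrected area must be > 0.")
  corrected_areas / s
}

#' Diffusion-corrected species abundances
#'
#' Full concentration-measurement chain: fit the average binding rate `k` on
#' the pooled event times, compute the abundance-weighted mean length from
#' the raw peak areas, derive `alpha = k / mean_length^beta` and per-species
#' rates `k_i = alpha * length_i^beta`, apply the finite-window correction to
#' each raw area, and renormalize. A single pass is performed by default;
#' `iterate = TRUE` repeats the mean-length/correction step to a fixed point.
#'
#' Species whose peak mean lies within `floor_sigmas` fitted widths of
#' `contrast_floor` are flagged `near_detection_floor`: their counts may be
#' depressed by non-unity detection efficiency (the known shortfall of the
#' shortest ladder species) and no efficiency correction is applied.
#'
#' @param peaks Data frame with columns `label`, `length`, `mu`, `sigma`,
#'   `area` (e.g. [peaks_with_lengths()] output).
#' @param event_times Pooled landing times of all species, seconds from
#'   sample addition.
#' @param window An [acquisition_window()].
#' @param beta Diffusion exponent, default -0.72.
#' @param mean_mode Mean-length convention, see [mean_length()].
#' @param iterate If `TRUE`, iterate mean length and correction to
#'   self-consistency instead of the default single pass.
#' @param rate_method Passed to [fit_binding_rate()].
#' @param contrast_floor Contrast detection floor used for the efficiency
#'   caveat flag (default 0, disabling the flag).
#' @param floor_sigmas Widths defining "near the floor".
#'
#' @return A tibble of class `mp_abundance`, one row per species: `label`,
#'   `length`, `raw_area`, `k_i`, `corrected_area`, `mole_fraction`,
#'   `near_detection_floor`. Attributes `kinetics` (list with `k`, `se`,
#'   `alpha`, `beta`, `mean_length`, window bounds) and `rate_fit`.
#' @export
correct_abundances <- function(peaks, event_times,
                               window = acquisition_window(),
                               beta = -0.72,
                               mean_mode = c("weighted", "literal"),
                               iterate = FALSE,
                               rate_method = c("mle", "binned"),
                               contrast_floor = 0,
                               floor_sigmas = 3) {
  mean_mode <- match.arg(mean_mode)
  rate_method <- match.arg(rate_method)
  stopifnot(all(c("label", "length", "mu", "sigma", "area") %in% names(peaks)))
  rate <- fit_binding_rate(event_times, window, method = rate_method)

  a <- peaks$area
  n_pass <- if (iterate) 100L else 1L
  for (pass in seq_len(n_pass)) {
    mbp <- as.numeric(mean_length(peaks$length, a, mode = mean_mode))
    alpha <- scaling_alpha(rate$k, mbp, beta)
    k_i <- species_rate(alpha, peaks$length, beta)
    a_new <- diffusion_correction(peaks$area, k_i, window)
    if (iterate && max(abs(a_new - a) / pmax(a, 1e-300)) < 1e-12) {
      a <- a_new
      break
    }
    a <- a_new
  }

  out <- tibble(
    label = peaks$label,
    length = peaks$length,
    raw_area = peaks$area,
    k_i = k_i,
    corrected_area = a,
    mole_fraction = mole_fractions(a),
    near_detection_floor = peaks$mu - floor_sigmas * peaks$sigma <= contrast_floor
  )
  structure(
    out,
    class = c("mp_abundance", class(out)),
    kinetics = list(k = rate$k, se = rate$se, alpha = alpha, beta = beta,
                    mean_length = mbp, mean_mode = mean_mode,
                    t0 = window$t0, t_final = window$t_final,
                    iterated = iterate),
    rate_fit = rate
  )
}

#' @export
print.mp_abundance <- function(x, ...) {
  kin <- attr(x, "kinetics")
  cat(sprintf(
    "<mp_abundance> k = %.4g s^-1, alpha = %.4g, beta = %g, <length> = %.1f\n",
    kin$k, kin$alpha, kin$beta, kin$mean_length))
  NextMethod()
}

#' @method glance mp_abundance
#' @export
glance.mp_abundance <- function(x, ...) {
  kin <- attr(x, "kinetics")
  tibble(k = kin$k, k_se = kin$se, alpha = kin$alpha, beta = kin$beta,
         mean_length = kin$mean_length, t0 = kin$t0, t_final = kin$t_final,
         n_species = nrow(x))
}

#' Delta-method sampling error of corrected mole fractions
#'
#' Treats each species' observed count as Poisson and propagates through the
#' fixed correction factors `g_i = corrected / raw`:
#' `Var(f_i) = [ (1 - f_i)^2 g_i^2 n_i + f_i^2 sum_{j != i} g_j^2 n_j ] / S^2`
#' with `S = sum_j g_j n_j`. Used to judge whether corrected fractions are
#' consistent with a nominal composition.
#'
#' @param abundance An `mp_abundance` tibble.
#' @param bin_width Histogram bin width that converts peak areas to counts;
#'   taken from the peaks fit upstream.
#' @return The abundance tibble with a `mole_fraction_se` column added.
#' @export
abundance_se <- function(abundance, bin_width = 1e-4) {
  n_i <- abundance$raw_area / bin_width
  g_i <- abundance$corrected_area / abundance$raw_area
  S <- sum(g_i * n_i)
  f <- abundance$mole_fraction
  var_f <- vapply(seq_along(f), function(i) {
    ((1 - f[i])^2 * g_i[i]^2 * n_i[i] +
       f[i]^2 * sum((g_i^2 * n_i)[-i])) / S^2
  }, numeric(1))
  abundance$mole_fraction_se <- sqrt(var_f)
  abundance
}
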