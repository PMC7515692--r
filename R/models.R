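#' Define a nucleic-acid species
#'
#' A species is one DNA component of a measured mixture: a length in base
#' pairs (dsDNA) or nucleotides (ssDNA), a relative solution concentration,
#' and the number of molecules available in solution when the sample is added.
#'
#' @param label Character label, e.g. `"800bp"`.
#' @param length Integer length in bp (double-stranded) or nt (single-stranded).
#' @param strandedness `"double"` or `"single"`.
#' @param mole_fraction Relative solution concentration in `[0, 1]`.
#' @param n_molecules Number of molecules in solution at sample addition.
#'
#' @return A one-row tibble with columns `label`, `length`, `strandedness`,
#'   `mole_fraction`, `n_molecules`.
#' @export
#' @examples
#' species("800bp", 800)
species <- function(label, length, strandedness = c("double", "single"),
                    mole_fraction = 1, n_molecules = 20000L) {
  strandedness <- match.arg(strandedness)
  if (length < 1) abort("`length` must be >= 1.")
  if (mole_fraction < 0 || mole_fraction > 1) {
    abort("`mole_fraction` must lie in [0, 1].")
  }
  if (n_molecules < 0) abort("`n_molecules` must be >= 0.")
  tibble(
    label = as.character(label),
    length = as.integer(length),
    strandedness = strandedness,
    mole_fraction = as.numeric(mole_fraction),
    n_molecules = as.integer(n_molecules)
  )
}

#' Build an equimolar mixture from species lengths
#'
#' @param lengths Integer vector of lengths (bp or nt).
#' @param strandedness `"double"` or `"single"`, recycled over species.
#' @param n_molecules Molecules in solution per species at sample addition.
#' @param unit Label suffix, `"bp"` or `"nt"`.
#'
#' @return A tibble of species (one row each) with equal mole fractions.
#' @export
equimolar_mixture <- function(lengths, strandedness = "double",
                              n_molecules = 20000L,
                              unit = if (strandedness == "double") "bp" else "nt") {
  purrr::map2_dfr(
    lengths, paste0(lengths, unit),
    function(len, lab) {
      species(lab, len, strandedness,
              mole_fraction = 1 / length(lengths),
              n_molecules = n_molecules)
    }
  )
}

#' Preset DNA mixtures
#'
#' Nominal compositions of the commercial samples the analysis was designed
#' around: a low-mass dsDNA ladder (100--2000 bp, six fragments), a 100 bp
#' ladder (13 fragments, 100--2000 bp), and a set of long circular ssDNA
#' species measured one run per species.
#'
#' @param name One of `"low_mass_ladder"`, `"100bp_ladder"`, `"ssdna_set"`.
#' @param n_molecules Molecules in solution per species at sample addition.
#'
#' @return A tibble of species with equal mole fractions.
#' @export
#' @examples
#' ladder_preset("low_mass_ladder")
ladder_preset <- function(name, n_molecules = 20000L) {
  presets <- list(
    low_mass_ladder = list(lengths = c(100L, 200L, 400L, 800L, 1200L, 2000L),
                           strandedness = "double"),
    `100bp_ladder` = list(
      lengths = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L,
                  900L, 1000L, 1200L, 1500L, 2000L),
      strandedness = "double"
    ),
    ssdna_set = list(lengths = c(4536L, 6048L, 7249L, 8064L),
                     strandedness = "single")
  )
  if (!name %in% names(presets)) {
    abort(paste0(
      "Unknown preset '", name, "'. Valid presets: ",
      paste(names(presets), collapse = ", "), "."
    ))
  }
  p <- presets[[name]]
  equimolar_mixture(p$lengths, p$strandedness, n_molecules = n_molecules)
}

#' Contrast model: linear length-to-contrast conversion with length-dependent spread
#'
#' Interferometric contrast is modelled as proportional to the number of bases,
#' `contrast = intercept + kappa * length`, with a per-molecule multiplicative
#' Gaussian spread whose coefficient of variation steps from `cv_small` to
#' `cv_large` at `crossover_length`, mimicking the broader peaks observed for
#' long strands.
#'
#' @param kappa Contrast per unit length (per bp or per nt). Default
#'   `1.22e-5`, the dsDNA conversion factor.
#' @param intercept Contrast offset, default 0 (direct proportionality).
#' @param cv_small Relative contrast spread below `crossover_length`.
#' @param cv_large Relative contrast spread at or above `crossover_length`.
#' @param crossover_length Length (bp/nt) at which the spread transitions.
#'
#' @return A list of class `mp_contrast_model`.
#' @export
contrast_model <- function(kappa = 1.22e-5, intercept = 0,
                           cv_small = 0.02, cv_large = 0.06,
                           crossover_length = 400L) {
  if (kappa <= 0) abort("`kappa` must be > 0.")
  if (cv_small < 0 || cv_large < 0) abort("contrast CVs must be >= 0.")
  structure(
    list(kappa = kappa, intercept = intercept, cv_small = cv_small,
         cv_large = cv_large, crossover_length = as.integer(crossover_length)),
    class = "mp_contrast_model"
  )
}

#' @export
print.mp_contrast_model <- function(x, ...) {
  cat("<mp_contrast_model>\n")
  cat(sprintf("  kappa: %.4g per bp/nt, intercept: %.4g\n", x$kappa, x$intercept))
  cat(sprintf("  CV: %.3g (< %d bp/nt) -> %.3g\n",
              x$cv_small, x$crossover_length, x$cv_large))
  invisible(x)
}

#' Expected contrast and spread under a contrast model
#'
#' @param model An [contrast_model()] object.
#' @param length Vector of lengths (bp or nt).
#' @return For `contrast_mean`, the noise-free contrast; for `contrast_cv`,
#'   the per-molecule coefficient of variation.
#' @export
contrast_mean <- function(model, length) {
  model$intercept + model$kappa * length
}

#' @rdname contrast_mean
#' @export
contrast_cv <- function(model, length) {
  ifelse(length < model$crossover_length, model$cv_small, model$cv_large)
}

#' Acquisition window
#'
#' Time is measured from sample addition (`t = 0`). Binding begins at sample
#' addition but the movie only covers `[t0, t_final]`; the gap `[0, t0)` is
#' what the diffusion correction accounts for.
#'
#' @param t0 Acquisition start, seconds after sample addition. Default 15 s.
#' @param t_final Acquisition end, seconds after sample addition. Default
#'   135 s (a 120 s movie started 15 s after addition).
#'
#' @return A list of class `mp_window` with elements `t0`, `t_final`.
#' @export
acquisition_window <- function(t0 = 15, t_final = 135) {
  if (t0 < 0 || t_final <= t0) abort("require 0 <= t0 < t_final.")
  structure(list(t0 = t0, t_final = t_final), class = "mp_window")
}

#' @export
print.mp_window <- function(x, ...) {
  cat(sprintf("<mp_window> [%g, %g] s after sample addition\n", x$t0, x$t_final))
  invisible(x)
}

#' Diffusion-limited binding kinetics
#'
#' Per-species binding rates follow the power law `k_i = alpha * length^beta`
#' with the diffusion exponent `beta = -0.72` for DNA. The model can be
#' specified either by `alpha` directly, or by an average rate `k` at a mean
#' length, in which case `alpha = k / mean_length^beta`.
#'
#' @param alpha Scaling factor (s^-1 per unit `length^beta`). Default 0.2,
#'   giving rates of roughly 0.001--0.007 s^-1 across a 100--2000 bp ladder.
#' @param beta Diffusion exponent, default -0.72.
#' @param k Average binding rate (s^-1); alternative to `alpha`.
#' @param mean_length Mean length associated with `k` (bp or nt).
#'
#' @return A list of class `mp_kinetics` with `alpha`, `beta`, and, when
#'   derived from a fit, `k` and `mean_length`.
#' @export
#' @examples
#' kinetics_model(alpha = 0.2)
#' kinetics_model(k = 0.02, mean_length = 200)
kinetics_model <- function(alpha = 0.2, beta = -0.72,
                           k = NULL, mean_length = NULL) {
  if (beta >= 0) abort("`beta` must be negative (rates fall with length).")
  if (!is.null(k)) {
    if (is.null(mean_length)) {
      abort("supply `mean_length` together with `k`.")
    }
    if (k <= 0 || mean_length <= 0) abort("`k` and `mean_length` must be > 0.")
    alpha <- k / mean_length^beta
  }
  if (alpha <= 0) abort("`alpha` must be > 0.")
  structure(
    list(alpha = alpha, beta = beta, k = k, mean_length = mean_length),
    class = "mp_kinetics"
  )
}

#' @export
print.mp_kinetics <- function(x, ...) {
  cat(sprintf("<mp_kinetics> k_i = %.4g * length^%g s^-1\n", x$alpha, x$beta))
  if (!is.null(x$k)) {
    cat(sprintf("  from average k = %.4g s^-1 at <length> = %.4g\n",
                x$k, x$mean_length))
  }
  invisible(x)
}
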