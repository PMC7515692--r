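#' Kernel density estimate of a contrast distribution
#'
#' Gaussian-kernel density on a uniform grid spanning
#' `[min - 4*bandwidth, max + 4*bandwidth]`, renormalized so the trapezoid
#' integral over the grid is exactly 1. The bandwidth is the standard
#' deviation of the Gaussian kernel in absolute contrast units (the
#' convention used for published contrast KDEs, e.g. width 2.1e-4). A
#' relative convention, `bandwidth = bw_factor * sd(contrasts)`, is available
#' for plotting via `bw_factor`.
#'
#' @param contrasts Numeric vector of event contrasts (>= 2 values).
#' @param bandwidth Kernel standard deviation in contrast units.
#' @param n_grid Number of grid points (>= 512 recommended).
#' @param bw_factor If supplied, overrides `bandwidth` with
#'   `bw_factor * sd(contrasts)` (violin-plot style convention).
#'
#' @return A list of class `mp_density`: tibble `curve` (`contrast`,
#'   `density`) and `bandwidth`.
#' @export
contrast_kde <- function(contrasts, bandwidth = 2.1e-4, n_grid = 512L,
                         bw_factor = NULL) {
  contrasts <- contrasts[is.finite(contrasts)]
  if (length(contrasts) < 2) abort("need at least 2 events for a KDE.")
  if (!is.null(bw_factor)) bandwidth <- bw_factor * sd(contrasts)
  if (bandwidth <= 0) abort("`bandwidth` must be > 0.")
  d <- density(contrasts, bw = bandwidth, kernel = "gaussian",
               from = min(contrasts) - 4 * bandwidth,
               to = max(contrasts) + 4 * bandwidth,
               n = max(512L, n_grid))
  area <- .trapz(d$x, d$y)
  structure(
    list(curve = tibble(contrast = d$x, density = d$y / area),
         bandwidth = bandwidth, n = length(contrasts)),
    class = "mp_density"
  )
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' @export
print.mp_density <- function(x, ...) {
  cat(sprintf("<mp_density> %d events, bandwidth %.3g, grid of %d points\n",
              x$n, x$bandwidth, nrow(x$curve)))
  invisible(x)
}

#' Initial peak guesses from a density curve
#'
#' Local maxima of the density with topographic prominence of at least
#' `min_prominence` times the global maximum, used to initialize the
#' sum-of-Gaussians fit. Prominence of a peak is its height minus the highest
#' saddle separating it from higher ground (the global minimum on a side with
#' no higher peak).
#'
#' @param density An `mp_density` from [contrast_kde()].
#' @param min_prominence Fraction of the maximum density, in `[0, 1]`.
#'
#' @return Tibble of guesses (`mu`, `A`, `prominence`), sorted by `mu`.
#' @export
find_contrast_peaks <- function(density, min_prominence = 0.01) {
  y <- density$curve$density
  x <- density$curve$contrast
  n <- length(y)
  i <- 2:(n - 1)
  locmax <- i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
  if (length(locmax) == 0) return(tibble(mu = numeric(), A = numeric(),
                                         prominence = numeric()))
  prom <- vapply(locmax, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    right <- y[(p + 1):n]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(p - 1)])
              else min(left)
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
              else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  keep <- prom >= min_prominence * max(y)
  tibble(mu = x[locmax][keep], A = y[locmax][keep],
         prominence = prom[keep]) |>
    dplyr::arrange(.data$mu)
}

#' Fit a sum of Gaussians to a contrast histogram
#'
#' The event contrasts are binned at fixed `bin_width` and the histogram
#' counts are fit by least squares to a sum of Gaussian components
#' initialized from the supplied guesses (typically [find_contrast_peaks()]
#' on a KDE). The component count equals the guess count; no model selection
#' is performed. Under the count-density convention the area of each
#' component, `a = A * sigma * sqrt(2*pi)`, estimates (events in that peak)
#' times `bin_width`, so `a / bin_width` is the molecule count per species.
#'
#' As an alternative, `target = "kde"` fits the Gaussians to the KDE curve
#' itself instead of the histogram; areas are then fractions of total density
#' and are rescaled to the same count-times-bin-width convention.
#'
#' @param contrasts Numeric vector of event contrasts (>= 50).
#' @param init Tibble of guesses with columns `mu` and optionally `A`;
#'   or an integer giving the number of components, in which case guesses
#'   come from [find_contrast_peaks()] with the default KDE bandwidth.
#' @param bin_width Histogram bin width in contrast units.
#' @param bandwidth KDE bandwidth used when guesses must be derived.
#' @param target `"histogram"` (default) or `"kde"`.
#'
#' @return A tibble of class `mp_peaks`, one row per component sorted by
#'   `mu`: columns `peak`, `A`, `mu`, `sigma`, `area`. Attributes:
#'   `bin_width`, `residual` (root-mean-square residual relative to the peak
#'   histogram count), `converged`, `n_events`, and `underfit` (TRUE when the
#'   residual suggests fewer components than modes in the data).
#' @export
fit_gaussian_mixture <- function(contrasts, init = NULL, bin_width = 1e-4,
                                 bandwidth = 2.1e-4,
                                 target = c("histogram", "kde")) {
  target <- match.arg(target)
  contrasts <- contrasts[is.finite(contrasts)]
  if (length(contrasts) < 50) abort("need at least 50 events for a mixture fit.")
  if (bin_width <= 0) abort("`bin_width` must be > 0.")

  kde <- contrast_kde(contrasts, bandwidth = bandwidth)
  if (is.null(init)) init <- find_contrast_peaks(kde)
  if (is.numeric(init) && length(init) == 1) {
    guesses <- find_contrast_peaks(kde, min_prominence = 0)
    guesses <- guesses[order(-guesses$prominence), ]
    init <- dplyr::arrange(head(guesses, init), .data$mu)
  }
  if (nrow(init) < 1) abort("need at least one initial peak guess.")
  k <- nrow(init)

  fit_once <- function(bw_fit, mu0, sigma0, a_area0) {
    if (target == "histogram") {
      breaks <- seq(floor(min(contrasts) / bw_fit) * bw_fit,
                    max(contrasts) + bw_fit, by = bw_fit)
      h <- graphics::hist(contrasts, breaks = breaks, plot = FALSE)
      xs <- h$mids
      ys <- h$counts
    } else {
      xs <- kde$curve$contrast
      ys <- kde$curve$density
    }
    # expected value per bin: component mass integrated over the bin (erf
    # model), so coarse binning does not bias the fitted centres
    model <- function(p) {
      A <- p[seq_len(k)]; mu <- p[k + seq_len(k)]
      sg <- abs(p[2 * k + seq_len(k)])
      if (target == "histogram") {
        rowSums(vapply(seq_len(k), function(j) {
          mass <- A[j] * sg[j] * sqrt(2 * pi) *
            (stats::pnorm(xs + bw_fit / 2, mu[j], sg[j]) -
               stats::pnorm(xs - bw_fit / 2, mu[j], sg[j]))
          mass / bw_fit
        }, numeric(length(xs))))
      } else {
        rowSums(vapply(seq_len(k), function(j) {
          A[j] * exp(-(xs - mu[j])^2 / (2 * sg[j]^2))
        }, numeric(length(xs))))
      }
    }
    a0 <- if (is.null(a_area0)) {
      vapply(seq_len(k), function(j) ys[which.min(abs(xs - init$mu[j]))],
             numeric(1))
    } else {
      a_area0 / (sigma0 * sqrt(2 * pi))
    }
    fit <- minpack.lm::nls.lm(
      par = c(a0, mu0, sigma0), fn = function(p) ys - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    p <- fit$par
    list(A = abs(p[seq_len(k)]), mu = p[k + seq_len(k)],
         sg = abs(p[2 * k + seq_len(k)]),
         resid = sqrt(mean((ys - model(p))^2)) / max(ys),
         info = fit$info)
  }

  sigma0 <- rep(max(bandwidth, bin_width), k)
  if (k > 1) {
    gaps <- diff(sort(init$mu))
    sigma0 <- pmax(sigma0, min(gaps) / 6)
  }
  res <- fit_once(bin_width, init$mu, sigma0, NULL)
  used_bin <- bin_width
  if (target == "histogram" && any(res$sg < bin_width)) {
    # narrow components under-resolved by the requested binning: refit once
    # at a bin width that resolves the narrowest fitted component
    used_bin <- max(min(res$sg) / 2, diff(range(contrasts)) / 5000)
    if (used_bin < bin_width) {
      res2 <- fit_once(used_bin, res$mu,
                       pmax(res$sg, used_bin / 2),
                       res$A * res$sg * sqrt(2 * pi))
      res2$A <- res2$A * bin_width / used_bin  # report on the requested scale
      res <- res2
    } else {
      used_bin <- bin_width
    }
  }
  A <- res$A; mu <- res$mu; sg <- res$sg
  if (any(sg <= 0)) abort("fit produced a non-positive component width.")
  ord <- order(mu)
  rel_resid <- res$resid
  peaks <- tibble(
    peak = seq_len(k),
    A = A[ord] * (if (target == "kde") length(contrasts) * bin_width else 1),
    mu = mu[ord],
    sigma = sg[ord]
  )
  peaks$area <- peak_area(peaks$A, peaks$sigma)
  structure(
    peaks,
    class = c("mp_peaks", class(peaks)),
    bin_width = bin_width,
    residual = rel_resid,
    converged = res$info %in% 1:4,
    n_events = length(contrasts),
    underfit = rel_resid > 0.1
  )
}

#' Area under a Gaussian peak
#'
#' `a = A * sigma * sqrt(2*pi)`: the integral of a Gaussian of height `A` and
#' standard deviation `sigma`. Under the histogram count-density convention
#' this is (molecule count in the peak) times the histogram bin width.
#'
#' @param A Peak height at the centroid (>= 0).
#' @param sigma Standard deviation (> 0). Alternatively pass an `mp_peaks`
#'   row or tibble as `A` and leave `sigma` missing.
#' @return Numeric area(s).
#' @export
#' @examples
#' peak_area(1, 1)  # sqrt(2 * pi)
peak_area <- function(A, sigma) {
  if (missing(sigma) && is.data.frame(A)) {
    sigma <- A$sigma
    A <- A$A
  }
  if (any(sigma <= 0)) abort("`sigma` must be > 0.")
  A * sigma * sqrt(2 * pi)
}

#' @export
print.mp_peaks <- function(x, ...) {
  cat(sprintf("<mp_peaks> %d component(s), %d events, rel. residual %.3g%s\n",
              nrow(x), attr(x, "n_events"), attr(x, "residual"),
              if (isTRUE(attr(x, "underfit"))) " [possible underfit]" else ""))
  NextMethod()
}

#' @method glance mp_peaks
#' @export
glance.mp_peaks <- function(x, ...) {
  tibble(
    n_components = nrow(x),
    n_events = attr(x, "n_events"),
    bin_width = attr(x, "bin_width"),
    residual = attr(x, "residual"),
    converged = attr(x, "converged"),
    underfit = attr(x, "underfit")
  )
}
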