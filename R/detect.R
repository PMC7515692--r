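#' Ratiometric differential stack
#'
#' Consecutive non-overlapping batches of `n_binned` frames are averaged, and
#' differential frame `j` is `(batch[j+1] - batch[j]) / batch[j]`,
#' element-wise, so that static background divides out and only reflectivity
#' changes (landing events) remain. Differential frame `j` is timestamped at
#' the boundary between batches `j` and `j+1`.
#'
#' @param movie An `mp_movie` (or any list with `frames`, `frame_period`,
#'   `t_start`).
#' @param n_binned Frames per averaging batch (>= 1).
#'
#' @return A list of class `mp_diff_stack`: `frames` (array `t` x `y` x `x`),
#'   `times` (seconds from sample addition, one per differential frame),
#'   `n_binned`, `psf_sigma_px`.
#' @export
ratiometric_stack <- function(movie, n_binned = 8L) {
  n_binned <- as.integer(n_binned)
  if (n_binned < 1) abort("`n_binned` must be >= 1.")
  nf <- dim(movie$frames)[1]
  if (nf < 2L * n_binned) {
    abort(paste0("need at least ", 2L * n_binned, " frames (2 batches of ",
                 n_binned, "); got ", nf, "."))
  }
  n_batches <- nf %/% n_binned
  ny <- dim(movie$frames)[2]; nx <- dim(movie$frames)[3]
  batches <- array(0, dim = c(n_batches, ny, nx))
  for (b in seq_len(n_batches)) {
    idx <- ((b - 1L) * n_binned + 1L):(b * n_binned)
    batches[b, , ] <- colMeans(movie$frames[idx, , , drop = FALSE], dims = 1)
  }
  out <- array(0, dim = c(n_batches - 1L, ny, nx))
  for (j in seq_len(n_batches - 1L)) {
    out[j, , ] <- (batches[j + 1L, , ] - batches[j, , ]) / batches[j, , ]
  }
  times <- movie$t_start + movie$frame_period * n_binned * seq_len(n_batches - 1L)
  structure(
    list(frames = out, times = times, n_binned = n_binned,
         psf_sigma_px = movie$psf_sigma_px %||% 1.4),
    class = "mp_diff_stack"
  )
}

#' Radial symmetry of a PSF candidate patch
#'
#' Gradient-alignment score: the fraction of image-gradient energy pointing
#' along the radial direction through the patch centre,
#' `sum((g . rhat)^2) / sum(|g|^2)` over all pixels with central-difference
#' gradient `g` and unit radial vector `rhat`. A perfectly radially symmetric
#' patch scores 1; the score is invariant under 90-degree rotation and
#' decreases with asymmetry. Pure noise scores about 0.5 on average.
#'
#' @param patch Square numeric matrix with odd side length, centred on the
#'   candidate pixel.
#' @return A score in `[0, 1]`.
#' @export
radial_symmetry_score <- function(patch) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch)) {
    abort("`patch` must be a square matrix.")
  }
  n <- nrow(patch)
  if (n %% 2 == 0) abort("`patch` must have odd side length.")
  if (n < 3) abort("`patch` must be at least 3 x 3.")
  c0 <- (n + 1) / 2
  inner <- 2:(n - 1)
  # central differences; gy along rows, gx along columns
  gy <- (patch[inner + 1, inner, drop = FALSE] -
           patch[inner - 1, inner, drop = FALSE]) / 2
  gx <- (patch[inner, inner + 1, drop = FALSE] -
           patch[inner, inner - 1, drop = FALSE]) / 2
  ry <- matrix(inner - c0, length(inner), length(inner))
  rx <- t(ry)
  rr <- sqrt(rx^2 + ry^2)
  keep <- rr > 0
  g2 <- gx^2 + gy^2
  if (sum(g2[keep]) == 0) return(0)
  radial <- (gx * rx / rr + gy * ry / rr)^2
  sum(radial[keep]) / sum(g2[keep])
}

#' Detection parameters
#'
#' @param n_binned Frames per averaging batch. Defaults follow the dsDNA
#'   analysis settings (8 binned frames); long ssDNA used 5.
#' @param threshold1 Amplitude criterion: candidate pixels must exceed
#'   `threshold1` times the per-frame robust noise scale (1.4826 x median
#'   absolute deviation) of the matched-filtered differential image.
#'   Default 1; raise to 3 when background demands it.
#' @param threshold2 Radial-symmetry criterion in `[0, 1]`; default 0.2,
#'   relaxed to 0.3 for species approaching the diffraction limit.
#' @param patch_radius_px Half-width of the PSF analysis window in pixels.
#' @return A list of class `mp_detect_params`.
#' @export
detect_params <- function(n_binned = 8L, threshold1 = 1, threshold2 = 0.2,
                          patch_radius_px = 4L) {
  if (n_binned < 1) abort("`n_binned` must be >= 1.")
  if (threshold1 < 0) abort("`threshold1` must be >= 0.")
  if (threshold2 < 0 || threshold2 > 1) abort("`threshold2` must be in [0, 1].")
  if (patch_radius_px < 1) abort("`patch_radius_px` must be >= 1.")
  structure(
    list(n_binned = as.integer(n_binned), threshold1 = threshold1,
         threshold2 = threshold2, patch_radius_px = as.integer(patch_radius_px)),
    class = "mp_detect_params"
  )
}

# separable Gaussian smoothing (matched filter for PSF-sized spots);
# row-normalized band matrix so edges stay unbiased
.smooth_kernel <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

# local maxima of |frame| above thr, 8-neighbourhood, interior pixels only
.local_maxima <- function(absf, thr) {
  ny <- nrow(absf); nx <- ncol(absf)
  if (ny < 3 || nx < 3) return(cbind(integer(0), integer(0)))
  ci <- 2:(ny - 1); cj <- 2:(nx - 1)
  m <- absf[ci, cj]
  ok <- m > thr &
    m >= absf[ci - 1, cj] & m >= absf[ci + 1, cj] &
    m >= absf[ci, cj - 1] & m >= absf[ci, cj + 1] &
    m >= absf[ci - 1, cj - 1] & m >= absf[ci - 1, cj + 1] &
    m >= absf[ci + 1, cj - 1] & m >= absf[ci + 1, cj + 1]
  w <- which(ok, arr.ind = TRUE)
  cbind(w[, 1] + 1L, w[, 2] + 1L)
}

# least-squares 2-D Gaussian (amplitude, centre, width, offset) on a patch
.fit_psf_amplitude <- function(patch, sigma0) {
  n <- nrow(patch)
  c0 <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  med <- median(patch)
  a0 <- patch[c0, c0] - med
  obj <- function(p) {
    g <- p[1] * exp(-((xs - p[2])^2 + (ys - p[3])^2) / (2 * p[4]^2)) + p[5]
    sum((patch - g)^2)
  }
  fit <- tryCatch(
    stats::optim(c(a0, c0, c0, sigma0, med), obj, method = "L-BFGS-B",
                 lower = c(-Inf, c0 - 2, c0 - 2, 0.4, -Inf),
                 upper = c(Inf, c0 + 2, c0 + 2, 4 * sigma0, Inf)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    list(amplitude = a0, x = c0, y = c0, sigma = sigma0)
  } else {
    list(amplitude = fit$par[1], x = fit$par[2], y = fit$par[3],
         sigma = fit$par[4])
  }
}

#' Detect landing events in a differential stack
#'
#' A molecule that lands inside an averaging batch splits its reflectivity
#' step across the two consecutive differential frames bracketing that batch,
#' so detection operates on paired differential images, `frames[j] +
#' frames[j+1]`: the pair sum equals the two-batch differential, always
#' contains the full step of any landing in the middle batch, and has the
#' same noise level as a single differential frame because the shared middle
#' batch cancels. The paired image is matched-filtered with a PSF-sized
#' Gaussian for the candidate search; candidate pixels are local maxima of
#' the absolute filtered image exceeding `threshold1` times its robust noise
#' scale (1.4826 x median absolute deviation). Candidates within `patch_radius_px`
#' of a brighter candidate are suppressed. Each survivor is scored for radial
#' symmetry and kept iff the score is at least `threshold2`. The event
#' contrast is the magnitude of a fitted 2-D Gaussian amplitude over the
#' candidate patch; detections at the same site in consecutive paired frames
#' (one landing appears in up to three, at partial amplitude in the outer
#' two) are merged, keeping the larger amplitude. The event time is the
#' timestamp of the differential frame where the event first appears.
#'
#' @param diff_stack An `mp_diff_stack` from [ratiometric_stack()].
#' @param params An [detect_params()] object.
#'
#' @return An event table: tibble with `time_s`, `contrast`, `x_px`, `y_px`
#'   (0-based pixel coordinates, origin top-left, x = column) and
#'   `symmetry_score`. An empty table is a valid result.
#' @export
detect_events <- function(diff_stack, params = detect_params()) {
  stopifnot(inherits(params, "mp_detect_params"))
  r <- params$patch_radius_px
  sigma0 <- diff_stack$psf_sigma_px %||% 1.4
  nd <- dim(diff_stack$frames)[1]
  ny <- dim(diff_stack$frames)[2]; nx <- dim(diff_stack$frames)[3]
  nfr <- max(1L, nd - 1L)

  Ky <- .smooth_kernel(ny, sigma0)
  Kx <- .smooth_kernel(nx, sigma0)
  per_frame <- vector("list", nfr)
  for (f in seq_len(nfr)) {
    fr <- if (nd == 1L) diff_stack$frames[1, , ]
          else diff_stack$frames[f, , ] + diff_stack$frames[f + 1L, , ]
    # candidate search on the matched-filtered image: convolving with a
    # PSF-sized Gaussian suppresses single-pixel noise while retaining
    # PSF-shaped signal, so Threshold 1 counts multiples of the robust
    # noise scale of the filtered frame
    sm <- Ky %*% fr %*% t(Kx)
    noise <- mad(sm, center = median(sm))
    if (noise == 0) next
    absf <- abs(sm)
    cand <- .local_maxima(absf, params$threshold1 * noise)
    if (nrow(cand) == 0) next
    # greedy suppression: keep brighter of any pair within patch_radius
    amp <- absf[cand]
    ord <- order(amp, decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!keep[i]) next
      if (i < nrow(cand)) {
        j <- (i + 1L):nrow(cand)
        close <- abs(cand[j, 1] - cand[i, 1]) <= r &
          abs(cand[j, 2] - cand[i, 2]) <= r
        keep[j][close] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    rows <- NULL
    for (i in seq_len(nrow(cand))) {
      yi <- cand[i, 1]; xi <- cand[i, 2]
      if (yi - r < 1 || yi + r > ny || xi - r < 1 || xi + r > nx) next
      patch <- fr[(yi - r):(yi + r), (xi - r):(xi + r)]
      score <- radial_symmetry_score(patch)
      if (score < params$threshold2) next
      psf <- .fit_psf_amplitude(patch, sigma0)
      rows <- rbind(rows, data.frame(
        frame = f,
        time_s = diff_stack$times[f],
        contrast = abs(psf$amplitude),
        x_px = xi - 1 + (psf$x - (r + 1)),
        y_px = yi - 1 + (psf$y - (r + 1)),
        symmetry_score = score
      ))
    }
    per_frame[[f]] <- rows
  }
  ev <- dplyr::bind_rows(per_frame)
  empty <- tibble(time_s = numeric(), contrast = numeric(),
                  x_px = numeric(), y_px = numeric(),
                  symmetry_score = numeric())
  if (is.null(ev) || nrow(ev) == 0) return(empty)

  # merge same-site detections in consecutive differential frames
  ev <- ev[order(ev$frame, -ev$contrast), ]
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!keep[i]) next
    later <- which(keep & ev$frame == ev$frame[i] + 1L &
                     abs(ev$x_px - ev$x_px[i]) <= r &
                     abs(ev$y_px - ev$y_px[i]) <= r)
    later <- setdiff(later, i)
    for (j in later) {
      if (ev$contrast[j] > ev$contrast[i]) {
        keep[i] <- FALSE
        break
      } else {
        keep[j] <- FALSE
      }
    }
  }
  ev <- ev[keep, c("time_s", "contrast", "x_px", "y_px", "symmetry_score")]
  dplyr::arrange(as_tibble(ev), .data$time_s)
}
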