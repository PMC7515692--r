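#' Simulate a landing-event stream
#'
#' Each molecule of species `i` binds irreversibly to the coverslip at a time
#' drawn from an exponential distribution with rate `k_i = alpha * length^beta`,
#' measured from sample addition (`t = 0`). Only events falling inside the
#' acquisition window are emitted. The contrast of an emitted event is the
#' species' mean contrast times `(1 + eps)`, `eps ~ N(0, cv(length))`, stored
#' as a positive ratiometric magnitude. Landing positions are uniform over the
#' field of view. Ground-truth species labels are carried in a sidecar column;
#' downstream detection and fitting never read them.
#'
#' @param mixture Species tibble, e.g. from [ladder_preset()] or
#'   [equimolar_mixture()].
#' @param contrast_model A [contrast_model()].
#' @param kinetics A [kinetics_model()].
#' @param window An [acquisition_window()].
#' @param seed Non-negative integer seed; identical seeds give identical
#'   tables.
#' @param field_px Field-of-view side length in pixels for the simulated
#'   positions.
#'
#' @return An event table: a tibble with columns `time_s`, `contrast`,
#'   `x_px`, `y_px`, `species_label`, sorted by time.
#' @export
#' @examples
#' ev <- simulate_event_stream(ladder_preset("low_mass_ladder"), seed = 1)
#' dplyr::count(ev, species_label)
simulate_event_stream <- function(mixture,
                                  contrast_model = mpdna::contrast_model(),
                                  kinetics = kinetics_model(),
                                  window = acquisition_window(),
                                  seed = 1L,
                                  field_px = 128L) {
  stopifnot(inherits(contrast_model, "mp_contrast_model"),
            inherits(kinetics, "mp_kinetics"),
            inherits(window, "mp_window"))
  if (length(seed) != 1 || is.na(seed) || seed < 0) {
    abort("`seed` must be a single non-negative integer.")
  }
  empty <- tibble(time_s = numeric(), contrast = numeric(),
                  x_px = numeric(), y_px = numeric(),
                  species_label = character())
  if (is.null(mixture) || nrow(mixture) == 0) {
    warn("empty mixture: returning an empty event table")
    return(empty)
  }
  if (any(mixture$n_molecules < 0)) abort("`n_molecules` must be >= 0.")
  if (abs(sum(mixture$mole_fraction) - 1) > 1e-9) {
    warn("mixture mole fractions do not sum to 1")
  }

  set.seed(as.integer(seed))
  rows <- purrr::pmap_dfr(
    mixture[, c("label", "length", "n_molecules")],
    function(label, length, n_molecules) {
      if (n_molecules == 0) return(NULL)
      k_i <- species_rate(kinetics$alpha, length, kinetics$beta)
      t_bind <- rexp(n_molecules, rate = k_i)
      t_bind <- t_bind[t_bind >= window$t0 & t_bind <= window$t_final]
      n <- length(t_bind)
      if (n == 0) return(NULL)
      mu <- contrast_mean(contrast_model, length)
      cv <- contrast_cv(contrast_model, length)
      tibble(
        time_s = t_bind,
        contrast = abs(mu * (1 + rnorm(n, 0, cv))),
        x_px = runif(n, 0, field_px),
        y_px = runif(n, 0, field_px),
        species_label = label
      )
    }
  )
  if (nrow(rows) == 0) {
    if (sum(mixture$n_molecules) == 0) {
      warn("no molecules in solution: returning an empty event table")
    }
    return(empty)
  }
  dplyr::arrange(rows, .data$time_s)
}

#' Simulate a ratiometric movie stack from an event table
#'
#' Builds a frame stack containing a static random background (reflectivity
#' reference level 1 plus frozen spatial roughness) and, for each landing
#' event, a step change: a 2-D Gaussian point spread function of amplitude
#' `contrast * reference` appearing at the event time and persisting to the
#' last frame (binding is irreversible). Per-pixel, per-frame shot noise is
#' Gaussian with standard deviation `sqrt(level / photon_budget)`.
#'
#' @param events Event table (`time_s`, `contrast`, `x_px`, `y_px`); times are
#'   seconds from sample addition and must fall inside the movie's span.
#' @param psf_sigma_px PSF standard deviation in pixels (> 0).
#' @param background_rms RMS amplitude of the static background roughness,
#'   relative to the reference level 1.
#' @param photon_budget Effective photons per pixel per frame; shot-noise RMS
#'   on a level-1 pixel is `1/sqrt(photon_budget)`.
#' @param frame_period Seconds per (already temporally averaged) frame.
#' @param frame_count Number of frames.
#' @param shape Integer vector `c(ny, nx)` in pixels.
#' @param t_start Movie start time, seconds from sample addition.
#' @param pixel_size_nm Effective pixel size (metadata only).
#' @param seed Integer seed; identical seeds give identical stacks.
#'
#' @return A list of class `mp_movie`: `frames` (array `t` x `y` x `x`),
#'   `frame_period`, `t_start`, `pixel_size_nm`, `psf_sigma_px`, and the
#'   ground-truth `events` tibble.
#' @export
simulate_movie <- function(events,
                           psf_sigma_px = 1.4,
                           background_rms = 0.02,
                           photon_budget = 2e6,
                           frame_period = 1 / 191,
                           frame_count = 400L,
                           shape = c(128L, 128L),
                           t_start = 15,
                           pixel_size_nm = 84.4,
                           seed = 1L) {
  if (psf_sigma_px <= 0) abort("`psf_sigma_px` must be > 0.")
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  t_end <- t_start + frame_count * frame_period
  if (nrow(events) > 0) {
    bad <- which(events$time_s < t_start | events$time_s > t_end)
    if (length(bad) > 0) {
      abort(paste0(
        "events outside the movie time span [", t_start, ", ",
        signif(t_end, 6), "] s: rows ",
        paste(head(bad, 5), collapse = ", "),
        if (length(bad) > 5) ", ..." else ""
      ))
    }
  }

  set.seed(as.integer(seed))
  background <- 1 + matrix(rnorm(ny * nx, 0, background_rms), ny, nx)

  # signal[y, x] accumulated per frame: events switch on at their frame
  frames <- array(0, dim = c(frame_count, ny, nx))
  signal <- matrix(0, ny, nx)
  if (nrow(events) > 0) {
    ev <- events[order(events$time_s), ]
    ev$frame <- pmin(
      frame_count,
      pmax(1L, 1L + floor((ev$time_s - t_start) / frame_period))
    )
  } else {
    ev <- events
  }
  half <- ceiling(4 * psf_sigma_px)
  next_ev <- 1L
  for (f in seq_len(frame_count)) {
    while (nrow(ev) > 0 && next_ev <= nrow(ev) && ev$frame[next_ev] == f) {
      x0 <- ev$x_px[next_ev]; y0 <- ev$y_px[next_ev]
      amp <- ev$contrast[next_ev]  # reference level is 1
      x_lo <- max(1L, floor(x0) - half); x_hi <- min(nx, ceiling(x0) + half)
      y_lo <- max(1L, floor(y0) - half); y_hi <- min(ny, ceiling(y0) + half)
      if (x_lo <= x_hi && y_lo <= y_hi) {
        xs <- x_lo:x_hi; ys <- y_lo:y_hi
        # pixel centres at 0-based coordinates (row-1, col-1)
        gx <- exp(-((xs - 1 - x0)^2) / (2 * psf_sigma_px^2))
        gy <- exp(-((ys - 1 - y0)^2) / (2 * psf_sigma_px^2))
        signal[ys, xs] <- signal[ys, xs] + amp * outer(gy, gx)
      }
      next_ev <- next_ev + 1L
    }
    level <- background * (1 + signal)
    noise_sd <- sqrt(pmax(level, 0) / photon_budget)
    frames[f, , ] <- level + rnorm(ny * nx, 0, 1) * noise_sd
  }

  structure(
    list(frames = frames, frame_period = frame_period, t_start = t_start,
         pixel_size_nm = pixel_size_nm, psf_sigma_px = psf_sigma_px,
         events = as_tibble(events)),
    class = "mp_movie"
  )
}

#' @export
print.mp_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<mp_movie> %d frames of %d x %d px, %.3f ms/frame, t = [%g, %g] s\n",
    d[1], d[2], d[3], 1000 * x$frame_period, x$t_start,
    x$t_start + d[1] * x$frame_period))
  cat(sprintf("  ground truth: %d events\n", nrow(x$events)))
  invisible(x)
}

#' Read and write event tables
#'
#' Event tables are plain CSV/TSV files with header columns `time_s`,
#' `contrast`, `x_px`, `y_px` and an optional `species_label` sidecar column,
#' so that simulated and detected events share one schema.
#'
#' @param events Event tibble.
#' @param path File path; `.tsv` extension selects tab separation.
#' @return `read_events()` returns the event tibble; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  if (grepl("\\.tsv$", path)) readr::write_tsv(events, path)
  else readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  f <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  ev <- f(path, show_col_types = FALSE)
  need <- c("time_s", "contrast")
  if (!all(need %in% names(ev))) {
    abort("event file must have columns time_s and contrast")
  }
  ev
}

#' Read and write movie stacks
#'
#' Movies are stored as multi-page 32-bit float TIFF stacks (one page per
#' frame) with a JSON metadata sidecar (`<path>.json`) holding the frame
#' period, start time, pixel size, PSF width and the ground-truth event list
#' when one exists.
#'
#' @param movie An `mp_movie` object.
#' @param path TIFF file path.
#' @return `read_movie()` returns an `mp_movie`; `write_movie()` returns
#'   `path` invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "mp_movie"))
  # TIFF samples live in [0, 1]; store affinely rescaled values and record
  # the transform in the sidecar
  lo <- min(movie$frames); hi <- max(movie$frames)
  if (hi <= lo) hi <- lo + 1
  pages <- purrr::map(seq_len(dim(movie$frames)[1]),
                      function(f) (movie$frames[f, , ] - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    scale_min = lo, scale_max = hi,
    frame_period = movie$frame_period, t_start = movie$t_start,
    pixel_size_nm = movie$pixel_size_nm, psf_sigma_px = movie$psf_sigma_px,
    events = movie$events
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) frames[f, , ] <- pages[[f]]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  if (!is.null(meta$scale_min) && !is.null(meta$scale_max)) {
    frames <- frames * (meta$scale_max - meta$scale_min) + meta$scale_min
  }
  events <- if (!is.null(meta$events) && length(meta$events) > 0) {
    as_tibble(meta$events)
  } else {
    tibble(time_s = numeric(), contrast = numeric(),
           x_px = numeric(), y_px = numeric())
  }
  structure(
    list(frames = frames,
         frame_period = meta$frame_period %||% (1 / 191),
         t_start = meta$t_start %||% 15,
         pixel_size_nm = meta$pixel_size_nm %||% 84.4,
         psf_sigma_px = meta$psf_sigma_px %||% 1.4,
         events = events),
    class = "mp_movie"
  )
}
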