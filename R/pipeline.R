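#' Pipeline run configuration
#'
#' Assembles the configuration for a full simulate -> (movie -> detect) ->
#' peaks -> calibrate -> abundance run. Defaults mirror the standard dsDNA
#' ladder analysis: 8 binned frames, Threshold 1 = 1, Threshold 2 = 0.2,
#' window 15--135 s, KDE width 2.1e-4, beta = -0.72. All parameters are
#' echoed into the run report; nothing defaults silently.
#'
#' @param mixture A species tibble, or a preset name for [ladder_preset()].
#' @param mode `"events_only"` (simulate the event table directly) or
#'   `"full_movie"` (render a movie and re-detect the events).
#' @param contrast_model,kinetics,window,detection Model components; see
#'   [contrast_model()], [kinetics_model()], [acquisition_window()],
#'   [detect_params()].
#' @param bandwidth KDE bandwidth (contrast units).
#' @param bin_width Histogram bin width for the mixture fit.
#' @param exclude Species labels excluded from the calibration fit.
#' @param n_replicates Number of replicate simulations.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param movie Optional list of overrides for [simulate_movie()] in
#'   `full_movie` mode (e.g. `frame_count`, `shape`, `photon_budget`).
#' @return A list of class `mp_run_config`.
#' @export
run_config <- function(mixture = "low_mass_ladder",
                       mode = c("events_only", "full_movie"),
                       contrast_model = mpdna::contrast_model(),
                       kinetics = kinetics_model(),
                       window = acquisition_window(),
                       detection = detect_params(),
                       bandwidth = 2.1e-4,
                       bin_width = 1e-4,
                       exclude = character(),
                       n_replicates = 1L,
                       seed = 1L,
                       movie = list()) {
  mode <- match.arg(mode)
  if (is.character(mixture)) mixture <- ladder_preset(mixture)
  structure(
    list(mixture = mixture, mode = mode, contrast_model = contrast_model,
         kinetics = kinetics, window = window, detection = detection,
         bandwidth = bandwidth, bin_width = bin_width, exclude = exclude,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         movie = movie),
    class = "mp_run_config"
  )
}

#' Named pipeline presets
#'
#' `"figure2_ladder"`: events-only run of the six-species low-mass dsDNA
#' ladder. `"equimolar_roundtrip"`: the 200--1200 bp equimolar subset used to
#' demonstrate the diffusion-correction round trip. `"ssdna_runs"`: the long
#' ssDNA set, analysed per the single-stranded settings.
#'
#' @param name Preset name.
#' @param seed Base seed.
#' @return An `mp_run_config`.
#' @export
pipeline_preset <- function(name, seed = 1L) {
  switch(
    name,
    figure2_ladder = run_config("low_mass_ladder", seed = seed),
    equimolar_roundtrip = run_config(
      equimolar_mixture(c(200L, 400L, 800L, 1200L)), seed = seed),
    ssdna_runs = run_config(
      "ssdna_set",
      contrast_model = contrast_model(kappa = 0.71e-5),
      detection = detect_params(n_binned = 5L, threshold1 = 3, threshold2 = 0.3),
      seed = seed),
    abort(paste0("unknown preset '", name, "'; valid: figure2_ladder, ",
                 "equimolar_roundtrip, ssdna_runs"))
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (movie -> detect, in `full_movie` mode) -> KDE ->
#' sum-of-Gaussians fit -> calibration -> binding-rate fit -> diffusion
#' correction, persisting each intermediate as CSV/JSON under `out_dir` when
#' one is given. Identical config and seed give identical outputs. Stage
#' failures are recorded in the report with prior outputs preserved.
#'
#' @param config An [run_config()] or [pipeline_preset()] result.
#' @param out_dir Output directory; `NULL` keeps results in memory only.
#' @return A list of class `mp_run_report`: per-replicate stage results
#'   (`events`, `density`, `peaks`, `calibration`, `abundance`), pooled
#'   `calibration_summary`, `error_summary`, `log` (one record per stage),
#'   `config`, `version`, and output `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "mp_run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log <- list()
  note <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    log[[length(log) + 1]] <<- rec
    rec
  }
  paths <- list()
  persist <- function(obj, name, writer) {
    if (is.null(out_dir)) return(NULL)
    p <- file.path(out_dir, name)
    writer(obj, p)
    paths[[name]] <<- p
    p
  }

  reps <- vector("list", config$n_replicates)
  lengths_sorted <- sort(config$mixture$length)
  n_species <- nrow(config$mixture)

  for (r in seq_len(config$n_replicates)) {
    seed_r <- config$seed + r - 1L
    rep_out <- list(seed = seed_r)

    field <- if (config$mode == "full_movie") {
      min(config$movie$shape %||% c(128L, 128L))
    } else 128L
    ev <- simulate_event_stream(config$mixture, config$contrast_model,
                                config$kinetics, config$window,
                                seed = seed_r, field_px = field)
    rep_out$ground_truth <- ev
    note("simulate", replicate = r, seed = seed_r, n_events = nrow(ev))

    if (config$mode == "full_movie" && nrow(ev) > 0) {
      margs <- modifyList(
        list(events = ev, t_start = config$window$t0,
             frame_count = ceiling((config$window$t_final - config$window$t0) *
                                     191 / 5) * 5L,
             seed = seed_r),
        config$movie
      )
      movie <- do.call(simulate_movie, margs)
      dstack <- ratiometric_stack(movie, config$detection$n_binned)
      ev <- detect_events(dstack, config$detection)
      note("detect", replicate = r, n_events = nrow(ev),
           n_injected = nrow(rep_out$ground_truth))
    }
    rep_out$events <- ev
    persist(ev, sprintf("events_rep%d.csv", r), write_events)

    if (nrow(ev) < 50) {
      note("peaks", replicate = r, skipped = TRUE,
           reason = "fewer than 50 events")
      reps[[r]] <- rep_out
      next
    }

    res <- tryCatch({
      dens <- contrast_kde(ev$contrast, bandwidth = config$bandwidth)
      guesses <- find_contrast_peaks(dens)
      init <- if (nrow(guesses) == n_species) guesses else n_species
      pk <- fit_gaussian_mixture(ev$contrast, init = init,
                                 bin_width = config$bin_width,
                                 bandwidth = config$bandwidth)
      list(density = dens, peaks = pk)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      note("peaks", replicate = r, failed = TRUE,
           message = conditionMessage(res))
      reps[[r]] <- rep_out
      next
    }
    rep_out$density <- res$density
    pk <- peaks_with_lengths(
      res$peaks, lengths_sorted,
      labels = config$mixture$label[order(config$mixture$length)]
    )
    rep_out$peaks <- pk
    note("peaks", replicate = r, n_components = nrow(pk),
         residual = attr(res$peaks, "residual"))
    persist(pk, sprintf("peaks_rep%d.csv", r),
            function(o, p) readr::write_csv(o, p))

    rep_out$calibration <- tryCatch(
      fit_contrast_vs_length(pk, exclude = config$exclude),
      error = function(e) NULL
    )
    if (!is.null(rep_out$calibration)) {
      note("calibrate", replicate = r,
           slope = rep_out$calibration$slope,
           r_squared = rep_out$calibration$r_squared)
    }

    rep_out$abundance <- tryCatch(
      correct_abundances(pk, ev$time_s, config$window,
                         beta = config$kinetics$beta),
      error = function(e) NULL
    )
    if (!is.null(rep_out$abundance)) {
      persist(rep_out$abundance, sprintf("abundance_rep%d.csv", r),
              function(o, p) readr::write_csv(o, p))
      kin <- attr(rep_out$abundance, "kinetics")
      note("abundance", replicate = r, k = kin$k, alpha = kin$alpha)
    }
    reps[[r]] <- rep_out
  }

  calibs <- purrr::compact(purrr::map(reps, "calibration"))
  calibration_summary <- if (length(calibs) > 0) {
    tibble(
      replicate = seq_along(calibs),
      slope = purrr::map_dbl(calibs, "slope"),
      intercept = purrr::map_dbl(calibs, "intercept"),
      r_squared = purrr::map_dbl(calibs, "r_squared")
    )
  } else NULL

  error_summary <- NULL
  if (length(calibs) > 0) {
    mean_slope <- mean(calibration_summary$slope)
    per_rep <- purrr::imap_dfr(reps, function(rep_out, r) {
      if (is.null(rep_out$peaks) || is.null(rep_out$calibration)) return(NULL)
      pk <- rep_out$peaks
      est <- (pk$mu - rep_out$calibration$intercept) / mean_slope
      tibble(replicate = r, label = pk$label, nominal = pk$length,
             estimated = est, deviation = est - pk$length,
             excluded = pk$label %in% config$exclude)
    })
    kept <- per_rep[!per_rep$excluded, ]
    error_summary <- list(
      per_species = per_rep,
      mean_slope = mean_slope,
      mean_error = mean(kept$deviation),
      sd_error = if (nrow(kept) >= 2) sd(kept$deviation) else NA_real_
    )
  }

  report <- structure(
    list(replicates = reps, calibration_summary = calibration_summary,
         error_summary = error_summary, log = log, config = config,
         version = as.character(utils::packageVersion("mpdna")),
         paths = paths),
    class = "mp_run_report"
  )
  if (!is.null(out_dir)) {
    summ <- list(
      version = report$version,
      seed = config$seed,
      n_replicates = config$n_replicates,
      mode = config$mode,
      calibration = calibration_summary,
      mean_slope = error_summary$mean_slope,
      mean_length_error = error_summary$mean_error,
      sd_length_error = error_summary$sd_error,
      log = log
    )
    jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns",
                         null = "null", force = TRUE)
    report$paths[["report.json"]] <- file.path(out_dir, "report.json")
  }
  report
}

#' @export
print.mp_run_report <- function(x, ...) {
  cat(sprintf("<mp_run_report> %d replicate(s), mode %s, seed %d\n",
              x$config$n_replicates, x$config$mode, x$config$seed))
  if (!is.null(x$calibration_summary)) {
    cat(sprintf("  mean slope %.4g, R^2 range [%.6f, %.6f]\n",
                mean(x$calibration_summary$slope),
                min(x$calibration_summary$r_squared),
                max(x$calibration_summary$r_squared)))
  }
  if (!is.null(x$error_summary)) {
    cat(sprintf("  mean length error %.3g +/- %.3g\n",
                x$error_summary$mean_error, x$error_summary$sd_error))
  }
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' The file may name a `preset`, or spell out `mixture` (list of
#' label/length/strandedness/n_molecules), `contrast_model`, `kinetics`,
#' `window`, `detection`, `bandwidth`, `bin_width`, `exclude`,
#' `n_replicates`, `mode` and `seed`; omitted blocks use package defaults.
#'
#' @param path YAML file path.
#' @param seed Overrides the file's seed when not `NULL`.
#' @return An `mp_run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$preset)) {
    cfg <- pipeline_preset(y$preset, seed = y$seed %||% 1L)
  } else {
    mixture <- if (is.character(y$mixture)) ladder_preset(y$mixture)
    else purrr::map_dfr(y$mixture, function(s) {
      species(s$label, s$length, s$strandedness %||% "double",
              mole_fraction = s$mole_fraction %||% (1 / length(y$mixture)),
              n_molecules = s$n_molecules %||% 20000L)
    })
    cfg <- run_config(
      mixture = mixture,
      mode = y$mode %||% "events_only",
      contrast_model = do.call(contrast_model, y$contrast_model %||% list()),
      kinetics = do.call(kinetics_model, y$kinetics %||% list()),
      window = do.call(acquisition_window, y$window %||% list()),
      detection = do.call(detect_params, y$detection %||% list()),
      bandwidth = y$bandwidth %||% 2.1e-4,
      bin_width = y$bin_width %||% 1e-4,
      exclude = as.character(y$exclude %||% character()),
      n_replicates = y$n_replicates %||% 1L,
      seed = y$seed %||% 1L,
      movie = y$movie %||% list()
    )
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}
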