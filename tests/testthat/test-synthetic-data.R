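test_that("ladder presets match the nominal compositions", {
  lad <- ladder_preset("low_mass_ladder")
  expect_equal(lad$length, c(100L, 200L, 400L, 800L, 1200L, 2000L))
  expect_equal(lad$mole_fraction, rep(1 / 6, 6))
  expect_true(all(lad$strandedness == "double"))

  ss <- ladder_preset("ssdna_set")
  expect_equal(ss$length, c(4536L, 6048L, 7249L, 8064L))
  expect_true(all(ss$strandedness == "single"))

  expect_equal(nrow(ladder_preset("100bp_ladder")), 13)
  expect_error(ladder_preset("nonsense"), "low_mass_ladder")
})

test_that("event stream matches closed-form exponential survival counts", {
  # one species, k fixed by choosing alpha = k at length 1
  mix <- species("x", 1, n_molecules = 10000L)
  kin <- kinetics_model(alpha = 0.01, beta = -0.72)  # length 1 -> k = alpha
  win <- acquisition_window(15, 135)
  ev <- simulate_event_stream(mix, kinetics = kin, window = win, seed = 42)
  # oracle: integral of k exp(-k t) over [15, 135] = e^-0.15 - e^-1.35
  p <- exp(-0.15) - exp(-1.35)
  expected <- 10000 * p        # 6014.68
  sd_binom <- sqrt(10000 * p * (1 - p))
  expect_lt(abs(nrow(ev) - expected), 3 * sd_binom)
  expect_true(all(ev$time_s >= 15 & ev$time_s <= 135))
})

test_that("per-species in-window counts track n * (e^-k t0 - e^-k tf) over seeds", {
  mix <- ladder5(n_molecules = 3000L)
  kin <- kinetics_model(alpha = 0.2)
  win <- acquisition_window()
  k_i <- species_rate(kin$alpha, mix$length, kin$beta)
  p_i <- exp(-k_i * win$t0) - exp(-k_i * win$t_final)
  counts <- sapply(1:20, function(s) {
    ev <- simulate_event_stream(mix, kinetics = kin, window = win, seed = s)
    sapply(mix$label, function(l) sum(ev$species_label == l))
  })
  total <- rowSums(counts)
  expected <- 20 * 3000 * p_i
  sd_tot <- sqrt(20 * 3000 * p_i * (1 - p_i))
  expect_true(all(abs(total - expected) < 4 * sd_tot))
})

test_that("simulated contrast is centred on kappa * length", {
  mix <- ladder5(n_molecules = 5000L)
  cm <- contrast_model(kappa = 1.22e-5)
  ev <- simulate_event_stream(mix, contrast_model = cm, seed = 3)
  st <- dplyr::summarise(
    dplyr::group_by(ev, .data$species_label),
    m = mean(.data$contrast), se = sd(.data$contrast) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  len <- as.numeric(sub("bp", "", st$species_label))
  expect_true(all(abs(st$m - 1.22e-5 * len) < 3 * st$se))
})

test_that("the generator reproduces the depletion bias the correction must undo", {
  mix <- equimolar_mixture(c(200L, 400L, 800L, 1200L), n_molecules = 20000L)
  ev <- simulate_event_stream(mix, kinetics = kinetics_model(alpha = 0.2),
                              seed = 5)
  counts <- table(factor(ev$species_label,
                         levels = c("200bp", "400bp", "800bp", "1200bp")))
  # shorter species deplete faster, so in-window counts fall with length
  expect_true(all(diff(as.numeric(counts)) < 0))
})

test_that("the stream is deterministic in the seed and validates inputs", {
  mix <- ladder5(2000L)
  a <- simulate_event_stream(mix, seed = 42)
  b <- simulate_event_stream(mix, seed = 42)
  expect_identical(a, b)
  c <- simulate_event_stream(mix, seed = 43)
  expect_false(identical(a, c))

  expect_error(simulate_event_stream(mix, seed = -1), "seed")
  expect_warning(out <- simulate_event_stream(mix[0, ], seed = 1), "empty")
  expect_equal(nrow(out), 0)
  mix0 <- dplyr::mutate(mix, n_molecules = 0L)
  expect_warning(out0 <- simulate_event_stream(mix0, seed = 1), "no molecules")
  expect_equal(nrow(out0), 0)
})

test_that("movie: static background without events or noise, and seeded determinism", {
  no_events <- tibble::tibble(time_s = numeric(), contrast = numeric(),
                              x_px = numeric(), y_px = numeric())
  mv <- simulate_movie(no_events, background_rms = 0.01, photon_budget = Inf,
                       frame_count = 6L, shape = c(16L, 16L), seed = 2)
  for (f in 2:6) expect_equal(mv$frames[f, , ], mv$frames[1, , ])

  ev <- tibble::tibble(time_s = 15.05, contrast = 0.02, x_px = 8, y_px = 8)
  m1 <- simulate_movie(ev, frame_count = 20L, shape = c(32L, 32L), seed = 9)
  m2 <- simulate_movie(ev, frame_count = 20L, shape = c(32L, 32L), seed = 9)
  expect_identical(m1$frames, m2$frames)

  late <- tibble::tibble(time_s = 1e4, contrast = 0.02, x_px = 8, y_px = 8)
  expect_error(simulate_movie(late, frame_count = 20L, shape = c(32L, 32L)),
               "outside the movie time span")
})

test_that("a single injected event appears as one above-noise PSF step", {
  ev <- tibble::tibble(time_s = 15.1, contrast = 0.05, x_px = 20, y_px = 12)
  mv <- simulate_movie(ev, frame_count = 40L, shape = c(48L, 48L),
                       background_rms = 0.005, photon_budget = 1e7, seed = 4)
  step <- mv$frames[40, , ] - mv$frames[1, , ]
  peak <- which(step == max(step), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(13, 21))  # row = y + 1, col = x + 1
  expect_gt(max(step), 10 * sd(step[step < median(step) + 3 * sd(step)]))
})

test_that("movie stacks round-trip through TIFF with metadata sidecar", {
  ev <- tibble::tibble(time_s = 15.02, contrast = 0.03, x_px = 10, y_px = 6)
  mv <- simulate_movie(ev, frame_count = 8L, shape = c(24L, 24L), seed = 1)
  path <- file.path(tempdir(), "movie.tif")
  write_movie(mv, path)
  back <- read_movie(path)
  expect_equal(back$frames, mv$frames, tolerance = 1e-6)
  expect_equal(back$frame_period, mv$frame_period)
  expect_equal(back$events$contrast, mv$events$contrast)
  unlink(c(path, paste0(path, ".json")))
})

test_that("event tables round-trip through CSV and TSV", {
  ev <- simulate_event_stream(ladder5(500L), seed = 8)
  for (ext in c("csv", "tsv")) {
    p <- file.path(tempdir(), paste0("ev.", ext))
    write_events(ev, p)
    back <- read_events(p)
    expect_equal(as.data.frame(back), as.data.frame(ev), tolerance = 1e-12)
    unlink(p)
  }
})
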