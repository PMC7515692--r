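test_that("ratiometric stack: constant input gives all-zero differentials", {
  mv <- list(frames = array(3, dim = c(16, 8, 8)), frame_period = 0.01,
             t_start = 15, psf_sigma_px = 1.4)
  ds <- ratiometric_stack(mv, n_binned = 4L)
  expect_equal(dim(ds$frames), c(3, 8, 8))
  expect_true(all(ds$frames == 0))
})

test_that("ratiometric stack: a step between batches gives s/b in one frame", {
  # 2 batches of 3 frames on background b = 2, step s = 0.5 at one pixel
  b <- 2; s <- 0.5
  frames <- array(b, dim = c(6, 5, 5))
  frames[4:6, 3, 2] <- b + s
  ds <- ratiometric_stack(list(frames = frames, frame_period = 0.1,
                               t_start = 0), n_binned = 3L)
  expect_equal(dim(ds$frames)[1], 1)
  expect_equal(ds$frames[1, 3, 2], s / b)
  expect_equal(sum(ds$frames != 0), 1)
  expect_equal(ds$times, 0.3)  # batch boundary
})

test_that("ratiometric stack: n_binned = 1 degenerates to frame ratio-differences", {
  frames <- array(1, dim = c(3, 4, 4))
  frames[2, , ] <- 1.1
  frames[3, , ] <- 1.1
  ds <- ratiometric_stack(list(frames = frames, frame_period = 1, t_start = 0),
                          n_binned = 1L)
  expect_equal(dim(ds$frames)[1], 2)
  expect_equal(ds$frames[1, 1, 1], 0.1 / 1)
  expect_equal(ds$frames[2, 1, 1], 0)
  expect_error(ratiometric_stack(list(frames = array(0, c(3, 4, 4))), 2L),
               "at least 4 frames")
})

test_that("radial symmetry score: symmetric > stretched > typical noise; rotation-invariant", {
  g <- gaussian_patch(11, sigma = 1.5)
  s_sym <- radial_symmetry_score(g)
  expect_gte(s_sym, 0.95)
  expect_equal(radial_symmetry_score(t(g[nrow(g):1, ])), s_sym)  # 90 deg rotation

  stretched <- gaussian_patch(11, sx = 3, sy = 1.5)
  expect_lt(radial_symmetry_score(stretched), s_sym)

  set.seed(1)
  noise_scores <- replicate(100, radial_symmetry_score(matrix(rnorm(121), 11)))
  expect_lt(mean(noise_scores), s_sym)
  expect_true(all(noise_scores >= 0 & noise_scores <= 1))

  expect_error(radial_symmetry_score(matrix(0, 4, 4)), "odd")
  expect_error(radial_symmetry_score(matrix(0, 3, 5)), "square")
})

test_that("blank noise-only stacks yield at most ~1 false positive per 100 frames", {
  no_events <- tibble::tibble(time_s = numeric(), contrast = numeric(),
                              x_px = numeric(), y_px = numeric())
  mv <- simulate_movie(no_events, frame_count = 820L, shape = c(128L, 128L),
                       photon_budget = 2e6, t_start = 15, seed = 11)
  ds <- ratiometric_stack(mv, 8L)
  det <- detect_events(ds, detect_params(8, threshold1 = 5, threshold2 = 0.2))
  n_frames <- dim(ds$frames)[1]
  expect_lte(nrow(det), ceiling(n_frames / 100) + 1)
})

test_that("a single injected PSF is recovered at position and contrast", {
  ev <- tibble::tibble(time_s = 15.3, contrast = 0.01, x_px = 30.4, y_px = 22.6)
  mv <- toy_movie(ev, frame_count = 160L, shape = c(64L, 64L), seed = 21)
  ds <- ratiometric_stack(mv, 8L)
  noise <- mad(ds$frames[1, , ])
  expect_gt(0.01 / noise, 10)  # injected at >10x noise RMS
  det <- detect_events(ds, detect_params(8, threshold1 = 5, threshold2 = 0.2))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - ev$x_px), 1)
  expect_lt(abs(det$y_px - ev$y_px), 1)
  expect_lt(abs(det$contrast - 0.01) / 0.01, 0.1)
})

test_that("sub-threshold amplitudes yield no events beyond the blank's noise floor", {
  set.seed(31)
  ev <- tibble::tibble(time_s = runif(5, 15.2, 15.7), contrast = 2e-4,
                       x_px = runif(5, 10, 54), y_px = runif(5, 10, 54))
  mv <- toy_movie(ev, frame_count = 160L, seed = 31)
  blank <- toy_movie(ev[0, ], frame_count = 160L, seed = 31)  # same noise
  ds <- ratiometric_stack(mv, 8L)
  expect_lt(2e-4, 0.7 * 3 * mad(ds$frames[1, , ]))  # amplitude < threshold
  # in the false-positive-free regime the stack yields exactly zero events
  det5 <- detect_events(ds, detect_params(8, threshold1 = 5, threshold2 = 0.2))
  expect_equal(nrow(det5), 0)
  # at a permissive threshold the output is indistinguishable from the
  # blank with the same noise realization (up to borderline noise spikes
  # nudged across the threshold)
  p3 <- detect_params(8, threshold1 = 3, threshold2 = 0.2)
  det <- detect_events(ds, p3)
  det0 <- detect_events(ratiometric_stack(blank, 8L), p3)
  expect_lte(abs(nrow(det) - nrow(det0)), 2)
})

test_that("raising threshold2 never increases the event count", {
  set.seed(41)
  n <- 12
  ev <- tibble::tibble(time_s = sort(runif(n, 15.2, 16.5)), contrast = 0.008,
                       x_px = runif(n, 8, 56), y_px = runif(n, 8, 56))
  mv <- toy_movie(ev, frame_count = 320L, seed = 41)
  ds <- ratiometric_stack(mv, 8L)
  counts <- sapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.95), function(t2) {
    nrow(detect_events(ds, detect_params(8, threshold1 = 5, threshold2 = t2)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold2 choice does not shift the measured contrast", {
  set.seed(43)
  n <- 10
  ev <- tibble::tibble(time_s = sort(runif(n, 15.2, 16.5)), contrast = 0.01,
                       x_px = runif(n, 8, 56), y_px = runif(n, 8, 56))
  mv <- toy_movie(ev, frame_count = 320L, seed = 43)
  ds <- ratiometric_stack(mv, 8L)
  d_lo <- detect_events(ds, detect_params(8, 5, threshold2 = 0.2))
  d_hi <- detect_events(ds, detect_params(8, 5, threshold2 = 0.3))
  common <- dplyr::inner_join(d_lo, d_hi, by = c("x_px", "y_px", "time_s"))
  expect_gt(nrow(common), 0)
  expect_equal(common$contrast.x, common$contrast.y)
})

test_that("end-to-end: injected events recovered with unbiased contrast", {
  set.seed(53)
  recalls <- c(); spurious <- c(); rel_err <- c()
  for (s in 1:3) {
    n <- 25
    set.seed(100 + s)
    ev <- tibble::tibble(
      time_s = sort(runif(n, 15.3, 17.3)), contrast = 0.01,
      x_px = runif(n, 8, 120), y_px = runif(n, 8, 120)
    )
    mv <- simulate_movie(ev, frame_count = 500L, shape = c(128L, 128L),
                         photon_budget = 2e6, t_start = 15, seed = 200 + s)
    ds <- ratiometric_stack(mv, 8L)
    expect_gt(0.01 / mad(ds$frames[1, , ]), 8)
    det <- detect_events(ds, detect_params(8, 5, 0.2))
    matched <- sapply(seq_len(n), function(i) {
      hit <- abs(det$x_px - ev$x_px[i]) <= 2 & abs(det$y_px - ev$y_px[i]) <= 2 &
        abs(det$time_s - ev$time_s[i]) < 0.5
      if (any(hit)) which(hit)[1] else NA_integer_
    })
    recalls <- c(recalls, mean(!is.na(matched)))
    spurious <- c(spurious, (nrow(det) - sum(!is.na(matched))) / n)
    rel_err <- c(rel_err, det$contrast[matched[!is.na(matched)]] / 0.01 - 1)
  }
  expect_gte(mean(recalls), 0.95)
  expect_lte(mean(spurious), 0.05)
  expect_lt(abs(mean(rel_err)), 0.05)
})
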