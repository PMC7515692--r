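# shared fixtures built in code; no stored data

ladder5 <- function(n_molecules = 20000L) {
  equimolar_mixture(c(100L, 200L, 400L, 800L, 1200L), n_molecules = n_molecules)
}

# a centred 2-D Gaussian patch of odd side n
gaussian_patch <- function(n = 11, sigma = 1.5, amp = 1, sx = sigma, sy = sigma,
                           offset = 0) {
  c0 <- (n + 1) / 2
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), times = n), n, n)
  offset + amp * exp(-((x - c0)^2 / (2 * sx^2) + (y - c0)^2 / (2 * sy^2)))
}

# tiny movie with events injected at known positions/times
toy_movie <- function(events, frame_count = 160L, shape = c(64L, 64L),
                      photon_budget = 2e6, seed = 1L) {
  simulate_movie(events, frame_count = frame_count, shape = shape,
                 photon_budget = photon_budget, t_start = 15, seed = seed)
}
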