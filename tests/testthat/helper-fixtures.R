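# Small deterministic fixtures shared across the suite.

tiny_design <- function(n_nogo = 10L)
  task_design(n_go_per_condition = 2L * n_nogo,
              n_nogo_per_condition = n_nogo, n_blocks = 1L)

tiny_leadfield <- function(n_channels = 12L, shape = c(4L, 4L, 4L),
                           model = "random_full_rank", seed = 7L)
  make_leadfield(n_channels, shape, 1, model = model, seed = seed)

tiny_truth <- function(lf, ...) default_truth_for(lf, ...)

# epochs with a pure sinusoid on every channel (handy for filter tests)
sinusoid_epochs <- function(freq, sfreq = 500, dur = 4, n_channels = 3,
                            amplitude = 1, phase = 0) {
  times <- seq(-dur / 2, dur / 2 - 1 / sfreq, by = 1 / sfreq)
  x <- amplitude * sin(2 * pi * freq * times + phase)
  data <- array(rep(x, each = n_channels), c(1, n_channels, length(times)))
  sensor_epochs(data, sfreq, times, matrix(rnorm(n_channels * 3), ncol = 3),
                "nogo_overlap")
}

rms <- function(x) sqrt(mean(x^2))

# brute-force signed-rank two-sided p by enumerating all sign patterns
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  s_obs <- sum(sign(d) * r)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  s_all <- as.numeric(signs %*% r)
  mean(abs(s_all) >= abs(s_obs) - 1e-12)
}
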