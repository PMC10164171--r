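make_single_source_epochs <- function(lf, voxel, freq = 8, sfreq = 128,
                                      noise_sd = 0, n_trials = 6,
                                      seed = 1) {
  # project a sinusoid from one voxel (fixed orientation) to the sensors
  times <- seq(-1, 1 - 1 / sfreq, by = 1 / sfreq)
  u <- c(1, 0, 0)
  gvec <- as.numeric(lf$gain[, voxel, ] %*% u)
  sig <- sin(2 * pi * freq * times)
  set.seed(seed)
  n_ch <- dim(lf$gain)[1]
  data <- array(rnorm(n_trials * n_ch * length(times), sd = noise_sd),
                c(n_trials, n_ch, length(times)))
  for (tr in seq_len(n_trials))
    data[tr, , ] <- data[tr, , ] + outer(gvec, sig)
  list(epochs = sensor_epochs(data, sfreq, times, lf$channel_positions,
                              rep(c("nogo_overlap", "nogo_nonoverlap"),
                                  length.out = n_trials)),
       signal = sig, gvec = gvec)
}

test_that("covariance of the averaged data follows closed forms", {
  lf <- tiny_leadfield(seed = 3)
  n_ch <- dim(lf$gain)[1]
  times <- seq(-1, 1 - 1 / 128, by = 1 / 128)
  # amplitude-a sinusoid on channel 2 only: diagonal variance a^2/2
  a <- 3
  data <- array(0, c(4, n_ch, length(times)))
  for (tr in 1:4) data[tr, 2, ] <- a * sin(2 * pi * 4 * times)
  ep <- sensor_epochs(data, 128, times, lf$channel_positions,
                      rep("nogo_overlap", 4))
  C <- covariance_from_average(ep)
  expect_equal(C[2, 2], a^2 / 2, tolerance = 0.02)
  expect_lt(max(abs(C[-2, -2])), 1e-12)
  # zero data -> zero matrix
  epz <- ep; epz$data[] <- 0
  expect_true(all(covariance_from_average(epz) == 0))
  # averaging many white-noise trials shrinks off-diagonal structure
  set.seed(2)
  epn <- ep
  epn$data <- array(rnorm(length(ep$data)), dim(ep$data))
  Cn <- covariance_from_average(epn)
  expect_lt(median(abs(Cn[upper.tri(Cn)])) / median(diag(Cn)), 0.35)
})

test_that("LCMV filters satisfy the unit-gain constraint", {
  lf <- tiny_leadfield(seed = 5)
  set.seed(6)
  n_ch <- dim(lf$gain)[1]
  A <- matrix(rnorm(n_ch * n_ch), n_ch)
  C <- crossprod(A) / n_ch
  filt <- lcmv_filters(lf, C, reg_fraction = 0.05)
  Cr <- C + 0.05 * mean(diag(C)) * diag(n_ch)
  Ci <- solve(Cr)
  for (v in c(1, 7, 30)) {
    u <- filt$orientation[v, ]
    l <- as.numeric(lf$gain[, v, ] %*% u)
    expect_equal(as.numeric(filt$weights[v, ] %*% l), 1, tolerance = 1e-6)
    # orientation is the max-power eigenvector of (L' Cr^-1 L)^-1
    M <- solve(crossprod(lf$gain[, v, ], Ci %*% lf$gain[, v, ]))
    ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
    expect_equal(abs(sum(u * ev)), 1, tolerance = 1e-8)
  }
})

test_that("a noise-free single source is reconstructed at its voxel", {
  lf <- make_leadfield(24, c(4, 4, 4), 1.5, model = "dipole", seed = 7)
  vox <- select_voxels(lf)[10]
  sim <- make_single_source_epochs(lf, vox, noise_sd = 0)
  C <- covariance_from_average(sim$epochs)
  filt <- lcmv_filters(lf, C, reg_fraction = 0.05)
  src <- apply_filters(filt, sim$epochs)
  expect_gt(abs(cor(src$data[1, vox, ], sim$signal)), 0.99)
})

test_that("the maximal-power voxel is at or adjacent to the planted source", {
  lf <- make_leadfield(24, c(4, 4, 4), 1.5, model = "dipole", seed = 8)
  vox <- select_voxels(lf)[20]
  sim <- make_single_source_epochs(lf, vox, noise_sd = 0.01, seed = 3)
  C <- covariance_from_average(sim$epochs)
  filt <- lcmv_filters(lf, C)
  src <- apply_filters(filt, sim$epochs)
  pow <- rowMeans(src$data[1, , ]^2)
  best <- which.max(pow)
  d <- sqrt(sum((lf$grid_coords[best, ] - lf$grid_coords[vox, ])^2))
  expect_lte(d, 1.5 * lf$grid_spacing + 1e-9)
})

test_that("filter application is linear and channel-checked", {
  lf <- tiny_leadfield(seed = 9)
  sim <- make_single_source_epochs(lf, 5, noise_sd = 0.5)
  C <- covariance_from_average(sim$epochs)
  filt <- lcmv_filters(lf, C)
  src1 <- apply_filters(filt, sim$epochs)
  ep2 <- sim$epochs; ep2$data <- 2 * ep2$data
  src2 <- apply_filters(filt, ep2)
  expect_equal(src2$data, 2 * src1$data, tolerance = 1e-10)
  epz <- sim$epochs; epz$data[] <- 0
  expect_true(all(apply_filters(filt, epz)$data == 0))
  bad <- sim$epochs
  bad$data <- bad$data[, 1:5, , drop = FALSE]
  bad$channel_positions <- bad$channel_positions[1:5, ]
  expect_error(apply_filters(filt, bad), "channel")
})

test_that("voxel selection excludes unlabeled and cerebellar voxels", {
  gain <- array(rnorm(4 * 216 * 3), c(4, 216, 3))
  coords <- as.matrix(expand.grid(1:6, 1:6, 1:6))
  labels <- rep("Frontal_Sup_L", 216)
  labels[1:18] <- "Cerebellum"
  labels[19:30] <- "Unlabeled"
  lf <- lead_field(gain, coords, 1, labels, matrix(rnorm(12), 4))
  inc <- select_voxels(lf)
  expect_length(inc, 186)
  expect_true(all(inc > 30))
  lf2 <- lead_field(gain, coords, 1, rep("A", 216), matrix(rnorm(12), 4))
  expect_length(select_voxels(lf2), 216)
  lf3 <- lead_field(gain, coords, 1, rep("Unlabeled", 216),
                    matrix(rnorm(12), 4))
  expect_error(select_voxels(lf3), "no labeled")
})
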