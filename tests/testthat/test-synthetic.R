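test_that("default session reproduces the task design exactly", {
  ev <- generate_task_events(task_design(), seed = 1)
  expect_equal(nrow(ev), 560)
  counts <- table(ev$condition)
  expect_equal(unname(counts[["go_nonoverlap"]]), 196)
  expect_equal(unname(counts[["go_overlap"]]), 196)
  expect_equal(unname(counts[["nogo_nonoverlap"]]), 84)
  expect_equal(unname(counts[["nogo_overlap"]]), 84)
  expect_equal(mean(grepl("^go", ev$condition)), 0.7)
  # balance within each of the seven blocks
  per_block <- table(ev$block_index, ev$condition)
  expect_true(all(per_block[, "go_nonoverlap"] == 28))
  expect_true(all(per_block[, "nogo_overlap"] == 12))
  # strictly increasing onsets with ITIs inside the jitter range
  expect_true(all(diff(ev$onset) > 0))
  iti <- diff(ev$onset) - task_design()$response_window
  expect_true(all(iti >= 700 & iti <= 1100))
})

test_that("minimal design yields one event per condition", {
  ev <- generate_task_events(task_design(1, 1, 1), seed = 3)
  expect_equal(nrow(ev), 4)
  expect_setequal(ev$condition, c("go_nonoverlap", "go_overlap",
                                  "nogo_nonoverlap", "nogo_overlap"))
})

test_that("indivisible block counts are a configuration error", {
  expect_error(task_design(n_go_per_condition = 195), "divisible")
  expect_error(task_design(n_go_per_condition = 196,
                           n_nogo_per_condition = 85), "divisible")
})

test_that("generators are deterministic under a fixed seed", {
  expect_identical(generate_task_events(task_design(), 42),
                   generate_task_events(task_design(), 42))
  lf <- tiny_leadfield(seed = 5)
  expect_identical(lf$gain, tiny_leadfield(seed = 5)$gain)
  tr <- tiny_truth(lf)
  e1 <- simulate_subject_eeg(tiny_design(4L), tr, lf, seed = 9,
                             epoch_window = c(-1, 1.75))
  e2 <- simulate_subject_eeg(tiny_design(4L), tr, lf, seed = 9,
                             epoch_window = c(-1, 1.75))
  expect_identical(e1$data, e2$data)
})

test_that("simulated behavior reproduces the binding pattern", {
  lf <- tiny_leadfield()
  tr0 <- tiny_truth(lf, behavioral_binding_fa = 0)
  b0 <- simulate_behavior(task_design(), tr0, 400, seed = 2)
  d0 <- mean(b0$nogo_fa_rate[b0$condition == "overlap"]) -
    mean(b0$nogo_fa_rate[b0$condition == "nonoverlap"])
  expect_lt(abs(d0), 2)

  tr35 <- tiny_truth(lf, behavioral_binding_fa = 35)
  d <- mean(vapply(1:5, function(s) {
    b <- simulate_behavior(task_design(), tr35, 200, seed = s)
    mean(b$nogo_fa_rate[b$condition == "overlap"]) -
      mean(b$nogo_fa_rate[b$condition == "nonoverlap"])
  }, numeric(1)))
  expect_lt(abs(d - 35), 2)
  b <- simulate_behavior(task_design(), tr35, 200, seed = 2)
  # RT slowing under overlap
  expect_gt(mean(b$go_rt[b$condition == "overlap"]),
            mean(b$go_rt[b$condition == "nonoverlap"]))

  b1 <- simulate_behavior(task_design(), tr35, 1, seed = 4)
  expect_equal(nrow(b1), 2)
  expect_true(all(b1$nogo_fa_rate >= 0 & b1$nogo_fa_rate <= 100))
  expect_true(all(b1$go_hit_rate >= 0 & b1$go_hit_rate <= 100))
  expect_true(all(b1$go_rt > 0))
})

test_that("lead-field grids are regular lattices with atlas labels", {
  lf <- make_leadfield(20, c(6, 6, 6), 1, seed = 1)
  expect_equal(nrow(lf$grid_coords), 216)
  ux <- sort(unique(lf$grid_coords[, 1]))
  expect_equal(diff(ux), rep(1, 5))
  expect_true(any(lf$labels == "Cerebellum"))
  expect_true(any(lf$labels == "Unlabeled"))
  expect_gt(sum(!(lf$labels %in% c("Cerebellum", "Unlabeled"))), 0)
})

test_that("dipole gain decays with sensor-source distance", {
  lf <- make_leadfield(30, c(3, 3, 3), 2, model = "dipole",
                       reference = "none", seed = 2)
  # central voxel: per-sensor gain norm against distance
  v <- which.min(rowSums(sweep(lf$grid_coords, 2,
                               colMeans(lf$grid_coords))^2))
  gnorm <- sqrt(rowSums(lf$gain[, v, ]^2))
  dist <- sqrt(rowSums(sweep(lf$channel_positions, 2,
                             lf$grid_coords[v, ])^2))
  expect_lt(cor(dist, gnorm, method = "spearman"), -0.9)
})

test_that("orthogonal-pattern ground truth has zero cross-band inner product", {
  lf <- tiny_leadfield()
  tr <- tiny_truth(lf, shared_pattern = FALSE)
  pats <- bindecode:::shared_patterns(tr)
  expect_lt(abs(sum(pats$theta * pats$alpha)), 1e-10)
  tr2 <- tiny_truth(lf, shared_pattern = TRUE)
  pats2 <- bindecode:::shared_patterns(tr2)
  expect_equal(pats2$theta, pats2$alpha)
  # patterns are zero-mean: they do not move band-mean power
  expect_lt(abs(mean(pats$theta)), 1e-10)
})

test_that("planted theta effect appears at sensors nearest the source", {
  lf <- make_leadfield(20, c(5, 5, 5), 1, model = "dipole", seed = 3)
  tr <- tiny_truth(lf, effect_amplitude = 20, shared_amplitude = 0)
  ep <- simulate_subject_eeg(tiny_design(20L), tr, lf, noise_sd = 1,
                             sfreq = 128, epoch_window = c(-0.7, 1.7),
                             seed = 5)
  tfr <- morlet_tfr(ep, c(4, 5, 6, 7), decim = 4)
  bc <- band_power(tfr, c(4, 7))
  ov <- condition_average(bc, ep$condition_labels, "nogo_overlap")
  no <- condition_average(bc, ep$condition_labels, "nogo_nonoverlap")
  d <- ov$power[1, , ] - no$power[1, , ]
  sel <- bc$times >= 0 & bc$times <= 1
  ch_diff <- rowMeans(d[, sel])
  src <- colMeans(lf$grid_coords[tr$theta_effect_voxels, , drop = FALSE])
  nearest <- order(rowSums(sweep(lf$channel_positions, 2, src)^2))[1:3]
  expect_true(all(ch_diff[nearest] > 0))
})

test_that("epoch window must contain the effect envelope", {
  lf <- tiny_leadfield()
  tr <- tiny_truth(lf)
  expect_error(simulate_subject_eeg(tiny_design(2L), tr, lf,
                                    epoch_window = c(-0.1, 0.6), seed = 1),
               "envelope")
})

test_that("out-of-grid ground-truth voxels are rejected", {
  lf <- tiny_leadfield()
  tr <- ground_truth(theta_effect_voxels = nrow(lf$grid_coords) + 1L,
                     alpha_effect_voxels = 1L)
  expect_error(simulate_subject_eeg(tiny_design(2L), tr, lf, seed = 1),
               "grid")
})
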