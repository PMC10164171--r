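# feature arrays are built directly so ground truth is exact:
# trials x voxels x time with a condition pattern planted where stated

labels_for <- function(n) rep(c("nogo_nonoverlap", "nogo_overlap"),
                              each = n / 2)

test_that("label-independent noise decodes at chance (no leakage canary)", {
  set.seed(1)
  n <- 60
  course <- array(rnorm(n * 8 * 6), c(n, 8, 6))
  res <- temporal_mvpa(course, labels_for(n),
                       decoding_config(seed = 2),
                       times = seq(0, 1, length.out = 6))
  expect_true(all(res$auc_time >= 0.25 & res$auc_time <= 0.75))
  expect_gte(mean(res$auc_time), 0.40)
  expect_lte(mean(res$auc_time), 0.60)
})

test_that("chance calibration holds over repeated label permutations", {
  set.seed(3)
  n <- 40
  aucs <- vapply(1:15, function(r) {
    course <- array(rnorm(n * 6 * 3), c(n, 6, 3))
    labs <- sample(labels_for(n))
    mean(temporal_mvpa(course, labs, decoding_config(seed = r))$auc_time)
  }, numeric(1))
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
})

test_that("a separable pattern is decoded at its time only", {
  set.seed(4)
  n <- 60; n_t <- 8; t_star <- 4
  course <- array(rnorm(n * 10 * n_t), c(n, 10, n_t))
  labs <- labels_for(n)
  course[labs == "nogo_overlap", 1:3, t_star] <-
    course[labs == "nogo_overlap", 1:3, t_star] + 3
  res <- temporal_mvpa(course, labs, decoding_config(seed = 5))
  expect_gt(res$auc_time[t_star], 0.9)
  expect_lt(max(res$auc_time[-t_star]), 0.75)
})

test_that("two Gaussian classes reach the closed-form AUC", {
  set.seed(6)
  n <- 400; d <- 1.2
  course <- array(rnorm(n * 1 * 2), c(n, 1, 2))
  labs <- labels_for(n)
  course[labs == "nogo_overlap", 1, 1] <-
    course[labs == "nogo_overlap", 1, 1] + d
  res <- temporal_mvpa(course, labs, decoding_config(seed = 7))
  expect_equal(res$auc_time[1], pnorm(d / sqrt(2)), tolerance = 0.06)
  expect_lt(abs(res$auc_time[2] - 0.5), 0.08)
})

test_that("generalization diagonal equals temporal decoding", {
  set.seed(8)
  n <- 40; n_t <- 5
  course <- array(rnorm(n * 6 * n_t), c(n, 6, n_t))
  course[labels_for(n) == "nogo_overlap", 1:2, ] <-
    course[labels_for(n) == "nogo_overlap", 1:2, ] + 1
  cfg <- decoding_config(seed = 9)
  tm <- temporal_mvpa(course, labels_for(n), cfg)
  tg <- temporal_generalization(course, labels_for(n), cfg)
  expect_lt(mean(abs(diag(tg$auc_gen) - tm$auc_time)), 0.02)
})

test_that("a stationary pattern generalizes; a flipped one anti-generalizes", {
  set.seed(10)
  n <- 60; n_t <- 6
  labs <- labels_for(n)
  stationary <- array(rnorm(n * 8 * n_t), c(n, 8, n_t))
  stationary[labs == "nogo_overlap", 1:3, ] <-
    stationary[labs == "nogo_overlap", 1:3, ] + 2
  tg <- temporal_generalization(stationary, labs,
                                decoding_config(seed = 11))
  expect_gt(min(tg$auc_gen), 0.8)

  flip <- array(rnorm(n * 8 * n_t), c(n, 8, n_t))
  flip[labs == "nogo_overlap", 1:3, 1:3] <-
    flip[labs == "nogo_overlap", 1:3, 1:3] + 2
  flip[labs == "nogo_overlap", 1:3, 4:6] <-
    flip[labs == "nogo_overlap", 1:3, 4:6] - 2
  tf <- temporal_generalization(flip, labs, decoding_config(seed = 12))
  expect_gt(min(diag(tf$auc_gen)), 0.8)      # on-diagonal still decodes
  expect_lt(max(tf$auc_gen[1:3, 4:6]), 0.2)  # across the flip: below chance
})

test_that("cross-band transfer follows the shared-pattern geometry", {
  set.seed(13)
  n <- 140; n_vox <- 12; n_t <- 4
  labs <- labels_for(n)
  v <- rnorm(n_vox); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  w <- rnorm(n_vox); w <- w - mean(w)
  w <- w - sum(w * v) * v; w <- w / sqrt(sum(w^2))   # orthogonal pattern
  plant <- function(pattern) {
    arr <- array(rnorm(n * n_vox * n_t), c(n, n_vox, n_t))
    sgn <- ifelse(labs == "nogo_overlap", 1, -1)
    for (ti in seq_len(n_t))
      arr[, , ti] <- arr[, , ti] + outer(sgn, 2 * pattern)
    arr
  }
  theta <- plant(v)
  alpha_shared <- plant(v)
  alpha_orth <- plant(w)
  cfg <- decoding_config(seed = 14)
  tr_shared <- cross_band_mvpa(theta, alpha_shared, labs, cfg,
                               diag_only = TRUE)
  tr_orth <- cross_band_mvpa(theta, alpha_orth, labs, cfg,
                             diag_only = TRUE)
  expect_gt(mean(diag(tr_shared$auc_gen)), 0.85)
  expect_lt(abs(mean(diag(tr_orth$auc_gen)) - 0.5), 0.12)
})

test_that("spatial MVPA ranks the effect voxels on top", {
  set.seed(15)
  n <- 60; n_vox <- 20; n_t <- 6
  labs <- labels_for(n)
  course <- array(rnorm(n * n_vox * n_t), c(n, n_vox, n_t))
  eff <- 3:5
  course[labs == "nogo_overlap", eff, ] <-
    course[labs == "nogo_overlap", eff, ] + 1.5
  res <- spatial_mvpa(course, labs, rep(TRUE, n_t),
                      decoding_config(seed = 16))
  expect_setequal(order(res$auc_voxel, decreasing = TRUE)[1:3], eff)
  expect_lt(abs(mean(res$auc_voxel[-eff]) - 0.5), 0.06)
})

test_that("voxel-map re-insertion zero-fills excluded positions exactly", {
  auc <- runif(186, 0.4, 0.7)
  included <- setdiff(1:216, 1:30)
  maps <- reinsert_voxel_map(auc, included, 216)
  expect_equal(sum(maps$auc == 0), 30)
  expect_equal(sum(maps$chance == 0), 30)
  expect_identical(maps$auc[included], auc)   # bit-exact at included voxels
  expect_true(all(maps$chance[included] == 0.5))
  all_in <- reinsert_voxel_map(auc, 1:186, 186)
  expect_true(all(all_in$auc == auc))
})

test_that("group test against chance flags a planted region only", {
  set.seed(17)
  n_sub <- 12; n_t <- 20
  null_maps <- matrix(0.5 + rnorm(n_sub * n_t, sd = 0.03), n_sub)
  g0 <- group_test_vs_chance(null_maps, n_permutations = 300, seed = 18)
  planted <- null_maps
  planted[, 6:12] <- planted[, 6:12] + 0.12
  g1 <- group_test_vs_chance(planted, n_permutations = 300, seed = 18)
  expect_true(any(g1$sig_mask[6:12]))
  expect_false(any(g1$sig_mask[c(1:3, 16:20)]))
  expect_lte(sum(g0$sig_mask), 2)
})

test_that("generalization duration measures diagonal runs", {
  n <- 11
  times <- seq(0, 1, length.out = n)          # 100 ms steps
  auc <- matrix(0.6, n, n)
  full <- generalization_duration(auc, matrix(TRUE, n, n), times)
  expect_equal(full$mean_duration_ms, 1100, tolerance = 1)
  expect_equal(full$frac_significant, 1)
  expect_equal(full$mean_sig_auc, 0.6)

  band <- abs(row(auc) - col(auc)) <= 1       # +/- one 100 ms sample
  bd <- generalization_duration(auc, band, times)
  expect_equal(bd$mean_duration_ms, mean(c(2, rep(3, n - 2), 2)) * 100,
               tolerance = 1)
  empty <- generalization_duration(auc, matrix(FALSE, n, n), times)
  expect_equal(empty$mean_duration_ms, 0)
})

test_that("decoding is deterministic and rejects degenerate input", {
  set.seed(19)
  course <- array(rnorm(40 * 5 * 3), c(40, 5, 3))
  labs <- labels_for(40)
  r1 <- temporal_mvpa(course, labs, decoding_config(seed = 20))
  r2 <- temporal_mvpa(course, labs, decoding_config(seed = 20))
  expect_identical(r1$auc_time, r2$auc_time)
  expect_error(temporal_mvpa(course, rep("nogo_overlap", 40),
                             decoding_config(seed = 1)), "two classes")
})
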