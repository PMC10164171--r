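# Canned simulation experiments: null calibration of the sensor-level
# cluster test, chance calibration of group decoding, planted-effect
# recovery (sensor signs, peak latencies, spatial DBSCAN recovery) and the
# cross-band transfer contrast. These fix the study conditions used by the
# package's validation suite; the geometry is deliberately scaled down
# (details and rationale in the methods vignette).

experiment_bands <- list(theta = c(4, 7), alpha = c(8, 12))

# per-subject sensor band-power course (trials kept), windowed to 0..1 s
sensor_band_course <- function(epochs, band, width = 5, decim = 4L,
                               window = c(0, 1)) {
  tfr <- morlet_tfr(epochs, seq(band[1], band[2], by = 1), width = width,
                    decim = decim)
  window_course(band_power(tfr, band), window)
}

# per-subject source band-power course on the included voxels
source_band_course <- function(epochs, leadfield, included, band,
                               reg_fraction = 0.05, width = 5, decim = 4L,
                               window = c(0, 1)) {
  C <- covariance_from_average(epochs)
  filt <- lcmv_filters(leadfield, C, reg_fraction = reg_fraction)
  src <- apply_filters(filt, epochs)
  dat <- src$data[, included, , drop = FALSE]
  tfr <- morlet_tfr(dat, seq(band[1], band[2], by = 1), width = width,
                    decim = decim, times = src$times, sfreq = src$sfreq)
  window_course(band_power(tfr, band, level = "source"), window)
}

subject_condition_arrays <- function(courses, labels_list) {
  # subjects x locations x time arrays per condition
  get <- function(cond) {
    mats <- lapply(seq_along(courses), function(i)
      condition_average(courses[[i]], labels_list[[i]], cond)$power[1, , ])
    arr <- array(0, c(length(mats), dim(mats[[1]])))
    for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
    arr
  }
  list(overlap = get("nogo_overlap"), nonoverlap = get("nogo_nonoverlap"))
}

#' Null calibration of the sensor-level cluster permutation test
#'
#' Repeatedly simulates groups with `effect_amplitude = 0` (conditions
#' exchangeable) and runs the theta-band sensor cluster test; the fraction
#' of repetitions with any significant cluster estimates the family-wise
#' false-positive rate, which should sit near the nominal alpha.
#'
#' @param n_reps Monte-Carlo repetitions.
#' @param n_subjects,n_channels group geometry.
#' @param n_trials Nogo trials per condition and subject.
#' @param n_permutations sign-flip draws per test.
#' @param alpha cluster-level level.
#' @param sfreq,epoch_window simulation timing (reduced for throughput).
#' @param seed master seed.
#' @return List with `fpr`, logical `rejections` per repetition and the
#'   parameters used.
#' @export
null_cluster_fpr <- function(n_reps = 200L, n_subjects = 15L,
                             n_channels = 20L, n_trials = 8L,
                             n_permutations = 500L, alpha = 0.05,
                             sfreq = 128, epoch_window = c(-0.7, 1.7),
                             seed = 1L) {
  lf <- make_leadfield(n_channels, c(5L, 5L, 5L), 1,
                       model = "random_full_rank", seed = seed)
  truth <- default_truth_for(lf, effect_amplitude = 0, shared_amplitude = 0)
  design <- task_design(n_go_per_condition = 2L * n_trials,
                        n_nogo_per_condition = n_trials, n_blocks = 1L)
  adj <- channel_adjacency(lf$channel_positions)
  rejections <- vapply(seq_len(n_reps), function(r) {
    group <- simulate_group(n_subjects, design, truth, lf, sfreq = sfreq,
                            epoch_window = epoch_window,
                            seed = seed_child(seed, r))
    courses <- lapply(group, sensor_band_course,
                      band = experiment_bands$theta)
    arrs <- subject_condition_arrays(courses, group_labels(group))
    rep <- permutation_p(arrs$overlap, arrs$nonoverlap, statistic = "t",
                         n_permutations = n_permutations, alpha = alpha,
                         adjacency = adj, min_neighbor_pairs = 2L,
                         seed = seed_child(seed, 10000L + r))
    length(significant_clusters(rep)) > 0
  }, logical(1))
  list(fpr = mean(rejections), rejections = rejections,
       n_reps = n_reps, alpha = alpha)
}

group_labels <- function(group) lapply(group, `[[`, "condition_labels")

#' Group decoding AUC under the null
#'
#' One group simulated with `effect_amplitude = 0`; sensor-level temporal
#' MVPA per subject. The grand-mean AUC estimates the decoder's chance
#' level (0.5 when nothing leaks).
#'
#' @inheritParams null_cluster_fpr
#' @param n_trials Nogo trials per condition (must allow the folds).
#' @return List with `mean_auc` and the per-subject mean AUCs.
#' @export
null_group_auc <- function(n_subjects = 15L, n_channels = 20L,
                           n_trials = 12L, sfreq = 128,
                           epoch_window = c(-0.7, 1.7), seed = 1L) {
  lf <- make_leadfield(n_channels, c(5L, 5L, 5L), 1,
                       model = "random_full_rank", seed = seed)
  truth <- default_truth_for(lf, effect_amplitude = 0, shared_amplitude = 0)
  design <- task_design(n_go_per_condition = 2L * n_trials,
                        n_nogo_per_condition = n_trials, n_blocks = 1L)
  group <- simulate_group(n_subjects, design, truth, lf, sfreq = sfreq,
                          epoch_window = epoch_window, seed = seed)
  per_subject <- vapply(seq_along(group), function(i) {
    course <- sensor_band_course(group[[i]], experiment_bands$theta)
    res <- temporal_mvpa(course, group[[i]]$condition_labels,
                         decoding_config(seed = seed_child(seed, 500L + i)))
    mean(res$auc_time, na.rm = TRUE)
  }, numeric(1))
  list(mean_auc = mean(per_subject), per_subject = per_subject)
}

#' Planted-effect recovery at the sensor level
#'
#' Simulates one high-signal group carrying both band effects, runs the
#' preprocessing chain and both sensor-level cluster tests, and estimates
#' per-subject peak latencies of the band difference courses.
#'
#' @param n_subjects group size.
#' @param effect_amplitude,noise_sd signal and noise scales (defaults give
#'   a high-SNR group).
#' @param n_trials Nogo trials per condition.
#' @param n_permutations sign-flip draws.
#' @param seed master seed.
#' @return List with per-band cluster reports and significant-cluster
#'   signs, per-subject theta/alpha latencies, their medians, and the
#'   paired Wilcoxon comparison of the latencies.
#' @export
sensor_recovery_experiment <- function(n_subjects = 15L,
                                       effect_amplitude = 20,
                                       noise_sd = 5, n_trials = 30L,
                                       n_permutations = 500L, seed = 1L) {
  lf <- make_leadfield(20L, c(6L, 6L, 6L), 1, model = "dipole", seed = seed)
  truth <- default_truth_for(lf, effect_amplitude = effect_amplitude,
                             shared_amplitude = 0)
  design <- task_design(n_go_per_condition = 2L * n_trials,
                        n_nogo_per_condition = n_trials, n_blocks = 1L)
  group <- simulate_group(n_subjects, design, truth, lf,
                          noise_sd = noise_sd, seed = seed)
  group <- lapply(group, preprocess_subject)
  adj <- channel_adjacency(lf$channel_positions)
  labels_list <- group_labels(group)
  out <- list(truth = truth)
  for (band in c("theta", "alpha")) {
    courses <- lapply(group, sensor_band_course,
                      band = experiment_bands[[band]])
    arrs <- subject_condition_arrays(courses, labels_list)
    rep <- permutation_p(arrs$overlap, arrs$nonoverlap, statistic = "t",
                         n_permutations = n_permutations,
                         adjacency = adj, min_neighbor_pairs = 2L,
                         seed = seed_child(seed, 77L))
    sgn <- if (band == "theta") +1 else -1
    lats <- subject_peak_latencies(courses, labels_list, sign = sgn)
    out[[band]] <- list(
      report = rep,
      sig_signs = vapply(significant_clusters(rep), `[[`, numeric(1),
                         "sign"),
      latencies = lats, median_latency = stats::median(lats))
  }
  out$latency_test <- wilcoxon_signed_rank(out$theta$latencies,
                                           out$alpha$latencies)
  out$wavelet_sd_s <- 5 / (2 * pi * mean(experiment_bands$theta))
  out
}

#' Spatial recovery of planted theta voxels via MVPA + DBSCAN
#'
#' Repeated high-SNR runs of the source pipeline: LCMV projection, theta
#' band power, per-voxel spatial MVPA, group-mean map, top-percentile
#' DBSCAN. A run counts as recovered when the cluster with the highest
#' mean AUC contains at least one planted theta voxel.
#'
#' @param n_runs seeded repetitions.
#' @param n_subjects subjects per run.
#' @param effect_amplitude,noise_sd signal and noise scales.
#' @param n_trials Nogo trials per condition.
#' @param seed master seed.
#' @return List with `recovery_rate`, logical `recovered` per run, and the
#'   planted voxel set.
#' @export
spatial_recovery_experiment <- function(n_runs = 20L, n_subjects = 5L,
                                        effect_amplitude = 20,
                                        noise_sd = 5, n_trials = 24L,
                                        seed = 1L) {
  lf <- make_leadfield(20L, c(5L, 5L, 5L), 1, model = "dipole", seed = seed)
  truth <- default_truth_for(lf, effect_amplitude = effect_amplitude,
                             shared_amplitude = 0)
  design <- task_design(n_go_per_condition = 2L * n_trials,
                        n_nogo_per_condition = n_trials, n_blocks = 1L)
  included <- select_voxels(lf)
  n_total <- nrow(lf$grid_coords)
  recovered <- vapply(seq_len(n_runs), function(r) {
    group <- simulate_group(n_subjects, design, truth, lf,
                            noise_sd = noise_sd, sfreq = 128,
                            epoch_window = c(-0.7, 1.7),
                            seed = seed_child(seed, 100L * r))
    maps <- vapply(seq_along(group), function(i) {
      course <- source_band_course(group[[i]], lf, included,
                                   experiment_bands$theta)
      sp <- spatial_mvpa(course, group[[i]]$condition_labels,
                         rep(TRUE, length(course$times)),
                         decoding_config(seed = seed_child(seed, r * 31L + i)))
      reinsert_voxel_map(sp$auc_voxel, included, n_total)$auc
    }, numeric(n_total))
    mean_map <- rowMeans(maps)
    cl <- find_decoding_clusters(mean_map, lf)
    if (length(cl$cluster_set$clusters) == 0) return(FALSE)
    top <- cl$cluster_set$clusters[[which.max(cl$summary$mean_auc)]]
    length(intersect(top, truth$theta_effect_voxels)) > 0
  }, logical(1))
  list(recovery_rate = mean(recovered), recovered = recovered,
       theta_voxels = truth$theta_effect_voxels)
}

#' Cross-band transfer contrast (shared vs orthogonal patterns)
#'
#' Simulates a group whose condition information lives solely in the
#' shared representational pattern (`effect_amplitude = 0`), decodes every
#' subject with theta training and alpha testing at matched times, and
#' tests the group AUC curve against chance. With `shared_pattern = TRUE`
#' the transfer is above chance; with orthogonal patterns it stays at
#' chance.
#'
#' @param shared_pattern logical, identical vs orthogonal band patterns.
#' @param n_subjects subjects.
#' @param shared_amplitude pattern modulation amplitude.
#' @param noise_sd sensor noise SD.
#' @param n_trials Nogo trials per condition.
#' @param n_permutations sign-flip draws for the group test.
#' @param seed master seed.
#' @return List with `mean_auc` (grand mean over subjects and times),
#'   `sig_positive` (any significant positive cluster), and the per-subject
#'   AUC curves.
#' @export
transfer_experiment <- function(shared_pattern = TRUE, n_subjects = 10L,
                                shared_amplitude = 15, noise_sd = 5,
                                n_trials = 24L, n_permutations = 500L,
                                seed = 1L) {
  lf <- make_leadfield(20L, c(5L, 5L, 5L), 1, model = "dipole", seed = seed)
  truth <- default_truth_for(lf, effect_amplitude = 0,
                             shared_amplitude = shared_amplitude,
                             shared_pattern = shared_pattern)
  design <- task_design(n_go_per_condition = 2L * n_trials,
                        n_nogo_per_condition = n_trials, n_blocks = 1L)
  included <- select_voxels(lf)
  group <- simulate_group(n_subjects, design, truth, lf,
                          noise_sd = noise_sd, sfreq = 128,
                          epoch_window = c(-0.7, 1.7), seed = seed)
  curves <- NULL
  for (i in seq_along(group)) {
    th <- source_band_course(group[[i]], lf, included,
                             experiment_bands$theta)
    al <- source_band_course(group[[i]], lf, included,
                             experiment_bands$alpha)
    res <- cross_band_mvpa(th, al, group[[i]]$condition_labels,
                           decoding_config(seed = seed_child(seed, 900L + i)),
                           diag_only = TRUE)
    if (is.null(curves))
      curves <- matrix(NA_real_, length(group), length(res$auc_time))
    curves[i, ] <- res$auc_time
  }
  valid <- !apply(curves, 2, anyNA)
  grp <- group_test_vs_chance(curves[, valid, drop = FALSE], chance = 0.5,
                              n_permutations = n_permutations,
                              seed = seed_child(seed, 999L))
  pos_sig <- any(vapply(significant_clusters(grp$report),
                        function(cl) cl$sign > 0, logical(1)))
  list(mean_auc = mean(curves[, valid]), sig_positive = pos_sig,
       curves = curves)
}
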