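# End-to-end orchestration: simulate -> preprocess -> sensor statistics ->
# beamform -> source band power -> decode (theta, alpha, theta->alpha) ->
# DBSCAN clusters -> brain-behavior regression. Stages run in a fixed
# order, write their artifacts to a run directory as they finish, and draw
# their seeds deterministically from the master seed, so a run is exactly
# reproducible and individual stages can be re-examined.

#' Pipeline run configuration
#'
#' Default values give the scaled-down study geometry used throughout the
#' package: 15 subjects, 20 channels, a 6 x 6 x 6 grid at 1 cm and 40 Nogo
#' trials per condition. The full-scale study geometry (79 subjects, 60
#' channels, 84 Nogo trials per condition, 2 to 15 Hz source decomposition)
#' is reachable through the same fields.
#'
#' @param n_subjects number of simulated subjects.
#' @param n_channels sensors in the synthetic montage.
#' @param grid_shape,grid_spacing voxel lattice (see [make_leadfield()]).
#' @param leadfield_model `"dipole"` or `"random_full_rank"`.
#' @param design a [task_design()]; its `n_nogo_per_condition` sets the
#'   epochs per condition.
#' @param effect_amplitude,shared_pattern,shared_amplitude,behavioral_binding_fa
#'   ground-truth effect settings (see [ground_truth()]).
#' @param noise_sd,base_amp,sfreq,epoch_window simulation parameters (see
#'   [simulate_subject_eeg()]).
#' @param bands named list of frequency bands (Hz).
#' @param morlet_width Morlet parameter (cycles).
#' @param tfr_decim decimation of the power time courses.
#' @param analysis_window time window (s) submitted to statistics and
#'   decoding.
#' @param n_folds,c_param decoding settings (see [decoding_config()]).
#' @param n_permutations,alpha,alpha_element,min_neighbor_pairs cluster
#'   test settings.
#' @param percentile,eps_factor,min_pts DBSCAN settings.
#' @param removal_p regression backward-elimination threshold.
#' @param reg_fraction LCMV regularization.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 15L, n_channels = 20L,
                       grid_shape = c(6L, 6L, 6L), grid_spacing = 1,
                       leadfield_model = "dipole",
                       design = scaled_task_design(),
                       effect_amplitude = 10, shared_pattern = TRUE,
                       shared_amplitude = effect_amplitude,
                       behavioral_binding_fa = 35.3,
                       noise_sd = 10, base_amp = 10, sfreq = 256,
                       epoch_window = c(-1, 1.75),
                       bands = list(theta = c(4, 7), alpha = c(8, 12)),
                       morlet_width = 5, tfr_decim = 8L,
                       analysis_window = c(0, 1),
                       n_folds = 5L, c_param = 1,
                       n_permutations = 500L, alpha = 0.05,
                       alpha_element = 0.05, min_neighbor_pairs = 2L,
                       percentile = 0.02, eps_factor = 1.5, min_pts = 2L,
                       removal_p = 0.10, reg_fraction = 0.05, seed = 1L) {
  stopifnot(length(bands) == 2, all(c("theta", "alpha") %in% names(bands)),
            bands$theta[2] < bands$alpha[1])   # bands disjoint
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Default ground truth for a lead field
#'
#' Picks two compact, disjoint blobs of included voxels (one frontal-ish
#' for theta, one posterior for alpha) so planted effects sit in labeled
#' gray matter.
#'
#' @param leadfield a [lead_field()].
#' @param ... further arguments passed to [ground_truth()].
#' @return A [ground_truth()].
#' @export
default_truth_for <- function(leadfield, ...) {
  inc <- select_voxels(leadfield)
  co <- leadfield$grid_coords
  blob <- function(ref, exclude = integer(0)) {
    cand <- setdiff(inc, exclude)
    d <- sqrt(colSums((t(co[cand, , drop = FALSE]) - ref)^2))
    seed_vox <- cand[which.min(d)]
    d2 <- sqrt(colSums((t(co[cand, , drop = FALSE]) - co[seed_vox, ])^2))
    sort(cand[d2 <= 1.01 * leadfield$grid_spacing])
  }
  span <- apply(co, 2, range)
  theta_ref <- c(mean(span[, 1]) + 0.25 * diff(span[, 1]),
                 span[2, 2] - 0.2 * diff(span[, 2]),
                 span[2, 3] - 0.2 * diff(span[, 3]))
  th <- blob(theta_ref)
  alpha_ref <- c(mean(span[, 1]) - 0.25 * diff(span[, 1]),
                 span[1, 2] + 0.2 * diff(span[, 2]),
                 mean(span[, 3]))
  al <- blob(alpha_ref, exclude = th)
  ground_truth(theta_effect_voxels = th, alpha_effect_voxels = al, ...)
}

stage_file <- function(dir, name) file.path(dir, paste0(name, ".rds"))

save_stage <- function(dir, name, value) {
  saveRDS(value, stage_file(dir, name))
  value
}

# restrict a band course to the analysis window
window_course <- function(course, window) {
  sel <- course$times >= window[1] & course$times <= window[2]
  band_power_course(course$power[, , sel, drop = FALSE],
                    course$times[sel], course$band, course$level,
                    course$n_trials_averaged)
}

band_freqs <- function(band, step = 0.5) seq(band[1], band[2], by = step)

#' Run the full analysis pipeline
#'
#' Executes all stages in order on synthetic data and writes one artifact
#' file per stage under `out_dir`, plus a JSON manifest with the
#' configuration, per-stage seeds and artifact hashes. Re-running with an
#' identical configuration reproduces identical artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if missing).
#' @param verbose print stage progress.
#' @return Invisibly, the path `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- stats::setNames(
    vapply(1:8, function(i) seed_child(config$seed, i), integer(1)),
    c("simulate", "preprocess", "sensorstats", "beamform", "bandpower",
      "decode", "clusters", "regress"))

  ## 1 simulate ------------------------------------------------------------
  say("stage simulate")
  lf <- make_leadfield(config$n_channels, config$grid_shape,
                       config$grid_spacing, model = config$leadfield_model,
                       seed = seeds["simulate"])
  truth <- default_truth_for(
    lf, effect_amplitude = config$effect_amplitude,
    shared_pattern = config$shared_pattern,
    shared_amplitude = config$shared_amplitude,
    behavioral_binding_fa = config$behavioral_binding_fa)
  events <- generate_task_events(config$design, seed = seeds["simulate"])
  behavior <- simulate_behavior(config$design, truth, config$n_subjects,
                                seed = seeds["simulate"])
  group <- simulate_group(config$n_subjects, config$design, truth, lf,
                          noise_sd = config$noise_sd, sfreq = config$sfreq,
                          epoch_window = config$epoch_window,
                          seed = seeds["simulate"],
                          base_amp = config$base_amp)
  save_stage(out_dir, "simulate",
             list(leadfield = lf, truth = truth, events = events,
                  behavior = behavior))

  ## 2 preprocess ----------------------------------------------------------
  say("stage preprocess")
  group <- lapply(group, preprocess_subject)
  save_stage(out_dir, "preprocess",
             list(log = lapply(group, `[[`, "log"),
                  n_trials = vapply(group, function(g) dim(g$data)[1],
                                    integer(1))))

  ## 3 sensor statistics ---------------------------------------------------
  say("stage sensorstats")
  adj <- channel_adjacency(lf$channel_positions)
  sensor <- list()
  for (band in c("theta", "alpha")) {
    courses <- lapply(group, function(g) {
      tfr <- morlet_tfr(g, band_freqs(config$bands[[band]]),
                        width = config$morlet_width,
                        decim = config$tfr_decim)
      band_power(tfr, config$bands[[band]])
    })
    labels_list <- lapply(group, `[[`, "condition_labels")
    avg <- function(cond) {
      arr <- vapply(seq_along(courses), function(i) {
        co <- window_course(condition_average(courses[[i]], labels_list[[i]],
                                              cond), config$analysis_window)
        co$power[1, , ]
      }, matrix(0, dim(courses[[1]]$power)[2],
                sum(courses[[1]]$times >= config$analysis_window[1] &
                      courses[[1]]$times <= config$analysis_window[2])))
      aperm(arr, c(3, 1, 2))               # subjects x channels x time
    }
    ov <- avg("nogo_overlap"); no <- avg("nogo_nonoverlap")
    report <- permutation_p(ov, no, statistic = "t",
                            n_permutations = config$n_permutations,
                            alpha = config$alpha,
                            alpha_element = config$alpha_element,
                            adjacency = adj,
                            min_neighbor_pairs = config$min_neighbor_pairs,
                            seed = seeds["sensorstats"])
    sgn <- if (band == "theta") +1 else -1
    lats <- subject_peak_latencies(courses, labels_list, sign = sgn,
                                   window = config$analysis_window)
    sensor[[band]] <- list(report = report, latencies = lats)
  }
  sensor$latency_test <- wilcoxon_signed_rank(sensor$theta$latencies,
                                              sensor$alpha$latencies)
  save_stage(out_dir, "sensorstats", sensor)

  ## 4+5 beamform and source band power ------------------------------------
  say("stage beamform/bandpower")
  included <- select_voxels(lf)
  source_courses <- list(theta = list(), alpha = list())
  labels_list <- list()
  for (i in seq_along(group)) {
    C <- covariance_from_average(group[[i]])
    filt <- lcmv_filters(lf, C, reg_fraction = config$reg_fraction)
    src <- apply_filters(filt, group[[i]])
    src$data <- src$data[, included, , drop = FALSE]
    for (band in c("theta", "alpha")) {
      tfr <- morlet_tfr(src$data, band_freqs(config$bands[[band]]),
                        width = config$morlet_width,
                        decim = config$tfr_decim,
                        times = src$times, sfreq = src$sfreq)
      source_courses[[band]][[i]] <-
        window_course(band_power(tfr, config$bands[[band]],
                                 level = "source"),
                      config$analysis_window)
    }
    labels_list[[i]] <- group[[i]]$condition_labels
  }
  save_stage(out_dir, "beamform",
             list(included = included, n_included = length(included),
                  n_total = nrow(lf$grid_coords)))

  ## 6 decode --------------------------------------------------------------
  say("stage decode")
  dec_times <- source_courses$theta[[1]]$times
  n_sub <- length(group)
  modes <- list(theta = c("theta", "theta"), alpha = c("alpha", "alpha"),
                theta2alpha = c("theta", "alpha"))
  decode_out <- list()
  for (mode in names(modes)) {
    trb <- modes[[mode]][1]; teb <- modes[[mode]][2]
    cfg_dec <- function(i) decoding_config(
      c_param = config$c_param, n_folds = config$n_folds,
      seed = seed_child(seeds["decode"], i))
    curves <- matrix(NA_real_, n_sub, length(dec_times))
    gens <- array(NA_real_, c(n_sub, length(dec_times), length(dec_times)))
    for (i in seq_len(n_sub)) {
      if (trb == teb) {
        g <- temporal_generalization(source_courses[[trb]][[i]],
                                     labels_list[[i]], cfg_dec(i))
      } else {
        g <- cross_band_mvpa(source_courses[[trb]][[i]],
                             source_courses[[teb]][[i]],
                             labels_list[[i]], cfg_dec(i))
      }
      curves[i, ] <- g$auc_time
      gens[i, , ] <- g$auc_gen
    }
    grp_time <- group_test_vs_chance(
      curves, chance = 0.5, n_permutations = config$n_permutations,
      alpha = config$alpha, alpha_element = config$alpha_element,
      seed = seed_child(seeds["decode"], 100))
    grp_gen <- group_test_vs_chance(
      gens, chance = 0.5, adjacency = chain_adjacency(length(dec_times)),
      n_permutations = config$n_permutations,
      alpha = config$alpha, alpha_element = config$alpha_element,
      seed = seed_child(seeds["decode"], 101))
    gen_mean <- apply(gens, c(2, 3), mean)
    dur <- generalization_duration(gen_mean, grp_gen$sig_mask, dec_times)
    sig_time <- grp_time$sig_mask
    if (!any(sig_time)) sig_time <- rep(TRUE, length(dec_times))
    voxel_maps <- matrix(NA_real_, n_sub, nrow(lf$grid_coords))
    for (i in seq_len(n_sub)) {
      sp <- spatial_mvpa(source_courses[[trb]][[i]], labels_list[[i]],
                         sig_time, cfg_dec(i))
      voxel_maps[i, ] <- reinsert_voxel_map(sp$auc_voxel, included,
                                            nrow(lf$grid_coords))$auc
    }
    chance_map <- reinsert_voxel_map(rep(0.5, length(included)), included,
                                     nrow(lf$grid_coords))$chance
    grp_vox <- group_test_vs_chance(
      voxel_maps[, included, drop = FALSE], chance = 0.5,
      adjacency = grid_adjacency(lf$grid_coords[included, , drop = FALSE],
                                 config$grid_spacing),
      n_permutations = config$n_permutations, alpha = config$alpha,
      alpha_element = config$alpha_element,
      seed = seed_child(seeds["decode"], 102))
    decode_out[[mode]] <- list(
      curves = curves, group_time = grp_time, gen_mean = gen_mean,
      group_gen = grp_gen, duration = dur, voxel_maps = voxel_maps,
      chance_map = chance_map, group_voxel = grp_vox, times = dec_times)
  }
  save_stage(out_dir, "decode", decode_out)

  ## 7 DBSCAN clusters -----------------------------------------------------
  say("stage clusters")
  clusters <- lapply(decode_out, function(d)
    find_decoding_clusters(colMeans(d$voxel_maps), lf,
                           percentile = config$percentile,
                           eps_factor = config$eps_factor,
                           min_pts = config$min_pts))
  save_stage(out_dir, "clusters", clusters)

  ## 8 regression ----------------------------------------------------------
  say("stage regress")
  fa <- stats::reshape(behavior[, c("subject", "condition", "nogo_fa_rate")],
                       direction = "wide", idvar = "subject",
                       timevar = "condition")
  y <- binding_effect(fa$nogo_fa_rate.overlap, fa$nogo_fa_rate.nonoverlap)
  preds <- list()
  for (mode in names(clusters))
    for (k in seq_along(clusters[[mode]]$cluster_set$clusters)) {
      mem <- clusters[[mode]]$cluster_set$clusters[[k]]
      preds[[paste0(mode, "_c", k)]] <-
        rowMeans(decode_out[[mode]]$voxel_maps[, mem, drop = FALSE])
    }
  regress <- NULL
  if (length(preds) >= 1 && length(y) > length(preds) + 1) {
    X <- do.call(cbind, preds)
    regress <- tryCatch(backward_elimination(y, X, config$removal_p),
                        error = function(e) e)
  }
  save_stage(out_dir, "regress",
             list(y = y, predictors = preds, result = regress))

  manifest <- list(
    package_version = as.character(utils::packageVersion("bindecode")),
    seeds = as.list(seeds),
    config = config[setdiff(names(config), "design")],
    design = unclass(config$design),
    artifacts = as.list(tools::md5sum(list.files(out_dir, "\\.rds$",
                                                 full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of [run_pipeline()] and tabulates the study-style
#' summary: sensor cluster statistics, peak latencies, per-mode AUC
#' summaries over significant entries, generalization durations, DBSCAN
#' cluster anatomy and the regression trace. Purely a reader; nothing is
#' recomputed.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return A `pipeline_report` list.
#' @export
report_run <- function(run_dir) {
  need <- c("simulate", "sensorstats", "decode", "clusters", "regress")
  missing <- need[!file.exists(stage_file(run_dir, need))]
  if (length(missing))
    stop("incomplete run; missing artifacts: ", paste(missing, collapse = ", "))
  sensor <- readRDS(stage_file(run_dir, "sensorstats"))
  decode <- readRDS(stage_file(run_dir, "decode"))
  clusters <- readRDS(stage_file(run_dir, "clusters"))
  regress <- readRDS(stage_file(run_dir, "regress"))
  modes <- lapply(names(decode), function(mode) {
    d <- decode[[mode]]
    sig <- d$group_time$sig_mask
    curve <- colMeans(d$curves)
    list(mode = mode,
         auc_mean = if (any(sig)) mean(curve[sig]) else NA_real_,
         auc_min = if (any(sig)) min(curve[sig]) else NA_real_,
         auc_max = if (any(sig)) max(curve[sig]) else NA_real_,
         frac_time_significant = mean(sig),
         generalization = d$duration,
         n_clusters = length(clusters[[mode]]$cluster_set$clusters),
         cluster_summary = clusters[[mode]]$summary)
  })
  names(modes) <- names(decode)
  structure(list(
    sensor = list(
      theta_clusters = lapply(sensor$theta$report$clusters,
                              function(cl) cl[c("stat_sum", "sign", "p")]),
      alpha_clusters = lapply(sensor$alpha$report$clusters,
                              function(cl) cl[c("stat_sum", "sign", "p")]),
      median_theta_latency = stats::median(sensor$theta$latencies),
      median_alpha_latency = stats::median(sensor$alpha$latencies),
      latency_test = sensor$latency_test),
    modes = modes,
    regression = regress$result), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== sensor level ==\n")
  cat(sprintf("  median peak latency: theta %.3f s, alpha %.3f s (Z = %.2f, p = %.3g)\n",
              x$sensor$median_theta_latency, x$sensor$median_alpha_latency,
              x$sensor$latency_test$z, x$sensor$latency_test$p))
  for (mode in names(x$modes)) {
    m <- x$modes[[mode]]
    cat(sprintf("== %s ==\n", mode))
    if (is.na(m$auc_mean)) {
      cat("  no significant decoding cluster\n")
    } else
      cat(sprintf("  AUC mean/min/max over significant times: %.3f/%.3f/%.3f (%.0f%% of times)\n",
                  m$auc_mean, m$auc_min, m$auc_max,
                  100 * m$frac_time_significant))
    cat(sprintf("  generalization: %.0f ms mean duration, %.0f%% significant cells\n",
                m$generalization$mean_duration_ms,
                100 * m$generalization$frac_significant))
    if (m$n_clusters == 0) cat("  no clusters\n") else
      cat(sprintf("  %d DBSCAN cluster(s); top labels: %s\n", m$n_clusters,
                  paste(utils::head(m$cluster_summary$labels, 2),
                        collapse = " | ")))
  }
  if (!is.null(x$regression) && inherits(x$regression, "regression_result")) {
    cat("== regression ==\n")
    print(x$regression)
  }
  invisible(x)
}
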