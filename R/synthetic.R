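# Synthetic Go/Nogo study generator: task events, behavior, lead fields and
# multi-subject sensor EEG with planted theta/alpha condition effects.

#' Go/Nogo task design
#'
#' Parameters of the feature-overlap Go/Nogo session. Defaults reproduce the
#' full study design: 196 trials per Go condition and 84 per Nogo condition
#' (70:30 Go:Nogo), seven equal blocks, 450 ms stimuli, a 1700 ms response
#' window and inter-trial intervals jittered uniformly between 700 and
#' 1100 ms.
#'
#' @param n_go_per_condition Go trials per condition (overlapping and
#'   non-overlapping).
#' @param n_nogo_per_condition Nogo trials per condition.
#' @param n_blocks number of equal blocks; every per-condition count must be
#'   divisible by `n_blocks` so conditions stay balanced within blocks.
#' @param stim_duration stimulus duration (ms).
#' @param response_window maximal response latency ending a trial (ms).
#' @param iti_range length-2 numeric, uniform inter-trial-interval jitter (ms).
#'
#' @return A `task_design` list.
#' @export
task_design <- function(n_go_per_condition = 196L,
                        n_nogo_per_condition = 84L,
                        n_blocks = 7L,
                        stim_duration = 450,
                        response_window = 1700,
                        iti_range = c(700, 1100)) {
  stopifnot(n_go_per_condition >= 1, n_nogo_per_condition >= 1,
            n_blocks >= 1, length(iti_range) == 2,
            iti_range[1] <= iti_range[2], stim_duration > 0)
  total <- 2L * (n_go_per_condition + n_nogo_per_condition)
  if (total %% n_blocks != 0)
    stop("total trial count (", total, ") not divisible by n_blocks (",
         n_blocks, ")")
  if (n_go_per_condition %% n_blocks != 0 ||
      n_nogo_per_condition %% n_blocks != 0)
    stop("per-condition trial counts must be divisible by n_blocks ",
         "to balance conditions within blocks")
  structure(list(n_go_per_condition = as.integer(n_go_per_condition),
                 n_nogo_per_condition = as.integer(n_nogo_per_condition),
                 n_blocks = as.integer(n_blocks),
                 stim_duration = stim_duration,
                 response_window = response_window,
                 iti_range = as.numeric(iti_range)),
            class = "task_design")
}

#' Scaled-down task design for simulations
#'
#' A reduced session (40 Nogo trials per condition) preserving the 70:30
#' Go:Nogo ratio approximately, used as the default for synthetic EEG runs.
#'
#' @param n_nogo_per_condition Nogo trials per condition.
#' @return A `task_design`.
#' @export
scaled_task_design <- function(n_nogo_per_condition = 40L) {
  task_design(n_go_per_condition = 2L * n_nogo_per_condition,
              n_nogo_per_condition = n_nogo_per_condition,
              n_blocks = 2L)
}

condition_levels <- c("go_nonoverlap", "go_overlap",
                      "nogo_nonoverlap", "nogo_overlap")

# stimulus identities of the task (word_color), two per overlapping condition
stimulus_table <- list(
  go_nonoverlap   = "PRESS_green",
  nogo_nonoverlap = "STOPP_red",
  go_overlap      = c("DRUECK_white", "XXXXX_blue"),
  nogo_overlap    = c("DRUECK_blue", "XXXXX_white")
)

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic per-subject / per-stage seed fan-out from a master seed
seed_child <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 9176) %%
               2147483646) + 1L
}

#' Generate the trial sequence of a session
#'
#' Produces the full pseudorandomized event list: exact per-condition counts,
#' conditions balanced within every block, strictly increasing onsets and
#' uniformly jittered inter-trial intervals.
#'
#' @param design a [task_design()].
#' @param seed integer seed; the sequence is deterministic given the seed.
#'
#' @return A data.frame with one row per trial: `block_index`, `onset` (ms
#'   from session start), `condition`, `stimulus_id`, `responded`, `rt` (ms,
#'   NA when no response).
#' @export
generate_task_events <- function(design, seed = 1L) {
  stopifnot(inherits(design, "task_design"))
  with_seed(seed, {
    per_block <- c(go_nonoverlap = design$n_go_per_condition %/% design$n_blocks,
                   go_overlap = design$n_go_per_condition %/% design$n_blocks,
                   nogo_nonoverlap = design$n_nogo_per_condition %/% design$n_blocks,
                   nogo_overlap = design$n_nogo_per_condition %/% design$n_blocks)
    rows <- vector("list", design$n_blocks)
    for (b in seq_len(design$n_blocks)) {
      conds <- sample(rep(names(per_block), times = per_block))
      stim <- vapply(seq_along(conds), function(i) {
        ids <- stimulus_table[[conds[i]]]
        ids[(i %% length(ids)) + 1L]
      }, character(1))
      rows[[b]] <- data.frame(block_index = b, condition = conds,
                              stimulus_id = stim,
                              stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, rows)
    n <- nrow(ev)
    iti <- stats::runif(n, design$iti_range[1], design$iti_range[2])
    trial_len <- design$response_window + iti
    ev$onset <- cumsum(c(0, trial_len[-n]))
    # Go trials get a response at a plausible latency; Nogo trials none
    is_go <- grepl("^go", ev$condition)
    ev$responded <- is_go
    ev$rt <- ifelse(is_go,
                    pmin(pmax(stats::rnorm(n, 445, 50), 150),
                         design$response_window), NA_real_)
    ev[, c("block_index", "onset", "condition", "stimulus_id",
           "responded", "rt")]
  })
}

#' Ground truth of the planted neurophysiological and behavioral effects
#'
#' Defines where, when and how strongly the two Nogo conditions differ in the
#' synthetic data. Two kinds of effect are planted per frequency band:
#'
#' * a mean-power effect at `theta_effect_voxels` / `alpha_effect_voxels`
#'   with a Gaussian temporal envelope: theta power is higher in the
#'   overlapping condition (sign +1) peaking at `theta_peak_latency`, alpha
#'   power is lower in the overlapping condition (sign -1) peaking at
#'   `alpha_peak_latency`;
#' * a zero-mean, mixed-sign spatial pattern over `shared_voxels` whose
#'   condition modulation has the same sign in both bands. When
#'   `shared_pattern` is `TRUE` the theta and alpha patterns are identical,
#'   making the condition representation transferable from theta to alpha
#'   (cross-band decoding above chance); when `FALSE` the two bands carry
#'   orthogonal patterns and nothing transfers. Because the pattern is
#'   zero-mean it leaves the band-mean power signs untouched.
#'
#' @param theta_effect_voxels,alpha_effect_voxels integer voxel indices into
#'   the lead-field grid carrying the band mean-power effects (disjoint sets).
#' @param shared_voxels voxel indices carrying the shared representational
#'   pattern; default is the union of the two effect sets.
#' @param theta_peak_latency,alpha_peak_latency group-mean envelope peaks (s).
#' @param latency_sd length-2 numeric, between-subject SD of the theta and
#'   alpha peak latencies (s).
#' @param theta_effect_sign,alpha_effect_sign +1/-1 sign of the
#'   overlapping-minus-non-overlapping power difference.
#' @param shared_pattern logical; identical (TRUE) vs orthogonal (FALSE)
#'   cross-band difference patterns.
#' @param effect_amplitude amplitude of the mean-power condition effect
#'   (source units; 0 yields exchangeable conditions).
#' @param shared_amplitude amplitude of the shared-pattern modulation.
#' @param envelope_sd temporal SD of the Gaussian effect envelope (s).
#' @param shared_centers length-2 numeric, envelope centers (s) of the shared
#'   pattern in theta and alpha.
#' @param shared_env_sd temporal SD of the shared-pattern envelope (s).
#' @param behavioral_binding_fa group-mean excess Nogo false-alarm rate
#'   (percentage points) in the overlapping condition.
#' @param rt_binding group-mean Go RT slowing (ms) in the overlapping
#'   condition.
#' @param pattern_seed seed fixing the shared spatial pattern vectors.
#'
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(theta_effect_voxels,
                         alpha_effect_voxels,
                         shared_voxels = NULL,
                         theta_peak_latency = 0.52,
                         alpha_peak_latency = 0.59,
                         latency_sd = c(0.16, 0.21),
                         theta_effect_sign = +1,
                         alpha_effect_sign = -1,
                         shared_pattern = TRUE,
                         effect_amplitude = 10,
                         shared_amplitude = effect_amplitude,
                         envelope_sd = 0.15,
                         shared_centers = c(0.5, 0.5),
                         shared_env_sd = 0.35,
                         behavioral_binding_fa = 35.3,
                         rt_binding = 11,
                         pattern_seed = 42L) {
  stopifnot(effect_amplitude >= 0, shared_amplitude >= 0, envelope_sd > 0,
            length(latency_sd) == 2, length(shared_centers) == 2)
  if (length(intersect(theta_effect_voxels, alpha_effect_voxels)) > 0)
    stop("theta and alpha effect voxel sets must be disjoint")
  if (is.null(shared_voxels))
    shared_voxels <- sort(union(theta_effect_voxels, alpha_effect_voxels))
  structure(list(theta_effect_voxels = as.integer(theta_effect_voxels),
                 alpha_effect_voxels = as.integer(alpha_effect_voxels),
                 shared_voxels = as.integer(shared_voxels),
                 theta_peak_latency = theta_peak_latency,
                 alpha_peak_latency = alpha_peak_latency,
                 latency_sd = latency_sd,
                 theta_effect_sign = theta_effect_sign,
                 alpha_effect_sign = alpha_effect_sign,
                 shared_pattern = isTRUE(shared_pattern),
                 effect_amplitude = effect_amplitude,
                 shared_amplitude = shared_amplitude,
                 envelope_sd = envelope_sd,
                 shared_centers = shared_centers,
                 shared_env_sd = shared_env_sd,
                 behavioral_binding_fa = behavioral_binding_fa,
                 rt_binding = rt_binding,
                 pattern_seed = as.integer(pattern_seed)),
            class = "ground_truth")
}

# zero-mean unit-norm shared pattern vectors for the two bands
shared_patterns <- function(truth) {
  k <- length(truth$shared_voxels)
  with_seed(truth$pattern_seed, {
    v1 <- stats::rnorm(k)
    v1 <- v1 - mean(v1); v1 <- v1 / sqrt(sum(v1^2))
    if (truth$shared_pattern) {
      v2 <- v1
    } else {
      v2 <- stats::rnorm(k)
      v2 <- v2 - mean(v2)
      v2 <- v2 - sum(v2 * v1) * v1          # orthogonal to the theta pattern
      v2 <- v2 / sqrt(sum(v2^2))
    }
    list(theta = v1, alpha = v2)
  })
}

#' Simulate per-subject behavioral outcomes
#'
#' Draws per-subject hit rates, Go RTs and Nogo false-alarm rates around the
#' condition means of the study (Go hits 99.3 vs 98.7 %, Go RT 439 vs 450 ms,
#' Nogo false alarms 2.2 % in the non-overlapping condition and
#' `2.2 + behavioral_binding_fa` in the overlapping condition), with the
#' study's between-subject spreads, clipped to valid ranges.
#'
#' @param design a [task_design()] (carried for trial counts; the rates are
#'   generated directly).
#' @param truth a [ground_truth()]; `behavioral_binding_fa` and `rt_binding`
#'   set the condition differences.
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#'
#' @return A data.frame with columns `subject`, `condition`
#'   (`"nonoverlap"`/`"overlap"`), `go_hit_rate`, `go_rt`, `nogo_fa_rate`.
#' @export
simulate_behavior <- function(design, truth, n_subjects, seed = 1L) {
  stopifnot(n_subjects >= 1)
  with_seed(seed, {
    clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    # the overlap spread grows with the planted binding effect: false-alarm
    # rates near the floor cannot vary as widely as mid-range rates
    sd_ov <- 3.0 + (17.1 - 3.0) * truth$behavioral_binding_fa / 35.3
    fa_non <- clip(stats::rnorm(n_subjects, 2.2, 3.0), 0, 100)
    fa_ov  <- clip(stats::rnorm(n_subjects, 2.2 + truth$behavioral_binding_fa,
                                sd_ov), 0, 100)
    hit_non <- clip(stats::rnorm(n_subjects, 99.3, 0.9), 0, 100)
    hit_ov  <- clip(stats::rnorm(n_subjects, 98.7, 1.4), 0, 100)
    rt_non <- clip(stats::rnorm(n_subjects, 439, 52), 150,
                   design$response_window)
    rt_ov  <- clip(stats::rnorm(n_subjects, 439 + truth$rt_binding, 54), 150,
                   design$response_window)
    data.frame(
      subject = rep(sprintf("s%02d", seq_len(n_subjects)), 2),
      condition = rep(c("nonoverlap", "overlap"), each = n_subjects),
      go_hit_rate = c(hit_non, hit_ov),
      go_rt = c(rt_non, rt_ov),
      nogo_fa_rate = c(fa_non, fa_ov),
      stringsAsFactors = FALSE)
  })
}

# sensors spread on the upper hemisphere of a sphere (Fibonacci lattice)
eeg_montage <- function(n_channels, radius = 9) {
  stopifnot(n_channels >= 2)
  i <- seq_len(n_channels) - 0.5
  z <- i / n_channels              # upper hemisphere only: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i
  r_xy <- sqrt(1 - z^2)
  pos <- radius * cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = z)
  rownames(pos) <- sprintf("E%02d", seq_len(n_channels))
  pos
}

# synthetic atlas: name voxels by coordinate octant, mark the lowest slab as
# cerebellar and a seeded fraction as unlabeled
synthetic_atlas <- function(coords, unlabeled_frac = 0.08, seed = 7L) {
  n <- nrow(coords)
  z0 <- min(coords[, 3])
  labels <- character(n)
  cereb <- coords[, 3] == z0 & coords[, 2] < stats::median(coords[, 2])
  hemi <- ifelse(coords[, 1] < 0, "L", "R")
  ap <- ifelse(coords[, 2] >= stats::median(coords[, 2]), "Frontal", "Occipital")
  dv <- ifelse(coords[, 3] >= stats::median(coords[, 3]), "Sup", "Mid")
  labels <- paste(ap, dv, hemi, sep = "_")
  labels[cereb] <- "Cerebellum"
  with_seed(seed, {
    free <- which(!cereb)
    n_un <- round(unlabeled_frac * n)
    if (n_un > 0) labels[sample(free, min(n_un, length(free)))] <- "Unlabeled"
  })
  labels
}

#' Construct a synthetic lead field on a regular voxel grid
#'
#' Builds the forward gain matrix mapping unit dipoles at every voxel (three
#' Cartesian orientations) to the sensors. Two models are available:
#' `"dipole"`, the closed-form potential of a current dipole in a homogeneous
#' conductor (gain decays with sensor-source distance), and
#' `"random_full_rank"`, a seeded Gaussian gain for fast unit tests. A
#' synthetic atlas labels most voxels with region names and marks the rest
#' cerebellar or unlabeled so that exclusion logic is exercised.
#'
#' @param n_channels number of sensors (placed on an upper spherical cap).
#' @param grid_shape length-3 integer, voxels per axis.
#' @param grid_spacing lattice spacing (cm).
#' @param model `"dipole"` or `"random_full_rank"`.
#' @param seed integer seed (atlas unlabeled-voxel draw; random gain).
#' @param reference `"average"` applies the average-reference projector to
#'   the gain, `"none"` leaves raw potentials.
#' @param unlabeled_frac fraction of voxels marked `"Unlabeled"`.
#'
#' @return A [lead_field()].
#' @export
make_leadfield <- function(n_channels = 20L, grid_shape = c(6L, 6L, 6L),
                           grid_spacing = 1, model = c("dipole",
                                                       "random_full_rank"),
                           seed = 1L, reference = c("average", "none"),
                           unlabeled_frac = 0.08) {
  model <- match.arg(model)
  reference <- match.arg(reference)
  stopifnot(n_channels >= 2, length(grid_shape) == 3, all(grid_shape >= 1),
            grid_spacing > 0)
  pos <- eeg_montage(n_channels)
  dmin <- min(stats::dist(pos))
  if (dmin < 1e-9) stop("degenerate geometry: coincident sensors")
  ax <- lapply(grid_shape, function(k) (seq_len(k) - (k + 1) / 2) * grid_spacing)
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  coords[, 3] <- coords[, 3] + 1            # grid sits inside the upper head
  n_vox <- nrow(coords)
  gain <- array(0, c(n_channels, n_vox, 3))
  if (model == "dipole") {
    for (v in seq_len(n_vox)) {
      d <- sweep(pos, 2, coords[v, ])       # sensor - source vectors
      r3 <- rowSums(d^2)^1.5
      gain[, v, ] <- d / (4 * pi * r3)
    }
    gain <- gain / stats::median(sqrt(colSums(apply(gain, 2:3, identity)^2)))
  } else {
    gain <- with_seed(seed, array(stats::rnorm(n_channels * n_vox * 3),
                                  c(n_channels, n_vox, 3)))
  }
  if (reference == "average") {
    mu <- apply(gain, c(2, 3), mean)
    gain <- gain - aperm(array(mu, c(n_vox, 3, n_channels)), c(3, 1, 2))
  }
  labels <- synthetic_atlas(coords, unlabeled_frac = unlabeled_frac,
                            seed = seed)
  lead_field(gain, coords, grid_spacing, labels, pos)
}

# Gaussian amplitude envelope
gauss_env <- function(t, center, sd) exp(-(t - center)^2 / (2 * sd^2))

theta_freq <- 5.5   # band-center oscillation frequencies (Hz)
alpha_freq <- 10

#' Simulate one subject's epoched Nogo EEG
#'
#' Generates `n_nogo_per_condition` epochs per Nogo condition. Each planted
#' source voxel carries an ongoing band-center oscillation (theta 5.5 Hz,
#' alpha 10 Hz) whose amplitude is modulated, per trial, by the condition:
#' the amplitude envelope is `base_amp` plus a Gaussian bump at the
#' subject's peak latency whose height is `+/- effect_amplitude / 2`
#' depending on the condition and the band's effect sign. The shared
#' representational pattern modulates the per-voxel amplitudes around
#' `base_amp` with a broad envelope (see [ground_truth()]). Oscillation
#' phase is randomized per trial and voxel; white sensor noise of SD
#' `noise_sd` is added.
#'
#' @param design a [task_design()]; `n_nogo_per_condition` sets trial counts.
#' @param truth a [ground_truth()].
#' @param leadfield a [lead_field()].
#' @param noise_sd sensor noise SD (microvolts).
#' @param sfreq sampling rate (Hz).
#' @param epoch_window length-2 numeric (s), half-open epoch
#'   `[from, to)` relative to stimulus onset; must contain the effect
#'   envelopes (peak +/- 2 SD).
#' @param seed integer seed; everything (latencies, phases, noise) is
#'   deterministic given the seed.
#' @param base_amp ongoing oscillation amplitude at planted voxels (source
#'   units); must exceed `effect_amplitude / 2`.
#' @param amp_jitter trial-to-trial SD of the effect bump height.
#' @param subject_id identifier stored in the result.
#' @param response_rates named numeric, probability of a (false-alarm)
#'   response per condition; responded trials get an RT and are later
#'   excluded by [select_and_reject()]. Default: none.
#'
#' @return A [sensor_epochs()] with trials of both Nogo conditions
#'   interleaved.
#' @export
simulate_subject_eeg <- function(design, truth, leadfield,
                                 noise_sd = 10, sfreq = 256,
                                 epoch_window = c(-1, 1.75),
                                 seed = 1L, base_amp = 10,
                                 amp_jitter = 1,
                                 subject_id = "s01",
                                 response_rates = c(nogo_nonoverlap = 0,
                                                    nogo_overlap = 0)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(leadfield, "lead_field"))
  n_vox <- nrow(leadfield$grid_coords)
  all_vox <- c(truth$theta_effect_voxels, truth$alpha_effect_voxels,
               truth$shared_voxels)
  if (any(all_vox < 1 | all_vox > n_vox))
    stop("ground-truth voxel sets outside the lead-field grid")
  for (pk in c(truth$theta_peak_latency, truth$alpha_peak_latency))
    if (pk - 2 * truth$envelope_sd < epoch_window[1] ||
        pk + 2 * truth$envelope_sd > epoch_window[2])
      stop("epoch window shorter than the effect envelope")
  if (base_amp < truth$effect_amplitude / 2)
    warning("base_amp < effect_amplitude/2: amplitudes will be clipped at 0")

  times <- seq(epoch_window[1], epoch_window[2] - 1 / sfreq, by = 1 / sfreq)
  n_t <- length(times)
  n_ch <- dim(leadfield$gain)[1]
  n_per <- design$n_nogo_per_condition
  conds <- rep(c("nogo_nonoverlap", "nogo_overlap"), times = n_per)[
    order(rep(seq_len(n_per), 2))]          # interleaved
  n_tr <- length(conds)

  # fixed radial source orientations: identical across subjects
  orient <- leadfield$grid_coords
  nrm <- sqrt(rowSums(orient^2))
  zero <- nrm < 1e-9
  if (any(zero))
    orient[zero, ] <- matrix(c(0, 0, 1), sum(zero), 3, byrow = TRUE)
  orient <- orient / pmax(sqrt(rowSums(orient^2)), 1e-9)
  gain_vecs <- function(vox)  # channels x length(vox) fixed-orientation gains
    vapply(vox, function(v) as.numeric(leadfield$gain[, v, ] %*% orient[v, ]),
           numeric(n_ch))

  pats <- shared_patterns(truth)

  with_seed(seed, {
    # subject-specific effect latencies: alpha trails theta by a positive lag
    th_lat <- min(max(stats::rnorm(1, truth$theta_peak_latency,
                                   truth$latency_sd[1]),
                      epoch_window[1] + 2 * truth$envelope_sd), 1)
    gap_mu <- truth$alpha_peak_latency - truth$theta_peak_latency
    gap <- max(stats::rnorm(1, gap_mu, truth$latency_sd[2] / 3), 0.01)
    al_lat <- min(th_lat + gap, epoch_window[2] - 2 * truth$envelope_sd)
    subj_scale <- max(stats::rnorm(1, 1, 0.15), 0.3)

    cvec <- ifelse(conds == "nogo_overlap", +0.5, -0.5)
    data <- array(stats::rnorm(n_tr * n_ch * n_t, sd = noise_sd),
                  c(n_tr, n_ch, n_t))

    for (band in c("theta", "alpha")) {
      freq <- if (band == "theta") theta_freq else alpha_freq
      sgn <- if (band == "theta") truth$theta_effect_sign else truth$alpha_effect_sign
      lat <- if (band == "theta") th_lat else al_lat
      vox <- if (band == "theta") truth$theta_effect_voxels else truth$alpha_effect_voxels
      w <- rep(1 / sqrt(length(vox)), length(vox))
      env <- gauss_env(times, lat, truth$envelope_sd)
      shared_env <- gauss_env(times,
                              truth$shared_centers[if (band == "theta") 1 else 2],
                              truth$shared_env_sd)
      pat <- if (band == "theta") pats$theta else pats$alpha
      G_eff <- gain_vecs(vox)
      G_sh <- if (truth$shared_amplitude > 0) gain_vecs(truth$shared_voxels)
      k_sh <- length(truth$shared_voxels)
      for (tr in seq_len(n_tr)) {
        bump <- subj_scale *
          (sgn * truth$effect_amplitude * cvec[tr] + stats::rnorm(1, 0, amp_jitter))
        # k x time source amplitude envelopes; the effect blob is a locally
        # coherent patch: one oscillation phase per trial and band
        amp <- pmax(outer(w * base_amp, rep(1, n_t)) + outer(w * bump, env), 0)
        osc <- sin(outer(rep(stats::runif(1, 0, 2 * pi), length(vox)),
                         rep(1, n_t)) + rep(2 * pi * freq * times,
                                            each = length(vox)))
        data[tr, , ] <- data[tr, , ] + G_eff %*% (amp * osc)
        if (truth$shared_amplitude > 0) {
          s <- subj_scale * truth$shared_amplitude * cvec[tr]
          amp_s <- pmax(base_amp / sqrt(k_sh) +
                          outer(s * pat, shared_env), 0)
          osc_s <- sin(outer(stats::runif(k_sh, 0, 2 * pi), rep(1, n_t)) +
                         rep(2 * pi * freq * times, each = k_sh))
          data[tr, , ] <- data[tr, , ] + G_sh %*% (amp_s * osc_s)
        }
      }
    }

    rates <- response_rates[conds]
    rates[is.na(rates)] <- 0
    responded <- stats::runif(n_tr) < rates
    rt <- ifelse(responded, stats::runif(n_tr, 200, 1400), NA_real_)
    sensor_epochs(data, sfreq, times, leadfield$channel_positions,
                  conds, responded, rt, subject_id = subject_id)
  })
}

#' Simulate a multi-subject study
#'
#' Fans the master seed out to one deterministic child seed per subject and
#' calls [simulate_subject_eeg()] for each.
#'
#' @param n_subjects number of subjects.
#' @param design,truth,leadfield,noise_sd,sfreq,epoch_window,base_amp,amp_jitter,response_rates
#'   passed to [simulate_subject_eeg()].
#' @param seed master seed.
#'
#' @return A list of [sensor_epochs()], one per subject.
#' @export
simulate_group <- function(n_subjects, design, truth, leadfield,
                           noise_sd = 10, sfreq = 256,
                           epoch_window = c(-1, 1.75), seed = 1L,
                           base_amp = 10, amp_jitter = 1,
                           response_rates = c(nogo_nonoverlap = 0,
                                              nogo_overlap = 0)) {
  lapply(seq_len(n_subjects), function(i)
    simulate_subject_eeg(design, truth, leadfield, noise_sd = noise_sd,
                         sfreq = sfreq, epoch_window = epoch_window,
                         seed = seed_child(seed, i), base_amp = base_amp,
                         amp_jitter = amp_jitter,
                         subject_id = sprintf("s%02d", i),
                         response_rates = response_rates))
}
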