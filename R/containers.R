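#' Epoched multichannel sensor data
#'
#' Container for a single subject's epoched EEG: a trials x channels x time
#' amplitude array together with the sampling rate, the time axis relative to
#' stimulus onset, channel geometry and per-trial condition labels.
#'
#' @param data numeric array, trials x channels x time (microvolts).
#' @param sfreq sampling rate in Hz.
#' @param times numeric vector of time points (s, 0 = stimulus onset); must be
#'   uniform at spacing 1/sfreq and match `dim(data)[3]`.
#' @param channel_positions n_channels x 3 matrix of sensor coordinates (cm).
#' @param condition_labels character or factor, one label per trial.
#' @param responded logical per trial: TRUE if a (false-alarm) response
#'   occurred within the response window. Default all FALSE.
#' @param rt numeric per trial: response latency in ms, NA when no response.
#' @param subject_id identifier for the subject.
#'
#' @return An object of class `sensor_epochs`.
#' @export
sensor_epochs <- function(data, sfreq, times, channel_positions,
                          condition_labels, responded = NULL, rt = NULL,
                          subject_id = "s01") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  n_trials <- dim(data)[1]
  n_ch <- dim(data)[2]
  n_t <- dim(data)[3]
  if (length(times) != n_t)
    stop("`times` length must equal the third data dimension")
  dt <- diff(times)
  if (any(abs(dt - 1 / sfreq) > 1e-6))
    stop("`times` must be uniform at 1/sfreq")
  channel_positions <- as.matrix(channel_positions)
  if (nrow(channel_positions) != n_ch)
    stop("channel_positions must have one row per channel")
  condition_labels <- as.character(condition_labels)
  if (length(condition_labels) != n_trials)
    stop("one condition label per trial required")
  if (is.null(responded)) responded <- rep(FALSE, n_trials)
  if (is.null(rt)) rt <- rep(NA_real_, n_trials)
  stopifnot(length(responded) == n_trials, length(rt) == n_trials)
  structure(list(
    data = data, sfreq = sfreq, times = as.numeric(times),
    channel_positions = channel_positions,
    condition_labels = condition_labels,
    responded = as.logical(responded), rt = as.numeric(rt),
    subject_id = subject_id
  ), class = "sensor_epochs")
}

#' @export
print.sensor_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sensor_epochs> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
    x$subject_id, d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  time %.3f .. %.3f s; conditions: %s\n",
              min(x$times), max(x$times),
              paste(sprintf("%s(%d)", names(table(x$condition_labels)),
                            table(x$condition_labels)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sensor_epochs <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1]

#' Lead field (forward gain) container
#'
#' @param gain numeric array channels x voxels x 3 orientations: sensor
#'   amplitude produced by a unit dipole along each Cartesian axis.
#' @param grid_coords voxels x 3 matrix of voxel positions (cm).
#' @param grid_spacing lattice spacing (cm).
#' @param labels character per voxel: an anatomical label, or one of
#'   `"Unlabeled"` / `"Cerebellum"` which mark voxels for exclusion.
#' @param channel_positions n_channels x 3 matrix of sensor positions (cm).
#'
#' @return An object of class `lead_field`.
#' @export
lead_field <- function(gain, grid_coords, grid_spacing, labels,
                       channel_positions) {
  stopifnot(is.array(gain), length(dim(gain)) == 3, dim(gain)[3] == 3)
  grid_coords <- as.matrix(grid_coords)
  stopifnot(nrow(grid_coords) == dim(gain)[2],
            length(labels) == dim(gain)[2],
            all(is.finite(gain)))
  structure(list(
    gain = gain, grid_coords = grid_coords,
    grid_spacing = grid_spacing, labels = as.character(labels),
    channel_positions = as.matrix(channel_positions)
  ), class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d channels x %d voxels, spacing %g cm (%d excluded)\n",
              dim(x$gain)[1], dim(x$gain)[2], x$grid_spacing,
              sum(x$labels %in% c("Unlabeled", "Cerebellum"))))
  invisible(x)
}

#' Band-limited power time course
#'
#' Power of one frequency band as a function of time, per trial (or averaged)
#' and per location (channel or voxel).
#'
#' @param power numeric array trials x locations x time (or locations x time
#'   for a condition average, which is stored as 1 x locations x time).
#' @param times time axis (s).
#' @param band length-2 numeric, band edges in Hz.
#' @param level `"sensor"` or `"source"`.
#' @param n_trials_averaged number of trials behind an average (1 for
#'   single-trial data).
#'
#' @return An object of class `band_power_course`.
#' @export
band_power_course <- function(power, times, band, level = "sensor",
                              n_trials_averaged = 1L) {
  if (length(dim(power)) == 2)
    power <- array(power, c(1L, dim(power)))
  stopifnot(length(dim(power)) == 3, dim(power)[3] == length(times),
            length(band) == 2, band[1] <= band[2])
  structure(list(power = power, times = as.numeric(times),
                 band = as.numeric(band), level = level,
                 n_trials_averaged = n_trials_averaged),
            class = "band_power_course")
}

#' @export
print.band_power_course <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<band_power_course> %g-%g Hz (%s): %d trials x %d locations x %d samples\n",
              x$band[1], x$band[2], x$level, d[1], d[2], d[3]))
  invisible(x)
}
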