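# Offline preprocessing chain: IIR band-pass + notch filtering, resampling,
# average re-referencing, trial selection / artifact rejection, baseline
# correction. The canonical order is
# filter -> resample -> re-reference -> select/reject -> baseline,
# as applied by preprocess_subject(); each step logs itself on the object.

log_step <- function(epochs, msg) {
  epochs$log <- c(epochs$log, msg)
  epochs
}

apply_over_trials <- function(epochs, fun) {
  # fun maps a channels x time matrix to a channels x time matrix
  for (tr in seq_len(dim(epochs$data)[1]))
    epochs$data[tr, , ] <- fun(epochs$data[tr, , , drop = TRUE])
  epochs
}

#' Zero-phase band-pass and notch filtering
#'
#' Applies a 4th-order Butterworth band-pass and a Butterworth band-stop
#' around the notch frequency, both forward-backward (zero phase) so that
#' filtering cannot bias latency estimates.
#'
#' @param epochs a [sensor_epochs()].
#' @param low,high band-pass edges (Hz); `high` must be below Nyquist.
#' @param notch line frequency to suppress (Hz), or `NULL` to skip (e.g.
#'   when the notch lies outside the passband or above Nyquist).
#' @param notch_halfwidth half width of the stop band (Hz).
#'
#' @return The filtered `sensor_epochs`.
#' @export
bandpass_and_notch <- function(epochs, low = 0.5, high = 40, notch = 50,
                               notch_halfwidth = 5) {
  nyq <- epochs$sfreq / 2
  if (!(low < high)) stop("low must be below high")
  if (high >= nyq) stop("high edge at or above Nyquist (", nyq, " Hz)")
  bp <- signal::butter(4, c(low, high) / nyq, type = "pass")
  bs <- NULL
  if (!is.null(notch)) {
    if (notch + notch_halfwidth >= nyq)
      stop("notch band reaches Nyquist; pass notch = NULL to skip")
    bs <- signal::butter(3, c(notch - notch_halfwidth,
                              notch + notch_halfwidth) / nyq, type = "stop")
  }
  filt1 <- function(x) {
    y <- signal::filtfilt(bp, x)
    if (!is.null(bs)) y <- signal::filtfilt(bs, y)
    y
  }
  epochs <- apply_over_trials(epochs, function(m) t(apply(m, 1, filt1)))
  log_step(epochs, sprintf("bandpass %g-%g Hz (butter4, zero-phase)%s",
                           low, high,
                           if (is.null(notch)) "" else
                             sprintf(" + notch %g Hz", notch)))
}

#' Resample epochs to a lower rate
#'
#' Polyphase anti-aliased resampling of every trial and channel; the time
#' axis is rebuilt at the new rate starting from the first original sample.
#'
#' @param epochs a [sensor_epochs()].
#' @param target_sfreq new sampling rate (Hz), at most the current rate.
#'
#' @return The resampled `sensor_epochs`.
#' @export
resample_epochs <- function(epochs, target_sfreq) {
  if (target_sfreq == epochs$sfreq) return(epochs)
  if (target_sfreq > epochs$sfreq)
    stop("target rate above current rate; only downsampling is supported")
  ratio <- target_sfreq / epochs$sfreq
  fr <- as.integer(c(target_sfreq, epochs$sfreq) /
                     pracma_gcd(target_sfreq, epochs$sfreq))
  n_old <- dim(epochs$data)[3]
  n_new <- ceiling(n_old * fr[1] / fr[2])
  d <- dim(epochs$data)
  out <- array(0, c(d[1], d[2], n_new))
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      out[tr, ch, ] <- signal::resample(epochs$data[tr, ch, ], fr[1], fr[2])
  epochs$data <- out
  epochs$times <- epochs$times[1] + (seq_len(n_new) - 1) / target_sfreq
  epochs$sfreq <- target_sfreq
  log_step(epochs, sprintf("resampled to %g Hz", target_sfreq))
}

pracma_gcd <- function(a, b) {
  a <- round(a); b <- round(b)
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over channels, so that the channel mean
#' is zero at every sample. Idempotent.
#'
#' @param epochs a [sensor_epochs()] with at least two channels.
#' @return The re-referenced `sensor_epochs`.
#' @export
rereference_average <- function(epochs) {
  if (dim(epochs$data)[2] < 2)
    stop("average reference requires at least two channels")
  epochs <- apply_over_trials(epochs, function(m)
    sweep(m, 2, colMeans(m)))
  log_step(epochs, "average reference")
}

#' Artifact rejection policy
#'
#' @param amp_limit absolute amplitude limit (microvolts); samples beyond
#'   +/- `amp_limit` reject the trial.
#' @param flat_limit flat-signal limit: a trial is rejected when the
#'   peak-to-peak range within any sliding window of `flat_window` ms falls
#'   below `flat_limit` microvolts on any channel.
#' @param flat_window window length for the flatness rule (ms).
#' @return A `rejection_policy` list.
#' @export
rejection_policy <- function(amp_limit = 200, flat_limit = 0.5,
                             flat_window = 100) {
  stopifnot(amp_limit > flat_limit, flat_limit >= 0)
  structure(list(amp_limit = amp_limit, flat_limit = flat_limit,
                 flat_window = flat_window), class = "rejection_policy")
}

rolling_range_below <- function(m, w, limit) {
  # m: channels x time; TRUE if any channel has a full window of w samples
  # with max - min < limit
  n <- ncol(m)
  if (w < 2 || w > n || limit <= 0) return(FALSE)
  k <- n - w + 1L
  rmax <- rmin <- m[, seq_len(k), drop = FALSE]
  for (off in seq_len(w - 1L)) {
    shift <- m[, off + seq_len(k), drop = FALSE]
    rmax <- pmax(rmax, shift)
    rmin <- pmin(rmin, shift)
  }
  any(rmax - rmin < limit)
}

#' Select conditions and reject artifact trials
#'
#' Keeps only trials of the requested conditions with no response before
#' `response_cutoff` ms (correctly rejected Nogo trials), then drops trials
#' exceeding the amplitude limit anywhere or flat below `flat_limit` within
#' any `flat_window` ms window. Counts per rule are recorded in
#' `attr(result, "rejection_log")`.
#'
#' @param epochs a [sensor_epochs()].
#' @param policy a [rejection_policy()].
#' @param conditions character vector of condition labels to keep.
#' @param response_cutoff latency (ms) before which a response invalidates
#'   the trial.
#'
#' @return The reduced `sensor_epochs`; error if no trial survives.
#' @export
select_and_reject <- function(epochs, policy = rejection_policy(),
                              conditions = c("nogo_nonoverlap",
                                             "nogo_overlap"),
                              response_cutoff = 1500) {
  stopifnot(inherits(policy, "rejection_policy"))
  in_cond <- epochs$condition_labels %in% conditions
  no_resp <- !(epochs$responded & !is.na(epochs$rt) &
                 epochs$rt <= response_cutoff)
  keep <- in_cond & no_resp
  n_cond <- sum(!in_cond)
  n_resp <- sum(in_cond & !no_resp)
  w <- max(2L, round(policy$flat_window / 1000 * epochs$sfreq))
  amp_bad <- flat_bad <- logical(length(keep))
  for (tr in which(keep)) {
    m <- epochs$data[tr, , , drop = TRUE]
    amp_bad[tr] <- any(abs(m) > policy$amp_limit)
    if (!amp_bad[tr] && policy$flat_limit > 0)
      flat_bad[tr] <- rolling_range_below(m, w, policy$flat_limit)
  }
  keep <- keep & !amp_bad & !flat_bad
  if (!any(keep))
    stop("all trials rejected by selection/artifact rules")
  out <- epochs
  out$data <- epochs$data[keep, , , drop = FALSE]
  out$condition_labels <- epochs$condition_labels[keep]
  out$responded <- epochs$responded[keep]
  out$rt <- epochs$rt[keep]
  out <- log_step(out, sprintf(
    "select/reject: kept %d of %d (condition %d, response %d, amplitude %d, flat %d dropped)",
    sum(keep), length(keep), n_cond, n_resp, sum(amp_bad), sum(flat_bad)))
  attr(out, "rejection_log") <- list(
    n_in = length(keep), n_kept = sum(keep), dropped_condition = n_cond,
    dropped_response = n_resp, dropped_amplitude = sum(amp_bad),
    dropped_flat = sum(flat_bad))
  out
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window so that the mean over that window becomes exactly zero.
#'
#' @param epochs a [sensor_epochs()].
#' @param window length-2 numeric baseline window in ms relative to stimulus
#'   onset (default -200..0 ms); must lie within the epoch.
#'
#' @return The baseline-corrected `sensor_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  wsec <- window / 1000
  idx <- which(epochs$times >= wsec[1] & epochs$times <= wsec[2])
  if (length(idx) == 0 || wsec[1] < min(epochs$times) ||
      wsec[2] > max(epochs$times) + 1e-9)
    stop("baseline window outside the epoch")
  epochs <- apply_over_trials(epochs, function(m)
    m - rowMeans(m[, idx, drop = FALSE]))
  log_step(epochs, sprintf("baseline corrected (%g..%g ms)",
                           window[1], window[2]))
}

#' Run the standard preprocessing chain
#'
#' Fixed order: band-pass/notch filter, optional resampling, average
#' re-reference, condition selection with artifact rejection, baseline
#' correction. Every step is logged on the returned object (`$log`).
#'
#' @param epochs a [sensor_epochs()].
#' @param low,high,notch filter parameters, see [bandpass_and_notch()].
#' @param target_sfreq resampling target (Hz) or `NULL` to keep the rate.
#' @param policy a [rejection_policy()].
#' @param conditions condition labels to retain.
#' @param baseline_window baseline window (ms).
#'
#' @return The preprocessed `sensor_epochs`.
#' @export
preprocess_subject <- function(epochs, low = 0.5, high = 40, notch = 50,
                               target_sfreq = NULL,
                               policy = rejection_policy(),
                               conditions = c("nogo_nonoverlap",
                                              "nogo_overlap"),
                               baseline_window = c(-200, 0)) {
  if (!is.null(notch) && notch + 5 >= epochs$sfreq / 2) notch <- NULL
  epochs <- bandpass_and_notch(epochs, low, high, notch)
  if (!is.null(target_sfreq) && target_sfreq != epochs$sfreq)
    epochs <- resample_epochs(epochs, target_sfreq)
  epochs <- rereference_average(epochs)
  epochs <- select_and_reject(epochs, policy, conditions)
  baseline_correct(epochs, baseline_window)
}
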