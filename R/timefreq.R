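# Morlet wavelet time-frequency decomposition and band-power utilities.
#
# The wavelet has a fixed number of cycles m ("Morlet parameter", default 5),
# so its temporal standard deviation is sigma_t = m / (2 pi f) and its
# spectral standard deviation sigma_f = f / m. Samples closer than
# 3 sigma_t to either epoch edge are contaminated by the wavelet support and
# are set to NA ("invalid").

#' Complex Morlet wavelet
#'
#' @param freq center frequency (Hz).
#' @param sfreq sampling rate (Hz).
#' @param width number of cycles m; temporal SD is `m / (2 pi freq)`.
#' @return Complex vector of odd length `2 * ceiling(3 sigma_t sfreq) + 1`,
#'   normalized to unit energy.
#' @export
morlet_wavelet <- function(freq, sfreq, width = 5) {
  sigma_t <- width / (2 * pi * freq)
  h <- ceiling(3 * sigma_t * sfreq)
  t <- (-h:h) / sfreq
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet time-frequency decomposition
#'
#' Convolves every trial and location with complex Morlet wavelets and
#' returns squared magnitudes (power). Edge samples where the wavelet
#' extends beyond the epoch are NA. Accepts a [sensor_epochs()] or a plain
#' trials x locations x time array (then `times`/`sfreq` are required).
#'
#' @param x a `sensor_epochs` or a 3-D numeric array.
#' @param frequencies numeric vector of center frequencies (Hz), strictly
#'   increasing, all below Nyquist.
#' @param width Morlet parameter (cycles).
#' @param decim keep every `decim`-th time sample of the power (the
#'   convolution itself runs at full rate).
#' @param times,sfreq time axis and rate when `x` is a plain array.
#'
#' @return A `tfr` object: `power` (trials x locations x frequencies x
#'   time), `times`, `frequencies`, `width`, `sfreq`.
#' @export
morlet_tfr <- function(x, frequencies, width = 5, decim = 1L,
                       times = NULL, sfreq = NULL) {
  if (inherits(x, "sensor_epochs")) {
    data <- x$data; times <- x$times; sfreq <- x$sfreq
  } else {
    data <- x
    stopifnot(!is.null(times), !is.null(sfreq))
  }
  stopifnot(length(dim(data)) == 3, !is.unsorted(frequencies, strictly = TRUE))
  if (max(frequencies) >= sfreq / 2)
    stop("frequency at or above Nyquist")
  n_tr <- dim(data)[1]; n_loc <- dim(data)[2]; n_t <- dim(data)[3]
  sigma_max <- width / (2 * pi * min(frequencies))
  if (6 * sigma_max * sfreq > n_t)
    stop("lowest frequency not resolvable within the epoch length")

  # columns = (trial, location) series
  X <- matrix(aperm(data, c(3, 1, 2)), nrow = n_t)
  keep <- seq(1, n_t, by = decim)
  out <- array(NA_real_, c(n_tr, n_loc, length(frequencies), length(keep)))
  h_max <- ceiling(3 * sigma_max * sfreq)
  nfft <- stats::nextn(n_t + 2 * h_max + 1, 2)

  chunk <- max(1L, floor(4e6 / nfft))       # bound fft memory
  starts <- seq(1, ncol(X), by = chunk)
  for (s in starts) {
    cols <- s:min(s + chunk - 1, ncol(X))
    Xp <- rbind(X[, cols, drop = FALSE],
                matrix(0, nfft - n_t, length(cols)))
    FX <- stats::mvfft(Xp)
    for (fi in seq_along(frequencies)) {
      wav <- morlet_wavelet(frequencies[fi], sfreq, width)
      h <- (length(wav) - 1L) / 2L
      fw <- stats::fft(c(wav, rep(0, nfft - length(wav))))
      conv <- stats::mvfft(FX * fw, inverse = TRUE) / nfft
      # center of the wavelet aligned with each sample
      pw <- Mod(conv[(h + 1):(h + n_t), , drop = FALSE])^2
      pw[c(seq_len(min(h, n_t)),
           seq(max(1, n_t - h + 1), n_t)), ] <- NA_real_
      pw_dec <- pw[keep, , drop = FALSE]
      if (length(cols) == ncol(X)) {        # single chunk: block assign
        out[, , fi, ] <- aperm(array(pw_dec, c(length(keep), n_tr, n_loc)),
                               c(2, 3, 1))
      } else {
        out_idx <- arrayInd(cols, c(n_tr, n_loc))
        for (j in seq_along(cols))
          out[out_idx[j, 1], out_idx[j, 2], fi, ] <- pw_dec[, j]
      }
    }
  }
  structure(list(power = out, times = times[keep],
                 frequencies = as.numeric(frequencies),
                 width = width, sfreq = sfreq),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr> %d trials x %d locations x %d frequencies (%g-%g Hz) x %d samples, m = %g\n",
              d[1], d[2], d[3], min(x$frequencies), max(x$frequencies),
              d[4], x$width))
  invisible(x)
}

#' Average TFR power over a frequency band
#'
#' Means over the frequency bins whose centers lie inside the band,
#' inclusive at both edges. NA (edge-contaminated) samples propagate.
#'
#' @param tfr a [morlet_tfr()] result.
#' @param band length-2 numeric band edges (Hz).
#' @param level stored on the result (`"sensor"` or `"source"`).
#' @return A [band_power_course()].
#' @export
band_power <- function(tfr, band, level = "sensor") {
  stopifnot(inherits(tfr, "tfr"), length(band) == 2)
  sel <- which(tfr$frequencies >= band[1] & tfr$frequencies <= band[2])
  if (length(sel) == 0)
    stop("no frequency bins inside [", band[1], ", ", band[2], "] Hz")
  p <- tfr$power[, , sel, , drop = FALSE]
  d <- dim(p)
  # mean over the band's bins (dim 3), vectorized
  pm <- colMeans(matrix(aperm(p, c(3, 1, 2, 4)), nrow = d[3]))
  pw <- array(pm, d[c(1, 2, 4)])
  band_power_course(pw, tfr$times, band, level = level)
}

#' Average a band-power course over the trials of one condition
#'
#' @param course a [band_power_course()] with single-trial power.
#' @param labels per-trial condition labels.
#' @param condition the condition to average.
#' @return A [band_power_course()] with one (averaged) trial; the number of
#'   trials averaged is recorded in `n_trials_averaged`.
#' @export
condition_average <- function(course, labels, condition) {
  idx <- which(labels == condition)
  if (length(idx) == 0) stop("no trials in condition ", condition)
  avg <- apply(course$power[idx, , , drop = FALSE], c(2, 3), mean)
  band_power_course(avg, course$times, course$band, level = course$level,
                    n_trials_averaged = length(idx))
}

#' Latency of the largest local maximum of a time course
#'
#' Searches the window for interior local maxima (greater than the previous
#' sample, at least as large as the next) of a single time course, ignoring
#' NA (edge-invalid) samples, and returns the time of the largest one. When
#' no interior local maximum exists the window argmax is returned with
#' `boundary = TRUE`; an all-constant course is flagged `degenerate`.
#'
#' @param x numeric vector (one time course) or a [band_power_course()] with
#'   a single location and trial.
#' @param times time axis (s); taken from the course if `x` is one.
#' @param window length-2 search window (s), default 0..1.
#'
#' @return List with `time` (s), `value`, `boundary`, `degenerate`.
#' @export
peak_latency <- function(x, times = NULL, window = c(0, 1)) {
  if (inherits(x, "band_power_course")) {
    stopifnot(dim(x$power)[1] == 1, dim(x$power)[2] == 1)
    times <- x$times
    x <- as.numeric(x$power[1, 1, ])
  }
  stopifnot(length(x) == length(times))
  sel <- which(times >= window[1] & times <= window[2] & !is.na(x))
  if (length(sel) < 2) stop("search window contains fewer than two valid samples")
  xs <- x[sel]; ts <- times[sel]
  if (max(xs) - min(xs) < .Machine$double.eps * 100)
    return(list(time = ts[1], value = xs[1], boundary = TRUE,
                degenerate = TRUE))
  n <- length(xs)
  interior <- which(xs[2:(n - 1)] > xs[1:(n - 2)] &
                      xs[2:(n - 1)] >= xs[3:n]) + 1L
  if (length(interior) > 0) {
    best <- interior[which.max(xs[interior])]
    list(time = ts[best], value = xs[best], boundary = FALSE,
         degenerate = FALSE)
  } else {
    best <- which.max(xs)
    list(time = ts[best], value = xs[best], boundary = TRUE,
         degenerate = FALSE)
  }
}

#' Per-subject peak latencies of the condition difference
#'
#' For each subject, averages the overlapping-minus-non-overlapping band
#' power difference over locations (the sensor cluster), multiplies by the
#' band's effect sign so the planted effect is a positive bump, and locates
#' its largest local maximum in the window.
#'
#' @param courses list over subjects of single-trial [band_power_course()].
#' @param labels_list per-subject condition label vectors.
#' @param sign +1 (theta: overlap > non-overlap) or -1 (alpha).
#' @param window search window (s).
#' @param locations optional subset of location indices to average over.
#' @return Numeric vector of per-subject latencies (s).
#' @export
subject_peak_latencies <- function(courses, labels_list, sign = +1,
                                   window = c(0, 1), locations = NULL) {
  vapply(seq_along(courses), function(i) {
    co <- courses[[i]]
    ov <- condition_average(co, labels_list[[i]], "nogo_overlap")
    no <- condition_average(co, labels_list[[i]], "nogo_nonoverlap")
    d <- sign * (ov$power[1, , ] - no$power[1, , ])
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    if (!is.null(locations)) d <- d[locations, , drop = FALSE]
    peak_latency(colMeans(d), co$times, window)$time
  }, numeric(1))
}
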