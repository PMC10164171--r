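# LCMV beamforming: spatial filters from the sensor covariance of the
# time-locked average, projection of single trials to source space, and
# voxel bookkeeping (atlas labels, exclusions).

#' Sensor covariance of the time-locked average
#'
#' Averages the epochs over trials, restricts to the window, and returns the
#' channel covariance across time samples. After average referencing the
#' matrix is rank-deficient by one; the rank is reported as an attribute.
#'
#' @param epochs a [sensor_epochs()].
#' @param window length-2 time window (s) within the epoch; default the
#'   whole epoch.
#' @param trials optional trial subset (e.g. one condition).
#' @return Channels x channels covariance matrix with attribute `"rank"`.
#' @export
covariance_from_average <- function(epochs, window = NULL, trials = NULL) {
  if (is.null(trials)) trials <- seq_len(dim(epochs$data)[1])
  avg <- apply(epochs$data[trials, , , drop = FALSE], c(2, 3), mean)
  if (!is.null(window)) {
    if (window[1] < min(epochs$times) - 1e-9 ||
        window[2] > max(epochs$times) + 1e-9)
      stop("covariance window outside the epoch")
    avg <- avg[, epochs$times >= window[1] & epochs$times <= window[2],
               drop = FALSE]
  }
  centered <- avg - rowMeans(avg)
  C <- tcrossprod(centered) / (ncol(avg) - 1)
  attr(C, "rank") <- qr(C)$rank
  C
}

#' LCMV spatial filters
#'
#' Unit-gain minimum-variance filters per voxel. The covariance is
#' regularized as `C_r = C + reg_fraction * mean(diag(C)) * I`. Per voxel,
#' the 3x3 source covariance `(L' C_r^-1 L)^-1` is formed; the scalar
#' (max-power) orientation is its principal eigenvector `u`, and the weights
#' are `w = C_r^-1 l / (l' C_r^-1 l)` with `l = L u`, which satisfies the
#' unit-gain constraint `w'l = 1`. Voxels with a numerically singular
#' source covariance are flagged and excluded downstream.
#'
#' @param leadfield a [lead_field()].
#' @param covariance channel covariance, e.g. [covariance_from_average()].
#' @param reg_fraction diagonal-loading fraction of the mean sensor
#'   variance.
#' @return A `spatial_filter`: `weights` (voxels x channels),
#'   `orientation` (voxels x 3), `ok` (logical per voxel),
#'   `regularization`.
#' @export
lcmv_filters <- function(leadfield, covariance, reg_fraction = 0.05) {
  n_ch <- dim(leadfield$gain)[1]
  n_vox <- dim(leadfield$gain)[2]
  stopifnot(nrow(covariance) == n_ch)
  Cr <- covariance + reg_fraction * mean(diag(covariance)) * diag(n_ch)
  Ci <- tryCatch(solve(Cr), error = function(e)
    stop("covariance not invertible after regularization: ", conditionMessage(e)))
  W <- matrix(0, n_vox, n_ch)
  U <- matrix(0, n_vox, 3)
  ok <- rep(TRUE, n_vox)
  for (v in seq_len(n_vox)) {
    L <- leadfield$gain[, v, ]
    M <- crossprod(L, Ci %*% L)
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv) || !all(is.finite(Minv))) { ok[v] <- FALSE; next }
    u <- eigen(Minv, symmetric = TRUE)$vectors[, 1]
    l <- as.numeric(L %*% u)
    cil <- Ci %*% l
    denom <- as.numeric(crossprod(l, cil))
    if (!is.finite(denom) || abs(denom) < 1e-300) { ok[v] <- FALSE; next }
    W[v, ] <- cil / denom
    U[v, ] <- u
  }
  structure(list(weights = W, orientation = U, ok = ok,
                 regularization = reg_fraction), class = "spatial_filter")
}

#' Project epochs through spatial filters
#'
#' Linear projection of every trial: `source[tr, , ] = W %*% data[tr, , ]`.
#'
#' @param filters a [lcmv_filters()] result.
#' @param epochs a [sensor_epochs()] with matching channels.
#' @return A `source_epochs` list: `data` (trials x voxels x time),
#'   `times`, `sfreq`, `condition_labels`, `ok` voxel flags.
#' @export
apply_filters <- function(filters, epochs) {
  if (ncol(filters$weights) != dim(epochs$data)[2])
    stop("channel count of filters and epochs differ")
  d <- dim(epochs$data)
  out <- array(0, c(d[1], nrow(filters$weights), d[3]))
  for (tr in seq_len(d[1]))
    out[tr, , ] <- filters$weights %*% epochs$data[tr, , , drop = TRUE]
  structure(list(data = out, times = epochs$times, sfreq = epochs$sfreq,
                 condition_labels = epochs$condition_labels,
                 ok = filters$ok, subject_id = epochs$subject_id),
            class = "source_epochs")
}

#' @export
print.source_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<source_epochs> %d trials x %d voxels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  invisible(x)
}

#' Voxels retained for source analysis
#'
#' Indices of voxels with an anatomical label, excluding unlabeled and
#' cerebellar voxels.
#'
#' @param leadfield a [lead_field()].
#' @return Integer vector of included voxel indices (error when empty).
#' @export
select_voxels <- function(leadfield) {
  inc <- which(!(leadfield$labels %in% c("Unlabeled", "Cerebellum")))
  if (length(inc) == 0) stop("no labeled, non-cerebellar voxels to include")
  inc
}
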