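# Behavioral and brain-behavior statistics: normality screening, Wilcoxon
# signed-rank tests with Rosenthal effect sizes, the binding effect, and
# backward-elimination multiple regression with diagnostics.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the standard test, with the domain check made
#' explicit (3 <= n <= 5000).
#'
#' @param sample numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(sample) {
  sample <- sample[is.finite(sample)]
  if (length(sample) < 3 || length(sample) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(sample)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped; ranks of the absolute differences use
#' midranks for ties. The p-value is exact (signed-rank distribution) for
#' tie-free data with n <= 25 and otherwise uses the normal approximation
#' with tie-corrected variance. The normal deviate follows the SPSS
#' convention, `z = (min(W+, W-) - n(n+1)/4) / sigma` without continuity
#' correction, so z is never positive and matches published effect sizes
#' computed as `r = z / sqrt(n)` (Rosenthal).
#'
#' @param a,b paired numeric vectors.
#' @return A `paired_test_result`: `statistic` (W+, rank sum of positive
#'   differences), `z`, `p`, `r` (effect size over the n retained pairs),
#'   `n` (pairs after dropping zeros), `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  wminus <- sum(r[d < 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  wmin <- min(wplus, wminus)
  # SPSS convention: Z from the smaller rank sum, no continuity correction
  z <- if (sigma > 0) (wmin - mu) / sigma else 0
  z <- min(z, 0)
  has_ties <- any(duplicated(abs(d)))
  if (!has_ties && n <= 25) {
    p <- min(1, 2 * stats::psignrank(wmin, n))
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal"
  }
  structure(list(statistic = wplus, z = z, p = p,
                 r = effect_size_r(z, n), n = n, method = method),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank (%s): W+ = %g, Z = %.2f, p = %.4g, r = %.3f (n = %d)\n",
              x$method, x$statistic, x$z, x$p, x$r, x$n))
  invisible(x)
}

#' Rosenthal effect size r
#'
#' `r = z / sqrt(n)` for a rank test's normal deviate over n pairs.
#'
#' @param z standard normal deviate of the test.
#' @param n number of pairs.
#' @return Effect size r in `[-1, 1]` for |z| <= sqrt(n).
#' @export
effect_size_r <- function(z, n) {
  stopifnot(n >= 1)
  z / sqrt(n)
}

#' Binding effect
#'
#' The overlapping-minus-non-overlapping condition difference; positive
#' values mean a larger measure under feature overlap (e.g. the excess
#' Nogo false-alarm rate).
#'
#' @param overlapping,non_overlapping numeric values in the same units.
#' @return `overlapping - non_overlapping`.
#' @export
binding_effect <- function(overlapping, non_overlapping) {
  overlapping - non_overlapping
}

vif_values <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  vapply(seq_len(ncol(X)), function(j) {
    # a perfect fit here is exactly the collinear case being detected
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

durbin_watson <- function(residuals) {
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Backward-elimination multiple linear regression
#'
#' Starts from the full model and iteratively removes the predictor whose
#' removal least harms the fit, judged by the partial F-test of the
#' R-squared change (for a single predictor this equals its coefficient
#' t-test). Elimination stops when removing any remaining predictor would
#' change R-squared significantly at `removal_p`. Coefficients are
#' reported standardized (both y and X z-scored); diagnostics include the
#' adjusted R-squared, the overall F statistic, the Durbin-Watson
#' statistic of the residuals, the variance inflation factors at each step
#' (maximum logged) and the extreme standardized residuals.
#'
#' @param y numeric response (e.g. per-subject binding effects).
#' @param X numeric matrix or data.frame of predictors (e.g. per-subject
#'   cluster mean AUCs); must be full rank.
#' @param removal_p stopping threshold (default 0.10, the SPSS default).
#' @return A `regression_result`: `retained` (names), `beta`
#'   (standardized), `p` per retained coefficient, `adjusted_r2`, `f_stat`,
#'   `df`, `durbin_watson`, `vif`, `max_vif_trace`, `std_residual_range`,
#'   `steps` (elimination trace).
#' @export
backward_elimination <- function(y, X, removal_p = 0.10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (n <= ncol(X) + 1)
    stop("need more subjects than predictors + 1")
  v0 <- vif_values(X)
  if (any(!is.finite(v0)))
    stop("collinear predictors (infinite VIF): ",
         paste(names(v0)[!is.finite(v0)], collapse = ", "))
  ys <- as.numeric(scale(y))
  Xs <- scale(X)
  keep <- colnames(X)
  steps <- list()
  max_vif_trace <- numeric(0)
  repeat {
    df <- data.frame(y = ys, Xs[, keep, drop = FALSE])
    fit <- stats::lm(y ~ ., data = df)
    coefs <- summary(fit)$coefficients
    pvals <- coefs[-1, 4]
    names(pvals) <- keep
    max_vif_trace <- c(max_vif_trace,
                       max(vif_values(Xs[, keep, drop = FALSE])))
    worst <- which.max(pvals)
    steps[[length(steps) + 1L]] <- list(predictors = keep, p = pvals)
    if (length(keep) == 0 || pvals[worst] < removal_p) break
    keep <- setdiff(keep, names(pvals)[worst])
    if (length(keep) == 0) {
      fit <- stats::lm(y ~ 1, data = data.frame(y = ys))
      break
    }
  }
  sm <- summary(fit)
  res <- stats::residuals(fit)
  std_res <- res / stats::sd(res)
  fstat <- if (!is.null(sm$fstatistic)) sm$fstatistic else
    c(value = NA_real_, numdf = 0, dendf = n - 1)
  coefs <- sm$coefficients
  beta <- if (length(keep)) coefs[-1, 1] else numeric(0)
  pv <- if (length(keep)) coefs[-1, 4] else numeric(0)
  names(beta) <- names(pv) <- keep
  structure(list(
    retained = keep, beta = beta, p = pv,
    adjusted_r2 = sm$adj.r.squared,
    f_stat = unname(fstat[1]), df = unname(fstat[2:3]),
    durbin_watson = durbin_watson(res),
    vif = if (length(keep) > 1) vif_values(Xs[, keep, drop = FALSE])
          else stats::setNames(rep(1, length(keep)), keep),
    max_vif_trace = max_vif_trace,
    std_residual_range = range(std_res),
    steps = steps, removal_p = removal_p),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Backward elimination (removal p >= %g): %d predictor(s) retained\n",
              x$removal_p, length(x$retained)))
  if (length(x$retained))
    for (nm in x$retained)
      cat(sprintf("  %s: beta = %.3f, p = %.4g\n", nm, x$beta[nm], x$p[nm]))
  cat(sprintf("  adjusted R2 = %.3f, F(%g,%g) = %.2f, Durbin-Watson = %.2f, max VIF = %.2f\n",
              x$adjusted_r2, x$df[1], x$df[2], x$f_stat,
              x$durbin_watson, max(x$max_vif_trace)))
  invisible(x)
}
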