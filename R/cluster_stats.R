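# Cluster-based permutation testing over location x time domains.
#
# Element statistics (paired t or Wilcoxon signed rank against a reference)
# are thresholded at alpha_element; supra-threshold elements of equal sign
# are joined into clusters over the spatial adjacency graph and temporal
# contiguity; the cluster statistic is the sum of element statistics; its
# Monte-Carlo p-value comes from the permutation distribution of the
# maximal cluster statistic under subject-level sign flips (paired design),
# with positive and negative clusters searched separately and a two-tailed
# correction (p doubled, capped at 1).

#' Channel adjacency from sensor positions
#'
#' Distance-threshold neighborhoods: two channels are neighbors when their
#' Euclidean distance is at most `max_dist` (default `factor` times the
#' median nearest-neighbor distance of the montage). Symmetric, no
#' self-neighbors.
#'
#' @param positions n x 3 sensor coordinates.
#' @param max_dist absolute neighborhood radius, or `NULL` to derive it.
#' @param factor multiplier on the median nearest-neighbor distance.
#' @return List of integer neighbor vectors, one per channel.
#' @export
channel_adjacency <- function(positions, max_dist = NULL, factor = 1.5) {
  D <- as.matrix(stats::dist(positions))
  if (is.null(max_dist)) {
    diag(D) <- Inf
    max_dist <- factor * stats::median(apply(D, 1, min))
    diag(D) <- 0
  }
  lapply(seq_len(nrow(D)), function(i)
    setdiff(which(D[i, ] <= max_dist & D[i, ] > 0), i))
}

#' Voxel adjacency on a regular grid (6-connectivity)
#'
#' @param coords n x 3 voxel coordinates on a regular lattice.
#' @param spacing lattice spacing; neighbors are exactly one spacing apart.
#' @return List of integer neighbor vectors.
#' @export
grid_adjacency <- function(coords, spacing) {
  D <- as.matrix(stats::dist(coords))
  lapply(seq_len(nrow(D)), function(i)
    which(abs(D[i, ] - spacing) < 1e-6 * spacing))
}

#' Chain adjacency over an ordered axis
#'
#' Neighbors are the immediate predecessor and successor; used to give the
#' train-time axis of a generalization matrix temporal contiguity.
#'
#' @param n number of ordered locations.
#' @return List of neighbor index vectors.
#' @export
chain_adjacency <- function(n) {
  lapply(seq_len(n), function(i) intersect(c(i - 1L, i + 1L), seq_len(n)))
}

#' Paired t statistics per element
#'
#' @param data_a,data_b subjects x elements matrices (or subjects x loc x
#'   time arrays), paired by row.
#' @return List with `t` and two-sided `p`, shaped like one subject's data.
#'   Zero-variance nonzero differences give infinite t (p = 0), treated as
#'   maximal statistics downstream.
#' @export
element_stats_paired_t <- function(data_a, data_b) {
  d <- data_a - data_b
  dm <- if (length(dim(d)) > 2) matrix(d, nrow = dim(d)[1]) else as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("paired t needs at least 2 subjects")
  m <- colMeans(dm)
  v <- (colSums(dm^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  tval <- ifelse(v == 0 & m == 0, 0,
                 ifelse(v == 0, sign(m) * Inf, m / sqrt(v / n)))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  shape_out <- function(x) if (length(dim(d)) > 2)
    array(x, dim(d)[-1]) else x
  list(t = shape_out(tval), p = shape_out(p), df = n - 1)
}

# signed-rank statistic S = sum(sign(d) * rank(|d|)) per column, with the
# element-wise threshold |S| >= crit corresponding to P(|S| >= crit) <= alpha
signed_rank_matrix <- function(dm) {
  apply(dm, 2, function(d) {
    s <- sign(d)
    r <- rank(abs(d))
    r[s == 0] <- 0                         # zero differences drop out
    s * r
  })
}

# exact two-sided p for S = 2*Wplus - n(n+1)/2 (tie-free); NA on ties/zeros
signed_rank_p_exact <- function(S, n) {
  wplus <- (S + n * (n + 1) / 2) / 2
  lo <- pmin(wplus, n * (n + 1) / 2 - wplus)
  pmin(1, 2 * stats::psignrank(lo, n))
}

#' Wilcoxon signed-rank statistics per element against a reference value
#'
#' The element statistic is the signed rank sum
#' `S = sum(sign(x - null) * rank(|x - null|))` over subjects, zero
#' differences dropped. Two-sided p-values are exact (signed-rank
#' distribution) for tie-free columns with n <= 25, otherwise a normal
#' approximation with tie correction is used.
#'
#' @param data subjects x elements matrix (or subjects x loc x time array).
#' @param null_value reference value (e.g. 0.5 for AUC against chance).
#' @return List with `stat` (signed rank sums) and two-sided `p`.
#' @export
element_stats_wilcoxon_vs <- function(data, null_value = 0.5) {
  dm <- if (length(dim(data)) > 2)
    matrix(data, nrow = dim(data)[1]) else as.matrix(data)
  n_subj <- nrow(dm)
  if (n_subj < 5) stop("Wilcoxon element statistics need >= 5 subjects")
  d <- sweep(dm, 2, rep(null_value, length.out = ncol(dm)), "-")
  S <- colSums(signed_rank_matrix(d))
  p <- vapply(seq_len(ncol(d)), function(j) {
    dj <- d[, j]
    nz <- dj[dj != 0]
    n <- length(nz)
    if (n == 0) return(1)
    ties <- any(duplicated(abs(nz)))
    if (!ties && n <= 25) {
      signed_rank_p_exact(sum(sign(nz) * rank(abs(nz))), n)
    } else {
      r <- rank(abs(nz))
      s <- sum(sign(nz) * r)
      sigma <- sqrt(sum(r^2))
      z <- (abs(s) - 0.5) / sigma          # continuity-corrected
      min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }, numeric(1))
  shape_out <- function(x) if (length(dim(data)) > 2)
    array(x, dim(data)[-1]) else x
  list(stat = shape_out(S), p = shape_out(p))
}

# connected components of supra-threshold elements over the adjacency x
# temporal-contiguity graph; supra is an n_loc x n_t logical matrix
supra_components <- function(supra, adjacency) {
  n_loc <- nrow(supra); n_t <- ncol(supra)
  comp <- matrix(0L, n_loc, n_t)
  next_id <- 0L
  idx <- which(supra)
  for (start in idx) {
    if (comp[start] != 0L) next
    next_id <- next_id + 1L
    stack <- start
    comp[start] <- next_id
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      l <- ((cur - 1L) %% n_loc) + 1L
      t <- ((cur - 1L) %/% n_loc) + 1L
      nb <- adjacency[[l]] + (t - 1L) * n_loc
      if (t > 1L) nb <- c(nb, cur - n_loc)
      if (t < n_t) nb <- c(nb, cur + n_loc)
      nb <- nb[supra[nb] & comp[nb] == 0L]
      comp[nb] <- next_id
      stack <- c(stack, nb)
    }
  }
  comp
}

# number of distinct adjacent channel pairs co-significant at the best time
max_adjacent_pairs <- function(members_lt, adjacency) {
  # members_lt: matrix with columns (loc, time)
  best <- 0L
  for (t in unique(members_lt[, 2])) {
    locs <- members_lt[members_lt[, 2] == t, 1]
    if (length(locs) < 2) next
    pairs <- 0L
    for (l in locs)
      pairs <- pairs + sum(adjacency[[l]] %in% locs & adjacency[[l]] > l)
    best <- max(best, pairs)
  }
  best
}

#' Form candidate clusters from thresholded element statistics
#'
#' Connected components of supra-threshold (p < `alpha_element`) elements of
#' equal sign, over the spatial adjacency graph crossed with temporal
#' contiguity. Components that never contain at least `min_neighbor_pairs`
#' distinct adjacent location pairs at a single time sample are discarded
#' (set `min_neighbor_pairs = 0` for voxel or time-only domains). The
#' cluster statistic is the sum of its element statistics.
#'
#' @param stat,p numeric matrices locations x time (a vector is treated as
#'   one location over time).
#' @param alpha_element element-wise threshold.
#' @param adjacency list of neighbor index vectors per location (from
#'   [channel_adjacency()] or [grid_adjacency()]); `NULL` for a single
#'   location or pure time domain.
#' @param min_neighbor_pairs minimum adjacent location pairs required.
#' @return List of clusters: `members` (two-column matrix: location, time),
#'   `stat_sum`, `sign`.
#' @export
form_clusters <- function(stat, p, alpha_element = 0.05, adjacency = NULL,
                          min_neighbor_pairs = 0L) {
  if (is.null(dim(stat))) { stat <- matrix(stat, nrow = 1); p <- matrix(p, nrow = 1) }
  n_loc <- nrow(stat)
  if (is.null(adjacency)) adjacency <- rep(list(integer(0)), n_loc)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- !is.na(p) & p < alpha_element & sign(stat) == sgn
    if (!any(supra)) next
    comp <- supra_components(supra, adjacency)
    for (id in seq_len(max(comp))) {
      members <- which(comp == id, arr.ind = TRUE)
      colnames(members) <- c("loc", "time")
      if (min_neighbor_pairs > 0 &&
          max_adjacent_pairs(members, adjacency) < min_neighbor_pairs)
        next
      sel <- comp == id
      ssum <- sum(stat[sel][is.finite(stat[sel])]) +
        sum(sel & !is.finite(stat)) * sgn * .Machine$double.xmax^0.25
      out[[length(out) + 1L]] <-
        list(members = members, stat_sum = ssum, sign = sgn)
    }
  }
  out
}

max_cluster_stats <- function(clusters) {
  pos <- vapply(clusters, function(cl) if (cl$sign > 0) cl$stat_sum else 0,
                numeric(1))
  neg <- vapply(clusters, function(cl) if (cl$sign < 0) -cl$stat_sum else 0,
                numeric(1))
  c(pos = if (length(pos)) max(pos, 0) else 0,
    neg = if (length(neg)) max(neg, 0) else 0)
}

#' Cluster-based permutation test (paired or against a reference)
#'
#' Computes observed clusters and their Monte-Carlo p-values under
#' subject-level sign flips. Supply either `data_a` and `data_b` (paired
#' condition arrays, element statistic: paired t) or `data_a` and
#' `null_value` (e.g. AUC maps against 0.5, element statistic: Wilcoxon
#' signed rank). For each observed cluster,
#' `p = 2 * (1 + #\{permutation max >= observed\}) / (n_permutations + 1)`,
#' using the permutation distribution of the maximal same-sign cluster
#' statistic, capped at 1 (separate positive/negative searches with the
#' two-tailed floor `2 / (n_permutations + 1)`).
#'
#' @param data_a subjects x locations x time array (or subjects x elements
#'   matrix).
#' @param data_b paired array like `data_a`, or `NULL` to test `data_a`
#'   against `null_value`.
#' @param null_value reference value when `data_b` is `NULL`.
#' @param statistic `"t"` or `"wilcoxon"`.
#' @param n_permutations random sign-flip draws (>= 100).
#' @param alpha cluster-level significance level recorded on the report.
#' @param alpha_element element-wise threshold for cluster forming.
#' @param adjacency spatial adjacency (see [form_clusters()]).
#' @param min_neighbor_pairs minimum adjacent location pairs per cluster.
#' @param seed integer seed for the permutation draws.
#' @param exact if `TRUE`, enumerate all `2^n_subjects` sign patterns
#'   instead of random draws (feasible for small groups); `n_permutations`
#'   is ignored and p has no Monte-Carlo floor.
#'
#' @return A `cluster_report`: list of clusters (`members`, `stat_sum`,
#'   `sign`, `p`), plus `n_permutations`, `alpha`, `max_stat_distribution`.
#' @export
permutation_p <- function(data_a, data_b = NULL, null_value = 0.5,
                          statistic = c("t", "wilcoxon"),
                          n_permutations = 1000, alpha = 0.05,
                          alpha_element = 0.05, adjacency = NULL,
                          min_neighbor_pairs = 0L, seed = 1L,
                          exact = FALSE) {
  statistic <- match.arg(statistic)
  dims <- dim(data_a)
  n_subj <- dims[1]
  # matrix input: with a spatial adjacency the elements are locations at a
  # single time point, otherwise one location over time
  el_shape <- if (length(dims) > 2) dims[-1] else
    if (!is.null(adjacency)) c(dims[2], 1L) else c(1L, dims[2])
  D <- if (!is.null(data_b)) data_a - data_b else
    sweep(if (length(dims) > 2) matrix(data_a, nrow = n_subj) else data_a,
          2, null_value, "-")
  D <- if (length(dim(D)) > 2) matrix(D, nrow = n_subj) else as.matrix(D)
  if (!exact && n_permutations < 100) stop("need at least 100 permutations")

  if (statistic == "t") {
    S2 <- colSums(D^2)
    stat_fun <- function(s) {
      m <- as.numeric(s %*% D) / n_subj
      v <- (S2 - n_subj * m^2) / (n_subj - 1)
      v[v < 1e-300] <- 1e-300
      tval <- m / sqrt(v / n_subj)
      list(stat = tval, p = 2 * stats::pt(-abs(tval), df = n_subj - 1))
    }
  } else {
    if (n_subj < 5) stop("Wilcoxon element statistics need >= 5 subjects")
    R <- signed_rank_matrix(D)
    n_eff <- colSums(R != 0)
    # element threshold on |S| at alpha_element per effective n
    crit_for_n <- function(n) {
      if (n == 0) return(Inf)
      svals <- seq(n * (n + 1) / 2, 0, by = -2)
      pv <- vapply(svals, function(s) signed_rank_p_exact(s, n), numeric(1))
      ok <- which(pv < alpha_element + 1e-12)
      if (length(ok) == 0) Inf else min(svals[ok])
    }
    crit_cache <- vapply(sort(unique(n_eff)), crit_for_n, numeric(1))
    names(crit_cache) <- sort(unique(n_eff))
    crit <- crit_cache[as.character(n_eff)]
    stat_fun <- function(s) {
      S <- as.numeric(s %*% R)
      list(stat = S, p = ifelse(abs(S) >= crit, 0, 1))
    }
  }

  as_mat <- function(x) matrix(x, nrow = el_shape[1])
  obs <- stat_fun(rep(1, n_subj))
  obs_clusters <- form_clusters(as_mat(obs$stat), as_mat(obs$p),
                                alpha_element, adjacency,
                                min_neighbor_pairs)

  perm_sets <- if (exact) {
    n_permutations <- 2^n_subj
    lapply(seq_len(n_permutations) - 1L, function(k)
      2 * ((k %/% 2^(seq_len(n_subj) - 1)) %% 2) - 1)
  } else {
    with_seed(seed, lapply(seq_len(n_permutations), function(k)
      sample(c(-1, 1), n_subj, replace = TRUE)))
  }
  perm_max <- vapply(perm_sets, function(s) {
    st <- stat_fun(s)
    max_cluster_stats(form_clusters(as_mat(st$stat), as_mat(st$p),
                                    alpha_element, adjacency,
                                    min_neighbor_pairs))
  }, numeric(2))

  denom <- if (exact) n_permutations else n_permutations + 1
  for (i in seq_along(obs_clusters)) {
    cl <- obs_clusters[[i]]
    ref <- perm_max[if (cl$sign > 0) "pos" else "neg", ]
    count <- sum(ref >= abs(cl$stat_sum) - 1e-12)
    obs_clusters[[i]]$p <- min(1, 2 * (count + !exact) / denom)
  }
  structure(list(clusters = obs_clusters, n_permutations = n_permutations,
                 alpha = alpha, statistic = statistic,
                 max_stat_distribution = t(perm_max), exact = exact),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %s statistic, %d permutations%s\n",
              x$statistic, x$n_permutations,
              if (x$exact) " (exact enumeration)" else ""))
  if (length(x$clusters) == 0) {
    cat("  no clusters\n")
  } else for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  cluster %d: sign %+d, %d elements, stat_sum = %.2f, p = %.4g%s\n",
                i, cl$sign, nrow(cl$members), cl$stat_sum, cl$p,
                if (cl$p < x$alpha) " *" else ""))
  }
  invisible(x)
}

#' Significant clusters of a report
#'
#' @param report a `cluster_report`.
#' @param alpha threshold; defaults to the report's alpha.
#' @return The sublist of clusters with `p < alpha`.
#' @export
significant_clusters <- function(report, alpha = report$alpha) {
  Filter(function(cl) cl$p < alpha, report$clusters)
}

#' Significance mask from a cluster report
#'
#' @param report a `cluster_report`.
#' @param dims dimensions (locations, time) of the tested map.
#' @param alpha cluster threshold.
#' @return Logical matrix marking elements of significant clusters.
#' @export
cluster_mask <- function(report, dims, alpha = report$alpha) {
  m <- matrix(FALSE, dims[1], dims[2])
  for (cl in significant_clusters(report, alpha))
    m[cl$members] <- TRUE
  m
}
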