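# DBSCAN localization of peak-decoding voxels: top-percentile selection on
# the AUC map restricted to labeled gray matter, density clustering with
# eps = 1.5 x grid spacing, and per-cluster anatomical summaries.

#' Top-percentile voxel selection
#'
#' Voxels whose AUC reaches the `1 - percentile` quantile of the
#' included-voxel AUCs (ties at the threshold all included), intersected
#' with labeled (non-cerebellar) voxels. The quantile is computed over
#' included voxels only, since excluded positions carry the re-inserted
#' value 0.
#'
#' @param auc full-grid AUC vector (see [reinsert_voxel_map()]).
#' @param included integer indices of included voxels.
#' @param percentile fraction selected (default 0.02: the top 2 %).
#' @return Integer voxel indices; error when the included map is constant.
#' @export
top_percentile_mask <- function(auc, included, percentile = 0.02) {
  vals <- auc[included]
  if (max(vals) - min(vals) < .Machine$double.eps * 100)
    stop("AUC map is constant over included voxels")
  thr <- stats::quantile(vals, 1 - percentile, names = FALSE, type = 7)
  sel <- included[vals >= thr]
  if (length(sel) == 0) stop("top-percentile selection is empty")
  sel
}

#' DBSCAN clustering of selected voxels
#'
#' Density-based clustering with Euclidean metric on the grid coordinates.
#' A voxel is a core point when its eps-neighborhood (excluding itself)
#' holds at least `min_pts - 1` selected voxels; border points join the
#' cluster of a reachable core; unreachable voxels are noise. With
#' `min_pts = 2` ("at least one neighbor") the clusters equal the connected
#' components of the eps-neighborhood graph, singletons excluded.
#'
#' @param voxels integer indices of the selected voxels (full grid).
#' @param coords full-grid voxel coordinates.
#' @param eps neighborhood radius (same units as `coords`); default
#'   `1.5 * grid_spacing` is applied by [find_decoding_clusters()].
#' @param min_pts minimum points in a core neighborhood (>= 2).
#' @return A `voxel_cluster_set`: list of clusters (integer member indices),
#'   `eps`, `min_pts`, `noise` (unclustered voxel indices).
#' @export
dbscan_voxels <- function(voxels, coords, eps, min_pts = 2L) {
  stopifnot(eps > 0, min_pts >= 2)
  n <- length(voxels)
  P <- coords[voxels, , drop = FALSE]
  D <- as.matrix(stats::dist(P))
  nb <- lapply(seq_len(n), function(i) setdiff(which(D[i, ] <= eps), i))
  core <- vapply(nb, length, integer(1)) >= (min_pts - 1L)
  cluster_id <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (cluster_id[i] != 0L || !core[i]) next
    cur <- cur + 1L
    stack <- i
    cluster_id[i] <- cur
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (u in nb[[v]]) {
        if (cluster_id[u] == 0L) {
          cluster_id[u] <- cur                 # border or core joins
          if (core[u]) stack <- c(stack, u)    # only cores expand
        }
      }
    }
  }
  clusters <- lapply(seq_len(max(cluster_id, 0L)), function(k)
    sort(voxels[cluster_id == k]))
  structure(list(clusters = clusters, eps = eps, min_pts = as.integer(min_pts),
                 noise = sort(voxels[cluster_id == 0L])),
            class = "voxel_cluster_set")
}

#' @export
print.voxel_cluster_set <- function(x, ...) {
  cat(sprintf("<voxel_cluster_set> %d clusters (eps = %g, min_pts = %d), %d noise voxels\n",
              length(x$clusters), x$eps, x$min_pts, length(x$noise)))
  invisible(x)
}

#' Summarize DBSCAN voxel clusters
#'
#' @param cluster_set a [dbscan_voxels()] result.
#' @param auc full-grid AUC vector.
#' @param coords full-grid voxel coordinates.
#' @param labels full-grid atlas labels.
#' @return data.frame with one row per cluster: `cluster_id`, `n_voxels`,
#'   `mean_auc`, centroid coordinates and the sorted atlas labels present
#'   (`"label(n)"` comma-separated).
#' @export
summarize_clusters <- function(cluster_set, auc, coords, labels) {
  if (length(cluster_set$clusters) == 0)
    return(data.frame(cluster_id = integer(0), n_voxels = integer(0),
                      mean_auc = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), labels = character(0)))
  rows <- lapply(seq_along(cluster_set$clusters), function(k) {
    mem <- cluster_set$clusters[[k]]
    ctr <- colMeans(coords[mem, , drop = FALSE])
    tab <- sort(table(labels[mem]), decreasing = TRUE)
    data.frame(cluster_id = k, n_voxels = length(mem),
               mean_auc = mean(auc[mem]),
               x = ctr[1], y = ctr[2], z = ctr[3],
               labels = paste(sprintf("%s(%d)", names(tab), tab),
                              collapse = ", "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Locate clusters of best-decoding voxels
#'
#' Convenience wrapper: top-percentile selection on the re-inserted AUC
#' map over labeled voxels, DBSCAN with `eps = eps_factor * grid_spacing`,
#' and the per-cluster summary.
#'
#' @param auc full-grid AUC vector.
#' @param leadfield the [lead_field()] providing coordinates, spacing and
#'   labels.
#' @param percentile top fraction of AUC values (default 0.02).
#' @param eps_factor multiple of the grid spacing (default 1.5).
#' @param min_pts DBSCAN minimum neighborhood size.
#' @return List with `selection` (voxel indices), `cluster_set` and
#'   `summary` (data.frame).
#' @export
find_decoding_clusters <- function(auc, leadfield, percentile = 0.02,
                                   eps_factor = 1.5, min_pts = 2L) {
  included <- select_voxels(leadfield)
  sel <- top_percentile_mask(auc, included, percentile)
  cs <- dbscan_voxels(sel, leadfield$grid_coords,
                      eps = eps_factor * leadfield$grid_spacing,
                      min_pts = min_pts)
  list(selection = sel, cluster_set = cs,
       summary = summarize_clusters(cs, auc, leadfield$grid_coords,
                                    leadfield$labels))
}
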