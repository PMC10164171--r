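# Multivariate pattern analysis: temporal decoding, temporal
# generalization, cross-frequency (theta-train / alpha-test) transfer,
# per-voxel spatial decoding, voxel-map re-insertion and group-level
# significance against chance.
#
# Classifier: linear support vector machine (e1071) with continuous
# decision values; performance metric: area under the ROC curve, pooled
# over the held-out folds of a stratified cross-validation whose fold
# assignment is fixed per trial before any feature extraction (no
# train/test leakage).

#' Decoding configuration
#'
#' @param classifier only `"svm_linear"` (linear SVM with decision values).
#' @param c_param SVM cost (regularization strength; toolbox default 1).
#' @param n_folds stratified cross-validation folds.
#' @param metric only `"auc"`.
#' @param seed integer seed fixing the fold assignment.
#' @return A `decoding_config` list.
#' @export
decoding_config <- function(classifier = "svm_linear", c_param = 1,
                            n_folds = 5L, metric = "auc", seed = 1L) {
  stopifnot(classifier == "svm_linear", metric == "auc",
            n_folds >= 2, c_param > 0)
  structure(list(classifier = classifier, c_param = c_param,
                 n_folds = as.integer(n_folds), metric = metric,
                 seed = as.integer(seed)), class = "decoding_config")
}

#' Area under the ROC curve from continuous scores
#'
#' Rank-based (Mann-Whitney) AUC of `scores` for discriminating
#' `positive` trials; ties get average ranks.
#'
#' @param scores numeric decision values, higher = more "positive".
#' @param positive logical per trial.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' @param labels per-trial class labels (two classes).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids per trial; every class appears in
#'   every fold's training set.
#' @export
make_folds <- function(labels, n_folds = 5L, seed = 1L) {
  classes <- unique(labels)
  if (length(classes) < 2) stop("decoding requires two classes")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      if (length(idx) < n_folds)
        stop("class ", cl, " has fewer trials than folds")
      folds[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  })
  folds
}

# train a linear SVM and return a scorer: X_test -> decision values oriented
# so that larger values favor `positive_class`
svm_scorer <- function(X, y, positive_class, cost) {
  yf <- factor(y)
  fit <- e1071::svm(X, yf, kernel = "linear", cost = cost, scale = FALSE,
                    type = "C-classification")
  function(Xte) {
    pr <- stats::predict(fit, Xte, decision.values = TRUE)
    dv <- as.numeric(attr(pr, "decision.values"))
    # decision value is positive for the class named first in the colname
    nm <- colnames(attr(pr, "decision.values"))[1]
    lead <- strsplit(nm, "/")[[1]][1]
    sgn <- if (lead == positive_class) 1 else -1
    sgn * dv
  }
}

# z-score columns by training statistics
standardizer <- function(Xtr) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  function(X) sweep(sweep(X, 2, mu), 2, sd, "/")
}

positive_class_of <- function(labels) {
  # the "overlap" condition is scored as positive when present
  if ("nogo_overlap" %in% labels) "nogo_overlap" else sort(unique(labels))[2]
}

#' Temporal MVPA
#'
#' Per time sample, trains the classifier on the spatial pattern (all
#' locations) and scores held-out trials; AUC is pooled over folds.
#'
#' @param course trials x locations x time array, or a
#'   [band_power_course()] with single-trial power.
#' @param labels per-trial condition labels (two classes).
#' @param config a [decoding_config()].
#' @param times optional time axis (taken from the course if present).
#' @return A `decoding_result` with `auc_time` and `times`.
#' @export
temporal_mvpa <- function(course, labels, config = decoding_config(),
                          times = NULL) {
  if (inherits(course, "band_power_course")) {
    times <- course$times; course <- course$power
  }
  stopifnot(length(dim(course)) == 3, dim(course)[1] == length(labels))
  pos <- positive_class_of(labels)
  folds <- make_folds(labels, config$n_folds, config$seed)
  n_t <- dim(course)[3]
  valid_t <- which(apply(course, 3, function(m) !anyNA(m)))
  dv <- matrix(NA_real_, length(labels), n_t)
  for (ti in valid_t) {
    X <- course[, , ti, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      zs <- standardizer(X[tr, , drop = FALSE])
      sc <- svm_scorer(zs(X[tr, , drop = FALSE]), labels[tr], pos,
                       config$c_param)
      dv[!tr, ti] <- sc(zs(X[!tr, , drop = FALSE]))
    }
  }
  auc <- rep(NA_real_, n_t)
  auc[valid_t] <- vapply(valid_t, function(ti)
    auc_score(dv[, ti], labels == pos), numeric(1))
  structure(list(auc_time = auc, times = times, chance = 0.5,
                 mode = "temporal", config = config),
            class = "decoding_result")
}

# shared engine for generalization matrices; test features may come from a
# different course (cross-band transfer) but folds split trials only once
generalization_engine <- function(train_course, test_course, labels,
                                  config, times, diag_only = FALSE) {
  pos <- positive_class_of(labels)
  folds <- make_folds(labels, config$n_folds, config$seed)
  n_t <- dim(train_course)[3]
  valid_tr <- which(apply(train_course, 3, function(m) !anyNA(m)))
  valid_te <- which(apply(test_course, 3, function(m) !anyNA(m)))
  dv <- array(NA_real_, c(length(labels), n_t, n_t))   # trial x train x test
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    for (ti in valid_tr) {
      Xtr <- train_course[tr, , ti, drop = TRUE]
      if (is.null(dim(Xtr))) Xtr <- matrix(Xtr, ncol = 1)
      zs <- standardizer(Xtr)
      sc <- svm_scorer(zs(Xtr), labels[tr], pos, config$c_param)
      tj_set <- if (diag_only) intersect(ti, valid_te) else valid_te
      for (tj in tj_set) {
        Xte <- test_course[!tr, , tj, drop = TRUE]
        if (is.null(dim(Xte))) Xte <- matrix(Xte, ncol = 1)
        dv[!tr, ti, tj] <- sc(zs(Xte))
      }
    }
  }
  auc <- matrix(NA_real_, n_t, n_t)
  for (ti in valid_tr)
    for (tj in (if (diag_only) intersect(ti, valid_te) else valid_te))
      auc[ti, tj] <- auc_score(dv[, ti, tj], labels == pos)
  auc
}

#' Temporal generalization MVPA
#'
#' Trains at every time sample and tests at every other, within the same
#' cross-validation folds; the diagonal reproduces [temporal_mvpa()] up to
#' fold noise.
#'
#' @inheritParams temporal_mvpa
#' @return A `decoding_result` with `auc_gen` (train x test) and
#'   `auc_time` (its diagonal).
#' @export
temporal_generalization <- function(course, labels,
                                    config = decoding_config(),
                                    times = NULL) {
  if (inherits(course, "band_power_course")) {
    times <- course$times; course <- course$power
  }
  auc <- generalization_engine(course, course, labels, config, times)
  structure(list(auc_gen = auc, auc_time = diag(auc), times = times,
                 chance = 0.5, mode = "generalization", config = config),
            class = "decoding_result")
}

#' Cross-band transfer MVPA (train theta, test alpha)
#'
#' Trains on the features of `train_course` and scores the held-out trials
#' of the same folds on the features of `test_course` (same trials, never
#' mixed between training and testing). Returns the matched-time AUC curve
#' (diagonal) and the full train x test generalization matrix.
#'
#' @param train_course,test_course trials x locations x time arrays or
#'   [band_power_course()] objects sharing trials, locations and times.
#' @param labels per-trial condition labels.
#' @param config a [decoding_config()].
#' @param times optional time axis.
#' @param diag_only compute only the matched-time diagonal (faster when the
#'   generalization matrix is not needed).
#' @return A `decoding_result` with `auc_time` and `auc_gen`.
#' @export
cross_band_mvpa <- function(train_course, test_course, labels,
                            config = decoding_config(), times = NULL,
                            diag_only = FALSE) {
  if (inherits(train_course, "band_power_course")) {
    times <- train_course$times; train_course <- train_course$power
  }
  if (inherits(test_course, "band_power_course"))
    test_course <- test_course$power
  stopifnot(all(dim(train_course) == dim(test_course)))
  auc <- generalization_engine(train_course, test_course, labels, config,
                               times, diag_only = diag_only)
  structure(list(auc_gen = auc, auc_time = diag(auc), times = times,
                 chance = 0.5, mode = "cross_band", config = config),
            class = "decoding_result")
}

#' Spatial MVPA (per-voxel decoding with time as features)
#'
#' For each location, uses the band-power time course restricted to the
#' significant time samples as the feature vector and returns one
#' cross-validated AUC per location.
#'
#' @param course trials x locations x time array or [band_power_course()].
#' @param labels per-trial condition labels.
#' @param sig_time_mask logical per time sample (e.g. from the temporal
#'   MVPA group test); must select at least one sample.
#' @param config a [decoding_config()].
#' @return A `decoding_result` with `auc_voxel`.
#' @export
spatial_mvpa <- function(course, labels, sig_time_mask,
                         config = decoding_config()) {
  if (inherits(course, "band_power_course")) course <- course$power
  stopifnot(length(sig_time_mask) == dim(course)[3])
  tsel <- which(sig_time_mask & apply(course, 3, function(m) !anyNA(m)))
  if (length(tsel) == 0) stop("significant-time mask selects no valid sample")
  pos <- positive_class_of(labels)
  folds <- make_folds(labels, config$n_folds, config$seed)
  n_loc <- dim(course)[2]
  auc <- numeric(n_loc)
  for (v in seq_len(n_loc)) {
    X <- course[, v, tsel, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    dv <- numeric(length(labels))
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      zs <- standardizer(X[tr, , drop = FALSE])
      sc <- svm_scorer(zs(X[tr, , drop = FALSE]), labels[tr], pos,
                       config$c_param)
      dv[!tr] <- sc(zs(X[!tr, , drop = FALSE]))
    }
    auc[v] <- auc_score(dv, labels == pos)
  }
  structure(list(auc_voxel = auc, chance = 0.5, mode = "spatial",
                 config = config), class = "decoding_result")
}

#' Re-insert an included-voxel AUC map into the full grid
#'
#' Excluded voxels are set to 0 in both the AUC map and the paired
#' chance-level map (0.5 at included voxels, 0 elsewhere), re-establishing
#' the full 3-D grid for group statistics.
#'
#' @param auc_voxel AUC per included voxel.
#' @param included integer indices of included voxels in the full grid.
#' @param n_total total number of grid voxels.
#' @return List with `auc` and `chance`, both length `n_total`.
#' @export
reinsert_voxel_map <- function(auc_voxel, included, n_total) {
  stopifnot(length(auc_voxel) == length(included),
            all(included >= 1 & included <= n_total))
  auc <- numeric(n_total); auc[included] <- auc_voxel
  chance <- numeric(n_total); chance[included] <- 0.5
  list(auc = auc, chance = chance)
}

#' Group test of decoding performance against chance
#'
#' Cluster-based permutation test (Wilcoxon element statistic, subject
#' sign flips) of per-subject AUC maps or curves against the chance map.
#'
#' @param maps subjects x elements matrix (curves: elements = time;
#'   voxel maps: elements = voxels) or subjects x loc x time array.
#' @param chance chance reference (scalar 0.5 or per-element vector, e.g.
#'   a re-inserted chance map).
#' @param adjacency spatial adjacency for clustering (`NULL` for pure time
#'   courses).
#' @param n_permutations,alpha,alpha_element,seed,min_neighbor_pairs passed
#'   to [permutation_p()].
#' @return List with `report` (a `cluster_report`) and `sig_mask` shaped
#'   like one subject's map.
#' @export
group_test_vs_chance <- function(maps, chance = 0.5, adjacency = NULL,
                                 n_permutations = 1000, alpha = 0.05,
                                 alpha_element = 0.05, seed = 1L,
                                 min_neighbor_pairs = 0L) {
  dims <- dim(maps)
  report <- permutation_p(maps, data_b = NULL, null_value = chance,
                          statistic = "wilcoxon",
                          n_permutations = n_permutations, alpha = alpha,
                          alpha_element = alpha_element,
                          adjacency = adjacency,
                          min_neighbor_pairs = min_neighbor_pairs,
                          seed = seed)
  el_shape <- if (length(dims) > 2) dims[-1] else
    if (!is.null(adjacency)) c(dims[2], 1L) else c(1L, dims[2])
  mask <- cluster_mask(report, el_shape, alpha)
  if (length(dims) == 2) mask <- as.vector(mask)
  list(report = report, sig_mask = mask)
}

#' Temporal-generalization duration around the diagonal
#'
#' For every train time whose diagonal element is significant, measures the
#' contiguous significant run of test times containing the diagonal; the
#' duration is the mean run length over all train times (0 ms for
#' non-significant diagonal elements). Also reports the fraction of
#' significant train x test cells and their mean AUC.
#'
#' @param auc_gen train x test AUC matrix.
#' @param sig_mask logical matrix like `auc_gen`.
#' @param times time axis (s) of both dimensions.
#' @return List with `mean_duration_ms`, `frac_significant`,
#'   `mean_sig_auc`.
#' @export
generalization_duration <- function(auc_gen, sig_mask, times) {
  stopifnot(all(dim(auc_gen) == dim(sig_mask)),
            nrow(auc_gen) == length(times))
  dt_ms <- mean(diff(times)) * 1000
  n <- length(times)
  runs <- vapply(seq_len(n), function(i) {
    if (!isTRUE(sig_mask[i, i])) return(0)
    lo <- i; while (lo > 1 && isTRUE(sig_mask[i, lo - 1])) lo <- lo - 1
    hi <- i; while (hi < n && isTRUE(sig_mask[i, hi + 1])) hi <- hi + 1
    (hi - lo + 1) * dt_ms
  }, numeric(1))
  valid <- !is.na(auc_gen)
  list(mean_duration_ms = mean(runs),
       frac_significant = sum(sig_mask & valid) / sum(valid),
       mean_sig_auc = if (any(sig_mask & valid))
         mean(auc_gen[sig_mask & valid]) else NA_real_)
}
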