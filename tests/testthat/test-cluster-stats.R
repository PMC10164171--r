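test_that("paired t maps match the direct formula", {
  set.seed(1)
  a <- matrix(rnorm(5 * 4), 5)
  b <- matrix(rnorm(5 * 4), 5)
  st <- element_stats_paired_t(a, b)
  for (j in 1:4) {
    tt <- t.test(a[, j], b[, j], paired = TRUE)
    expect_equal(st$t[j], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(st$p[j], tt$p.value, tolerance = 1e-12)
  }
  same <- element_stats_paired_t(a, a)
  expect_true(all(same$t == 0))
  # constant nonzero difference: infinite t treated as maximal
  cst <- element_stats_paired_t(a + 2, a)
  expect_true(all(is.infinite(cst$t) & cst$t > 0))
  expect_true(all(cst$p == 0))
})

test_that("Wilcoxon element statistics match closed forms and enumeration", {
  x <- matrix(c(0.6, 0.7, 0.8, 0.9, 0.65, 0.75), ncol = 1)
  st <- element_stats_wilcoxon_vs(x, 0.5)
  expect_equal(st$stat[1], 6 * 7 / 2)        # all above: maximal rank sum
  sym <- matrix(c(-3, -2, -1, 1, 2, 3) + 0.5, ncol = 1)
  st2 <- element_stats_wilcoxon_vs(sym, 0.5)
  expect_equal(st2$stat[1], 0)
  expect_gt(st2$p[1], 0.9)
  set.seed(4)
  for (k in 1:5) {
    d <- rnorm(6)
    st3 <- element_stats_wilcoxon_vs(matrix(d + 0.5, ncol = 1), 0.5)
    expect_equal(st3$p[1], enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon p agrees with stats::wilcox.test", {
  set.seed(9)
  x <- matrix(rnorm(12 * 3, mean = 0.3), 12)
  st <- element_stats_wilcoxon_vs(x, 0)
  for (j in 1:3) {
    ref <- wilcox.test(x[, j], mu = 0, exact = TRUE)
    expect_equal(st$p[j], ref$p.value, tolerance = 1e-12)
  }
})

test_that("cluster forming follows adjacency, sign and the pair rule", {
  # 6 channels in a chain, 60 samples
  adj <- lapply(1:6, function(i) intersect(c(i - 1, i + 1), 1:6))
  stat <- matrix(0, 6, 60); p <- matrix(1, 6, 60)
  expect_length(form_clusters(stat, p, 0.05, adj, 2), 0)

  # planted 5-channel x 50-sample positive block
  stat[1:5, 6:55] <- 3; p[1:5, 6:55] <- 0.01
  cl <- form_clusters(stat, p, 0.05, adj, 2)
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$members), 5 * 50)
  expect_equal(cl[[1]]$stat_sum, sum(stat[1:5, 6:55]))
  expect_equal(cl[[1]]$sign, 1)

  # an isolated significant channel fails the two-pair rule
  stat2 <- matrix(0, 6, 60); p2 <- matrix(1, 6, 60)
  stat2[3, 10:20] <- 3; p2[3, 10:20] <- 0.01
  expect_length(form_clusters(stat2, p2, 0.05, adj, 2), 0)
  expect_length(form_clusters(stat2, p2, 0.05, adj, 0), 1)

  # opposite signs never join
  stat3 <- matrix(0, 6, 60); p3 <- matrix(1, 6, 60)
  stat3[1:3, 10] <- 3;  p3[1:3, 10] <- 0.01
  stat3[4:6, 10] <- -3; p3[4:6, 10] <- 0.01
  cl3 <- form_clusters(stat3, p3, 0.05, adj, 0)
  expect_length(cl3, 2)
  expect_setequal(vapply(cl3, `[[`, numeric(1), "sign"), c(1, -1))
})

test_that("cluster membership is invariant to location relabeling", {
  set.seed(7)
  n_loc <- 8
  adj <- lapply(seq_len(n_loc), function(i)
    intersect(c(i - 1, i + 1), seq_len(n_loc)))
  stat <- matrix(rnorm(n_loc * 20, sd = 2), n_loc)
  p <- 2 * pnorm(-abs(stat))
  cl <- form_clusters(stat, p, 0.05, adj, 0)
  perm <- sample(n_loc)                       # relabel locations
  inv <- order(perm)
  adj_p <- lapply(seq_len(n_loc), function(i) sort(perm[adj[[inv[i]]]]))
  cl_p <- form_clusters(stat[inv, ], p[inv, ], 0.05, adj_p, 0)
  canon <- function(cls, map = identity)
    sort(vapply(cls, function(c1)
      paste(sort(paste(map(c1$members[, 1]), c1$members[, 2])),
            collapse = ";"), character(1)))
  expect_equal(canon(cl, function(l) perm[l]), canon(cl_p))
})

test_that("permutation p-values hit the two-tailed Monte-Carlo floor", {
  set.seed(2)
  n_sub <- 16                                 # identity draw ~1/65536
  a <- array(rnorm(n_sub * 4 * 10), c(n_sub, 4, 10))
  b <- a - 5                                  # huge uniform effect
  adj <- lapply(1:4, function(i) setdiff(1:4, i))
  rep <- permutation_p(a, b, statistic = "t", n_permutations = 1000,
                       adjacency = adj, seed = 3)
  expect_gte(length(significant_clusters(rep)), 1)
  p_min <- min(vapply(rep$clusters, `[[`, numeric(1), "p"))
  expect_equal(p_min, 2 / 1001, tolerance = 1e-12)
  expect_equal(round(p_min, 3), 0.002)
})

test_that("exact permutation distribution matches a brute-force oracle", {
  skip_if_not_installed("igraph")
  set.seed(5)
  n_sub <- 6; n_loc <- 4; n_t <- 6
  D <- array(rnorm(n_sub * n_loc * n_t, mean = 0.6), c(n_sub, n_loc, n_t))
  adj <- lapply(seq_len(n_loc), function(i)
    intersect(c(i - 1, i + 1), seq_len(n_loc)))
  rep <- permutation_p(D, D * 0, statistic = "t", adjacency = adj,
                       exact = TRUE)

  # oracle: enumerate sign patterns; igraph components for clustering
  oracle_max <- function(Dm) {
    tcrit <- qt(0.975, n_sub - 1)
    tmap <- apply(Dm, c(2, 3), function(v)
      mean(v) / (sd(v) / sqrt(n_sub)))
    best <- c(pos = 0, neg = 0)
    for (sgn in c(1, -1)) {
      supra <- which(sgn * tmap > tcrit, arr.ind = TRUE)
      if (nrow(supra) == 0) next
      id <- function(l, t) paste(l, t)
      edges <- character(0)
      key <- id(supra[, 1], supra[, 2])
      for (r in seq_len(nrow(supra))) {
        l <- supra[r, 1]; t <- supra[r, 2]
        for (l2 in adj[[l]])
          if (id(l2, t) %in% key)
            edges <- c(edges, id(l, t), id(l2, t))
        if (id(l, t + 1) %in% key)
          edges <- c(edges, id(l, t), id(l, t + 1))
      }
      g <- igraph::graph_from_data_frame(
        if (length(edges)) matrix(edges, ncol = 2, byrow = TRUE) else
          matrix(character(0), ncol = 2),
        directed = FALSE, vertices = data.frame(name = key))
      comp <- igraph::components(g)$membership
      sums <- tapply(tmap[supra], comp[key], sum)
      best[if (sgn > 0) "pos" else "neg"] <- max(abs(sums))
    }
    best
  }
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_sub)))
  omax <- t(apply(signs, 1, function(s) oracle_max(D * s)))
  for (cl in rep$clusters) {
    side <- if (cl$sign > 0) "pos" else "neg"
    p_oracle <- min(1, 2 * mean(omax[, side] >= abs(cl$stat_sum) - 1e-9))
    expect_equal(cl$p, p_oracle, tolerance = 1e-12)
  }
})

test_that("under the null the cluster test rejects near the nominal rate", {
  set.seed(8)
  n_loc <- 6
  adj <- lapply(seq_len(n_loc), function(i)
    intersect(c(i - 1, i + 1), seq_len(n_loc)))
  rejections <- vapply(1:40, function(r) {
    D <- array(rnorm(10 * n_loc * 8), c(10, n_loc, 8))
    rep <- permutation_p(D, D * 0, statistic = "t", n_permutations = 199,
                         adjacency = adj, seed = r)
    length(significant_clusters(rep)) > 0
  }, logical(1))
  expect_lte(mean(rejections), 0.2)           # loose bound for 40 draws
})
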