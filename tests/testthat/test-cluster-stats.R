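test_that("correlation-T map matches the textbook Pearson computation", {
  # 8 hand-listed pairs, checked against cor.test as the independent route
  x <- c(0.1, 0.3, 0.5, 0.7, 0.2, 0.4, 0.6, 0.8)
  y <- c(1.2, 0.8, 0.9, 0.1, 1.0, 0.7, 0.4, 0.3)
  X <- matrix(y, ncol = 1)
  map <- correlation_t_map(X, x)
  ct <- cor.test(x, y)
  expect_equal(map$r[1, 1], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(map$t[1, 1], unname(ct$statistic), tolerance = 1e-9)
  expect_equal(map$df, 6L)

  # self-correlation and degenerate columns
  X2 <- cbind(x, rep(2, 8))
  map2 <- correlation_t_map(X2, x, n_time = 1)
  expect_equal(map2$r[1, 1], 1, tolerance = 1e-12)
  expect_equal(map2$r[1, 2], 0)
  expect_true(map2$degenerate[1, 2])

  # a predictor uncorrelated with a constant-per-observation dependent
  X3 <- matrix(rep(c(1, 2), 4), ncol = 1)
  expect_equal(correlation_t_map(X3, rep(c(3, 3, 5, 5), 2))$r[1, 1], 0,
               tolerance = 1e-12)
})

test_that("|r| is invariant under affine transforms of the predictor", {
  set.seed(5)
  X <- matrix(rnorm(20 * 6), 20, 6)
  pred <- rnorm(20)
  m0 <- correlation_t_map(X, pred, n_time = 3)
  m1 <- correlation_t_map(X, 2.5 * pred - 7, n_time = 3)
  m2 <- correlation_t_map(X, -0.3 * pred + 1, n_time = 3)
  expect_equal(m1$r, m0$r, tolerance = 1e-12)
  expect_equal(m2$r, -m0$r, tolerance = 1e-12)
})

test_that("cluster formation matches hand arithmetic on a toy grid", {
  # 4 time x 4 electrodes (chain adjacency); df = 20 -> t_crit = 2.086
  tmat <- matrix(0, 4, 4)
  tmat[1:2, 1] <- 3       # cluster A: electrode 1, times 1-2
  tmat[4, 3] <- 2.5       # isolated point, no supra neighbors
  tmat[2:3, 2] <- -4      # negative cluster B
  adj <- build_adjacency(toy_montage(4))
  map <- toy_stat_map(tmat, df = 20L)
  tcrit <- qt(0.975, 20)

  cl <- form_clusters(map, adj, min_neighbor_channels = 0)
  expect_length(cl, 3)
  wcms <- sort(vapply(cl, `[[`, 0, "wcm"))
  expect_equal(wcms, sort(c(2 * (3 - tcrit), 2.5 - tcrit,
                            -2 * (4 - tcrit))), tolerance = 1e-12)

  # weight exponent 2 squares each excess
  cl2 <- form_clusters(map, adj, min_neighbor_channels = 0, wcm_weight = 2)
  expect_equal(sort(vapply(cl2, `[[`, 0, "wcm")),
               sort(c(2 * (3 - tcrit)^2, (2.5 - tcrit)^2,
                      -2 * (4 - tcrit)^2)), tolerance = 1e-12)

  # min-neighbor rule removes points without supra-threshold neighbors:
  # every supra point here has 0 same-sign spatial neighbors
  expect_length(form_clusters(map, adj, min_neighbor_channels = 2), 0)

  # no supra-threshold points -> empty list
  expect_length(form_clusters(toy_stat_map(matrix(0.5, 4, 4)), adj,
                              min_neighbor_channels = 0), 0)
})

test_that("cluster formation equals brute-force flood-fill on random toy grids", {
  skip_if_not_installed("igraph")
  set.seed(99)
  adjs <- lapply(2:6, function(n) build_adjacency(toy_montage(n)))
  for (i in 1:120) {
    n_el <- sample(2:6, 1)
    n_ti <- sample(3:10, 1)
    # mix of sparse and dense supra-threshold maps
    tmat <- matrix(rnorm(n_ti * n_el, sd = sample(c(1, 2, 3), 1)),
                   n_ti, n_el)
    adj <- adjs[[n_el - 1L]]
    map <- toy_stat_map(tmat, df = 18L)
    got <- form_clusters(map, adj, min_neighbor_channels = 0)
    want <- brute_clusters(tmat, qt(0.975, 18), adj$neighbors)
    expect_identical(cluster_signature(got), cluster_signature(want))
  }
})

test_that("per-point minimum-neighbor rule matches a direct reimplementation", {
  set.seed(7)
  adj <- build_adjacency(toy_montage(5))
  for (i in 1:40) {
    tmat <- matrix(rnorm(8 * 5, sd = 2.2), 8, 5)
    map <- toy_stat_map(tmat, df = 15L)
    tcrit <- qt(0.975, 15)
    got <- form_clusters(map, adj, min_neighbor_channels = 1)
    # direct: drop supra points with < 1 same-sign supra neighbor, then
    # flood-fill with the oracle
    pruned <- tmat
    for (sgn in c(1, -1)) {
      mask <- if (sgn > 0) tmat > tcrit else tmat < -tcrit
      for (e in 1:5) for (ti in 1:8) {
        if (!mask[ti, e]) next
        if (sum(mask[ti, adj$neighbors[[e]]]) < 1) pruned[ti, e] <- 0
      }
    }
    want <- brute_clusters(pruned, tcrit, adj$neighbors)
    expect_identical(cluster_signature(got), cluster_signature(want))
  }
})

test_that("wcm and cluster extent respond monotonically to |t| and alpha", {
  set.seed(13)
  adj <- build_adjacency(toy_montage(4))
  tmat <- matrix(rnorm(10 * 4, sd = 2), 10, 4)
  map <- toy_stat_map(tmat, df = 20L)
  base <- form_clusters(map, adj, min_neighbor_channels = 0)
  # inflate one member's |t|: total |wcm| over that sign never decreases
  stopifnot(length(base) > 0)
  cl <- base[[1]]
  i <- cl$members[1, ]
  tmat2 <- tmat
  tmat2[i[1], i[2]] <- tmat2[i[1], i[2]] * 2
  after <- form_clusters(toy_stat_map(tmat2, df = 20L), adj,
                         min_neighbor_channels = 0)
  tot <- function(cls, pol) sum(vapply(
    Filter(function(c) c$polarity == pol, cls), function(c) abs(c$wcm), 0))
  expect_gte(tot(after, cl$polarity), tot(base, cl$polarity))

  # looser cluster-forming alpha never shrinks surviving member sets
  loose <- form_clusters(map, adj, cluster_alpha = 0.2,
                         min_neighbor_channels = 0)
  strict_pts <- do.call(rbind, lapply(base, `[[`, "members"))
  loose_pts <- do.call(rbind, lapply(loose, `[[`, "members"))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(strict_pts) %in% key(loose_pts)))
})

test_that("permutation test finds an overwhelming planted effect and is seeded", {
  set.seed(3)
  n_sub <- 8; vals <- c(10, 7, 4, 1) / 11
  pred <- rep(vals, n_sub)
  n_ti <- 10; n_el <- 4
  X <- matrix(rnorm(n_sub * 4 * n_ti * n_el, sd = 0.3), n_sub * 4)
  # plant a strong negative slope at electrodes 2-3, times 4-7
  for (e in 2:3) for (ti in 4:7)
    X[, (e - 1) * n_ti + ti] <- X[, (e - 1) * n_ti + ti] - 5 * pred
  attr(X, "n_time") <- n_ti
  adj <- build_adjacency(toy_montage(n_el))
  cfg <- permutation_config(n_permutations = 400, seed = 17,
                            min_neighbor_channels = 0)
  res <- permutation_test(X, vals, n_sub, adj, cfg)
  tb <- cluster_table(res)
  top <- tb[which.max(abs(tb$wcm)), ]
  expect_equal(top$polarity, "-")
  expect_true(top$significant)
  expect_lt(top$p_value, 0.05 / 2)

  res2 <- permutation_test(X, vals, n_sub, adj, cfg)
  expect_identical(cluster_table(res2), tb)
  expect_identical(res2$null_max, res$null_max)
})

test_that("cluster p-values are invariant under condition relabeling", {
  set.seed(23)
  n_sub <- 6; vals <- c(10, 7, 4, 1) / 11
  n_ti <- 8; n_el <- 3
  X <- matrix(rnorm(n_sub * 4 * n_ti * n_el), n_sub * 4)
  X[, 5] <- X[, 5] - 3 * rep(vals, n_sub)
  attr(X, "n_time") <- n_ti
  adj <- build_adjacency(toy_montage(n_el))
  cfg <- permutation_config(n_permutations = 2000, seed = 29,
                            min_neighbor_channels = 0)
  res <- permutation_test(X, vals, n_sub, adj, cfg)

  # relabel: reverse condition order together with the predictor values
  ord <- 4:1
  idx <- unlist(lapply(seq_len(n_sub), function(s) (s - 1) * 4 + ord))
  Xr <- X[idx, , drop = FALSE]
  attr(Xr, "n_time") <- n_ti
  resr <- permutation_test(Xr, vals[ord], n_sub, adj, cfg)

  # deterministic part identical
  expect_equal(resr$map$t, res$map$t, tolerance = 1e-12)
  tb <- cluster_table(res); tbr <- cluster_table(resr)
  expect_equal(tbr$wcm, tb$wcm, tolerance = 1e-12)
  # Monte Carlo part equal up to sampling noise
  expect_equal(tbr$p_value, tb$p_value, tolerance = 0.05)
})

test_that("window means reduce correctly", {
  m <- toy_montage(2)
  times <- seq(0, 0.099, by = 0.001)
  ave <- array(0, c(1, 2, 2, 2, length(times)),
               dimnames = list("S01", c("a", "b"), c("D", "S"),
                               m$labels, NULL))
  ave[1, , , , ] <- 3 # constant
  erps <- toy_erp_set(ave, times, m)
  expect_equal(unname(window_mean(erps, "E1", c(0.02, 0.04), "D")[1, ]),
               c(3, 3))

  # linear ramp: the window mean is the midpoint value
  ramp <- seq_along(times)
  ave[1, 1, 1, 1, ] <- ramp
  erps <- toy_erp_set(ave, times, m)
  expect_equal(window_mean(erps, "E1", c(0.010, 0.030), "D")[1, 1],
               mean(ramp[11:31]))
  # hand-built 5-sample window
  ave[1, 1, 1, 1, 1:5] <- c(1, 4, 2, 8, 5)
  erps <- toy_erp_set(ave, times, m)
  expect_equal(window_mean(erps, "E1", c(0, 0.004), "D")[1, 1], 4)
  expect_error(window_mean(erps, "E9", c(0, 0.004), "D"), "unknown channel")
  expect_error(window_mean(erps, "E1", c(0.5, 0.6), "D"), "no time samples")
})

test_that("Kruskal-Wallis wrapper reproduces the rank-sum formula", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(g)
  # H = 12/(N(N+1)) * sum(R_i^2 / n_i) - 3(N+1) with rank sums 6, 15, 24
  expect_equal(kw$statistic, 12 / 90 * (36 / 3 + 225 / 3 + 576 / 3) - 30,
               tolerance = 1e-10)
  expect_equal(kw$df, 2L)

  same <- kruskal_wallis(list(c(1, 1), c(1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  kw4 <- kruskal_wallis(list(1:3, 4:6, 7:9, 10:12))
  expect_equal(kw4$df, 3L)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Tukey-Kramer post hoc on ranks behaves at the extremes", {
  set.seed(8)
  a <- rnorm(20); b <- rnorm(20, 10)
  sep <- tukey_kramer_posthoc(list(lo = a, hi = b))
  expect_lt(sep$p_adj, 0.001)
  expect_true(sep$significant)

  same <- tukey_kramer_posthoc(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_gt(same$p_adj, 0.9)

  four <- tukey_kramer_posthoc(list(a = rnorm(5), b = rnorm(5),
                                    c = rnorm(5), d = rnorm(5)))
  expect_equal(nrow(four), 6)
  expect_equal(nrow(tukey_kramer_posthoc(list(a = 1:3))), 0)
})
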