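# Mass-univariate correlation-T maps over time x electrode, radius-based
# spatial adjacency, weighted-cluster-mass clustering, and within-subject
# Monte Carlo permutation p-values, plus confirmatory window tests.

#' Extract the dependent-measure matrix from an ERP set
#'
#' Flattens per-(subject, condition) ERPs of one analysis target into the
#' observations-by-points matrix consumed by the correlation map. Rows are
#' ordered subject-major (all conditions of subject 1, then subject 2, ...);
#' columns are electrode-major (`col = (electrode - 1) * n_time + time`).
#'
#' @param erps an `erp_set`.
#' @param target `"D"`, `"S"` or `"DW"` (difference wave).
#' @return numeric matrix `[n_subjects * n_conditions, n_electrodes * n_time]`
#'   with attributes `n_time`, `labels`, `times`, `n_subjects`,
#'   `conditions`.
#' @export
erp_dependent <- function(erps, target = c("D", "S", "DW")) {
  target <- match.arg(target)
  n_sub <- dim(erps$ave)[1]; n_cond <- dim(erps$ave)[2]
  n_ch <- dim(erps$ave)[4]; n_time <- dim(erps$ave)[5]
  a <- if (target == "DW") {
    if (is.null(erps$dw))
      stop("difference waves unavailable (S averages missing)", call. = FALSE)
    erps$dw
  } else {
    if (!target %in% dimnames(erps$ave)[[3]])
      stop("target ", target, " not present in this ERP set", call. = FALSE)
    arr <- erps$ave[, , target, , , drop = FALSE]
    array(arr, dim = dim(erps$ave)[-3], dimnames = dimnames(erps$ave)[-3])
  }
  # a: [subject, condition, channel, time]
  X <- matrix(NA_real_, n_sub * n_cond, n_ch * n_time)
  for (s in seq_len(n_sub)) for (cd in seq_len(n_cond)) {
    X[(s - 1L) * n_cond + cd, ] <- as.numeric(t(a[s, cd, , ]))
  }
  structure(X, n_time = n_time, labels = erps$montage$labels,
            times = erps$times, n_subjects = n_sub,
            conditions = erps$conditions)
}

# fast Pearson r of a predictor vector against all columns of a centered
# matrix with precomputed column sds (zero-variance columns -> r = 0)
.pearson_r_fast <- function(Xc, sdx, pred) {
  pc <- pred - mean(pred)
  r <- as.numeric(crossprod(pc, Xc)) / ((length(pred) - 1) * stats::sd(pred) * sdx)
  r[sdx == 0] <- 0
  r
}

.r_to_t <- function(r, df) r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-12))

#' Correlation-T map over time and electrode
#'
#' At every (time, electrode) point, the Pearson correlation between the
#' predictor (one value per subject-condition observation, e.g. p(S)) and
#' the ERP amplitude across all observations, with its T transform
#' `t = r * sqrt(df) / sqrt(1 - r^2)`, `df = n - 2`. Points with zero
#' variance in the dependent measure get r = 0 and a degenerate flag.
#'
#' @param X dependent matrix from [erp_dependent()] (observations x points).
#' @param pred numeric predictor, one value per row of `X`.
#' @param n_time number of time samples per electrode (column blocks of
#'   `X`); defaults to the attribute set by [erp_dependent()], or to
#'   `ncol(X)` (a single electrode) when absent.
#' @return An object of class `stat_map`: list with `r` and `t` (matrices
#'   `[n_time, n_electrode]`), `n_obs`, `df`, `degenerate` (logical matrix),
#'   `labels`, `times`.
#' @export
correlation_t_map <- function(X, pred, n_time = attr(X, "n_time")) {
  if (length(pred) != nrow(X))
    stop("`pred` must have one value per observation (row of X)", call. = FALSE)
  if (is.null(n_time)) n_time <- ncol(X)
  labels <- attr(X, "labels")
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sdx <- sqrt(colSums(Xc^2) / (n - 1))
  r <- .pearson_r_fast(Xc, sdx, pred)
  df <- n - 2L
  t <- .r_to_t(r, df)
  n_el <- length(r) / n_time
  structure(list(
    r = matrix(r, n_time, n_el),
    t = matrix(t, n_time, n_el),
    n_obs = n, df = df,
    degenerate = matrix(sdx == 0, n_time, n_el),
    labels = labels, times = attr(X, "times")
  ), class = "stat_map")
}

# connected components over supra-threshold points of one polarity.
# mask: logical [n_time, n_elec]; connectivity: same electrode at adjacent
# samples, or neighboring electrodes at the same sample.
.components <- function(mask, nb) {
  n_time <- nrow(mask); n_el <- ncol(mask)
  todo <- which(mask)
  comp <- integer(length(mask)) # 0 = unassigned
  comps <- list()
  for (seed in todo) {
    if (comp[seed] > 0L) next
    id <- length(comps) + 1L
    stack <- seed
    comp[seed] <- id
    members <- integer(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      tt <- (cur - 1L) %% n_time + 1L
      ee <- (cur - 1L) %/% n_time + 1L
      cand <- integer(0)
      if (tt > 1L) cand <- c(cand, cur - 1L)
      if (tt < n_time) cand <- c(cand, cur + 1L)
      if (length(nb[[ee]])) cand <- c(cand, (nb[[ee]] - 1L) * n_time + tt)
      cand <- cand[mask[cand] & comp[cand] == 0L]
      comp[cand] <- id
      stack <- c(stack, cand)
    }
    comps[[id]] <- members
  }
  comps
}

# per-point minimum-neighbor rule: a supra-threshold point survives only if
# at least `min_nb` neighboring electrodes are supra-threshold (same sign)
# at the same time sample
.apply_min_neighbors <- function(mask, nb, min_nb) {
  if (min_nb <= 0L) return(mask)
  keep <- mask
  for (e in seq_len(ncol(mask))) {
    cnt <- if (length(nb[[e]]))
      rowSums(mask[, nb[[e]], drop = FALSE]) else 0
    keep[, e] <- mask[, e] & cnt >= min_nb
  }
  keep
}

# cluster list for one polarity; excess = |t| - tcrit at member points
.clusters_one_sign <- function(tmat, tcrit, sign, nb, min_nb, rule, w) {
  mask <- if (sign > 0) tmat > tcrit else tmat < -tcrit
  if (!any(mask)) return(list())
  if (rule == "point") mask <- .apply_min_neighbors(mask, nb, min_nb)
  if (!any(mask)) return(list())
  comps <- .components(mask, nb)
  n_time <- nrow(tmat)
  out <- lapply(comps, function(m) {
    tt <- (m - 1L) %% n_time + 1L
    ee <- (m - 1L) %/% n_time + 1L
    excess <- abs(tmat[m]) - tcrit
    list(members = cbind(time = tt, electrode = ee),
         polarity = if (sign > 0) "+" else "-",
         wcm = sign * sum(excess^w),
         time_range = range(tt),
         electrodes = sort(unique(ee)))
  })
  if (rule == "cluster" && min_nb > 0L)
    out <- Filter(function(cl) length(cl$electrodes) >= min_nb, out)
  out
}

#' Form clusters from a statistic map
#'
#' Marks points whose |t| exceeds the two-tailed critical value at
#' `cluster_alpha` (with the map's df), splits them by sign, applies the
#' minimum-neighbor rule, and groups them into connected components, where
#' two points connect if they share an electrode at adjacent time samples or
#' are neighboring electrodes at the same sample. Each cluster's statistic
#' is the weighted cluster mass `wcm = sign * sum((|t| - t_crit)^wcm_weight)`
#' over its members.
#'
#' The default neighbor rule (`"point"`) retains a supra-threshold point
#' only if at least `min_neighbor_channels` of its neighboring electrodes
#' are supra-threshold with the same sign at that time sample. The
#' alternative `"cluster"` rule instead drops whole clusters spanning fewer
#' than `min_neighbor_channels` distinct electrodes.
#'
#' @param map a `stat_map`.
#' @param adj an `adjacency` over the map's electrodes.
#' @param cluster_alpha two-tailed point-wise threshold (default 0.05).
#' @param wcm_weight exponent on the supra-threshold excess (default 1).
#' @param min_neighbor_channels minimum neighbor count (default: from `adj`).
#' @param neighbor_rule `"point"` or `"cluster"` (see above).
#' @return list of clusters, each a list with `members` (matrix of
#'   time/electrode indices), `polarity`, `wcm`, `time_range`, `electrodes`;
#'   attribute `t_crit` carries the cluster-forming threshold.
#' @export
form_clusters <- function(map, adj, cluster_alpha = 0.05, wcm_weight = 1,
                          min_neighbor_channels = adj$min_neighbor_channels,
                          neighbor_rule = c("point", "cluster")) {
  neighbor_rule <- match.arg(neighbor_rule)
  if (length(adj$neighbors) != ncol(map$t))
    stop("adjacency and map electrode sets differ", call. = FALSE)
  tcrit <- stats::qt(1 - cluster_alpha / 2, map$df)
  cl <- c(.clusters_one_sign(map$t, tcrit, +1, adj$neighbors,
                             min_neighbor_channels, neighbor_rule, wcm_weight),
          .clusters_one_sign(map$t, tcrit, -1, adj$neighbors,
                             min_neighbor_channels, neighbor_rule, wcm_weight))
  attr(cl, "t_crit") <- tcrit
  cl
}

# max |wcm| per sign for one permuted predictor (0 when no cluster)
.max_wcm <- function(tmat, tcrit, nb, min_nb, rule, w) {
  pos <- .clusters_one_sign(tmat, tcrit, +1, nb, min_nb, rule, w)
  neg <- .clusters_one_sign(tmat, tcrit, -1, nb, min_nb, rule, w)
  c(pos = if (length(pos)) max(vapply(pos, `[[`, 0, "wcm")) else 0,
    neg = if (length(neg)) max(-vapply(neg, `[[`, 0, "wcm")) else 0)
}

#' Permutation-test configuration
#'
#' @param n_permutations Monte Carlo permutations (default 20000).
#' @param cluster_alpha two-tailed cluster-forming threshold (default 0.05).
#' @param final_alpha corrected two-tailed significance level (default 0.05;
#'   each polarity family is tested at `final_alpha / 2`).
#' @param wcm_weight weighted-cluster-mass exponent (default 1).
#' @param min_neighbor_channels per-point minimum neighbor count (default 2).
#' @param neighbor_rule `"point"` or `"cluster"` (see [form_clusters()]).
#' @param seed RNG seed for the permutation draws.
#' @return An object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 20000L, cluster_alpha = 0.05,
                               final_alpha = 0.05, wcm_weight = 1,
                               min_neighbor_channels = 2L,
                               neighbor_rule = "point", seed = 1L) {
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1", call. = FALSE)
  if (cluster_alpha <= 0 || cluster_alpha >= 1 ||
      final_alpha <= 0 || final_alpha >= 1)
    stop("alphas must lie in (0, 1)", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations),
                 cluster_alpha = cluster_alpha, final_alpha = final_alpha,
                 wcm_weight = wcm_weight,
                 min_neighbor_channels = as.integer(min_neighbor_channels),
                 neighbor_rule = match.arg(neighbor_rule,
                                           c("point", "cluster")),
                 seed = as.integer(seed)),
            class = "permutation_config")
}

#' Cluster-based permutation correlation test
#'
#' The full statistic: observed correlation-T map and clusters, then a Monte
#' Carlo null built by independently shuffling each subject's predictor
#' values across that subject's condition observations (within-subject
#' exchangeability of the repeated-measures design), recomputing the map and
#' clusters, and recording the maximum |wcm| per polarity. Each observed
#' cluster's p-value is `(1 + #{null maxima >= |wcm|}) / (1 + n_permutations)`
#' against its own polarity's null maxima (the add-one estimator, which
#' cannot return 0). A cluster is flagged significant when
#' `p < final_alpha / 2` (two-tailed correction over the two polarity
#' families).
#'
#' @param X dependent matrix from [erp_dependent()]; rows must be ordered
#'   subject-major with `length(pred_values)` conditions per subject.
#' @param pred_values the per-condition predictor levels (e.g. p(S) =
#'   10/11, 7/11, 4/11, 1/11).
#' @param n_subjects number of subjects (rows of `X` = `n_subjects *
#'   length(pred_values)`).
#' @param adj an `adjacency`.
#' @param cfg a `permutation_config`.
#' @return An object of class `cluster_test`: list with `map` (the observed
#'   `stat_map`), `clusters` (each augmented with `p_value` and
#'   `significant`), `null_max` (matrix of per-permutation max wcm per sign),
#'   `t_crit`, `cfg`.
#' @export
permutation_test <- function(X, pred_values, n_subjects, adj,
                             cfg = permutation_config()) {
  n_cond <- length(pred_values)
  if (nrow(X) != n_subjects * n_cond)
    stop("nrow(X) must equal n_subjects * length(pred_values)", call. = FALSE)
  if (n_cond < 2L) stop("need >= 2 predictor levels", call. = FALSE)
  pred <- rep(as.numeric(pred_values), times = n_subjects)

  map <- correlation_t_map(X, pred)
  clusters <- form_clusters(map, adj, cfg$cluster_alpha, cfg$wcm_weight,
                            cfg$min_neighbor_channels, cfg$neighbor_rule)
  tcrit <- attr(clusters, "t_crit")

  n_time <- nrow(map$t)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sdx <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
  nb <- adj$neighbors

  set.seed(cfg$seed)
  null_max <- matrix(0, cfg$n_permutations, 2,
                     dimnames = list(NULL, c("pos", "neg")))
  vals <- as.numeric(pred_values)
  for (b in seq_len(cfg$n_permutations)) {
    perm <- as.numeric(vapply(seq_len(n_subjects),
                              function(s) vals[sample.int(n_cond)],
                              numeric(n_cond)))
    r <- .pearson_r_fast(Xc, sdx, perm)
    tmat <- matrix(.r_to_t(r, map$df), n_time)
    null_max[b, ] <- .max_wcm(tmat, tcrit, nb, cfg$min_neighbor_channels,
                              cfg$neighbor_rule, cfg$wcm_weight)
  }

  clusters <- lapply(clusters, function(cl) {
    nulls <- if (cl$wcm > 0) null_max[, "pos"] else null_max[, "neg"]
    cl$p_value <- (1 + sum(nulls >= abs(cl$wcm))) / (1 + cfg$n_permutations)
    cl$significant <- cl$p_value < cfg$final_alpha / 2
    cl
  })
  res <- list(map = map, clusters = clusters, null_max = null_max,
              t_crit = tcrit, cfg = cfg)
  if (cfg$n_permutations < 2 / cfg$final_alpha)
    res$warning <- "n_permutations too small to resolve final_alpha/2"
  structure(res, class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Cluster-based permutation correlation test:",
      length(x$clusters), "cluster(s),",
      x$cfg$n_permutations, "permutations, t_crit =",
      round(x$t_crit, 3), "\n")
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: wcm = %.2f, p = %.4g%s, %d points, %d electrodes\n",
                cl$polarity, cl$wcm, cl$p_value,
                if (cl$significant) " *" else "",
                nrow(cl$members), length(cl$electrodes)))
  }
  invisible(x)
}

#' Summarize clusters as a data.frame
#'
#' @param test a `cluster_test`.
#' @return data.frame: polarity, wcm, p_value, significant, t_start_ms,
#'   t_end_ms, electrodes (comma-separated labels), n_points.
#' @export
cluster_table <- function(test) {
  if (!length(test$clusters))
    return(data.frame(polarity = character(), wcm = numeric(),
                      p_value = numeric(), significant = logical(),
                      t_start_ms = numeric(), t_end_ms = numeric(),
                      electrodes = character(), n_points = integer()))
  times <- test$map$times
  labels <- test$map$labels
  do.call(rbind, lapply(test$clusters, function(cl) data.frame(
    polarity = cl$polarity, wcm = cl$wcm, p_value = cl$p_value,
    significant = cl$significant,
    t_start_ms = if (!is.null(times)) 1000 * times[cl$time_range[1]] else cl$time_range[1],
    t_end_ms = if (!is.null(times)) 1000 * times[cl$time_range[2]] else cl$time_range[2],
    electrodes = if (!is.null(labels))
      paste(labels[cl$electrodes], collapse = ",") else
        paste(cl$electrodes, collapse = ","),
    n_points = nrow(cl$members))))
}

#' Mean ERP amplitude in a time window at one channel
#'
#' @param erps an `erp_set`.
#' @param channel channel label (e.g. "Fz").
#' @param window closed time window in seconds (e.g. `c(0.160, 0.180)`).
#' @param target `"D"`, `"S"` or `"DW"`.
#' @return matrix `[subject, condition]` of window means.
#' @export
window_mean <- function(erps, channel = "Fz", window = c(0.160, 0.180),
                        target = c("D", "S", "DW")) {
  target <- match.arg(target)
  ch <- match(channel, erps$montage$labels)
  if (is.na(ch)) stop("unknown channel: ", channel, call. = FALSE)
  idx <- .window_index(erps$times, window)
  a <- if (target == "DW") erps$dw[, , ch, idx, drop = FALSE] else
    erps$ave[, , target, ch, idx, drop = FALSE]
  m <- apply(a, c(1, 2), mean)
  dimnames(m) <- dimnames(erps$ave)[1:2]
  m
}

#' Kruskal-Wallis test across condition groups
#'
#' Rank-based H statistic with tie correction (via [stats::kruskal.test()]),
#' df = number of groups - 1, p from the chi-square approximation. When all
#' values are identical the statistic is 0 and p = 1.
#'
#' @param groups list of numeric vectors, one per condition.
#' @return list with `statistic` (H / chi-square), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(!lengths(groups))) stop("all groups must be non-empty", call. = FALSE)
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(list(statistic = 0, df = length(groups) - 1L, p_value = 1))
  k <- stats::kruskal.test(groups)
  list(statistic = unname(k$statistic), df = unname(k$parameter),
       p_value = k$p.value)
}

#' Tukey-Kramer post hoc comparisons on ranks
#'
#' Nonparametric pairwise follow-up to [kruskal_wallis()]: values are
#' rank-transformed jointly, group mean ranks are compared with the
#' studentized-range distribution using the tie-corrected rank variance
#' `N (N + 1) / 12`, the convention of the standard Kruskal-Wallis
#' multiple-comparison procedure.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return data.frame: group1, group2, diff_mean_rank, q, p_adj, significant.
#'   Empty for a single group.
#' @export
tukey_kramer_posthoc <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2L)
    return(data.frame(group1 = character(), group2 = character(),
                      diff_mean_rank = numeric(), q = numeric(),
                      p_adj = numeric(), significant = logical()))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  rk <- rank(vals)
  N <- length(vals)
  # tie-corrected variance of the ranks
  ties <- table(vals)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  s2 <- N * (N + 1) / 12 * tie_corr
  mean_rank <- tapply(rk, g, mean)[names(groups)]
  n_i <- lengths(groups)
  pairs <- utils::combn(names(groups), 2)
  out <- apply(pairs, 2, function(pr) {
    d <- abs(mean_rank[pr[1]] - mean_rank[pr[2]])
    se <- sqrt(s2 * (1 / n_i[pr[1]] + 1 / n_i[pr[2]]) / 2)
    q <- if (se == 0) 0 else d / se
    p <- if (se == 0) 1 else
      stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2], diff_mean_rank = unname(d),
               q = unname(q), p_adj = unname(p),
               significant = unname(p < alpha))
  })
  do.call(rbind, out)
}
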