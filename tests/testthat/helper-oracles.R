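# Shared fixtures and independent oracles.

# linear toy montage: n electrodes on a line, unit spacing; radius 1.1 makes
# a chain adjacency
toy_montage <- function(n) {
  structure(list(
    labels = paste0("E", seq_len(n)),
    coords = data.frame(label = paste0("E", seq_len(n)),
                        x = as.numeric(seq_len(n)), y = 0, scalp = TRUE,
                        stringsAsFactors = FALSE),
    neighbor_radius = 1.1
  ), class = "montage")
}

# wrap a bare t-matrix [n_time, n_elec] as a stat_map
toy_stat_map <- function(tmat, df = 20L, times = NULL, labels = NULL) {
  structure(list(
    r = tmat / sqrt(tmat^2 + df), t = tmat, n_obs = df + 2L, df = df,
    degenerate = matrix(FALSE, nrow(tmat), ncol(tmat)),
    labels = labels, times = times
  ), class = "stat_map")
}

# independent connected-components oracle over supra-threshold points of a
# t-matrix (both polarities, no minimum-neighbor rule), built on igraph
brute_clusters <- function(tmat, tcrit, neighbors, weight = 1) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- if (sgn > 0) tmat > tcrit else tmat < -tcrit
    pts <- which(mask, arr.ind = TRUE) # time, elec
    if (!nrow(pts)) next
    key <- paste(pts[, 1], pts[, 2])
    edges <- character(0)
    for (i in seq_len(nrow(pts))) {
      t0 <- pts[i, 1]; e0 <- pts[i, 2]
      if (t0 < nrow(tmat) && mask[t0 + 1, e0])
        edges <- c(edges, paste(t0, e0), paste(t0 + 1, e0))
      for (e1 in neighbors[[e0]])
        if (mask[t0, e1])
          edges <- c(edges, paste(t0, e0), paste(t0, e1))
    }
    g <- igraph::make_empty_graph(directed = FALSE) |>
      igraph::add_vertices(length(key), name = key)
    if (length(edges)) g <- igraph::add_edges(g, match(edges, key))
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      members <- pts[comp == cid, , drop = FALSE]
      excess <- abs(tmat[members]) - tcrit
      out[[length(out) + 1L]] <- list(
        polarity = if (sgn > 0) "+" else "-",
        wcm = sgn * sum(excess^weight),
        members = members[order(members[, 2], members[, 1]), , drop = FALSE])
    }
  }
  out
}

# canonical form for comparing cluster lists regardless of ordering
cluster_signature <- function(clusters) {
  sigs <- vapply(clusters, function(cl) {
    m <- cl$members
    m <- m[order(m[, 2], m[, 1]), , drop = FALSE]
    paste(cl$polarity, sprintf("%.10f", cl$wcm),
          paste(m[, 1], m[, 2], sep = ":", collapse = ","))
  }, character(1))
  sort(sigs)
}

# all permutations of 1..n (n small), by inserting n at every position
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# small erp_set for window/dependent tests: ave [sub, cond, type, chan, time]
toy_erp_set <- function(ave, times, montage,
                        conditions = stats::setNames(
                          seq_len(dim(ave)[2]) / dim(ave)[2],
                          dimnames(ave)[[2]])) {
  dw <- if (all(c("D", "S") %in% dimnames(ave)[[3]])) {
    d <- ave[, , "D", , , drop = FALSE] - ave[, , "S", , , drop = FALSE]
    array(d, dim = dim(ave)[-3], dimnames = dimnames(ave)[-3])
  } else NULL
  structure(list(
    ave = ave, dw = dw,
    counts = array(1L, dim(ave)[1:3], dimnames(ave)[1:3]),
    missing = array(FALSE, dim(ave)[1:3], dimnames(ave)[1:3]),
    times = times, fs = 1 / diff(times[1:2]), montage = montage,
    conditions = conditions
  ), class = "erp_set")
}
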