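# 10-20 montage geometry and radius-based electrode adjacency.

# Polar layout of the 13-channel montage: azimuth in degrees from the nose
# (positive to the right), radius normalized so the 10-20 outer scalp ring
# (Fp1/Fp2/T3/T4) sits at 1. Mastoids project slightly outside the disc.
.montage_polar <- data.frame(
  label  = c("Fp1", "Fp2", "F3", "Fz", "F4", "T3", "C3", "C4", "T4",
             "Cz", "Pz", "M1", "M2"),
  theta  = c(-18,    18,  -39.9,  0,  39.9, -90,  -90,   90,   90,
               0,   180,  -115,  115),
  radius = c(1,       1,  0.652, 0.5, 0.652,  1,   0.5,  0.5,   1,
               0,    0.5,  1.13, 1.13),
  scalp  = c(rep(TRUE, 11), FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' Default 13-channel 10-20 montage
#'
#' Eleven scalp electrodes (Fp1, Fp2, F3, Fz, F4, T3, C3, C4, T4, Cz, Pz)
#' plus the two mastoids (M1, M2), in a 2D polar projection with the head
#' radius normalized to 1 (mastoids sit just outside the disc). The default
#' `neighbor_radius` of 0.55 layout units yields a connected scalp neighbor
#' graph in which midline/frontal electrodes have 3-5 neighbors, the usual
#' nearest-neighbor structure of a sparse 10-20 cap.
#'
#' @param neighbor_radius adjacency radius in layout units (default 0.55).
#' @return An object of class `montage`: list with `labels`, `coords`
#'   (data.frame label/x/y/scalp) and `neighbor_radius`.
#' @export
make_default_montage <- function(neighbor_radius = 0.55) {
  p <- .montage_polar
  coords <- data.frame(
    label = p$label,
    x = p$radius * sinpi(p$theta / 180),
    y = p$radius * cospi(p$theta / 180),
    scalp = p$scalp,
    stringsAsFactors = FALSE
  )
  structure(list(labels = coords$label, coords = coords,
                 neighbor_radius = neighbor_radius),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("Montage:", length(x$labels), "channels (",
      sum(x$coords$scalp), "scalp +", sum(!x$coords$scalp), "mastoid ),",
      "neighbor radius", x$neighbor_radius, "\n")
  invisible(x)
}

#' Write a montage as a plain-text label/x/y table
#' @param montage a `montage`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_montage_tsv <- function(montage, path) {
  utils::write.table(montage$coords, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a radius-based electrode adjacency graph
#'
#' Two electrodes are neighbors iff the 2D Euclidean distance between them is
#' positive and at most `radius` (a circle centered at each electrode,
#' mirroring the neighborhood definition used for spatial clustering).
#' The graph is symmetric and irreflexive by construction.
#'
#' @param montage a `montage`.
#' @param radius neighborhood radius in layout units; defaults to the
#'   montage's `neighbor_radius`.
#' @param min_neighbor_channels minimum number of supra-threshold neighbors a
#'   point needs to enter a cluster (carried as metadata; default 2).
#' @return An object of class `adjacency`: list with `labels`, `neighbors`
#'   (list of integer vectors), `radius`, `min_neighbor_channels`.
#' @export
build_adjacency <- function(montage, radius = montage$neighbor_radius,
                            min_neighbor_channels = 2L) {
  if (!is.numeric(radius) || radius <= 0)
    stop("`radius` must be positive", call. = FALSE)
  xy <- as.matrix(montage$coords[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  nb <- lapply(seq_len(nrow(d)), function(i)
    which(d[i, ] > 0 & d[i, ] <= radius))
  structure(list(labels = montage$labels, neighbors = nb, radius = radius,
                 min_neighbor_channels = as.integer(min_neighbor_channels)),
            class = "adjacency")
}

#' Is the adjacency graph connected over a channel subset?
#' @param adj an `adjacency`.
#' @param channels integer indices to check (default: all).
#' @return logical.
#' @export
adjacency_connected <- function(adj, channels = seq_along(adj$labels)) {
  if (length(channels) <= 1L) return(TRUE)
  seen <- channels[1L]
  frontier <- seen
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(adj$neighbors[frontier])),
                             channels), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(channels)
}
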