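# Epochs -> condition-level ERPs: trial selection, baseline correction,
# joint-probability epoch rejection, averaging, zero-phase low-pass,
# difference waves.

#' Preprocessing configuration
#'
#' @param baseline_window baseline window in seconds (default `c(-0.1, 0)`).
#' @param rejection_z z threshold (SD units) for joint-probability epoch
#'   rejection (default 3).
#' @param n_bins histogram bins for the empirical value distribution used by
#'   the rejection statistic (default 50).
#' @param lowpass_cutoff low-pass cutoff in Hz (default 25).
#' @param filter_order Butterworth order, applied forward and reverse
#'   (default 6).
#' @param reject logical; apply epoch rejection (default TRUE).
#' @param select_rule trial selection rule; only
#'   `"D_and_closest_preceding_S"` is defined.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(baseline_window = c(-0.1, 0), rejection_z = 3,
                            n_bins = 50L, lowpass_cutoff = 25,
                            filter_order = 6L, reject = TRUE,
                            select_rule = "D_and_closest_preceding_S") {
  if (rejection_z <= 0) stop("`rejection_z` must be positive", call. = FALSE)
  structure(list(baseline_window = baseline_window,
                 rejection_z = rejection_z, n_bins = as.integer(n_bins),
                 lowpass_cutoff = lowpass_cutoff,
                 filter_order = as.integer(filter_order),
                 reject = isTRUE(reject),
                 select_rule = match.arg(select_rule,
                                         "D_and_closest_preceding_S")),
            class = "pipeline_config")
}

#' Select Deviant events and their closest preceding Standards
#'
#' For every Deviant event in a sequence, finds the nearest Standard event
#' strictly earlier in the sequence. Deviants with no preceding Standard
#' (possible only at the very start of a block) are dropped.
#'
#' @param seq a `stimulus_sequence` (or any list with a `roles` character
#'   vector of "S"/"D"/"F" labels).
#' @return data.frame with columns `d_event` and `s_event` (event indices).
#' @export
select_trials <- function(seq) {
  roles <- seq$roles
  d_idx <- which(roles == "D")
  last_s <- integer(length(roles))
  cur <- NA_integer_
  for (i in seq_along(roles)) {
    last_s[i] <- cur
    if (roles[i] == "S") cur <- i
  }
  s_for_d <- last_s[d_idx]
  keep <- !is.na(s_for_d)
  data.frame(d_event = d_idx[keep], s_event = s_for_d[keep])
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window.
#' Idempotent.
#'
#' @param epochs array `[epoch, channel, time]` or matrix `[channel, time]`.
#' @param times time axis in seconds.
#' @param window baseline window in seconds (closed at the left, open at 0 is
#'   immaterial on the sample grid; samples with `window[1] <= t <= window[2]`
#'   are used).
#' @return epochs with zero-mean baselines, same shape as the input.
#' @export
baseline_correct <- function(epochs, times, window = c(-0.1, 0)) {
  idx <- .window_index(times, window)
  if (is.matrix(epochs)) {
    return(epochs - rowMeans(epochs[, idx, drop = FALSE]))
  }
  stopifnot(length(dim(epochs)) == 3L)
  d <- dim(epochs)
  bl <- rowMeans(matrix(epochs[, , idx, drop = FALSE], nrow = d[1] * d[2]))
  epochs - array(bl, dim = d) # baseline means recycle over the time axis
}

#' Joint-probability epoch rejection
#'
#' Scores each epoch by how improbable its values are under the empirical
#' value distribution across all epochs: per channel, a 1D histogram density
#' (`n_bins` bins) is estimated from all epochs pooled, and an epoch's
#' channel score is its mean log-probability; a global score averages over
#' channels. Both scores are z-normalized across epochs and an epoch is
#' excluded when |z| exceeds `z` on any channel score or on the global
#' score. Constant score distributions (e.g. identical epochs) yield z = 0
#' and no rejection.
#'
#' @param epochs array `[epoch, channel, time]` with at least 10 epochs.
#' @param z rejection threshold in SD units (default 3).
#' @param n_bins histogram bins (default 50).
#' @return list with `kept` (the retained epochs array), `kept_idx`, and
#'   `log` (data.frame: epoch, global_z, max_channel_z, rejected).
#' @export
reject_improbable <- function(epochs, z = 3, n_bins = 50L) {
  stopifnot(length(dim(epochs)) == 3L)
  n_ep <- dim(epochs)[1]
  if (n_ep < 10L)
    stop("joint-probability rejection needs >= 10 epochs (got ", n_ep, ")",
         call. = FALSE)
  n_ch <- dim(epochs)[2]
  scores <- matrix(0, n_ep, n_ch)
  for (c in seq_len(n_ch)) {
    vals <- epochs[, c, ] # epoch x time
    rng <- range(vals)
    if (rng[1] == rng[2]) next # constant channel -> zero scores
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    bin <- findInterval(vals, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    p <- tabulate(bin, nbins = n_bins) / length(vals)
    p <- pmax(p, 0.5 / length(vals)) # floor empty bins
    lp <- matrix(log(p)[bin], nrow = n_ep)
    scores[, c] <- rowMeans(lp)
  }
  zmat <- apply(scores, 2, function(s) {
    sd_s <- stats::sd(s)
    if (!is.finite(sd_s) || sd_s == 0) rep(0, length(s))
    else (s - mean(s)) / sd_s
  })
  zmat <- matrix(zmat, nrow = n_ep)
  g <- rowMeans(scores)
  sd_g <- stats::sd(g)
  gz <- if (!is.finite(sd_g) || sd_g == 0) rep(0, n_ep) else (g - mean(g)) / sd_g
  rejected <- abs(gz) > z | apply(abs(zmat), 1, max) > z
  list(
    kept = epochs[!rejected, , , drop = FALSE],
    kept_idx = which(!rejected),
    log = data.frame(epoch = seq_len(n_ep), global_z = gz,
                     max_channel_z = apply(abs(zmat), 1, max),
                     rejected = rejected)
  )
}

#' Zero-phase Butterworth low-pass
#'
#' Forward-reverse application of an order-`order` Butterworth low-pass
#' (effective magnitude response squared, zero phase shift).
#'
#' @param x numeric vector, or matrix `[channel, time]` filtered row-wise.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (must be below Nyquist).
#' @param order filter order (default 6).
#' @return filtered data, same shape.
#' @export
lowpass_zero_phase <- function(x, fs, cutoff = 25, order = 6L) {
  if (cutoff >= fs / 2) stop("`cutoff` must be below Nyquist", call. = FALSE)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (is.matrix(x)) {
    t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Average epochs into ERPs, filter, and form difference waves
#'
#' Per (subject, condition, tone type) cell: arithmetic mean over epochs,
#' then the zero-phase 25 Hz Butterworth low-pass applied to the average
#' (not to single trials). Difference waves are Deviant minus Standard
#' averages, computed after filtering (the filter is linear, so the order
#' relative to subtraction is immaterial). Empty cells are flagged missing,
#' never imputed.
#'
#' @param collection an `epoch_collection` (optionally already
#'   baseline-corrected / rejected via [preprocess()]).
#' @param cfg a `pipeline_config`.
#' @return An object of class `erp_set`: list with `ave` (array
#'   `[subject, condition, type, channel, time]`), `dw` (array
#'   `[subject, condition, channel, time]`), `counts`
#'   (`[subject, condition, type]`), `missing` (logical like `counts`),
#'   `times`, `fs`, `montage`, `conditions`.
#' @export
average_and_filter <- function(collection, cfg = pipeline_config()) {
  subs <- names(collection$data)
  conds <- names(collection$conditions)
  types <- intersect(c("D", "S"), names(collection$data[[1]][[1]]))
  labels <- collection$montage$labels
  n_time <- length(collection$times)
  ave <- array(NA_real_,
               dim = c(length(subs), length(conds), length(types),
                       length(labels), n_time),
               dimnames = list(subs, conds, types, labels, NULL))
  counts <- array(0L, dim = c(length(subs), length(conds), length(types)),
                  dimnames = list(subs, conds, types))
  missing <- array(FALSE, dim = dim(counts), dimnames = dimnames(counts))
  for (s in seq_along(subs)) for (cd in seq_along(conds))
    for (tt in seq_along(types)) {
    ep <- collection$data[[s]][[conds[cd]]][[types[tt]]]
    if (is.null(ep) || dim(ep)[1] == 0L) {
      missing[s, cd, tt] <- TRUE
      next
    }
    counts[s, cd, tt] <- dim(ep)[1]
    m <- colMeans(ep, dims = 1)
    ave[s, cd, tt, , ] <- lowpass_zero_phase(m, collection$fs,
                                             cfg$lowpass_cutoff,
                                             cfg$filter_order)
  }
  dw <- if (all(c("D", "S") %in% types)) {
    d <- ave[, , "D", , , drop = FALSE] - ave[, , "S", , , drop = FALSE]
    array(d, dim = dim(ave)[-3], dimnames = dimnames(ave)[-3])
  } else NULL
  structure(list(ave = ave, dw = dw, counts = counts, missing = missing,
                 times = collection$times, fs = collection$fs,
                 montage = collection$montage,
                 conditions = collection$conditions),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  cat("ERP set:", dim(x$ave)[1], "subjects x", dim(x$ave)[2],
      "conditions x {D, S, DW};", dim(x$ave)[4], "channels,",
      dim(x$ave)[5], "samples\n")
  if (any(x$missing)) cat("  WARNING:", sum(x$missing), "missing cells\n")
  invisible(x)
}

#' Full preprocessing: baseline correction, rejection, averaging, filtering
#'
#' Applies [baseline_correct()] and (optionally) [reject_improbable()] to
#' every cell of an epoch collection, then [average_and_filter()].
#'
#' @param collection an `epoch_collection`.
#' @param cfg a `pipeline_config`.
#' @return list with `erps` (an `erp_set`) and `rejection` (data.frame:
#'   subject, condition, type, n_in, n_kept).
#' @export
preprocess <- function(collection, cfg = pipeline_config()) {
  rej <- list()
  for (s in names(collection$data)) {
    for (cd in names(collection$conditions)) {
      for (tt in c("D", "S")) {
        ep <- collection$data[[s]][[cd]][[tt]]
        if (is.null(ep)) next
        ep <- baseline_correct(ep, collection$times, cfg$baseline_window)
        n_in <- dim(ep)[1]
        if (cfg$reject && n_in >= 10L) {
          r <- reject_improbable(ep, cfg$rejection_z, cfg$n_bins)
          ep <- r$kept
        }
        collection$data[[s]][[cd]][[tt]] <- ep
        rej[[length(rej) + 1L]] <- data.frame(
          subject = s, condition = cd, type = tt,
          n_in = n_in, n_kept = dim(ep)[1])
      }
    }
  }
  list(erps = average_and_filter(collection, cfg),
       rejection = do.call(rbind, rej))
}
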