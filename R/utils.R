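# Shared helpers.

#' Derive a stage seed from a master seed
#'
#' Deterministic splitting rule so pipeline stages (sequence generation,
#' simulation of each subject, permutation draws, ...) can be rerun
#' independently while sharing one master seed. A small multiplicative hash
#' keeps the result a valid positive 32-bit integer.
#'
#' @param master master seed (integer).
#' @param stage stage index (integer; give each consumer a distinct one).
#' @return positive integer seed below 2^31.
#' @export
split_seed <- function(master, stage) {
  m <- 2147483629 # large prime below 2^31
  s <- (as.double(master) %% m) * 48271 + as.double(stage) * 16807 + 1
  as.integer(s %% m + 1)
}

# mean over a closed time window; `times` in seconds
.window_index <- function(times, window) {
  idx <- which(times >= window[1] & times <= window[2])
  if (!length(idx))
    stop("window [", window[1], ", ", window[2],
         "] contains no time samples", call. = FALSE)
  idx
}
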