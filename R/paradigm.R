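# Oddball paradigm: tone alphabet, microsequence-based sequence generation,
# validation, and pure-tone audio synthesis.

#' Build an equal-temperament tone alphabet
#'
#' Constructs the stimulus alphabet used by the precision-manipulated oddball
#' paradigm: `n_tones` pure-tone frequencies spaced `step` semitones apart
#' starting at `base_frequency`, i.e. `f[k] = base * 2^(step * (k-1) / 12)`.
#' For the canonical 11-tone alphabet (440 Hz base, 3-semitone steps) the
#' Standard role is assigned to 880 Hz (index 5) and the Deviant to 1046.5 Hz
#' (index 6); the remaining nine tones act as equiprobable fillers. Indices
#' are 1-based.
#'
#' @param base_frequency lowest frequency in Hz (default 440, A4).
#' @param step spacing between consecutive tones in semitones (default 3).
#' @param n_tones number of tones (default 11; must be >= 3).
#' @param s_index,d_index positions of the Standard and Deviant tones.
#'   Defaults follow the 880/1046.5 Hz design (5 and 6).
#' @return An object of class `tone_set`: list with `base_frequency`, `step`,
#'   `n_tones`, `frequencies` (full double precision), `s_index`, `d_index`,
#'   `filler_indices`.
#' @examples
#' ts <- build_tone_set()
#' round(ts$frequencies, 2)
#' @export
build_tone_set <- function(base_frequency = 440, step = 3, n_tones = 11,
                           s_index = if (n_tones == 11) 5L else 1L,
                           d_index = if (n_tones == 11) 6L else 2L) {
  if (!is.numeric(base_frequency) || base_frequency <= 0)
    stop("`base_frequency` must be a positive number", call. = FALSE)
  if (n_tones < 2)
    stop("`n_tones` must be at least 2 (need S and D roles)", call. = FALSE)
  s_index <- as.integer(s_index); d_index <- as.integer(d_index)
  if (s_index == d_index || s_index < 1L || d_index < 1L ||
      s_index > n_tones || d_index > n_tones)
    stop("`s_index` and `d_index` must be distinct positions in 1..n_tones",
         call. = FALSE)
  freqs <- base_frequency * 2^(step * (seq_len(n_tones) - 1L) / 12)
  structure(list(
    base_frequency = base_frequency,
    step = step,
    n_tones = as.integer(n_tones),
    frequencies = freqs,
    s_index = s_index,
    d_index = d_index,
    filler_indices = setdiff(seq_len(n_tones), c(s_index, d_index))
  ), class = "tone_set")
}

#' @export
print.tone_set <- function(x, ...) {
  cat("Tone set:", x$n_tones, "tones,", x$step, "semitone steps from",
      x$base_frequency, "Hz\n")
  cat("  S =", round(x$frequencies[x$s_index], 2), "Hz (index", x$s_index,
      ") | D =", round(x$frequencies[x$d_index], 2), "Hz (index", x$d_index, ")\n")
  invisible(x)
}

#' Specify one condition sequence
#'
#' A sequence is built by concatenating `n_micro` microsequences of
#' `micro_len` tones. Each microsequence contains exactly `p_s_numerator`
#' Standard tones, one Deviant, and fillers drawn equiprobably (with
#' replacement) from the nine filler tones, so that over a full block
#' p(S) = p_s_numerator/11 and p(D) = 1/11. The four study conditions differ
#' only in p(S): oddball 10/11, high 7/11 (high confidence), low 4/11
#' (low confidence), random 1/11 (with no tone repetition allowed anywhere).
#'
#' @param condition one of "oddball", "high", "low", "random".
#' @param p_s_numerator Standard count per microsequence; defaults to the
#'   study value for `condition` (10, 7, 4, 1).
#' @param n_micro number of microsequences (default 150).
#' @param micro_len tones per microsequence (default 11).
#' @param soa stimulus onset asynchrony in ms (default 333).
#' @param tone_duration tone duration in ms (default 50).
#' @param ramp rise/fall ramp duration in ms (default 5).
#' @param audio_rate audio sampling rate in Hz (default 44100).
#' @param seed RNG seed for sequence generation.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(condition = c("oddball", "high", "low", "random"),
                          p_s_numerator = NULL, n_micro = 150L,
                          micro_len = 11L, soa = 333, tone_duration = 50,
                          ramp = 5, audio_rate = 44100, seed = 1L) {
  condition <- match.arg(condition)
  default_ps <- c(oddball = 10L, high = 7L, low = 4L, random = 1L)
  if (is.null(p_s_numerator)) p_s_numerator <- default_ps[[condition]]
  p_s_numerator <- as.integer(p_s_numerator)
  if (p_s_numerator < 1L || p_s_numerator > micro_len - 1L)
    stop("`p_s_numerator` must leave room for one D tone per microsequence",
         call. = FALSE)
  if (soa <= tone_duration)
    stop("`soa` must exceed `tone_duration`", call. = FALSE)
  structure(list(
    condition = condition,
    p_s_numerator = p_s_numerator,
    p_d_numerator = 1L,
    n_micro = as.integer(n_micro),
    micro_len = as.integer(micro_len),
    soa = soa,
    tone_duration = tone_duration,
    ramp = ramp,
    audio_rate = audio_rate,
    seed = as.integer(seed)
  ), class = "sequence_spec")
}

#' Probability of the Standard tone implied by a sequence spec
#' @param spec a `sequence_spec`.
#' @return p(S) as a double (numerator / microsequence length).
#' @export
p_standard <- function(spec) spec$p_s_numerator / spec$micro_len

# One microsequence attempt: fixed role multiset, uniform shuffle.
.micro_attempt <- function(spec, ts) {
  n_f <- spec$micro_len - spec$p_s_numerator - 1L
  tones <- c(rep(ts$s_index, spec$p_s_numerator), ts$d_index,
             if (n_f > 0L) sample(ts$filler_indices, n_f, replace = TRUE))
  roles <- c(rep("S", spec$p_s_numerator), "D", rep("F", n_f))
  ord <- sample.int(spec$micro_len)
  list(tones = tones[ord], roles = roles[ord])
}

#' Generate one microsequence
#'
#' Draws the fixed role multiset (p_s_numerator Standards, one Deviant,
#' equiprobable fillers with replacement) and shuffles it uniformly. If the
#' first tone equals `forbidden_first` (the tone ending the previous
#' microsequence) the whole microsequence is regenerated, except when that
#' tone is the Standard in the oddball/high/low conditions. In the random
#' condition no two consecutive tones may share a frequency, within the
#' microsequence and across its boundary, enforced the same way.
#'
#' @param spec a `sequence_spec`.
#' @param ts a `tone_set`.
#' @param forbidden_first tone index that must not open this microsequence,
#'   or `NULL` at the start of a block.
#' @param max_retry regeneration budget before a constraint-failure error.
#' @return list with integer vector `tones` and character vector `roles`.
#' @export
generate_microsequence <- function(spec, ts, forbidden_first = NULL,
                                   max_retry = 1000L) {
  random_cond <- identical(spec$condition, "random")
  for (i in seq_len(max_retry)) {
    m <- .micro_attempt(spec, ts)
    if (random_cond) {
      if (any(diff(m$tones) == 0L)) next
      if (!is.null(forbidden_first) && m$tones[1L] == forbidden_first) next
    } else {
      # only the Standard tone is exempt from the boundary-repetition rule
      if (!is.null(forbidden_first) && m$tones[1L] == forbidden_first &&
          m$tones[1L] != ts$s_index) next
    }
    return(m)
  }
  stop("could not satisfy microsequence constraints within ", max_retry,
       " retries", call. = FALSE)
}

#' Generate a full condition sequence
#'
#' Concatenates `spec$n_micro` microsequences (1650 tones at the study
#' defaults), enforcing the cross-boundary repetition rule by full
#' microsequence regeneration. Deterministic given `spec$seed`.
#'
#' @param spec a `sequence_spec`.
#' @param ts a `tone_set`.
#' @return An object of class `stimulus_sequence`: list with `tone_indices`,
#'   `roles`, `onsets` (ms, `(k-1) * soa`), `micro_boundaries` (start index of
#'   each microsequence) and the generating `spec`.
#' @export
generate_sequence <- function(spec, ts = build_tone_set()) {
  stopifnot(inherits(spec, "sequence_spec"), inherits(ts, "tone_set"))
  set.seed(spec$seed)
  n <- spec$n_micro * spec$micro_len
  tones <- integer(n); roles <- character(n)
  last_tone <- NULL
  for (m in seq_len(spec$n_micro)) {
    ms <- generate_microsequence(spec, ts, forbidden_first = last_tone)
    idx <- ((m - 1L) * spec$micro_len + 1L):(m * spec$micro_len)
    tones[idx] <- ms$tones
    roles[idx] <- ms$roles
    last_tone <- ms$tones[spec$micro_len]
  }
  structure(list(
    tone_indices = tones,
    roles = roles,
    onsets = (seq_len(n) - 1) * spec$soa,
    micro_boundaries = seq(1L, n, by = spec$micro_len),
    spec = spec
  ), class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat("Stimulus sequence:", x$spec$condition, "condition,",
      length(x$tone_indices), "tones, p(S) =", x$spec$p_s_numerator, "/",
      x$spec$micro_len, "\n")
  invisible(x)
}

#' Validate a stimulus sequence against its design invariants
#'
#' Checks length, per-microsequence role counts, marginal tone probabilities,
#' the cross-boundary repetition rule, the random-condition no-repetition
#' rule, and onset spacing. Purely a reporting operation: never errors.
#'
#' @param seq a `stimulus_sequence`.
#' @param ts the `tone_set` the sequence indexes into.
#' @return A data.frame with columns `check`, `pass`, `observed`, `expected`;
#'   attribute `ok` is TRUE iff all checks pass.
#' @export
validate_sequence <- function(seq, ts = build_tone_set()) {
  spec <- seq$spec
  n_exp <- spec$n_micro * spec$micro_len
  n_obs <- length(seq$tone_indices)
  checks <- list()
  add <- function(check, pass, observed, expected)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, observed = as.character(observed),
      expected = as.character(expected), stringsAsFactors = FALSE)

  add("length", n_obs == n_exp, n_obs, n_exp)

  mi <- rep(seq_len(spec$n_micro), each = spec$micro_len)[seq_len(n_obs)]
  s_per <- tapply(seq$roles == "S", mi, sum)
  d_per <- tapply(seq$roles == "D", mi, sum)
  add("S count per microsequence", all(s_per == spec$p_s_numerator),
      paste(range(s_per), collapse = "-"), spec$p_s_numerator)
  add("D count per microsequence", all(d_per == 1L),
      paste(range(d_per), collapse = "-"), 1L)

  add("marginal p(D)", isTRUE(all.equal(mean(seq$roles == "D"),
                                        1 / spec$micro_len)),
      signif(mean(seq$roles == "D"), 6), signif(1 / spec$micro_len, 6))
  add("marginal p(S)", isTRUE(all.equal(mean(seq$roles == "S"),
                                        p_standard(spec))),
      signif(mean(seq$roles == "S"), 6), signif(p_standard(spec), 6))

  # boundary rule: tone opening microsequence m vs tone closing m-1
  starts <- seq$micro_boundaries[-1L]
  if (length(starts) && max(starts) <= n_obs) {
    open_t <- seq$tone_indices[starts]
    close_t <- seq$tone_indices[starts - 1L]
    viol <- if (identical(spec$condition, "random"))
      sum(open_t == close_t)
    else
      sum(open_t == close_t & open_t != ts$s_index)
    add("boundary repetition rule", viol == 0L, viol, 0L)
  }

  if (identical(spec$condition, "random")) {
    rep_adj <- sum(diff(seq$tone_indices) == 0L)
    add("no adjacent tone repetition", rep_adj == 0L, rep_adj, 0L)
  }

  onset_ok <- isTRUE(all.equal(seq$onsets,
                               (seq_along(seq$onsets) - 1) * spec$soa))
  add("onset spacing (SOA)", onset_ok, "computed", paste0(spec$soa, " ms grid"))

  out <- do.call(rbind, checks)
  attr(out, "ok") <- all(out$pass)
  out
}

#' Synthesize per-tone audio waveforms and a presentation schedule
#'
#' Each tone is a sine at its alphabet frequency, `tone_duration` ms long,
#' with raised-cosine (hann) on/off ramps of `ramp` ms. Waveforms are
#' returned once per tone index; the schedule pairs every event with its
#' onset and tone.
#'
#' @param seq a `stimulus_sequence`.
#' @param ts the `tone_set`.
#' @return list with `waveforms` (list of numeric vectors, one per tone
#'   index), `rate` (Hz) and `schedule` (data.frame: event_index, onset_ms,
#'   tone_index, frequency_hz, role).
#' @export
synthesize_audio <- function(seq, ts = build_tone_set()) {
  spec <- seq$spec
  if (spec$audio_rate < 2 * max(ts$frequencies))
    stop("audio_rate below Nyquist limit for the highest tone", call. = FALSE)
  n_samp <- round(spec$tone_duration / 1000 * spec$audio_rate)
  n_ramp <- round(spec$ramp / 1000 * spec$audio_rate)
  env <- rep(1, n_samp)
  if (n_ramp > 1) {
    up <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = n_ramp)))
    env[seq_len(n_ramp)] <- up
    env[(n_samp - n_ramp + 1L):n_samp] <- rev(up)
  }
  t <- (seq_len(n_samp) - 1) / spec$audio_rate
  used <- sort(unique(seq$tone_indices))
  waves <- stats::setNames(
    lapply(used, function(k) sin(2 * pi * ts$frequencies[k] * t) * env),
    as.character(used))
  schedule <- data.frame(
    event_index = seq_along(seq$tone_indices),
    onset_ms = seq$onsets,
    tone_index = seq$tone_indices,
    frequency_hz = ts$frequencies[seq$tone_indices],
    role = seq$roles
  )
  list(waveforms = waves, rate = spec$audio_rate, schedule = schedule)
}

#' Write a stimulus sequence as TSV
#'
#' Columns: event_index, onset_ms, tone_index, frequency_hz, role,
#' micro_index. UTF-8, header row.
#'
#' @param seq a `stimulus_sequence`.
#' @param path output file path.
#' @param ts the `tone_set`.
#' @return `path`, invisibly.
#' @export
write_sequence_tsv <- function(seq, path, ts = build_tone_set()) {
  df <- data.frame(
    event_index = seq_along(seq$tone_indices),
    onset_ms = seq$onsets,
    tone_index = seq$tone_indices,
    frequency_hz = ts$frequencies[seq$tone_indices],
    role = seq$roles,
    micro_index = rep(seq_len(seq$spec$n_micro),
                      each = seq$spec$micro_len)[seq_along(seq$tone_indices)]
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
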