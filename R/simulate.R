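# Synthetic epoched EEG with the statistical structure of a
# precision-manipulated oddball study: canonical components, a deviant
# modulation linear in p(S), subject random effects, AR(1) noise.

#' Frontocentral topography weights
#'
#' Channel weights peaking at Fz (weight exactly 1) and falling off toward
#' temporal and parietal sites; mastoids carry a small negative weight, the
#' usual polarity inversion of frontocentral generators under a nose
#' reference.
#'
#' @param montage a `montage` (order of the returned weights follows it).
#' @return named numeric vector of per-channel weights.
#' @export
frontocentral_topography <- function(montage = make_default_montage()) {
  w <- c(Fp1 = 0.5, Fp2 = 0.5, F3 = 0.7, Fz = 1, F4 = 0.7, T3 = 0.2,
         C3 = 0.6, C4 = 0.6, T4 = 0.2, Cz = 0.9, Pz = 0.4,
         M1 = -0.2, M2 = -0.2)
  w[montage$labels]
}

#' Default ERP component set
#'
#' Two canonical auditory components: a positive P50 (peak 50 ms) and a
#' larger negative N1 (peak 100 ms), both frontocentral, modeled as Gaussian
#' temporal kernels (peak latency + width in seconds, amplitude in
#' microvolts).
#'
#' @param montage a `montage`.
#' @return named list of components, each a list with `latency` (s), `width`
#'   (s, Gaussian sd), `amplitude` (uV) and `topography` (per-channel weights).
#' @export
default_components <- function(montage = make_default_montage()) {
  topo <- frontocentral_topography(montage)
  list(
    P50 = list(latency = 0.050, width = 0.015, amplitude = 2,  topography = topo),
    N1  = list(latency = 0.100, width = 0.020, amplitude = -3, topography = topo)
  )
}

#' Configuration for the synthetic EEG generator
#'
#' Defaults reproduce the study design: 20 subjects, four conditions graded
#' in Standard-tone probability (10/11, 7/11, 4/11, 1/11), 135 epochs per
#' tone type and condition (the typical per-condition retained-trial count),
#' 13 channels, 500 Hz, epochs covering \[-0.1, 0.3) s (exactly 200 samples).
#' Deviant epochs carry an additional modulation term
#' `precision_slope * p(S) * kernel(t) * topography`, a Gaussian bump
#' centered in `modulation_window` (default 120-200 ms) over frontocentral
#' channels; the default slope is negative, so deviant responses grow more
#' negative as the context becomes more stable. Standard epochs carry no
#' condition-dependent term by default (`s_slope = 0`), but a Standard
#' modulation can be planted for sensitivity studies. Noise is AR(1) in time
#' (coefficient 0.95) with marginal sd `noise_sd` per channel, independent
#' across channels and epochs; `noise_model = "iid"` gives white noise for
#' oracle tests.
#'
#' @param n_subjects number of subjects (default 20).
#' @param conditions named vector of p(S) levels.
#' @param n_epochs_per_type epochs per (condition, tone type) cell (135).
#' @param fs sampling rate, Hz (500).
#' @param epoch_window half-open epoch window in seconds, default
#'   `c(-0.1, 0.3)` so that `fs * 0.4 = 200` samples.
#' @param components list of ERP components (see [default_components()]).
#' @param precision_slope Deviant modulation slope, uV per unit p(S)
#'   (default -4).
#' @param modulation_window window of the planted modulation, seconds.
#' @param modulation_topography channel weights of the modulation.
#' @param s_slope optional Standard-tone modulation slope (default 0).
#' @param subject_sd sd (uV) of the per-subject additive random effect on
#'   each component amplitude (default 0.5).
#' @param noise_model `"ar1"` or `"iid"`.
#' @param noise_sd marginal noise sd per channel, uV (default 10).
#' @param ar_coef AR(1) coefficient (default 0.95).
#' @param seed master seed; per-subject streams are derived with
#'   [split_seed()].
#' @param montage a `montage`.
#' @param tone_types tone types to simulate, subset of `c("D", "S")`
#'   (default both; restricting to `"D"` halves the cost of studies that
#'   only analyze the deviant response).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 20L,
                              conditions = c(oddball = 10 / 11, high = 7 / 11,
                                             low = 4 / 11, random = 1 / 11),
                              n_epochs_per_type = 135L,
                              fs = 500,
                              epoch_window = c(-0.1, 0.3),
                              components = default_components(montage),
                              precision_slope = -4,
                              modulation_window = c(0.120, 0.200),
                              modulation_topography =
                                frontocentral_topography(montage),
                              s_slope = 0,
                              subject_sd = 0.5,
                              noise_model = c("ar1", "iid"),
                              noise_sd = 10,
                              ar_coef = 0.95,
                              seed = 1L,
                              montage = make_default_montage(),
                              tone_types = c("D", "S")) {
  noise_model <- match.arg(noise_model)
  tone_types <- match.arg(tone_types, several.ok = TRUE)
  if (n_epochs_per_type <= 0L) stop("`n_epochs_per_type` must be positive",
                                    call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (diff(epoch_window) <= 0) stop("`epoch_window` must be increasing",
                                    call. = FALSE)
  if (modulation_window[1] < epoch_window[1] ||
      modulation_window[2] > epoch_window[2])
    stop("`modulation_window` must lie inside `epoch_window`", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    conditions = conditions,
    n_epochs_per_type = as.integer(n_epochs_per_type),
    fs = fs,
    epoch_window = epoch_window,
    components = components,
    precision_slope = precision_slope,
    modulation_window = modulation_window,
    modulation_topography = modulation_topography,
    s_slope = s_slope,
    subject_sd = subject_sd,
    noise_model = noise_model,
    noise_sd = noise_sd,
    ar_coef = ar_coef,
    seed = as.integer(seed),
    montage = montage,
    tone_types = tone_types
  ), class = "simulation_config")
}

#' Time axis of an epoch window
#' @param cfg a `simulation_config` (or any list with `fs`, `epoch_window`).
#' @return numeric vector of sample times in seconds (half-open window).
#' @export
epoch_times <- function(cfg) {
  n <- round(cfg$fs * diff(cfg$epoch_window))
  cfg$epoch_window[1] + (seq_len(n) - 1) / cfg$fs
}

# Gaussian temporal kernel, unit peak.
.gauss_kernel <- function(times, latency, width) {
  exp(-0.5 * ((times - latency) / width)^2)
}

# kernel of the planted modulation: Gaussian centered in the window with
# sd = quarter window width, unit peak
.modulation_kernel <- function(times, window) {
  center <- mean(window)
  .gauss_kernel(times, center, diff(window) / 4)
}

# channels x time noise block for n_epochs epochs, returned as a 3D array
# [epoch, channel, time]
.simulate_noise <- function(cfg, n_chan, n_time, n_epochs) {
  if (cfg$noise_sd == 0)
    return(array(0, dim = c(n_epochs, n_chan, n_time)))
  n_series <- n_chan * n_epochs
  if (cfg$noise_model == "iid") {
    x <- matrix(stats::rnorm(n_time * n_series, sd = cfg$noise_sd),
                nrow = n_time)
  } else {
    burn <- 50L
    innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar_coef^2)
    e <- matrix(stats::rnorm((n_time + burn) * n_series, sd = innov_sd),
                nrow = n_time + burn)
    x <- stats::filter(e, cfg$ar_coef, method = "recursive")
    x <- x[(burn + 1L):(burn + n_time), , drop = FALSE]
  }
  # columns are (channel within epoch); reshape to [epoch, channel, time]
  aperm(array(as.numeric(x), dim = c(n_time, n_chan, n_epochs)), c(3, 2, 1))
}

#' Simulate one subject's epochs
#'
#' Signal model per epoch: sum of Gaussian-kernel components (amplitude
#' perturbed by the subject random effect, shared by all of this subject's
#' epochs), plus for Deviant epochs the planted precision modulation
#' `precision_slope * p(S) * kernel * topography`, plus noise. Deterministic
#' given `(cfg$seed, subject_id)`.
#'
#' @param cfg a `simulation_config`.
#' @param subject_id integer subject index.
#' @return nested list `[[condition]][[tone_type]]` of arrays
#'   `[epoch, channel, time]`, tone types `"D"` and `"S"`.
#' @export
simulate_subject <- function(cfg, subject_id) {
  set.seed(split_seed(cfg$seed, 1000L + subject_id))
  times <- epoch_times(cfg)
  n_time <- length(times)
  labels <- cfg$montage$labels
  n_chan <- length(labels)

  # subject random effect: one additive amplitude offset per component
  amps <- vapply(cfg$components, function(cp)
    cp$amplitude + stats::rnorm(1, 0, cfg$subject_sd), numeric(1))
  base <- matrix(0, n_chan, n_time)
  for (i in seq_along(cfg$components)) {
    cp <- cfg$components[[i]]
    base <- base + outer(cp$topography[labels],
                         amps[i] * .gauss_kernel(times, cp$latency, cp$width))
  }
  mod_shape <- outer(cfg$modulation_topography[labels],
                     .modulation_kernel(times, cfg$modulation_window))

  types <- if (is.null(cfg$tone_types)) c("D", "S") else cfg$tone_types
  n_cells <- length(cfg$conditions) * length(types)
  # one noise block for all of this subject's cells, sliced below
  noise <- .simulate_noise(cfg, n_chan, n_time,
                           cfg$n_epochs_per_type * n_cells)
  cell_i <- 0L
  out <- vector("list", length(cfg$conditions))
  names(out) <- names(cfg$conditions)
  for (cd in names(cfg$conditions)) {
    p_s <- cfg$conditions[[cd]]
    cell <- list()
    for (tt in types) {
      slope <- if (tt == "D") cfg$precision_slope else cfg$s_slope
      mean_sig <- base + slope * p_s * mod_shape
      rows <- cell_i * cfg$n_epochs_per_type + seq_len(cfg$n_epochs_per_type)
      cell_i <- cell_i + 1L
      eps <- noise[rows, , , drop = FALSE] +
        rep(mean_sig, each = cfg$n_epochs_per_type)
      dimnames(eps) <- list(NULL, labels, NULL)
      cell[[tt]] <- eps
    }
    out[[cd]] <- cell
  }
  out
}

#' Simulate a full multi-subject dataset
#'
#' Concatenates [simulate_subject()] over subjects and wraps the result with
#' montage, sampling and provenance metadata.
#'
#' @param cfg a `simulation_config`.
#' @return An object of class `epoch_collection`: list with `data`
#'   (`[[subject]][[condition]][[tone_type]]` arrays `[epoch, channel, time]`),
#'   `montage`, `fs`, `times`, `conditions` (named p(S) levels) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  data <- lapply(seq_len(cfg$n_subjects), function(s) simulate_subject(cfg, s))
  names(data) <- paste0("S", sprintf("%02d", seq_len(cfg$n_subjects)))
  structure(list(
    data = data,
    montage = cfg$montage,
    fs = cfg$fs,
    times = epoch_times(cfg),
    conditions = cfg$conditions,
    config = cfg
  ), class = "epoch_collection")
}

#' @export
print.epoch_collection <- function(x, ...) {
  cat("Epoch collection:", length(x$data), "subjects x",
      length(x$conditions), "conditions x 2 tone types;",
      length(x$montage$labels), "channels,", length(x$times),
      "samples @", x$fs, "Hz\n")
  invisible(x)
}

#' Serialize an epoch collection with a JSON sidecar
#'
#' Writes the numeric arrays with [saveRDS()] and a human-readable JSON
#' sidecar (`<path>.json`) recording montage, sampling, conditions and the
#' generator provenance.
#'
#' @param x an `epoch_collection`.
#' @param path output path for the RDS container.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(x, path) {
  saveRDS(x, path)
  side <- list(
    class = "epoch_collection",
    n_subjects = length(x$data),
    conditions = as.list(x$conditions),
    fs = x$fs,
    n_times = length(x$times),
    window = range(x$times),
    channels = x$montage$labels,
    seed = x$config$seed
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an epoch collection written by [write_epochs()]
#' @param path RDS container path.
#' @return an `epoch_collection`.
#' @export
read_epochs <- function(path) readRDS(path)
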