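# Orchestration: one call reproduces the whole analysis shape on synthetic
# data (sequence validation, simulation, preprocessing, D / S / DW cluster
# analyses, confirmatory window tests, figures, report).

#' Study configuration
#'
#' Bundles the per-stage configurations. Stage seeds are derived from
#' `master_seed` with [split_seed()] (sequences: stages 1-4 per condition,
#' simulation: stage 10, permutations: stages 20/21/22 per target), so any
#' stage can be rerun independently.
#'
#' @param simulation a `simulation_config`.
#' @param pipeline a `pipeline_config`.
#' @param permutation a `permutation_config`.
#' @param targets analysis targets, subset of `c("D", "S", "DW")`.
#' @param confirm_channel,confirm_window channel and closed time window (s)
#'   of the confirmatory Kruskal-Wallis / Tukey-Kramer test (default Fz,
#'   160-180 ms).
#' @param master_seed master RNG seed.
#' @return An object of class `study_config`.
#' @export
study_config <- function(simulation = simulation_config(),
                         pipeline = pipeline_config(),
                         permutation = permutation_config(),
                         targets = c("D", "S", "DW"),
                         confirm_channel = "Fz",
                         confirm_window = c(0.160, 0.180),
                         master_seed = 1L) {
  targets <- match.arg(targets, several.ok = TRUE)
  if (!length(targets)) stop("`targets` must be non-empty", call. = FALSE)
  structure(list(simulation = simulation, pipeline = pipeline,
                 permutation = permutation, targets = targets,
                 confirm_channel = confirm_channel,
                 confirm_window = confirm_window,
                 master_seed = as.integer(master_seed)),
            class = "study_config")
}

#' Run the full study on synthetic data
#'
#' Stages: (1) generate and validate the four condition sequences and report
#' the Deviant / closest-preceding-Standard pairing counts; (2) simulate the
#' epoched dataset; (3) preprocess (baseline, rejection, averaging,
#' filtering, difference waves); (4) for each target run the cluster-based
#' permutation correlation analysis plus the confirmatory window tests.
#' Result tables are written as TSV, a Markdown report summarizes
#' everything, and (optionally) figures show condition ERPs at Fz with the
#' r time course, window-mean boxplots, and the time-electrode r map.
#'
#' @param cfg a `study_config`.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param make_plots write PNG figures (default `!is.null(out_dir)`).
#' @return An object of class `study_report`: list with `sequences`
#'   (validation tables + pairing counts), `rejection`, `erps`, `analyses`
#'   (per target: `test`, `table`, `kruskal`, `posthoc`, `window_means`),
#'   `cfg`.
#' @export
run_study <- function(cfg = study_config(), out_dir = NULL,
                      make_plots = !is.null(out_dir)) {
  stopifnot(inherits(cfg, "study_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ts <- build_tone_set()
  conds <- names(cfg$simulation$conditions)
  default_ps <- c(oddball = 10L, high = 7L, low = 4L, random = 1L)
  seqs <- list()
  for (i in seq_along(conds)) {
    cd <- conds[i]
    sp <- sequence_spec(cd, p_s_numerator = default_ps[[cd]],
                        seed = split_seed(cfg$master_seed, i))
    sq <- generate_sequence(sp, ts)
    val <- validate_sequence(sq, ts)
    if (!attr(val, "ok"))
      stop("stage sequence-generation failed validation for condition ", cd,
           call. = FALSE)
    pairs <- select_trials(sq)
    seqs[[cd]] <- list(sequence = sq, validation = val,
                       n_pairs = nrow(pairs))
  }

  sim_cfg <- cfg$simulation
  sim_cfg$seed <- split_seed(cfg$master_seed, 10L)
  collection <- simulate_dataset(sim_cfg)

  pre <- preprocess(collection, cfg$pipeline)
  erps <- pre$erps
  if (any(erps$missing))
    stop("stage preprocessing produced missing ERP cells", call. = FALSE)

  adj <- build_adjacency(erps$montage,
                         min_neighbor_channels =
                           cfg$permutation$min_neighbor_channels)
  pred_values <- as.numeric(erps$conditions)

  analyses <- list()
  for (i in seq_along(cfg$targets)) {
    tg <- cfg$targets[i]
    pcfg <- cfg$permutation
    pcfg$seed <- split_seed(cfg$master_seed, 19L + i)
    X <- erp_dependent(erps, tg)
    test <- permutation_test(X, pred_values, dim(erps$ave)[1], adj, pcfg)
    wm <- window_mean(erps, cfg$confirm_channel, cfg$confirm_window, tg)
    groups <- lapply(seq_len(ncol(wm)), function(j) wm[, j])
    names(groups) <- colnames(wm)
    analyses[[tg]] <- list(
      test = test,
      table = cluster_table(test),
      window_means = wm,
      kruskal = kruskal_wallis(groups),
      posthoc = tukey_kramer_posthoc(groups)
    )
  }

  report <- structure(list(
    sequences = lapply(seqs, function(s) s[c("validation", "n_pairs")]),
    rejection = pre$rejection,
    erps = erps,
    analyses = analyses,
    cfg = cfg
  ), class = "study_report")

  if (!is.null(out_dir)) {
    .write_report_files(report, out_dir)
    if (make_plots) .write_report_plots(report, out_dir)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", length(x$analyses), "analysis target(s):",
      paste(names(x$analyses), collapse = ", "), "\n")
  for (tg in names(x$analyses)) {
    a <- x$analyses[[tg]]
    sig <- sum(a$table$significant)
    cat(sprintf("  %s: %d cluster(s), %d significant; Kruskal-Wallis chi2 = %.2f (df = %d, p = %.3g)\n",
                tg, nrow(a$table), sig, a$kruskal$statistic, a$kruskal$df,
                a$kruskal$p_value))
  }
  invisible(x)
}

.write_report_files <- function(report, out_dir) {
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  for (cd in names(report$sequences))
    w(report$sequences[[cd]]$validation,
      paste0("sequence_validation_", cd, ".tsv"))
  w(report$rejection, "rejection_log.tsv")
  lines <- c("# Precision-graded oddball study report", "")
  for (tg in names(report$analyses)) {
    a <- report$analyses[[tg]]
    w(a$table, paste0("clusters_", tg, ".tsv"))
    wm_df <- data.frame(subject = rownames(a$window_means), a$window_means)
    w(wm_df, paste0("window_means_", tg, ".tsv"))
    w(a$posthoc, paste0("posthoc_", tg, ".tsv"))
    lines <- c(lines, paste0("## Target ", tg), "",
               sprintf("- clusters: %d (%d significant)",
                       nrow(a$table), sum(a$table$significant)),
               sprintf("- Kruskal-Wallis: chi2 = %.3f, df = %d, p = %.4g",
                       a$kruskal$statistic, a$kruskal$df, a$kruskal$p_value),
               "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

.write_report_plots <- function(report, out_dir) {
  erps <- report$erps
  times_ms <- erps$times * 1000
  fz <- match("Fz", erps$montage$labels)
  for (tg in names(report$analyses)) {
    a <- report$analyses[[tg]]
    arr <- if (tg == "DW") erps$dw[, , fz, ] else erps$ave[, , tg, fz, ]
    ga <- apply(arr, c(2, 3), mean) # condition x time grand average
    df <- do.call(rbind, lapply(rownames(ga), function(cd)
      data.frame(time_ms = times_ms, amplitude = ga[cd, ], condition = cd)))
    r_fz <- a$test$map$r[, fz]
    rdf <- data.frame(time_ms = times_ms, r = r_fz)
    p1 <- ggplot2::ggplot(df, ggplot2::aes(x = time_ms,
                                           y = amplitude,
                                           color = condition)) +
      ggplot2::geom_line() +
      ggplot2::geom_line(data = rdf,
                         ggplot2::aes(x = time_ms, y = r),
                         inherit.aes = FALSE, linetype = "dotted") +
      ggplot2::labs(x = "Time (ms)", y = "Amplitude (uV) / r",
                    title = paste("Fz grand averages +", tg,
                                  "correlation time course"))
    ggplot2::ggsave(file.path(out_dir, paste0("erp_fz_", tg, ".png")), p1,
                    width = 7, height = 4, dpi = 120)

    wm <- a$window_means
    bdf <- do.call(rbind, lapply(colnames(wm), function(cd)
      data.frame(condition = cd, amplitude = wm[, cd])))
    p2 <- ggplot2::ggplot(bdf, ggplot2::aes(x = condition,
                                            y = amplitude)) +
      ggplot2::geom_boxplot() +
      ggplot2::labs(y = "Window mean (uV)",
                    title = paste(tg, "window means per condition"))
    ggplot2::ggsave(file.path(out_dir, paste0("window_means_", tg, ".png")),
                    p2, width = 5, height = 4, dpi = 120)

    rmap <- a$test$map$r
    mdf <- expand.grid(time_ms = times_ms,
                       electrode = factor(erps$montage$labels,
                                          levels = erps$montage$labels))
    mdf$r <- as.numeric(rmap)
    p3 <- ggplot2::ggplot(mdf, ggplot2::aes(x = time_ms,
                                            y = electrode,
                                            fill = r)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
      ggplot2::labs(x = "Time (ms)", title = paste(tg, "r map"))
    ggplot2::ggsave(file.path(out_dir, paste0("r_map_", tg, ".png")), p3,
                    width = 7, height = 4, dpi = 120)
  }
  invisible(out_dir)
}
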