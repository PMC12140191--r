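#' Analysis configuration
#'
#' Collects the tunable settings of the full analysis: which signals to
#' analyse, which condition contrasts to run, the bootstrap settings and the
#' window-selection rules. Every output records the seed and a configuration
#' fingerprint.
#'
#' @param signals Character vector among `pupil_x_right`, `pupil_x_left`,
#'   `pupil_y_right`, `pupil_y_left`, `pupil_diameter_right`,
#'   `pupil_diameter_left`, `ear_speed`, `whisker_speed`. Horizontal pupil
#'   positions are signed toward the threat using the manifest's per-eye
#'   signs.
#' @param contrasts Named list of contrast specifications; see
#'   [default_contrasts()]. Contrasts referencing conditions absent from the
#'   manifest are skipped and listed in the report.
#' @param n_boot Bootstrap iterations (default 10,000).
#' @param quantile_level Threshold quantile (default 0.95: the 5% level).
#' @param pre_window Seconds of pre-threat context in the analysis window
#'   (default 1; with the default 10 s threat hold this gives the 11 s
#'   window).
#' @param confidence_threshold Tracking-likelihood threshold for gap
#'   interpolation (default 0.9).
#' @param min_duration,merge_gap Window-selection settings, s.
#' @param mode `"signed"` or `"absolute"` bootstrap maximum.
#' @param seed Seed for the bootstrap draws (per-contrast seeds are derived
#'   from it).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(signals = c(
                              "pupil_x_right", "pupil_x_left",
                              "pupil_diameter_right", "pupil_diameter_left",
                              "ear_speed", "whisker_speed"
                            ),
                            contrasts = default_contrasts(),
                            n_boot = 10000,
                            quantile_level = 0.95,
                            pre_window = 1,
                            confidence_threshold = 0.9,
                            min_duration = 0.1,
                            merge_gap = 0.05,
                            mode = c("signed", "absolute"),
                            seed = 1L) {
  mode <- match.arg(mode)
  known <- c("pupil_x_right", "pupil_x_left", "pupil_y_right", "pupil_y_left",
             "pupil_diameter_right", "pupil_diameter_left",
             "ear_speed", "whisker_speed")
  bad <- setdiff(signals, known)
  if (length(bad) > 0) stop("unknown signal(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      signals = signals, contrasts = contrasts,
      n_boot = as.integer(n_boot), quantile_level = quantile_level,
      pre_window = pre_window,
      confidence_threshold = confidence_threshold,
      min_duration = min_duration, merge_gap = merge_gap,
      mode = mode, seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' Default condition contrasts
#'
#' The contrasts reported by the analysis: synchronous vs asynchronous
#' pairing within each object condition, each pairing condition vs the
#' threat-only control, and the difference-of-differences contrast
#' comparing the sync/async effect between the artificial-limb and block
#' experiments.
#'
#' @return A named list of contrast specifications (condition keys as in
#'   [condition_key()]).
#' @export
default_contrasts <- function() {
  list(
    limb_sync_vs_async = list(type = "paired", a = "limb_sync", b = "limb_async"),
    block_sync_vs_async = list(type = "paired", a = "block_sync", b = "block_async"),
    limb_sync_vs_none = list(type = "paired", a = "limb_sync", b = "none"),
    limb_async_vs_none = list(type = "paired", a = "limb_async", b = "none"),
    block_sync_vs_none = list(type = "paired", a = "block_sync", b = "none"),
    block_async_vs_none = list(type = "paired", a = "block_async", b = "none"),
    limb_vs_block_dod = list(
      type = "difference_of_differences",
      first = c("limb_sync", "limb_async"),
      second = c("block_sync", "block_async")
    )
  )
}

# Compute one signal's full-length series from a trial's side tables,
# after gap interpolation of every track it uses.
signal_series <- function(signal, tables, eye_sign, frame_rate,
                          confidence_threshold) {
  grab <- function(side, part, coord) {
    tt <- tables[[side]]
    if (is.null(tt)) stop("signal ", signal, " needs the ", side, " camera file")
    j <- match(part, tt$bodyparts)
    if (is.na(j)) stop("body part '", part, "' missing from ", side, " table")
    vals <- if (coord == "x") tt$x[, j] else tt$y[, j]
    interpolate_low_confidence(vals, tt$confidence[, j],
                               confidence_threshold)$values
  }
  side <- if (grepl("right", signal)) "right" else "left"
  switch(sub("_(right|left)$", "", signal),
    pupil_x = unname(eye_sign[[side]]) * grab(side, "pupil_center", "x"),
    pupil_y = grab(side, "pupil_center", "y"),
    pupil_diameter = pupil_diameter(
      grab(side, "pupil_top", "y"), grab(side, "pupil_bottom", "y")
    ),
    ear_speed = point_speed(
      grab("left", "ear", "x"), grab("left", "ear", "y"), frame_rate
    ),
    whisker_speed = point_speed(
      grab("left", "whisker", "x"), grab("left", "whisker", "y"), frame_rate
    ),
    stop("unknown signal: ", signal)
  )
}

sides_needed <- function(signals) {
  sides <- character(0)
  if (any(grepl("right", signals))) sides <- c(sides, "right")
  if (any(grepl("left", signals)) || any(grepl("speed", signals))) {
    sides <- c(sides, "left")
  }
  unique(sides)
}

#' Run the full embodiment analysis
#'
#' For every configured signal and contrast: builds per-mouse condition
#' averages (mouse-level averaging first, trials never pooled across mice),
#' the raw condition-difference trace over the analysis window, the
#' baseline-segment maximum-statistic bootstrap threshold, the
#' supra-threshold windows (W1/W2), per-mouse pre-threat-normalized window
#' means and the paired Wilcoxon signed-rank test. The significance
#' analysis runs on unnormalized differences; window quantification uses
#' pre-threat normalization.
#'
#' @param manifest A manifest path or the result of [read_manifest()].
#' @param config An [analysis_config()].
#' @param output_dir Optional directory; when given, writes `report.json`
#'   and tidy CSV tables (`difference_traces.csv`, `window_means.csv`,
#'   `tests.csv`, `thresholds.csv`).
#' @return The report, a nested list (class `embodiment_report`).
#' @export
run_full_analysis <- function(manifest, config = analysis_config(),
                              output_dir = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest, check_files = TRUE)
  stopifnot(inherits(config, "analysis_config"))
  timeline <- manifest$timeline
  fs <- timeline$frame_rate
  pre <- config$pre_window
  post <- timeline$threat_hold
  segment_length <- pre + post
  base_idx <- window_frames(0, timeline$pairing_start, fs)
  win_idx <- window_frames(timeline$threat_onset - pre,
                           timeline$threat_onset + post, fs)
  win_time <- -pre + (seq_along(win_idx) - 1) / fs

  trials <- manifest$trials
  used <- trials[!trials$excluded, , drop = FALSE]
  if (nrow(used) == 0) stop("manifest has no usable trials")
  used$key <- vapply(seq_len(nrow(used)), function(i) {
    condition_key(used$object_condition[i], used$pairing_condition[i])
  }, "")
  need_sides <- sides_needed(config$signals)

  # per signal, per trial: baseline segment + analysis-window segment (raw)
  base_parts <- lapply(config$signals, function(s) vector("list", nrow(used)))
  win_parts <- base_parts
  names(base_parts) <- names(win_parts) <- config$signals
  for (i in seq_len(nrow(used))) {
    tables <- list()
    for (side in need_sides) {
      f <- used[[paste0("file_", side)]][i]
      if (is.na(f)) stop("trial ", used$mouse_id[i], " s", used$session_index[i],
                         " has no ", side, " camera file")
      tables[[side]] <- tryCatch(
        read_tracking_table(file.path(manifest$dir, f)),
        error = function(e) stop("stage read_tracking_table failed for trial ",
                                 used$mouse_id[i], " session ",
                                 used$session_index[i], ": ",
                                 conditionMessage(e))
      )
    }
    for (s in config$signals) {
      series <- tryCatch(
        signal_series(s, tables, manifest$eye_sign, fs,
                      config$confidence_threshold),
        error = function(e) stop("stage signal_series(", s,
                                 ") failed for trial ", used$mouse_id[i],
                                 " session ", used$session_index[i], ": ",
                                 conditionMessage(e))
      )
      base_parts[[s]][[i]] <- series[base_idx]
      win_parts[[s]][[i]] <- series[win_idx]
    }
  }

  # per-mouse condition averages (sessions averaged within mouse)
  mouse_condition_mats <- function(parts, key) {
    rows <- which(used$key == key)
    if (length(rows) == 0) return(NULL)
    mice <- sort(unique(used$mouse_id[rows]))
    mat <- t(vapply(mice, function(m) {
      average_trials_per_mouse(parts[used$mouse_id == m & used$key == key])$mean
    }, numeric(length(parts[[rows[1]]]))))
    rownames(mat) <- mice
    mat
  }

  keys_present <- unique(used$key)
  report_contrasts <- list()
  skipped <- character(0)

  for (cname in names(config$contrasts)) {
    cs <- config$contrasts[[cname]]
    needed_keys <- if (cs$type == "paired") c(cs$a, cs$b) else c(cs$first, cs$second)
    if (!all(needed_keys %in% keys_present)) {
      skipped <- c(skipped, cname)
      next
    }
    per_signal <- list()
    for (s in config$signals) {
      cseed <- derive_seed(config$seed, cname, s)
      if (cs$type == "paired") {
        a_win <- mouse_condition_mats(win_parts[[s]], cs$a)
        b_win <- mouse_condition_mats(win_parts[[s]], cs$b)
        a_base <- mouse_condition_mats(base_parts[[s]], cs$a)
        b_base <- mouse_condition_mats(base_parts[[s]], cs$b)
        trace <- paired_difference_traces(a_win, b_win, time = win_time)
        null <- bootstrap_max_null(
          a_base[trace$mice, , drop = FALSE] - b_base[trace$mice, , drop = FALSE],
          frame_rate = fs, segment_length = segment_length,
          n_boot = config$n_boot, quantile_level = config$quantile_level,
          seed = cseed, mode = config$mode
        )
        report <- detect_windows(trace, null, config$min_duration,
                                 config$merge_gap)
        # quantification on pre-threat-normalized traces
        an <- a_win - rowMeans(a_win[, win_time < 0, drop = FALSE])
        bn <- b_win - rowMeans(b_win[, win_time < 0, drop = FALSE])
        windows <- window_quantification(an, bn, win_time, report)
        cond_traces <- stats::setNames(
          list(trace_summary(an), trace_summary(bn)), c(cs$a, cs$b)
        )
        per_signal[[s]] <- list(
          n_mice = trace$n_mice, mice = trace$mice,
          dropped_mice = trace$dropped_mice,
          threshold = null$threshold, seed = cseed,
          intervals = report$intervals,
          W1 = report$W1, W2 = report$W2,
          windows = windows,
          condition_traces = cond_traces,
          difference_trace = list(time = win_time, mean = unname(trace$mean),
                                  sem = unname(trace$sem))
        )
      } else {
        first <- paired_difference_traces(
          mouse_condition_mats(win_parts[[s]], cs$first[1]),
          mouse_condition_mats(win_parts[[s]], cs$first[2]),
          time = win_time
        )
        second <- paired_difference_traces(
          mouse_condition_mats(win_parts[[s]], cs$second[1]),
          mouse_condition_mats(win_parts[[s]], cs$second[2]),
          time = win_time
        )
        common <- intersect(first$mice, second$mice)
        fb <- mouse_condition_mats(base_parts[[s]], cs$first[1])[common, , drop = FALSE] -
          mouse_condition_mats(base_parts[[s]], cs$first[2])[common, , drop = FALSE]
        sb <- mouse_condition_mats(base_parts[[s]], cs$second[1])[common, , drop = FALSE] -
          mouse_condition_mats(base_parts[[s]], cs$second[2])[common, , drop = FALSE]
        dod <- contrast_of_contrasts(
          first, second, fb, sb, frame_rate = fs,
          segment_length = segment_length, n_boot = config$n_boot,
          quantile_level = config$quantile_level, seed = cseed,
          mode = config$mode, min_duration = config$min_duration,
          merge_gap = config$merge_gap
        )
        dn <- dod$trace$per_mouse -
          rowMeans(dod$trace$per_mouse[, win_time < 0, drop = FALSE])
        windows <- window_quantification(dn, NULL, win_time, dod$report)
        per_signal[[s]] <- list(
          n_mice = dod$trace$n_mice, mice = dod$trace$mice,
          dropped_mice = dod$trace$dropped_mice,
          threshold = dod$null$threshold, seed = cseed,
          intervals = dod$report$intervals,
          W1 = dod$report$W1, W2 = dod$report$W2,
          windows = windows,
          difference_trace = list(time = win_time,
                                  mean = unname(dod$trace$mean),
                                  sem = unname(dod$trace$sem))
        )
      }
    }
    report_contrasts[[cname]] <- list(type = cs$type, signals = per_signal)
  }

  config_echo <- config_fingerprintable(config)
  report <- structure(
    list(
      package = "embodir",
      version = as.character(utils::packageVersion("embodir")),
      seed = config$seed,
      config = config_echo,
      config_hash = fnv1a32(paste(deparse(config_echo), collapse = "")),
      timeline = unclass(timeline),
      n_trials = nrow(trials),
      n_trials_used = nrow(used),
      excluded_trials = trials[trials$excluded,
                               c("mouse_id", "session_index",
                                 "pairing_condition"), drop = FALSE],
      skipped_contrasts = skipped,
      contrasts = report_contrasts
    ),
    class = "embodiment_report"
  )

  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

# Per-window quantification: per-mouse window means and the paired
# signed-rank test. When `b` is NULL (difference-of-differences), the
# per-mouse second-order means are tested against zero.
window_quantification <- function(a, b, time, report) {
  out <- list()
  labels <- c("W1", "W2")
  wins <- list(report$W1, report$W2)
  for (k in 1:2) {
    if (is.null(wins[[k]])) next
    w <- wins[[k]]
    if (is.null(b)) {
      idx <- which(time >= w[1] & time < w[2])
      means <- rowMeans(a[, idx, drop = FALSE])
      test <- wilcoxon_signed_rank(means)
      wm <- data.frame(mouse = rownames(a), difference = unname(means),
                       stringsAsFactors = FALSE)
    } else {
      wm <- window_means(a, b, time, w)
      test <- wilcoxon_signed_rank(wm$a, wm$b)
    }
    out[[labels[k]]] <- list(
      window = w, window_means = wm,
      wilcoxon = list(statistic = test$statistic, p.value = test$p.value,
                      n = test$n, method = test$method)
    )
  }
  out
}

trace_summary <- function(mat) {
  n <- nrow(mat)
  list(
    mean = unname(colMeans(mat)),
    sem = if (n > 1) unname(apply(mat, 2, stats::sd) / sqrt(n)) else NULL,
    n_mice = n
  )
}

config_fingerprintable <- function(config) {
  out <- unclass(config)
  out$contrasts <- lapply(out$contrasts, function(cs) lapply(cs, unname))
  out
}

#' Write an analysis report to disk
#'
#' Writes `report.json` plus tidy CSV tables of the difference traces,
#' thresholds, window means and test results. Outputs are deterministic:
#' identical seeds yield byte-identical files.
#'
#' @param report An `embodiment_report` from [run_full_analysis()].
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    unclass(report), file.path(output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    dataframe = "columns"
  )
  traces <- list(); wmeans <- list(); tests <- list(); thr <- list()
  for (cname in names(report$contrasts)) {
    for (s in names(report$contrasts[[cname]]$signals)) {
      rec <- report$contrasts[[cname]]$signals[[s]]
      tr <- rec$difference_trace
      traces[[length(traces) + 1L]] <- data.frame(
        contrast = cname, signal = s, time = tr$time, mean = tr$mean,
        sem = tr$sem %||% NA_real_
      )
      thr[[length(thr) + 1L]] <- data.frame(
        contrast = cname, signal = s, threshold = rec$threshold,
        n_mice = rec$n_mice
      )
      for (wl in names(rec$windows)) {
        w <- rec$windows[[wl]]
        wm <- w$window_means
        wm$contrast <- cname; wm$signal <- s; wm$window <- wl
        wmeans[[length(wmeans) + 1L]] <- wm
        tests[[length(tests) + 1L]] <- data.frame(
          contrast = cname, signal = s, window = wl,
          start = w$window[1], end = w$window[2],
          statistic = w$wilcoxon$statistic, p.value = w$wilcoxon$p.value,
          n = w$wilcoxon$n, method = w$wilcoxon$method
        )
      }
    }
  }
  write_tidy <- function(lst, fn) {
    if (length(lst) > 0) {
      data.table::fwrite(data.table::rbindlist(lst, fill = TRUE),
                         file.path(output_dir, fn))
    }
  }
  write_tidy(traces, "difference_traces.csv")
  write_tidy(thr, "thresholds.csv")
  write_tidy(wmeans, "window_means.csv")
  write_tidy(tests, "tests.csv")
  invisible(output_dir)
}

#' @export
print.embodiment_report <- function(x, ...) {
  cat(sprintf(
    "<embodiment_report> %d/%d trials used | %d contrast(s) | seed %d\n",
    x$n_trials_used, x$n_trials, length(x$contrasts), x$seed
  ))
  for (cname in names(x$contrasts)) {
    for (s in names(x$contrasts[[cname]]$signals)) {
      rec <- x$contrasts[[cname]]$signals[[s]]
      nw <- nrow(rec$intervals)
      ps <- vapply(rec$windows, function(w) w$wilcoxon$p.value, 0)
      cat(sprintf(
        "  %s / %s: n = %d, threshold = %.3g px, %d window(s)%s\n",
        cname, s, rec$n_mice, rec$threshold, nw,
        if (length(ps) > 0) {
          paste0("; Wilcoxon p: ", paste(sprintf("%s=%.3g", names(ps), ps),
                                         collapse = ", "))
        } else ""
      ))
    }
  }
  if (length(x$skipped_contrasts) > 0) {
    cat("  skipped (conditions absent):",
        paste(x$skipped_contrasts, collapse = ", "), "\n")
  }
  invisible(x)
}
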