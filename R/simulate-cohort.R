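#' Build a cohort design table
#'
#' One row per trial. For paired experiments each session holds two trials
#' (synchronous and asynchronous) whose within-session order alternates
#' across sessions, as in the protocol; the threat-only control has a single
#' `none`/`none` trial per session.
#'
#' @param n_mice,n_sessions Cohort size.
#' @param object_condition `"artificial_limb"`, `"block"` or `"none"`.
#' @param mouse_ids Optional explicit mouse identifiers.
#' @param exclude Optional list of exclusions. Each element is a list with
#'   `mouse_id` and optionally `session_index`: without a session the mouse
#'   is dropped from the design entirely (animal removed from the pool);
#'   with a session those trials stay listed but are flagged `excluded`
#'   (e.g. a faulty camera session).
#' @return A data.frame with columns `mouse_id`, `session_index`,
#'   `object_condition`, `pairing_condition`, `trial_order`, `excluded`.
#' @examples
#' design <- cohort_design(10, 5)
#' nrow(design) # 100 trials
#' @export
cohort_design <- function(n_mice, n_sessions,
                          object_condition = "artificial_limb",
                          mouse_ids = NULL,
                          exclude = NULL) {
  object_condition <- match.arg(object_condition, c("artificial_limb", "block", "none"))
  if (is.null(mouse_ids)) mouse_ids <- sprintf("m%02d", seq_len(n_mice))
  if (length(mouse_ids) != n_mice) stop("mouse_ids must have length n_mice")

  pairings <- if (object_condition == "none") {
    function(session) data.frame(pairing_condition = "none", trial_order = 1L)
  } else {
    function(session) {
      # order changes at each session: odd sessions sync first
      ord <- if (session %% 2 == 1) {
        c("synchronous", "asynchronous")
      } else {
        c("asynchronous", "synchronous")
      }
      data.frame(pairing_condition = ord, trial_order = 1:2)
    }
  }

  rows <- list()
  for (m in mouse_ids) {
    for (s in seq_len(n_sessions)) {
      tr <- pairings(s)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = m, session_index = s,
        object_condition = object_condition,
        pairing_condition = tr$pairing_condition,
        trial_order = tr$trial_order,
        stringsAsFactors = FALSE
      )
    }
  }
  design <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(
      mouse_id = character(0), session_index = integer(0),
      object_condition = character(0), pairing_condition = character(0),
      trial_order = integer(0), stringsAsFactors = FALSE
    )
  }
  design$excluded <- rep(FALSE, nrow(design))

  for (ex in exclude %||% list()) {
    if (is.null(ex$mouse_id)) stop("each exclusion needs a mouse_id")
    if (is.null(ex$session_index)) {
      design <- design[design$mouse_id != ex$mouse_id, , drop = FALSE]
    } else {
      hit <- design$mouse_id == ex$mouse_id &
        design$session_index == ex$session_index
      if (!any(hit)) {
        stop("exclusion does not match any trial: ", ex$mouse_id,
             " session ", ex$session_index)
      }
      design$excluded[hit] <- TRUE
    }
  }
  rownames(design) <- NULL
  validate_design(design)
  design
}

validate_design <- function(design) {
  needed <- c("mouse_id", "session_index", "object_condition",
              "pairing_condition", "trial_order")
  if (!all(needed %in% names(design))) {
    stop("design must have columns: ", paste(needed, collapse = ", "))
  }
  key <- paste(design$mouse_id, design$session_index, design$object_condition,
               design$pairing_condition)
  if (anyDuplicated(key)) {
    stop("duplicate (mouse, session, condition) rows in design: ",
         key[duplicated(key)][1])
  }
  ok_obj <- design$object_condition %in% c("artificial_limb", "block", "none")
  ok_pair <- design$pairing_condition %in% c("synchronous", "asynchronous", "none")
  if (!all(ok_obj)) stop("unknown object_condition: ", design$object_condition[!ok_obj][1])
  if (!all(ok_pair)) stop("unknown pairing_condition: ", design$pairing_condition[!ok_pair][1])
  invisible(design)
}

#' Simulate a cohort to disk
#'
#' Runs [simulate_trial()] for every row of the design and writes one
#' tracking CSV per trial per camera side (suffixes `_right`/`_left`), a
#' JSON manifest describing the design, file paths, per-eye toward-threat
#' signs and stroke schedules, and a model-parameters sidecar for
#' provenance.
#'
#' @param model A [cohort_model()].
#' @param output_dir Directory to write into (created if needed).
#' @param design Optional design table from [cohort_design()]; defaults to
#'   the model's `n_mice` x `n_sessions` paired design.
#' @param object_condition Object condition for the default design.
#' @param exclude Passed to [cohort_design()] when `design` is NULL.
#' @return The manifest, invisibly, as returned by [read_manifest()].
#' @examples
#' model <- cohort_model(n_mice = 1, n_sessions = 1,
#'                       timeline = trial_timeline(5, 10, 2, 20), seed = 1)
#' dir <- tempfile(); manifest <- simulate_cohort(model, dir)
#' nrow(manifest$trials)
#' @export
simulate_cohort <- function(model, output_dir, design = NULL,
                            object_condition = "artificial_limb",
                            exclude = NULL) {
  stopifnot(inherits(model, "cohort_model"))
  if (is.null(design)) {
    design <- cohort_design(model$n_mice, model$n_sessions,
                            object_condition = object_condition,
                            exclude = exclude)
  } else {
    validate_design(design)
    if (is.null(design$excluded)) design$excluded <- FALSE
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  trials <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    rec <- simulate_trial(
      model, row$mouse_id, row$session_index,
      row$object_condition, row$pairing_condition,
      trial_order = row$trial_order
    )
    stem <- sprintf("%s_s%02d_%s", row$mouse_id, row$session_index,
                    condition_key(row$object_condition, row$pairing_condition))
    tables <- recording_to_tables(rec)
    files <- list()
    for (side in names(tables)) {
      fn <- paste0(stem, "_", side, ".csv")
      write_tracking_table(tables[[side]], file.path(output_dir, fn))
      files[[side]] <- fn
    }
    trials[[i]] <- list(
      mouse_id = row$mouse_id,
      session_index = row$session_index,
      object_condition = row$object_condition,
      pairing_condition = row$pairing_condition,
      trial_order = row$trial_order,
      excluded = isTRUE(row$excluded),
      seed = rec$seed,
      files = files,
      schedule = if (is.null(rec$schedule)) NULL else list(
        visual_onsets = rec$schedule$visual_onsets,
        tactile_onsets = rec$schedule$tactile_onsets,
        stroke_duration = rec$schedule$stroke_duration,
        sweep_distance = rec$schedule$sweep_distance
      )
    )
  }

  manifest <- list(
    format = "embodir-manifest",
    version = 1L,
    seed = model$seed,
    timeline = unclass(model$timeline),
    eye_sign = as.list(model$eye_sign),
    interval_law = "truncated_exponential(rate=1, min=0.6, max=2)",
    trials = trials
  )
  jsonlite::write_json(
    manifest, file.path(output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  jsonlite::write_json(
    model_parameters(model), file.path(output_dir, "model_parameters.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(read_manifest(file.path(output_dir, "manifest.json")))
}

# Serializable view of a cohort model (provenance sidecar).
model_parameters <- function(model) {
  out <- unclass(model)
  out$timeline <- unclass(out$timeline)
  out$eye_sign <- as.list(out$eye_sign)
  out$fast_amp <- as.list(out$fast_amp)
  out$sustained_amp <- as.list(out$sustained_amp)
  out
}

#' Read a cohort manifest
#'
#' @param path Path to a `manifest.json` written by [simulate_cohort()] (or
#'   following the same schema).
#' @param check_files If TRUE, error when a referenced tracking file is
#'   missing.
#' @return A list with `trials` (data.frame: mouse, session, conditions,
#'   order, excluded flag, per-side file paths, trial seed), `timeline`,
#'   `eye_sign`, `interval_law`, `seed`, `dir`, and `schedules` (per-trial
#'   stroke trains, where present).
#' @export
read_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(raw$format, "embodir-manifest")) {
    stop("not an embodir manifest: ", path)
  }
  dir <- dirname(path)
  trials <- raw$trials %||% list()
  df <- data.frame(
    mouse_id = vapply(trials, function(t) t$mouse_id, ""),
    session_index = vapply(trials, function(t) as.integer(t$session_index), 0L),
    object_condition = vapply(trials, function(t) t$object_condition, ""),
    pairing_condition = vapply(trials, function(t) t$pairing_condition, ""),
    trial_order = vapply(trials, function(t) as.integer(t$trial_order), 0L),
    excluded = vapply(trials, function(t) isTRUE(t$excluded), FALSE),
    seed = vapply(trials, function(t) as.integer(t$seed %||% NA_integer_), 0L),
    file_right = vapply(trials, function(t) t$files$right %||% NA_character_, ""),
    file_left = vapply(trials, function(t) t$files$left %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
  validate_design(df)
  if (check_files) {
    for (f in stats::na.omit(c(df$file_right, df$file_left))) {
      if (!file.exists(file.path(dir, f))) {
        stop("tracking file referenced by manifest is missing: ", f)
      }
    }
  }
  eye_sign <- unlist(raw$eye_sign)
  timeline <- trial_timeline(
    pairing_start = raw$timeline$pairing_start,
    threat_onset = raw$timeline$threat_onset,
    threat_hold = raw$timeline$threat_hold,
    frame_rate = raw$timeline$frame_rate
  )
  list(
    trials = df,
    timeline = timeline,
    eye_sign = eye_sign,
    interval_law = raw$interval_law,
    seed = raw$seed,
    dir = dir,
    schedules = lapply(trials, function(t) t$schedule)
  )
}
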