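#' Pose-tracking tables
#'
#' In-memory representation of a markerless pose-estimation export: a scorer
#' label, an ordered set of body-part names, and per part three per-frame
#' columns (x px, y px, likelihood in \[0, 1\]). Frames are contiguous from 0.
#'
#' @param x,y Numeric frame-by-part matrices (px). `NaN` marks missing
#'   samples.
#' @param confidence Numeric frame-by-part matrix of tracking likelihoods in
#'   \[0, 1\].
#' @param bodyparts Character vector of unique body-part names, one per
#'   column.
#' @param scorer Scorer label written to the file header.
#' @return An object of class `tracking_table`.
#' @examples
#' tab <- tracking_table(
#'   x = matrix(1:6, 3), y = matrix(0, 3, 2),
#'   confidence = matrix(1, 3, 2), bodyparts = c("a", "b")
#' )
#' @export
tracking_table <- function(x, y, confidence, bodyparts, scorer = "embodir") {
  x <- as.matrix(x); y <- as.matrix(y); confidence <- as.matrix(confidence)
  storage.mode(x) <- "double"
  storage.mode(y) <- "double"
  storage.mode(confidence) <- "double"
  p <- length(bodyparts)
  if (anyDuplicated(bodyparts)) stop("duplicate body-part names")
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(confidence)) ||
      ncol(x) != p) {
    stop("x, y and confidence must be frame-by-part matrices matching bodyparts")
  }
  cf <- confidence[!is.na(confidence)]
  if (any(cf < 0 | cf > 1)) stop("confidence values must lie in [0, 1]")
  colnames(x) <- colnames(y) <- colnames(confidence) <- bodyparts
  structure(
    list(scorer = scorer, bodyparts = bodyparts,
         x = x, y = y, confidence = confidence),
    class = "tracking_table"
  )
}

#' @export
print.tracking_table <- function(x, ...) {
  cat(sprintf(
    "<tracking_table> scorer '%s' | %d frames | %d body parts: %s\n",
    x$scorer, nrow(x$x), length(x$bodyparts),
    paste(x$bodyparts, collapse = ", ")
  ))
  invisible(x)
}

n_frames <- function(table) nrow(table$x)

#' Write a pose-tracking table
#'
#' Emits the common pose-estimation CSV dialect: three header rows
#' (`scorer`, `bodyparts`, `coords`), a leading frame-index column counting
#' from 0, and per body part the columns `x`, `y`, `likelihood`
#' (bodypart-major order). Values are written with full float precision so
#' the file round-trips exactly; missing samples become empty cells.
#'
#' @param table A [tracking_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(table, path) {
  stopifnot(inherits(table, "tracking_table"))
  p <- length(table$bodyparts)
  header <- c(
    paste(c("scorer", rep(table$scorer, 3 * p)), collapse = ","),
    paste(c("bodyparts", rep(table$bodyparts, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), p)), collapse = ",")
  )
  n <- n_frames(table)
  con <- tryCatch(file(path, "wt"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(header, con)
  if (n > 0) {
    cols <- vector("list", 1 + 3 * p)
    cols[[1]] <- as.character(0:(n - 1))
    for (j in seq_len(p)) {
      cols[[3 * j - 1]] <- format_numeric_cells(table$x[, j])
      cols[[3 * j]] <- format_numeric_cells(table$y[, j])
      cols[[3 * j + 1]] <- format_numeric_cells(table$confidence[, j])
    }
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

# Shortest-exact decimal strings; NA/NaN become empty cells.
format_numeric_cells <- function(v) {
  out <- sprintf("%.17g", v)
  short <- sprintf("%.15g", v)
  keep <- !is.na(v) & (as.numeric(short) == v)
  out[keep] <- short[keep]
  out[is.na(v)] <- ""
  out
}

#' Read a pose-tracking table
#'
#' Parses the three-row-header CSV dialect written by
#' [write_tracking_table()] (and by common pose-estimation exporters) and
#' validates it strictly: the `coords` row must repeat `x`, `y`,
#' `likelihood` for every body part, body parts must be unique, all cells
#' numeric, all rows the same width, and frame indices contiguous from 0.
#' Empty cells are surfaced as `NaN` positions with confidence 0.
#'
#' @param path Path to a tracking CSV.
#' @return A [tracking_table()].
#' @export
read_tracking_table <- function(path) {
  if (!file.exists(path)) stop("tracking file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (length(txt) < 3) stop("format error in '", path, "': missing header rows")
  hdr <- strsplit(txt[1:3], ",", fixed = TRUE)
  scorer_row <- hdr[[1]]; parts_row <- hdr[[2]]; coords_row <- hdr[[3]]
  if (length(scorer_row) < 4 ||
      scorer_row[1] != "scorer" || parts_row[1] != "bodyparts" ||
      coords_row[1] != "coords") {
    stop("format error in '", path,
         "': expected header rows scorer / bodyparts / coords")
  }
  width <- length(scorer_row)
  if (length(parts_row) != width || length(coords_row) != width ||
      (width - 1) %% 3 != 0) {
    stop("format error in '", path, "': ragged or incomplete header")
  }
  p <- (width - 1) %/% 3
  if (!all(scorer_row[-1] == scorer_row[2])) {
    stop("format error in '", path, "': inconsistent scorer row")
  }
  bodyparts <- parts_row[1 + 3 * seq_len(p) - 2]
  if (!identical(parts_row[-1], rep(bodyparts, each = 3))) {
    stop("format error in '", path,
         "': bodyparts row must repeat each name three times")
  }
  if (anyDuplicated(bodyparts)) {
    stop("format error in '", path, "': duplicate body part '",
         bodyparts[duplicated(bodyparts)][1], "'")
  }
  if (!identical(coords_row[-1], rep(c("x", "y", "likelihood"), p))) {
    bad <- which(coords_row[-1] != rep(c("x", "y", "likelihood"), p))[1]
    stop("format error in '", path, "': coords row column ", bad + 1,
         " is '", coords_row[-1][bad], "' (expected x/y/likelihood triplets)")
  }

  body <- txt[-(1:3)]
  n <- length(body)
  if (n == 0) {
    z <- matrix(numeric(0), 0, p)
    return(tracking_table(z, z, z, bodyparts, scorer = scorer_row[2]))
  }
  raw <- tryCatch(
    data.table::fread(
      text = body, header = FALSE, sep = ",", colClasses = "character",
      na.strings = "", fill = FALSE, data.table = FALSE
    ),
    error = function(e) {
      stop("format error in '", path, "': ", conditionMessage(e))
    }
  )
  if (ncol(raw) != width) {
    stop("format error in '", path, "': data rows have ", ncol(raw),
         " columns, header has ", width)
  }
  num <- matrix(NA_real_, n, width)
  for (j in seq_len(width)) {
    v <- raw[[j]]
    z <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(z))
    if (length(bad) > 0) {
      stop("format error in '", path, "': non-numeric cell '", v[bad[1]],
           "' at data row ", bad[1], ", column ", j)
    }
    num[, j] <- z
  }
  frames <- num[, 1]
  if (anyNA(frames) || !isTRUE(all.equal(frames, as.numeric(0:(n - 1))))) {
    stop("format error in '", path,
         "': frame indices must be contiguous from 0")
  }
  x <- num[, 1 + 3 * seq_len(p) - 2, drop = FALSE]
  y <- num[, 1 + 3 * seq_len(p) - 1, drop = FALSE]
  confidence <- num[, 1 + 3 * seq_len(p), drop = FALSE]
  # missing samples: empty position cells -> NaN, empty likelihood -> 0
  x[is.na(x)] <- NaN
  y[is.na(y)] <- NaN
  confidence[is.na(confidence)] <- 0
  tracking_table(x, y, confidence, bodyparts, scorer = scorer_row[2])
}

# Split a trial recording into one tracking table per camera side, with the
# side suffix stripped from body-part names (files are per side).
recording_to_tables <- function(recording) {
  sides <- unique(point_side(names(recording$tracks)))
  out <- list()
  for (side in sides) {
    pts <- names(recording$tracks)[point_side(names(recording$tracks)) == side]
    stems <- sub("_(right|left)$", "", pts)
    x <- sapply(pts, function(pn) recording$tracks[[pn]]$x)
    y <- sapply(pts, function(pn) recording$tracks[[pn]]$y)
    cf <- sapply(pts, function(pn) recording$tracks[[pn]]$confidence)
    if (is.null(dim(x))) { # single frame
      x <- matrix(x, 1); y <- matrix(y, 1); cf <- matrix(cf, 1)
    }
    out[[side]] <- tracking_table(x, y, cf, stems)
  }
  out
}
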