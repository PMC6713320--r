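# Capture file schemas
#
# Two plain-text dialects are supported. Neither is a vendor format; they are
# the package's documented interchange schemas for labelled 3D marker data.
#
# tsv_wide: header lines, then one row per frame of x/y/z triplets:
#     FRAME_RATE   100
#     START_TIME   0
#     ZERO_AS_MISSING  0            (optional; 1 = treat (0,0,0) as occluded)
#     AXES         x:forward y:left z:up   (optional, informational)
#     MARKER_NAMES L4  T12  ...
#     <x> <y> <z>  <x> <y> <z> ...  (tab-separated; blank cell = occluded)
# csv_long: columns frame,time,marker,x,y,z; a missing (frame, marker) row
#     means the marker was occluded at that frame. Frames are 0-based.

#' Read a marker-trajectory table
#'
#' Parses a capture file in one of the two supported plain-text dialects into
#' a [trajectory_set()]. Frames where a marker's coordinates are absent
#' (blank cells in `tsv_wide`, missing rows in `csv_long`) get
#' `valid = FALSE`. Some motion-capture exports write `(0,0,0)` for occluded
#' markers; that convention is honoured only when the `tsv_wide` header sets
#' `ZERO_AS_MISSING 1` (or `zero_as_missing = TRUE` is passed), so legitimate
#' near-origin points are not destroyed by default.
#'
#' @param path file path.
#' @param dialect `"tsv_wide"` or `"csv_long"`.
#' @param zero_as_missing treat exact `(0,0,0)` rows as occluded. Default
#'   `NA`: use the file header's `ZERO_AS_MISSING` flag if present, else off.
#' @return a `trajectory_set`.
#' @export
read_trajectory_table <- function(path, dialect = c("tsv_wide", "csv_long"),
                                  zero_as_missing = NA) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv_wide") {
    read_tsv_wide(path, zero_as_missing)
  } else {
    read_csv_long(path, zero_as_missing)
  }
}

read_tsv_wide <- function(path, zero_as_missing) {
  lines <- readLines(path)
  header <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    key <- parts[1L]
    if (!key %in% c("FRAME_RATE", "START_TIME", "ZERO_AS_MISSING",
                    "AXES", "MARKER_NAMES")) break
    header[[key]] <- parts[-1L]
    i <- i + 1L
    if (key == "MARKER_NAMES") break
  }
  if (is.null(header$FRAME_RATE) || is.null(header$MARKER_NAMES))
    stop("format error: tsv_wide header must declare FRAME_RATE and ",
         "MARKER_NAMES", call. = FALSE)
  frame_rate <- as.numeric(header$FRAME_RATE[1L])
  start_time <- if (!is.null(header$START_TIME))
    as.numeric(header$START_TIME[1L]) else 0
  if (is.na(zero_as_missing))
    zero_as_missing <- !is.null(header$ZERO_AS_MISSING) &&
      header$ZERO_AS_MISSING[1L] == "1"
  labels <- header$MARKER_NAMES
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncol_expect <- 3L * length(labels)
  mat <- matrix(NA_real_, nrow = length(body), ncol = ncol_expect)
  for (r in seq_along(cells)) {
    row <- cells[[r]]
    if (length(row) > ncol_expect)
      stop("format error: row ", r, " has ", length(row),
           " fields, expected ", ncol_expect, call. = FALSE)
    length(row) <- ncol_expect            # pad trailing blanks
    row[!nzchar(row) | is.na(row)] <- NA
    mat[r, ] <- suppressWarnings(as.numeric(row))
  }
  markers <- list()
  for (k in seq_along(labels)) {
    pos <- mat[, (3L * (k - 1L) + 1L):(3L * k), drop = FALSE]
    valid <- rowSums(is.na(pos)) == 0L
    if (zero_as_missing)
      valid <- valid & !(rowSums(pos == 0, na.rm = TRUE) == 3L & valid)
    markers[[labels[k]]] <- list(positions = pos, valid = valid)
  }
  trajectory_set(markers, frame_rate = frame_rate, start_time = start_time)
}

read_csv_long <- function(path, zero_as_missing) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time", "marker", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("format error: csv_long needs columns ",
         paste(need, collapse = ","), call. = FALSE)
  if (nrow(df) == 0L) stop("format error: empty capture", call. = FALSE)
  frames <- sort(unique(df$frame))
  if (!identical(frames, seq.int(min(frames), max(frames))))
    stop("structure error: frame indices are not contiguous", call. = FALSE)
  n <- length(frames)
  f0 <- min(frames)
  # frame rate from the time column; start_time from the first frame
  fit <- stats::coef(stats::lm(time ~ frame, data = df))
  frame_rate <- 1 / fit[["frame"]]
  start_time <- fit[["(Intercept)"]] + f0 * fit[["frame"]]
  if (isTRUE(zero_as_missing)) {
    zero <- df$x == 0 & df$y == 0 & df$z == 0
    df <- df[!zero, , drop = FALSE]
  }
  markers <- list()
  for (lab in unique(df$marker)) {
    sub <- df[df$marker == lab, , drop = FALSE]
    pos <- matrix(NA_real_, n, 3L)
    idx <- sub$frame - f0 + 1L
    pos[idx, ] <- as.matrix(sub[, c("x", "y", "z")])
    markers[[lab]] <- list(positions = pos, valid = !is.na(pos[, 1L]))
  }
  trajectory_set(markers, frame_rate = round(frame_rate, 9),
                 start_time = round(start_time, 9))
}

#' Write a marker-trajectory table
#'
#' Inverse of [read_trajectory_table()]; round-trips a `trajectory_set`
#' losslessly (numbers to better than 1e-9 relative).
#'
#' @param ts a `trajectory_set`.
#' @param path output file path.
#' @param dialect `"tsv_wide"` or `"csv_long"`.
#' @return invisibly `path`.
#' @export
write_trajectory_table <- function(ts, path,
                                   dialect = c("tsv_wide", "csv_long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ts, "trajectory_set"))
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  if (dialect == "tsv_wide") {
    labels <- names(ts$markers)
    head <- c(
      paste("FRAME_RATE", sprintf("%.10g", ts$frame_rate), sep = "\t"),
      paste("START_TIME", sprintf("%.10g", ts$start_time), sep = "\t"),
      paste(c("MARKER_NAMES", labels), collapse = "\t")
    )
    block <- do.call(cbind, lapply(ts$markers, function(m) m$positions))
    rows <- apply(block, 1L, function(r) paste(fmt(r), collapse = "\t"))
    writeLines(c(head, rows), path)
  } else {
    n <- n_frames(ts)
    t <- frame_times(ts)
    out <- do.call(rbind, lapply(names(ts$markers), function(lab) {
      m <- ts$markers[[lab]]
      keep <- m$valid
      data.frame(frame = which(keep) - 1L, time = t[keep], marker = lab,
                 x = m$positions[keep, 1L], y = m$positions[keep, 2L],
                 z = m$positions[keep, 3L])
    }))
    out <- out[order(out$frame, out$marker), , drop = FALSE]
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Fill short occlusion gaps by linear interpolation
#'
#' Interior runs of invalid frames no longer than `max_gap_frames` are
#' replaced, per coordinate, by linear interpolation between the flanking
#' valid frames and marked valid. Longer gaps, and gaps touching either end
#' of the capture, are left untouched. The operation is idempotent.
#'
#' @param ts a `trajectory_set`.
#' @param max_gap_frames maximum gap length (frames) to fill; >= 0.
#' @return a new `trajectory_set`.
#' @export
fill_gaps <- function(ts, max_gap_frames) {
  stopifnot(inherits(ts, "trajectory_set"),
            is.numeric(max_gap_frames), max_gap_frames >= 0)
  n <- n_frames(ts)
  markers <- lapply(ts$markers, function(m) {
    v <- m$valid
    if (all(v) || max_gap_frames == 0) return(m)
    runs <- rle(v)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in seq_along(runs$values)) {
      if (runs$values[j]) next
      a <- starts[j]; b <- ends[j]
      if (a == 1L || b == n) next                     # edge gap
      if (runs$lengths[j] > max_gap_frames) next
      lo <- a - 1L; hi <- b + 1L
      w <- (seq.int(a, b) - lo) / (hi - lo)
      for (c in 1:3)
        m$positions[a:b, c] <- m$positions[lo, c] +
          w * (m$positions[hi, c] - m$positions[lo, c])
      m$valid[a:b] <- TRUE
    }
    m
  })
  trajectory_set(markers, frame_rate = ts$frame_rate,
                 start_time = ts$start_time)
}

#' Write the per-frame derived-record file
#'
#' Stores the quantities the live system logged every 10 ms: timestamp, all
#' 3D marker positions, the non-dimensional spine bend `sb` and barbell-foot
#' distance `bfd`, and — for sonification sessions — the distortion level and
#' the two output channel volumes. Control (no-feedback) sessions pass
#' `controls = NULL`; the three audio columns are then emitted blank.
#'
#' Column order (tab-separated): `time`, `<marker>_x/_y/_z` for each marker,
#' `sb`, `bfd`, `distortion`, `volume_right`, `volume_left`. Distortion is
#' `1 - quality`; the left channel carries the front gain, the right channel
#' the surround gain (the live routing's channel assignment).
#'
#' @param ts a `trajectory_set`.
#' @param derived a `derived_series` (see [derive_series()]).
#' @param controls a `control_series` (see [control_series()]) or `NULL`.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_derived_records <- function(ts, derived, controls = NULL, path) {
  stopifnot(inherits(ts, "trajectory_set"),
            inherits(derived, "derived_series"))
  n <- n_frames(ts)
  if (nrow(derived) != n)
    stop("contract error: derived series has ", nrow(derived),
         " frames, capture has ", n, call. = FALSE)
  if (!is.null(controls)) {
    stopifnot(inherits(controls, "control_series"))
    if (nrow(controls) != n)
      stop("contract error: control series has ", nrow(controls),
           " frames, capture has ", n, call. = FALSE)
  }
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  labels <- names(ts$markers)
  pos_cols <- paste(rep(labels, each = 3L), c("x", "y", "z"), sep = "_")
  header <- paste(c("time", pos_cols, "sb", "bfd",
                    "distortion", "volume_right", "volume_left"),
                  collapse = "\t")
  if (n == 0L) { writeLines(header, path); return(invisible(path)) }
  block <- do.call(cbind, lapply(ts$markers, function(m) m$positions))
  aud <- if (is.null(controls)) matrix(NA_real_, n, 3L) else
    cbind(1 - controls$quality, controls$gain_surround, controls$gain_front)
  tab <- cbind(frame_times(ts), block, derived$sb, derived$bfd, aud)
  rows <- apply(tab, 1L, function(r) paste(fmt(r), collapse = "\t"))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a derived-record file
#'
#' @param path a file written by [write_derived_records()].
#' @return a data.frame with the file's columns; blank audio cells become
#'   `NA`.
#' @export
read_derived_records <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("time", "sb", "bfd", "distortion", "volume_right", "volume_left")
  if (!all(need %in% names(df)))
    stop("format error: not a derived-record file", call. = FALSE)
  df
}
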