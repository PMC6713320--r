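# Repetition segmentation from the vertical bar path
#
# The bar-height signal (midpoint of the two barbell extremity markers) is
# low-pass filtered, lift tops are detected as prominent peaks, and each
# repetition spans valley to valley around one peak. The first repetitions
# of a set and the last ones are discarded before averaging, to strip
# transient effects at the start and end of a series.

#' Vertical bar-height signal of a capture
#' @param ts a `trajectory_set`.
#' @param roles a [marker_role_map()].
#' @return numeric vector (mm): per-frame height of the barbell midpoint,
#'   `NA` where either extremity is occluded.
#' @export
bar_height <- function(ts, roles) {
  check_roles(ts, roles)
  z <- (role_positions(ts, roles, "barbell_end_left")[, 3L] +
        role_positions(ts, roles, "barbell_end_right")[, 3L]) / 2
  z
}

#' Segment a capture into deadlift repetitions
#'
#' Low-pass filters the bar-height signal (zero-phase Butterworth, `cutoff`
#' Hz), finds local maxima with topographic prominence at least
#' `min_amplitude_frac` times the filtered signal's range and at least
#' `min_period` apart, and brackets each peak by the minima toward its
#' neighbouring peaks (signal ends for the outermost). Repetition spans tile
#' the covered region without overlap.
#'
#' @param bar_z bar height per frame (mm); interior `NA`s are linearly
#'   bridged before filtering.
#' @param frame_rate Hz.
#' @param min_amplitude_frac peak prominence threshold as a fraction of the
#'   signal range (default 0.5).
#' @param min_period minimum peak separation in seconds (default 1.0).
#' @param cutoff low-pass cutoff in Hz (default 4).
#' @return data.frame of class `repetition_set`: columns `index`,
#'   `start_frame`, `top_frame`, `end_frame` (1-based, inclusive). A flat
#'   signal yields zero rows.
#' @export
segment_reps <- function(bar_z, frame_rate, min_amplitude_frac = 0.5,
                         min_period = 1.0, cutoff = 4) {
  stopifnot(is.numeric(bar_z), frame_rate > 0)
  if (length(bar_z) < 2 * frame_rate)
    stop("input error: need at least 2 s of signal", call. = FALSE)
  if (all(is.na(bar_z)))
    stop("input error: bar-height signal is entirely missing", call. = FALSE)
  z <- bridge_na(bar_z)
  if (any(!is.finite(z)))
    stop("input error: non-finite bar-height signal", call. = FALSE)
  rng <- diff(range(z))
  empty <- data.frame(index = integer(), start_frame = integer(),
                      top_frame = integer(), end_frame = integer())
  class(empty) <- c("repetition_set", "data.frame")
  if (rng == 0) return(empty)
  zf <- lowpass(z, frame_rate, cutoff)
  peaks <- find_prominent_peaks(zf, min_prominence = min_amplitude_frac *
                                  diff(range(zf)),
                                min_sep = round(min_period * frame_rate))
  if (length(peaks) == 0L) return(empty)
  # valleys: minimum between consecutive peaks; signal ends outside
  k <- length(peaks)
  valleys <- integer(k + 1L)
  valleys[1L] <- which.min(zf[1:peaks[1L]])
  if (k > 1L) for (j in seq_len(k - 1L)) {
    seg <- peaks[j]:peaks[j + 1L]
    valleys[j + 1L] <- seg[which.min(zf[seg])]
  }
  valleys[k + 1L] <- (peaks[k]:length(zf))[which.min(zf[peaks[k]:length(zf)])]
  out <- data.frame(
    index = seq_len(k),
    start_frame = valleys[1:k],
    top_frame = peaks,
    end_frame = c(if (k > 1L) valleys[2:k] - 1L, valleys[k + 1L])
  )
  class(out) <- c("repetition_set", "data.frame")
  out
}

# linear interpolation across interior NA runs; edge NAs held at nearest
bridge_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) < 2L) return(x)
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

# zero-phase low-pass (2nd-order Butterworth, forward-backward)
lowpass <- function(x, fs, cutoff) {
  if (cutoff >= fs / 2) return(x)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "low")
  # reflect-pad to tame filtfilt edge transients on short signals
  np <- min(length(x) - 1L, as.integer(3 * fs / cutoff))
  xp <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[length(x)] -
            x[(length(x) - 1L):(length(x) - np)])
  y <- signal::filtfilt(bf, xp)
  y[(np + 1L):(np + length(x))]
}

# local maxima with topographic prominence >= min_prominence and pairwise
# separation >= min_sep frames (greedy by height)
find_prominent_peaks <- function(x, min_prominence, min_sep) {
  n <- length(x)
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  # plateaus: rising then flat then falling
  if (length(cand) == 0L) return(integer())
  prom <- vapply(cand, function(p) {
    h <- x[p]
    # walk left to the previous strictly higher point
    lmin <- h
    i <- p
    while (i > 1L) { i <- i - 1L; if (x[i] > h) break; lmin <- min(lmin, x[i]) }
    if (x[i] <= h) lmin <- min(lmin, x[i])
    rmin <- h
    i <- p
    while (i < n) { i <- i + 1L; if (x[i] > h) break; rmin <- min(rmin, x[i]) }
    if (x[i] <= h) rmin <- min(rmin, x[i])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1L) return(keep)
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer()
  for (p in ord)
    if (all(abs(p - sel) >= min_sep)) sel <- c(sel, p)
  sort(sel)
}

#' Apply the repetition discard rule
#'
#' Drops the first `discard_head` and last `discard_tail` detected
#' repetitions; the remainder feed the session averages. With the defaults,
#' a 10-repetition set retains the middle five. If nothing remains, an empty
#' set is returned with a warning.
#'
#' @param reps a `repetition_set` from [segment_reps()].
#' @param discard_head repetitions dropped from the start (default 3).
#' @param discard_tail repetitions dropped from the end (default 2).
#' @return a `repetition_set` (indices renumbered from 1).
#' @export
retain_reps <- function(reps, discard_head = 3, discard_tail = 2) {
  stopifnot(inherits(reps, "repetition_set"),
            discard_head >= 0, discard_tail >= 0)
  n <- nrow(reps)
  if (n - discard_head - discard_tail <= 0) {
    if (n > 0)
      warning("discard rule leaves no repetitions (", n, " detected, ",
              discard_head, " + ", discard_tail, " discarded)")
    out <- reps[integer(), , drop = FALSE]
    class(out) <- c("repetition_set", "data.frame")
    return(out)
  }
  out <- reps[(discard_head + 1L):(n - discard_tail), , drop = FALSE]
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("repetition_set", "data.frame")
  out
}

#' Per-repetition means of the derived series
#'
#' @param derived a `derived_series`.
#' @param reps a `repetition_set`.
#' @return the `repetition_set` with `mean_sb` and `mean_bfd` columns
#'   (mean over the repetition's frames, missing frames excluded; `NaN`
#'   when a repetition has no valid frame).
#' @export
rep_means <- function(derived, reps) {
  stopifnot(inherits(derived, "derived_series"),
            inherits(reps, "repetition_set"))
  mean_over <- function(v, a, b) mean(v[a:b], na.rm = TRUE)
  reps$mean_sb <- mapply(mean_over, reps$start_frame, reps$end_frame,
                         MoreArgs = list(v = derived$sb))
  reps$mean_bfd <- mapply(mean_over, reps$start_frame, reps$end_frame,
                          MoreArgs = list(v = derived$bfd))
  reps
}

#' Summarise a session over its retained repetitions
#'
#' The session-level quantity is the two-stage mean: the unweighted mean of
#' the per-repetition means, which matches averaging "over repetitions" and
#' is robust to repetitions of different duration. A pooled-frame variant is
#' available via `method = "pooled"`. Repetitions with no valid frame are
#' excluded.
#'
#' @param derived a `derived_series`.
#' @param reps retained repetitions ([retain_reps()] output), with or
#'   without precomputed means.
#' @param participant_id,condition session metadata; condition one of
#'   `"control"`, `"spine"`, `"barbell"`, `"combination"`.
#' @param n_detected optionally, the repetition count before the discard
#'   rule (for bookkeeping).
#' @param method `"two_stage"` (default) or `"pooled"`.
#' @return one-row data.frame of class `session_summary`: `participant_id`,
#'   `condition`, `n_reps_detected`, `n_reps_retained`, `mean_sb`,
#'   `mean_bfd`.
#' @export
summarize_session <- function(derived, reps, participant_id = NA_character_,
                              condition = c("control", "spine", "barbell",
                                            "combination"),
                              n_detected = NA_integer_,
                              method = c("two_stage", "pooled")) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  stopifnot(inherits(reps, "repetition_set"))
  if (nrow(reps) == 0L)
    stop("summary error: no retained repetitions for participant ",
         participant_id, " (", condition, ")", call. = FALSE)
  if (method == "two_stage") {
    if (is.null(reps$mean_sb)) reps <- rep_means(derived, reps)
    msb <- mean(reps$mean_sb[is.finite(reps$mean_sb)])
    mbfd <- mean(reps$mean_bfd[is.finite(reps$mean_bfd)])
  } else {
    fr <- unlist(mapply(seq.int, reps$start_frame, reps$end_frame,
                        SIMPLIFY = FALSE))
    msb <- mean(derived$sb[fr], na.rm = TRUE)
    mbfd <- mean(derived$bfd[fr], na.rm = TRUE)
  }
  out <- data.frame(participant_id = participant_id, condition = condition,
                    n_reps_detected = n_detected,
                    n_reps_retained = nrow(reps),
                    mean_sb = msb, mean_bfd = mbfd,
                    stringsAsFactors = FALSE)
  class(out) <- c("session_summary", "data.frame")
  out
}
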