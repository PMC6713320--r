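# Offline feedback renderer
#
# The live system degraded a playing music track in real time; this renderer
# applies the same control stream to a WAV file after the fact, so sessions
# can be auralised and the mapping audited. Controls are held
# piecewise-constant between control frames (zero-order hold; the live
# control period was 10 ms).
#
# Spine channel: sample-and-hold decimation. Quality q in (0, 1] gives a
# hold length h = round(1 / max(q, q_min)) samples; within each control
# frame every run of h samples repeats its first sample. q = 1 is the
# identity; falling q lengthens the hold, producing the aliased "metallic"
# downsampling character.
#
# Barbell channel: the output is gain_surround * (original image) +
# gain_front * (front downmix), where the front downmix is the mid (mono)
# signal in both channels. gains (front = 0, surround = 1) is the identity;
# (1, 0) collapses the stereo width to a frontal mono image.

#' Render a control series onto audio
#'
#' @param audio a `wav` object (see [read_wav()], [wav()]).
#' @param controls a `control_series`; its frame rate is inferred from the
#'   `time` column and must not exceed the audio sample rate. Controls are
#'   zero-order-held across each control frame; audio beyond the last
#'   control frame keeps the last control value.
#' @param mode `"spine"` (degradation only), `"barbell"` (spatial gains
#'   only), or `"combination"` (degradation, then gains).
#' @param q_min floor on quality when converting to a hold length; caps the
#'   worst-case hold at `round(1/q_min)` samples.
#' @return a `wav` of the same length, channel count, rate and bit depth.
#' @export
render_feedback <- function(audio, controls,
                            mode = c("spine", "barbell", "combination"),
                            q_min = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(audio, "wav"), inherits(controls, "control_series"),
            nrow(controls) >= 1L, q_min > 0)
  x <- audio$samples
  n <- nrow(x)
  ctrl_rate <- if (nrow(controls) > 1L)
    1 / stats::median(diff(controls$time)) else 1
  if (ctrl_rate > audio$sample_rate)
    stop("control frame rate exceeds the audio sample rate", call. = FALSE)
  # control frame index of each audio sample (zero-order hold)
  t <- (seq_len(n) - 1L) / audio$sample_rate
  idx <- findInterval(t, controls$time - controls$time[1L])
  idx[idx < 1L] <- 1L
  idx[idx > nrow(controls)] <- nrow(controls)

  if (mode %in% c("spine", "combination")) {
    q <- pmax(controls$quality, q_min)
    q[is.na(q)] <- 1                      # missing frames: leave pristine
    hold <- pmax(1L, as.integer(round(1 / q)))
    # frame boundaries in sample space
    changes <- c(1L, which(diff(idx) != 0L) + 1L, n + 1L)
    for (b in seq_len(length(changes) - 1L)) {
      a <- changes[b]; e <- changes[b + 1L] - 1L
      h <- hold[idx[a]]
      if (h > 1L) {
        rel <- seq.int(a, e) - a
        src <- a + (rel %/% h) * h
        x[a:e, ] <- x[src, , drop = FALSE]
      }
    }
  }
  if (mode %in% c("barbell", "combination")) {
    gf <- controls$gain_front[idx]
    gs <- controls$gain_surround[idx]
    gf[is.na(gf)] <- 0; gs[is.na(gs)] <- 1
    mid <- rowMeans(x)
    x <- x * gs + matrix(mid, n, ncol(x)) * gf
  }
  wav(x, sample_rate = audio$sample_rate, bit_depth = audio$bit_depth)
}
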