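# Logistic mapping from movement quantities to audio control
#
# Both feedback channels use the same decreasing logistic
#     y = 1 - 1 / (1 + exp(-alpha * (x - beta)))
# with channel-specific steepness alpha and midpoint beta:
#   spine   channel: alpha = 10, beta = 0.2  (input sb,  output = quality fed
#           to the sample-rate degradation; 1 = pristine)
#   barbell channel: alpha = 15, beta = 0.6  (input bfd, output = front gain;
#           surround gain is its complement)
# beta leaves a margin of movement around perfect form before the feedback
# bites; alpha sets how abruptly it bites.

#' Logistic mapping parameters
#'
#' @param alpha steepness (> 0, dimensionless).
#' @param beta midpoint (dimensionless): the input value mapped to 0.5.
#' @return object of class `mapping_params`.
#' @export
mapping_params <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(list(alpha = alpha, beta = beta), class = "mapping_params")
}

#' Default spine-channel parameters (alpha = 10, beta = 0.2)
#' @return a [mapping_params()].
#' @export
spine_params <- function() mapping_params(10, 0.2)

#' Default barbell-channel parameters (alpha = 15, beta = 0.6)
#' @return a [mapping_params()].
#' @export
barbell_params <- function() mapping_params(15, 0.6)

#' Decreasing logistic map
#'
#' `y = 1 - 1/(1 + exp(-alpha * (x - beta)))`. Strictly decreasing in `x`,
#' `y(beta) = 0.5`, asymptotes 1 (x -> -Inf) and 0 (x -> +Inf), and
#' symmetric about the midpoint: `y(beta + d) + y(beta - d) = 1`.
#'
#' @param x numeric input (vectorised); `NA` propagates.
#' @param params a [mapping_params()].
#' @return numeric in (0, 1).
#' @examples
#' logistic_map(0.2, spine_params())   # 0.5
#' logistic_map(0, spine_params())     # 1 - 1/(1 + exp(2)) = 0.8807971
#' @export
logistic_map <- function(x, params) {
  stopifnot(inherits(params, "mapping_params"))
  1 - stats::plogis(params$alpha * (x - params$beta))
}

#' Spine feedback control: degradation quality
#'
#' Maps the non-dimensional spine bend through the spine-channel logistic.
#' The output is the quality input of the sample-rate degradation: near 1
#' for neutral or extended spine (no distortion), falling toward 0 as
#' forward flexion approaches the calibrated maximum.
#'
#' @param sb non-dimensional spine bend (vectorised; `NA` propagates).
#' @param params spine-channel [mapping_params()].
#' @return quality in (0, 1).
#' @export
spine_control <- function(sb, params = spine_params()) {
  logistic_map(sb, params)
}

#' Barbell feedback control: front/surround channel gains
#'
#' Maps the non-dimensional barbell-foot distance through the barbell-channel
#' logistic; the output is the gain of the frontal speaker group and the
#' surround group gets the complement, so the two always sum to 1. A bar
#' drifting toward the toes (`bfd -> 0`) collapses the sound to the front;
#' a vertical bar path (`bfd >= 1`) keeps the full immersive image.
#'
#' @param bfd non-dimensional barbell-foot distance (vectorised).
#' @param params barbell-channel [mapping_params()].
#' @return data.frame with columns `gain_front`, `gain_surround`.
#' @export
barbell_control <- function(bfd, params = barbell_params()) {
  y <- logistic_map(bfd, params)
  data.frame(gain_front = y, gain_surround = 1 - y)
}

#' Build a per-frame control series
#'
#' Combines the spine and barbell channels into the per-frame audio-control
#' record: degradation quality and the two complementary gains.
#'
#' @param time frame timestamps (s).
#' @param sb,bfd non-dimensional kinematic series (same length as `time`).
#' @param spine,barbell channel [mapping_params()].
#' @return data.frame of class `control_series` with columns `time`,
#'   `quality`, `gain_front`, `gain_surround`.
#' @export
control_series <- function(time, sb, bfd,
                           spine = spine_params(),
                           barbell = barbell_params()) {
  stopifnot(length(time) == length(sb), length(sb) == length(bfd))
  g <- barbell_control(bfd, barbell)
  out <- data.frame(time = time, quality = spine_control(sb, spine),
                    gain_front = g$gain_front,
                    gain_surround = g$gain_surround)
  class(out) <- c("control_series", "data.frame")
  out
}

#' Derive the control series of a capture
#'
#' Convenience wrapper: [derive_series()] followed by [control_series()].
#' @param derived a `derived_series`.
#' @inheritParams control_series
#' @return a `control_series`.
#' @export
controls_from_derived <- function(derived, spine = spine_params(),
                                  barbell = barbell_params()) {
  stopifnot(inherits(derived, "derived_series"))
  control_series(derived$time, derived$sb, derived$bfd, spine, barbell)
}

#' Write / read a control series as CSV
#' @param cs a `control_series`.
#' @param path file path.
#' @return invisibly `path` (write) or a `control_series` (read).
#' @export
write_control_series <- function(cs, path) {
  stopifnot(inherits(cs, "control_series"))
  utils::write.csv(as.data.frame(cs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_control_series
#' @export
read_control_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "quality", "gain_front", "gain_surround")
  if (!all(need %in% names(df)))
    stop("format error: not a control-series file", call. = FALSE)
  class(df) <- c("control_series", "data.frame")
  df
}
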