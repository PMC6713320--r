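# Kinematic quantities of the deadlift
#
# Two physical quantities drive the feedback:
#   spine bend  — length of the 4-marker vertebral chain L4-T12-T7-C2 (mm);
#                 forward flexion stretches the chain.
#   B-F distance — horizontal offset between the barbell axis and the
#                 front-of-foot markers (mm, signed); the bar should travel
#                 vertically over the mid-foot, not drift out to the toes.
# Per-athlete calibration turns both into non-dimensional forms:
#   sb  = (spine_bend - neutral_spine) / (max_spine_bend - neutral_spine)
#   bfd = bf_distance / initial_bf_distance

#' Spine-chain length
#'
#' Sum of the consecutive Euclidean distances along the four spine markers,
#' caudal to cranial: |L4-T12| + |T12-T7| + |T7-C2|. Vectorised over frames;
#' invariant under rigid motion of the whole frame.
#'
#' @param p_L4,p_T12,p_T7,p_C2 3D points in mm: length-3 vectors or
#'   `n x 3` matrices.
#' @return numeric vector of chain lengths (mm); `NA` where any input row
#'   contains `NA`.
#' @examples
#' spine_length(c(0, 0, 0), c(0, 0, 100), c(0, 0, 200), c(0, 0, 300)) # 300
#' @export
spine_length <- function(p_L4, p_T12, p_T7, p_C2) {
  m <- lapply(list(p_L4, p_T12, p_T7, p_C2), as_points)
  seg <- function(a, b) sqrt(rowSums((a - b)^2))
  seg(m[[1]], m[[2]]) + seg(m[[2]], m[[3]]) + seg(m[[3]], m[[4]])
}

as_points <- function(p) {
  if (is.matrix(p)) { stopifnot(ncol(p) == 3L); p }
  else { stopifnot(length(p) == 3L); matrix(as.numeric(p), 1L, 3L) }
}

#' Signed horizontal barbell-foot distance
#'
#' All points are projected onto the horizontal (floor) plane. The barbell
#' axis is the infinite line through the two projected barbell extremities;
#' the perpendicular distance from each projected front-foot marker to that
#' line is computed and the smaller magnitude of the two is returned. The
#' sign is carried by `axis`, a unit horizontal vector: positive when the
#' barbell line lies on the side of the (nearer) foot marker that `axis`
#' points toward, negative on the opposite side. In the pipeline `axis`
#' points from the front-foot markers toward the athlete (see
#' [estimate_sign_axis()]), so the usual setup — bar over the mid-foot,
#' behind the toe markers — gives positive values, and a bar drifting past
#' the toes goes negative.
#'
#' An alternative reading of "horizontal component" measures the offset along
#' `axis` itself rather than perpendicular to the bar line; set
#' `projection = "axis"` to compare. The two agree when the bar is
#' perpendicular to `axis` (no yaw).
#'
#' @param barbell_left,barbell_right barbell extremity points (mm); vectors
#'   or `n x 3` matrices. Swapping them does not change the result.
#' @param foot_left,foot_right front-of-foot marker points (mm).
#' @param axis length-2 or length-3 numeric; its horizontal part is
#'   normalised and fixes the sign.
#' @param projection `"perpendicular"` (default) or `"axis"`.
#' @return numeric vector of signed distances (mm); `NA` where inputs are
#'   `NA`.
#' @export
bf_distance <- function(barbell_left, barbell_right, foot_left, foot_right,
                        axis, projection = c("perpendicular", "axis")) {
  projection <- match.arg(projection)
  b1 <- as_points(barbell_left)[, 1:2, drop = FALSE]
  b2 <- as_points(barbell_right)[, 1:2, drop = FALSE]
  f  <- list(as_points(foot_left)[, 1:2, drop = FALSE],
             as_points(foot_right)[, 1:2, drop = FALSE])
  a <- as.numeric(axis)[1:2]
  na <- sqrt(sum(a^2))
  if (!is.finite(na) || na == 0)
    stop("axis must have a nonzero horizontal component", call. = FALSE)
  a <- a / na
  d <- b2 - b1
  len <- sqrt(rowSums(d^2))
  if (any(is.finite(len) & len < 1e-9))
    stop("geometry error: barbell extremities coincide after horizontal ",
         "projection", call. = FALSE)
  signed_to <- function(fp) {
    if (projection == "perpendicular") {
      # closest point on the line to the foot, then its offset along axis
      tpar <- (rowSums((fp - b1) * d)) / len^2
      cp <- b1 + d * tpar
      off <- cp - fp
      perp <- sqrt(rowSums(off^2))
      s <- sign(off[, 1L] * a[1L] + off[, 2L] * a[2L])
      s[s == 0] <- 1
      perp * s
    } else {
      # offset of the line from the foot measured along axis
      tn <- cbind(-d[, 2L], d[, 1L]) / len      # line normal
      num <- rowSums((b1 - fp) * tn)
      den <- tn[, 1L] * a[1L] + tn[, 2L] * a[2L]
      num / den
    }
  }
  d1 <- signed_to(f[[1]])
  d2 <- signed_to(f[[2]])
  ifelse(is.na(d1) | is.na(d2), NA_real_,
         ifelse(abs(d1) <= abs(d2), d1, d2))
}

#' Estimate the sign axis from a static pose
#'
#' Unit horizontal vector from the midpoint of the two front-foot markers
#' toward the L4 marker (toe-to-athlete direction), median over the capture's
#' valid frames. Used as the `axis` argument of [bf_distance()], making the
#' setup distance positive and past-the-toes excursions negative.
#'
#' @param ts a `trajectory_set`.
#' @param roles a [marker_role_map()].
#' @return length-2 unit vector (horizontal plane).
#' @export
estimate_sign_axis <- function(ts, roles) {
  check_roles(ts, roles)
  l4 <- role_positions(ts, roles, "spine_L4")[, 1:2, drop = FALSE]
  fm <- (role_positions(ts, roles, "foot_front_left") +
         role_positions(ts, roles, "foot_front_right"))[, 1:2, drop = FALSE] / 2
  ok <- role_valid(ts, roles, "spine_L4") &
    role_valid(ts, roles, "foot_front_left") &
    role_valid(ts, roles, "foot_front_right")
  if (!any(ok)) stop("no frames with L4 and both foot markers valid",
                     call. = FALSE)
  v <- c(stats::median(l4[ok, 1L] - fm[ok, 1L]),
         stats::median(l4[ok, 2L] - fm[ok, 2L]))
  n <- sqrt(sum(v^2))
  if (n == 0) stop("degenerate pose: L4 directly above the mid-foot",
                   call. = FALSE)
  v / n
}

#' Per-athlete calibration from a static pose capture
#'
#' Three short static captures define the athlete's reference values: the
#' unloaded neutral spine-chain length, the chain length at instructed
#' maximal (incorrect) bend, and the horizontal barbell-foot distance in the
#' setup position over the mid-foot. Each call returns the median of the
#' relevant quantity over a window at the start of the capture; the median
#' resists marker jitter and brief occlusions.
#'
#' @param static_capture a `trajectory_set` of the held pose.
#' @param roles a [marker_role_map()].
#' @param pose one of `"neutral_spine"`, `"max_spine_bend"`, `"initial_bfd"`.
#' @param window seconds of capture to use (default 1.0).
#' @param axis sign axis for the `initial_bfd` pose; default estimated from
#'   the capture itself via [estimate_sign_axis()].
#' @return scalar mm.
#' @export
calibrate <- function(static_capture, roles,
                      pose = c("neutral_spine", "max_spine_bend",
                               "initial_bfd"),
                      window = 1.0, axis = NULL) {
  pose <- match.arg(pose)
  check_roles(static_capture, roles)
  n <- n_frames(static_capture)
  nw <- floor(window * static_capture$frame_rate)
  if (n < nw)
    stop("calibration error (", pose, "): capture of ", n,
         " frames is shorter than the ", window, " s window", call. = FALSE)
  idx <- seq_len(nw)
  if (pose %in% c("neutral_spine", "max_spine_bend")) {
    vals <- spine_length(
      role_positions(static_capture, roles, "spine_L4")[idx, , drop = FALSE],
      role_positions(static_capture, roles, "spine_T12")[idx, , drop = FALSE],
      role_positions(static_capture, roles, "spine_T7")[idx, , drop = FALSE],
      role_positions(static_capture, roles, "spine_C2")[idx, , drop = FALSE])
  } else {
    if (is.null(axis)) axis <- estimate_sign_axis(static_capture, roles)
    vals <- bf_distance(
      role_positions(static_capture, roles, "barbell_end_left")[idx, , drop = FALSE],
      role_positions(static_capture, roles, "barbell_end_right")[idx, , drop = FALSE],
      role_positions(static_capture, roles, "foot_front_left")[idx, , drop = FALSE],
      role_positions(static_capture, roles, "foot_front_right")[idx, , drop = FALSE],
      axis = axis)
  }
  ok <- is.finite(vals)
  if (mean(ok) < 0.5)
    stop("calibration error (", pose, "): required markers valid in fewer ",
         "than half of the window frames", call. = FALSE)
  stats::median(vals[ok])
}

#' Assemble a calibration profile
#'
#' @param neutral_spine,max_spine_bend spine-chain lengths (mm) from the
#'   neutral and maximal-bend static poses; `max_spine_bend` must exceed
#'   `neutral_spine`.
#' @param initial_bf_distance setup barbell-foot distance (mm), > 0.
#' @return an object of class `calibration_profile`.
#' @export
calibration_profile <- function(neutral_spine, max_spine_bend,
                                initial_bf_distance) {
  stopifnot(is.numeric(neutral_spine), is.numeric(max_spine_bend),
            is.numeric(initial_bf_distance))
  if (!(max_spine_bend > neutral_spine))
    stop("max_spine_bend must exceed neutral_spine", call. = FALSE)
  if (!(initial_bf_distance > 0))
    stop("initial_bf_distance must be positive", call. = FALSE)
  structure(list(neutral_spine = neutral_spine,
                 max_spine_bend = max_spine_bend,
                 initial_bf_distance = initial_bf_distance),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<calibration_profile>\n",
    "  neutral spine length : %8.2f mm\n",
    "  max spine-bend length: %8.2f mm\n",
    "  initial B-F distance : %8.2f mm\n"),
    x$neutral_spine, x$max_spine_bend, x$initial_bf_distance))
  invisible(x)
}

#' Normalise physical series against a calibration profile
#'
#' `sb = (spine_bend - neutral) / (max - neutral)`: 0 at the neutral chain
#' length, 1 at the calibrated maximal bend. `bfd = bf_distance / initial`:
#' 1 at the setup distance, 0 when the bar reaches the toe markers, negative
#' beyond them. Both maps are affine and order-preserving.
#'
#' @param spine_bend,bf_dist numeric vectors (mm).
#' @param profile a [calibration_profile()].
#' @return list with components `sb` and `bfd`.
#' @export
normalize_series <- function(spine_bend, bf_dist, profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  list(
    sb = (spine_bend - profile$neutral_spine) /
      (profile$max_spine_bend - profile$neutral_spine),
    bfd = bf_dist / profile$initial_bf_distance
  )
}

#' Derive the per-frame kinematic series of a capture
#'
#' Runs [spine_length()] and [bf_distance()] over every frame of a capture
#' and normalises them with the athlete's calibration profile. Frames with
#' any required marker occluded yield `NA` in all four series and are
#' excluded from downstream means.
#'
#' @param ts a `trajectory_set`.
#' @param roles a [marker_role_map()].
#' @param profile a [calibration_profile()].
#' @param axis sign axis (length-2); default estimated from the capture.
#' @param projection passed to [bf_distance()].
#' @return a data.frame of class `derived_series` with columns `time`,
#'   `spine_bend`, `bf_distance`, `sb`, `bfd`.
#' @export
derive_series <- function(ts, roles, profile, axis = NULL,
                          projection = "perpendicular") {
  check_roles(ts, roles)
  stopifnot(inherits(profile, "calibration_profile"))
  if (is.null(axis)) axis <- estimate_sign_axis(ts, roles)
  sp <- spine_length(role_positions(ts, roles, "spine_L4"),
                     role_positions(ts, roles, "spine_T12"),
                     role_positions(ts, roles, "spine_T7"),
                     role_positions(ts, roles, "spine_C2"))
  bf <- bf_distance(role_positions(ts, roles, "barbell_end_left"),
                    role_positions(ts, roles, "barbell_end_right"),
                    role_positions(ts, roles, "foot_front_left"),
                    role_positions(ts, roles, "foot_front_right"),
                    axis = axis, projection = projection)
  nd <- normalize_series(sp, bf, profile)
  out <- data.frame(time = frame_times(ts), spine_bend = sp,
                    bf_distance = bf, sb = nd$sb, bfd = nd$bfd)
  class(out) <- c("derived_series", "data.frame")
  attr(out, "frame_rate") <- ts$frame_rate
  out
}
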