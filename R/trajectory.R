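#' Construct a marker-trajectory set
#'
#' A `trajectory_set` holds time-synchronised 3D positions (mm) for a set of
#' labelled reflective markers, as exported by an optical motion-capture
#' system. Every marker carries a per-frame validity mask: `FALSE` where the
#' marker was occluded (missing coordinates).
#'
#' @param markers named list; each element a list with `positions` (an
#'   `n x 3` numeric matrix, mm) and optionally `valid` (logical length `n`).
#'   A bare `n x 3` matrix is accepted and wrapped.
#' @param frame_rate capture frequency in Hz (> 0).
#' @param start_time time of the first frame in seconds.
#' @return An object of class `trajectory_set`.
#' @examples
#' ts <- trajectory_set(
#'   list(A = matrix(rnorm(30), 10, 3), B = matrix(rnorm(30), 10, 3)),
#'   frame_rate = 100
#' )
#' n_frames(ts)
#' @export
trajectory_set <- function(markers, frame_rate = 100, start_time = 0) {
  stopifnot(is.list(markers), length(markers) >= 1L,
            !is.null(names(markers)), all(nzchar(names(markers))),
            is.numeric(frame_rate), length(frame_rate) == 1L, frame_rate > 0)
  markers <- lapply(markers, function(m) {
    if (is.matrix(m)) m <- list(positions = m)
    pos <- m$positions
    if (!is.matrix(pos) || ncol(pos) != 3L)
      stop("marker positions must be an n x 3 matrix", call. = FALSE)
    storage.mode(pos) <- "double"
    colnames(pos) <- c("x", "y", "z")
    valid <- m$valid
    if (is.null(valid)) valid <- rowSums(!is.finite(pos)) == 0L
    stopifnot(is.logical(valid), length(valid) == nrow(pos))
    pos[!valid, ] <- NA_real_
    if (any(!is.finite(pos[valid, , drop = FALSE])))
      stop("non-finite coordinates in frames flagged valid", call. = FALSE)
    list(positions = pos, valid = valid)
  })
  n <- vapply(markers, function(m) nrow(m$positions), integer(1))
  if (length(unique(n)) != 1L)
    stop("structure error: markers have differing frame counts (",
         paste(unique(n), collapse = ", "), ")", call. = FALSE)
  structure(
    list(frame_rate = frame_rate, start_time = start_time, markers = markers),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d markers x %d frames @ %g Hz (%.2f s)\n",
    length(x$markers), n_frames(x), x$frame_rate, n_frames(x) / x$frame_rate
  ))
  occl <- vapply(x$markers, function(m) sum(!m$valid), integer(1))
  if (any(occl > 0))
    cat("  occluded frames:",
        paste(sprintf("%s=%d", names(occl)[occl > 0], occl[occl > 0]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a trajectory set
#' @param ts a `trajectory_set`.
#' @return integer frame count.
#' @export
n_frames <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  nrow(ts$markers[[1L]]$positions)
}

#' Frame timestamps of a trajectory set
#' @param ts a `trajectory_set`.
#' @return numeric vector of times in seconds (`start_time + frame/frame_rate`,
#'   frames indexed from 0).
#' @export
frame_times <- function(ts) {
  ts$start_time + (seq_len(n_frames(ts)) - 1L) / ts$frame_rate
}

#' Map functional marker roles onto marker labels
#'
#' The kinematic pipeline needs to know which marker labels play which
#' anatomical/equipment role: the four spine markers (L4, T12, T7, C2
#' vertebral heights), the two front-foot markers, and the two barbell
#' extremity markers.
#'
#' @param spine_L4,spine_T12,spine_T7,spine_C2 spine marker labels, caudal
#'   to cranial.
#' @param foot_front_left,foot_front_right front-of-foot marker labels.
#' @param barbell_end_left,barbell_end_right barbell extremity labels.
#' @return A named character vector of class `marker_role_map`.
#' @export
marker_role_map <- function(spine_L4, spine_T12, spine_T7, spine_C2,
                            foot_front_left, foot_front_right,
                            barbell_end_left, barbell_end_right) {
  roles <- c(spine_L4 = spine_L4, spine_T12 = spine_T12,
             spine_T7 = spine_T7, spine_C2 = spine_C2,
             foot_front_left = foot_front_left,
             foot_front_right = foot_front_right,
             barbell_end_left = barbell_end_left,
             barbell_end_right = barbell_end_right)
  stopifnot(all(vapply(roles, is.character, logical(1))),
            all(nzchar(roles)))
  if (anyDuplicated(roles))
    stop("roles must map to distinct marker labels", call. = FALSE)
  class(roles) <- "marker_role_map"
  roles
}

#' Default role map for the synthetic capture model
#'
#' Marker labels emitted by [simulate_session()]; convenient for examples and
#' for real captures that follow the same labelling.
#' @return a [marker_role_map()].
#' @export
default_role_map <- function() {
  marker_role_map("L4", "T12", "T7", "C2",
                  "FOOT_FRONT_L", "FOOT_FRONT_R",
                  "BAR_END_L", "BAR_END_R")
}

#' Validate a role map against a trajectory set
#' @param ts a `trajectory_set`.
#' @param roles a `marker_role_map`.
#' @return invisibly `TRUE`; errors if a mapped label is absent.
#' @export
check_roles <- function(ts, roles) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(roles, "marker_role_map"))
  missing <- setdiff(unname(roles), names(ts$markers))
  if (length(missing))
    stop("role map refers to markers absent from the capture: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# internal: n x 3 position matrix for one role, NA rows where occluded
role_positions <- function(ts, roles, role) {
  ts$markers[[roles[[role]]]]$positions
}

role_valid <- function(ts, roles, role) {
  ts$markers[[roles[[role]]]]$valid
}
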