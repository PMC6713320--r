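# Synthetic capture generator
#
# Emits labelled marker trajectories that conform to the capture model of
# the live system — 22 body markers plus 4 barbell markers at 100 Hz — with
# exact ground truth under this package's own kinematic definitions. The
# generator controls the non-dimensional quantities directly rather than
# modelling musculoskeletal dynamics:
#
#   * bar height follows one raised-cosine cycle per repetition
#     (phase u in [0,1]: 0.5 * (1 - cos(2*pi*u)); bottom at the boundaries,
#     lockout at mid-repetition);
#   * the spine chain is a 4-marker zig-zag whose two middle markers (T12,
#     T7) sit a controlled distance behind the L4-C2 line. Growing that
#     offset lengthens the chain smoothly, so any target spine-bend profile
#     — here sb(t) = spine_fault_amplitude * phase(t) — is realised exactly;
#     the neutral pose keeps a built-in posterior bow so negative amplitudes
#     (extension) are representable too;
#   * the bar drifts horizontally toward the toes so bfd(t) =
#     1 - (1 - barbell_drift) * phase(t), dipping to `barbell_drift` at
#     mid-lift.
#
# The remaining 16 body markers (head x4, shoulders, elbows, wrists, and a
# 6-marker trouser set) are kinematically plausible decoys riding on the
# lift phase; they exist so that readers and validators face realistic
# label sets, and are not physiological.

#' Configuration for a synthetic deadlift session
#'
#' @param n_reps repetitions in the set (>= 1; the live protocol used 10).
#' @param rep_period seconds per repetition (default 3, a middle-low pace).
#' @param frame_rate capture rate in Hz (default 100, the system's rate).
#' @param spine_fault_amplitude peak true `sb` at mid-lift (0 = perfect
#'   neutral spine; 1 = the calibrated maximal fault; may be negative for
#'   extension, down to about -0.9).
#' @param barbell_drift minimum true `bfd` at mid-lift (1 = no drift,
#'   0 = bar reaches the toe markers, negative = beyond them).
#' @param marker_noise_sd i.i.d. Gaussian noise added to every marker
#'   coordinate, mm (default 0).
#' @param seed integer RNG seed for the session's noise stream.
#' @param neutral_spine_bow posterior offset (mm) of T12/T7 in the neutral
#'   pose; sets how much extension is representable.
#' @param spine_segment vertical spacing (mm) between consecutive spine
#'   markers.
#' @param max_bend_delta chain-length increase (mm) from neutral to the
#'   calibrated maximal bend.
#' @param bar_travel vertical bar travel per repetition (mm).
#' @param initial_bf_mm setup barbell-foot distance (mm).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_reps = 10, rep_period = 3, frame_rate = 100,
                              spine_fault_amplitude = 0.4,
                              barbell_drift = 0.2, marker_noise_sd = 0,
                              seed = 1L, neutral_spine_bow = 80,
                              spine_segment = 160, max_bend_delta = 40,
                              bar_travel = 520, initial_bf_mm = 80) {
  stopifnot(n_reps >= 1, rep_period > 0, frame_rate > 0,
            marker_noise_sd >= 0, neutral_spine_bow > 0, spine_segment > 0,
            max_bend_delta > 0, bar_travel > 0, initial_bf_mm > 0)
  s <- spine_segment
  neutral <- 2 * sqrt(neutral_spine_bow^2 + s^2) + s
  sb_min <- (3 * s - neutral) / max_bend_delta
  if (spine_fault_amplitude < sb_min)
    stop("spine_fault_amplitude below the representable minimum (",
         round(sb_min, 3), ") for this neutral bow", call. = FALSE)
  structure(list(n_reps = n_reps, rep_period = rep_period,
                 frame_rate = frame_rate,
                 spine_fault_amplitude = spine_fault_amplitude,
                 barbell_drift = barbell_drift,
                 marker_noise_sd = marker_noise_sd, seed = as.integer(seed),
                 neutral_spine_bow = neutral_spine_bow,
                 spine_segment = spine_segment,
                 max_bend_delta = max_bend_delta, bar_travel = bar_travel,
                 initial_bf_mm = initial_bf_mm),
            class = "simulation_config")
}

# chain geometry: posterior offset of T12/T7 that gives chain length L
bow_for_length <- function(L, s) {
  half <- (L - s) / 2
  sqrt(pmax(half^2 - s^2, 0))
}

#' Marker labels of the synthetic capture model
#'
#' The generator emits 22 body markers and 4 barbell markers, mirroring the
#' full-body marker set-up of the live system (4 spine, 2 front-foot, head,
#' shoulders, elbows, wrists and a 6-marker trouser set; bar extremities
#' plus two asymmetric collar markers).
#' @return character vector of labels.
#' @export
synthetic_body_labels <- function() {
  c("L4", "T12", "T7", "C2",
    "FOOT_FRONT_L", "FOOT_FRONT_R",
    paste0("HEAD_", 1:4), "SHOULDER_L", "SHOULDER_R",
    "ELBOW_L", "ELBOW_R", "WRIST_L", "WRIST_R",
    paste0("TROUSER_", 1:6))
}

#' @rdname synthetic_body_labels
#' @export
synthetic_barbell_labels <- function() {
  c("BAR_END_L", "BAR_END_R", "BAR_COLLAR_1", "BAR_COLLAR_2")
}

# noiseless marker positions for given lift phase / sb / bfd (scalars or
# vectors over frames); returns a named list of n x 3 matrices
synthetic_geometry <- function(cfg, phase, sb, bfd) {
  s <- cfg$spine_segment
  neutral <- 2 * sqrt(cfg$neutral_spine_bow^2 + s^2) + s
  chain <- neutral + sb * cfg$max_bend_delta
  bow <- bow_for_length(chain, s)
  n <- length(phase)
  x_toe <- cfg$initial_bf_mm             # bar starts at x = 0; +x = forward
  x_bar <- x_toe - bfd * cfg$initial_bf_mm
  z_bar <- 110 + cfg$bar_travel * phase
  z_hip <- 900 + 150 * phase             # pelvis rises as the hips extend
  x_spine <- -150 - 60 * (1 - phase)     # torso inclines forward at bottom
  col3 <- function(x, y, z) cbind(rep_len(x, n), rep_len(y, n),
                                  rep_len(z, n))
  m <- list(
    L4  = col3(x_spine, 0, z_hip),
    T12 = col3(x_spine - bow, 0, z_hip + s),
    T7  = col3(x_spine - bow, 0, z_hip + 2 * s),
    C2  = col3(x_spine, 0, z_hip + 3 * s),
    FOOT_FRONT_L = col3(x_toe, 150, 30),
    FOOT_FRONT_R = col3(x_toe, -150, 30),
    BAR_END_L = col3(x_bar, 800, z_bar),
    BAR_END_R = col3(x_bar, -800, z_bar),
    BAR_COLLAR_1 = col3(x_bar, 650, z_bar),
    BAR_COLLAR_2 = col3(x_bar, 560, z_bar)
  )
  # decoys: ride on the hip/bar phase with fixed offsets
  m$HEAD_1 <- col3(x_spine + 30, 40, z_hip + 3 * s + 150)
  m$HEAD_2 <- col3(x_spine + 30, -40, z_hip + 3 * s + 150)
  m$HEAD_3 <- col3(x_spine - 40, 60, z_hip + 3 * s + 160)
  m$HEAD_4 <- col3(x_spine - 40, -60, z_hip + 3 * s + 160)
  m$SHOULDER_L <- col3(x_spine + 10, 190, z_hip + 3 * s - 40)
  m$SHOULDER_R <- col3(x_spine + 10, -190, z_hip + 3 * s - 40)
  m$ELBOW_L <- col3(x_bar - 30, 330, (z_bar + z_hip + 2 * s) / 2)
  m$ELBOW_R <- col3(x_bar - 30, -330, (z_bar + z_hip + 2 * s) / 2)
  m$WRIST_L <- col3(x_bar, 300, z_bar + 40)
  m$WRIST_R <- col3(x_bar, -300, z_bar + 40)
  for (k in 1:6)
    m[[paste0("TROUSER_", k)]] <-
      col3(x_spine + 40 + 10 * k, c(120, -120)[(k %% 2) + 1L],
           z_hip - 150 - 40 * (k %/% 2))
  m[c(synthetic_body_labels(), synthetic_barbell_labels())]
}

#' Simulate one deadlift session with exact ground truth
#'
#' @param cfg a [simulation_config()].
#' @return list of class `synthetic_session`:
#'   `trajectories` (a `trajectory_set`, 26 markers),
#'   `truth` (data.frame `time`, `sb`, `bfd` — the noiseless values under
#'   this package's kinematic definitions),
#'   `reps` (data.frame `start_frame`, `end_frame` per repetition),
#'   `profile` (the [calibration_profile()] the geometry was built from),
#'   and `config`.
#' @examples
#' ses <- simulate_session(simulation_config(n_reps = 4, seed = 7))
#' ses$trajectories
#' @export
simulate_session <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  fr <- cfg$frame_rate
  n <- round(cfg$n_reps * cfg$rep_period * fr)
  t <- (seq_len(n) - 1L) / fr
  u <- (t %% cfg$rep_period) / cfg$rep_period
  phase <- 0.5 * (1 - cos(2 * pi * u))
  sb <- cfg$spine_fault_amplitude * phase
  bfd <- 1 - (1 - cfg$barbell_drift) * phase
  m <- synthetic_geometry(cfg, phase, sb, bfd)
  if (cfg$marker_noise_sd > 0) {
    set.seed(cfg$seed)
    m <- lapply(m, function(p)
      p + matrix(stats::rnorm(length(p), 0, cfg$marker_noise_sd),
                 nrow(p), 3L))
  }
  ts <- trajectory_set(m, frame_rate = fr, start_time = 0)
  s <- cfg$spine_segment
  neutral <- 2 * sqrt(cfg$neutral_spine_bow^2 + s^2) + s
  profile <- calibration_profile(neutral, neutral + cfg$max_bend_delta,
                                 cfg$initial_bf_mm)
  starts <- round((seq_len(cfg$n_reps) - 1L) * cfg$rep_period * fr) + 1L
  reps <- data.frame(start_frame = starts,
                     end_frame = c(starts[-1L] - 1L, n))
  structure(list(trajectories = ts,
                 truth = data.frame(time = t, sb = sb, bfd = bfd),
                 reps = reps, profile = profile, config = cfg),
            class = "synthetic_session")
}

#' Simulate a static calibration pose
#'
#' A held pose suitable for [calibrate()]: the neutral setup, the instructed
#' maximal spine bend, or the initial barbell-foot setup (which is the
#' neutral pose as far as the bar is concerned).
#'
#' @param cfg a [simulation_config()] (noise and seed are honoured).
#' @param pose `"neutral_spine"`, `"max_spine_bend"`, or `"initial_bfd"`.
#' @param duration seconds (default 1.5).
#' @return a `trajectory_set`.
#' @export
simulate_static_pose <- function(cfg = simulation_config(),
                                 pose = c("neutral_spine", "max_spine_bend",
                                          "initial_bfd"),
                                 duration = 1.5) {
  pose <- match.arg(pose)
  stopifnot(inherits(cfg, "simulation_config"))
  n <- round(duration * cfg$frame_rate)
  sb <- if (pose == "max_spine_bend") 1 else 0
  m <- synthetic_geometry(cfg, phase = rep(0, n), sb = rep(sb, n),
                          bfd = rep(1, n))
  if (cfg$marker_noise_sd > 0) {
    set.seed(cfg$seed + 17L)
    m <- lapply(m, function(p)
      p + matrix(stats::rnorm(length(p), 0, cfg$marker_noise_sd),
                 nrow(p), 3L))
  }
  trajectory_set(m, frame_rate = cfg$frame_rate)
}

#' Run the offline pipeline on one capture
#'
#' Derivation, segmentation, discard rule and session summary in one call —
#' the per-session half of the evaluation pipeline.
#'
#' @param ts a `trajectory_set`.
#' @param roles a [marker_role_map()] (default the synthetic labels).
#' @param profile a [calibration_profile()].
#' @param participant_id,condition metadata for the summary row.
#' @param discard_head,discard_tail repetition discard rule (defaults 3, 2).
#' @param min_amplitude_frac,min_period segmentation thresholds
#'   (see [segment_reps()]).
#' @param method summary method, `"two_stage"` or `"pooled"`.
#' @return list: `derived`, `reps` (all detected, with means), `retained`,
#'   `summary` (a `session_summary` row).
#' @export
process_session <- function(ts, roles = default_role_map(), profile,
                            participant_id = NA_character_,
                            condition = "control",
                            discard_head = 3, discard_tail = 2,
                            min_amplitude_frac = 0.5, min_period = 1.0,
                            method = "two_stage") {
  derived <- derive_series(ts, roles, profile)
  reps <- segment_reps(bar_height(ts, roles), ts$frame_rate,
                       min_amplitude_frac = min_amplitude_frac,
                       min_period = min_period)
  reps <- rep_means(derived, reps)
  retained <- retain_reps(reps, discard_head, discard_tail)
  summ <- summarize_session(derived, retained,
                            participant_id = participant_id,
                            condition = condition, n_detected = nrow(reps),
                            method = method)
  list(derived = derived, reps = reps, retained = retained, summary = summ)
}

#' Simulate a two-group cohort with known ground truth
#'
#' Generates per-participant control and feedback sessions for an
#' instruction group and a sonification group, with participant-level
#' random effects, and returns the cohort table the statistical pipeline
#' consumes. Per participant, the control-session mean `sb` and `bfd` are
#' drawn from group baseline distributions, the feedback session shifts
#' them by a participant-specific improvement drawn around the group
#' effect, and the generator realises each target mean exactly (a
#' raised-cosine repetition has mean phase 1/2, so a session with fault
#' amplitude `2m` has true mean `sb = m`, and drift `2m - 1` has true mean
#' `bfd = m`).
#'
#' `method = "session"` synthesises full marker captures and runs them
#' through the kinematic pipeline (the reference path);
#' `method = "summary"` draws the summary means from the identical
#' statistical model without marker synthesis, which makes hundreds of
#' replicate cohorts affordable. The two paths share the model of the
#' participant effects.
#'
#' @param n_instruction,n_sonification group sizes (>= 3).
#' @param effect_sb named or unnamed length-2 numeric: mean `sb`
#'   improvement (feedback - control) for instruction and sonification
#'   (defaults -0.108, -0.124).
#' @param effect_bfd mean `bfd` improvement per group (defaults 0.573,
#'   0.755).
#' @param effect_sd_sb,effect_sd_bfd between-participant sd of the
#'   improvements (defaults 0.12, 0.73).
#' @param baseline_sb,baseline_sd_sb control-condition `sb` mean and sd
#'   (defaults 0.02, 0.25).
#' @param baseline_bfd,baseline_sd_bfd control-condition `bfd` mean and sd
#'   (defaults 0.45, 0.45).
#' @param expertise_mix per-group expertise level proportions for levels
#'   A/B/C (defaults mirror the cohort composition 2/9/5 and 3/6/6).
#' @param expertise_shift_bfd optional named numeric (`A`, `B`, `C`) added
#'   to the `bfd` improvement by expertise level (default zeros).
#' @param condition feedback condition label (default `"combination"`).
#' @param seed integer master seed; per-participant session seeds are split
#'   from it.
#' @param method `"session"` or `"summary"`.
#' @param n_reps,marker_noise_sd session-method generator settings.
#' @return list of class `synthetic_cohort`: `records` (cohort table, one
#'   row per participant x condition), `truth` (per-participant drawn
#'   control means and improvements).
#' @export
simulate_cohort <- function(n_instruction = 16, n_sonification = 15,
                            effect_sb = c(instruction = -0.108,
                                          sonification = -0.124),
                            effect_bfd = c(instruction = 0.573,
                                           sonification = 0.755),
                            effect_sd_sb = 0.12, effect_sd_bfd = 0.73,
                            baseline_sb = 0.02, baseline_sd_sb = 0.25,
                            baseline_bfd = 0.45, baseline_sd_bfd = 0.45,
                            expertise_mix = list(
                              instruction = c(A = 2, B = 9, C = 5) / 16,
                              sonification = c(A = 3, B = 6, C = 6) / 15),
                            expertise_shift_bfd = c(A = 0, B = 0, C = 0),
                            condition = "combination", seed = 1L,
                            method = c("summary", "session"),
                            n_reps = 10, marker_noise_sd = 1) {
  method <- match.arg(method)
  if (n_instruction < 3 || n_sonification < 3)
    stop("precondition error: group sizes must be >= 3", call. = FALSE)
  set.seed(seed)
  groups <- c(rep("instruction", n_instruction),
              rep("sonification", n_sonification))
  n_tot <- length(groups)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  expertise <- unlist(lapply(c("instruction", "sonification"), function(g) {
    ng <- sum(groups == g)
    mix <- expertise_mix[[g]]
    counts <- floor(mix * ng)
    while (sum(counts) < ng) {
      k <- which.max(mix * ng - counts); counts[k] <- counts[k] + 1
    }
    sample(rep(names(mix), counts))
  }))
  gi <- ifelse(groups == "instruction", 1L, 2L)
  truth <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n_tot)),
    group = groups, expertise = expertise,
    sex = sample(c("F", "M"), n_tot, replace = TRUE),
    ctl_sb = stats::rnorm(n_tot, baseline_sb, baseline_sd_sb),
    ctl_bfd = stats::rnorm(n_tot, baseline_bfd, baseline_sd_bfd),
    stringsAsFactors = FALSE
  )
  truth$delta_sb <- stats::rnorm(n_tot, effect_sb[gi], effect_sd_sb)
  truth$delta_bfd <- stats::rnorm(n_tot, effect_bfd[gi], effect_sd_bfd) +
    expertise_shift_bfd[truth$expertise]
  # representable range of the session generator (see simulation_config)
  clamp_sb <- function(m) {
    cfg0 <- simulation_config()
    s <- cfg0$spine_segment
    neutral <- 2 * sqrt(cfg0$neutral_spine_bow^2 + s^2) + s
    lo <- (3 * s - neutral) / cfg0$max_bend_delta / 2 + 1e-6
    pmax(m, lo)
  }
  truth$ctl_sb <- clamp_sb(truth$ctl_sb)
  truth$fb_sb <- clamp_sb(truth$ctl_sb + truth$delta_sb)
  truth$fb_bfd <- truth$ctl_bfd + truth$delta_bfd
  truth$delta_sb <- truth$fb_sb - truth$ctl_sb

  one_session <- function(target_sb, target_bfd, sub_seed, id, cond) {
    if (method == "summary") {
      return(data.frame(participant_id = id, condition = cond,
                        n_reps_detected = n_reps,
                        n_reps_retained = n_reps - 5L,
                        mean_sb = target_sb, mean_bfd = target_bfd,
                        stringsAsFactors = FALSE))
    }
    cfg <- simulation_config(n_reps = n_reps,
                             spine_fault_amplitude = 2 * target_sb,
                             barbell_drift = 2 * target_bfd - 1,
                             marker_noise_sd = marker_noise_sd,
                             seed = sub_seed)
    ses <- simulate_session(cfg)
    pr <- process_session(ses$trajectories, default_role_map(),
                          ses$profile, participant_id = id,
                          condition = cond)
    pr$summary
  }
  rows <- vector("list", 2L * n_tot)
  for (i in seq_len(n_tot)) {
    rows[[2L * i - 1L]] <- one_session(truth$ctl_sb[i], truth$ctl_bfd[i],
                                       sub_seeds[i], truth$participant_id[i],
                                       "control")
    rows[[2L * i]] <- one_session(truth$fb_sb[i], truth$fb_bfd[i],
                                  (sub_seeds[i] + 1L) %%
                                    .Machine$integer.max,
                                  truth$participant_id[i], condition)
  }
  records <- do.call(rbind, rows)
  records <- merge(truth[, c("participant_id", "group", "expertise",
                             "sex")],
                   records, by = "participant_id", sort = FALSE)
  records <- records[order(records$participant_id, records$condition), ]
  rownames(records) <- NULL
  structure(list(records = records, truth = truth),
            class = "synthetic_cohort")
}
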