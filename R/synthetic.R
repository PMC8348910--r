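# Synthetic work-cycle generator: smooth multi-joint trajectories
# emulating a short repetitive manufacturing cycle, so the whole pipeline
# can be exercised and tested without capture hardware.

# smooth raised-cosine pulse: 0 outside [t0, t1], peaking at 1 mid-window
smooth_pulse <- function(t, t0, t1) {
  u <- (t - t0) / (t1 - t0)
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- 0.5 - 0.5 * cos(2 * pi * u[inside])
  out
}

#' Generate a synthetic capture
#'
#' Deterministic (per seed) smooth joint-angle trajectories for named
#' scenarios:
#' \describe{
#'   \item{static_stand}{neutral standing pose, all rotations zero.}
#'   \item{wide_arcs}{every assessed joint sweeps wide sinusoidal arcs
#'     near its range of motion, the movement pattern of the
#'     threshold-calibration protocol.}
#'   \item{lift_place}{a lift-and-place cycle: trunk flexion to reach a
#'     3.5 kg part, both-hands carry (declared as a (0, -3.5, 0) kgf
#'     action with a hook grasp over the lift frames) and return.}
#'   \item{screw_task}{arm raised towards a suspended screwdriver with
#'     wrist oscillation and a declared (0, 0, -0.2) kg m tool torque.}
#' }
#'
#' @param scenario one of `"static_stand"`, `"wide_arcs"`,
#'   `"lift_place"`, `"screw_task"`.
#' @param duration capture length in seconds.
#' @param frame_rate sampling rate, Hz.
#' @param seed integer seed for the small random phase/amplitude jitter.
#' @return list with elements `series` (a `capture_series`), `actions`
#'   (an `action_table`, possibly empty) and `supports` (empty
#'   `support_table`).
#' @export
generate_synthetic_capture <- function(scenario = c("static_stand", "wide_arcs",
                                                    "lift_place", "screw_task"),
                                       duration = 4, frame_rate = 60, seed = 1) {
  scenario <- match.arg(scenario)
  nf <- max(3L, as.integer(round(duration * frame_rate)))
  t <- (seq_len(nf) - 1) / frame_rate
  set.seed(seed)
  ang <- list()
  actions <- action_table()

  if (scenario == "wide_arcs") {
    f <- 0.4  # Hz, brisk but work-like arc frequency
    amp <- list(lumbar = c(40, 25, 20), head = c(35, 45, 25),
                arm_R = c(90, 30, 60), arm_L = c(90, 30, 60),
                forearm_R = c(70, 45, 0), forearm_L = c(70, 45, 0),
                hand_R = c(40, 15, 15), hand_L = c(40, 15, 15))
    for (b in names(amp)) {
      ph <- stats::runif(3, 0, 2 * pi)
      a <- amp[[b]]
      for (k in 1:3) {
        if (a[k] > 0) {
          ang[[paste0(b, "_R", c("x", "y", "z")[k])]] <-
            a[k] * sin(2 * pi * f * t + ph[k])
        }
      }
    }
    # knees flex one leg at a time so the other foot stays grounded
    half <- duration / 2
    ang$shin_R_Rx <- 60 * smooth_pulse(t, 0.05 * half, 0.95 * half)
    ang$shin_L_Rx <- 60 * smooth_pulse(t, half + 0.05 * half, half + 0.95 * half)
  } else if (scenario == "lift_place") {
    Tc <- duration
    reach <- c(0.05, 0.30) * Tc
    carry <- c(0.30, 0.60) * Tc
    place <- c(0.55, 0.80) * Tc
    bend <- smooth_pulse(t, reach[1], carry[2])
    # stoop lift: trunk flexion with planted feet
    ang$lumbar_Rx <- 45 * bend
    ang$head_Rx <- 20 * bend
    reach_arm <- smooth_pulse(t, reach[1], place[2])
    for (s in c("R", "L")) {
      ang[[paste0("arm_", s, "_Rx")]] <- -70 * reach_arm
      ang[[paste0("forearm_", s, "_Rx")]] <- 40 * reach_arm
      ang[[paste0("hand_", s, "_Rx")]] <- 20 * smooth_pulse(t, carry[1], place[2])
    }
    lift0 <- round(carry[1] * frame_rate)
    lift1 <- round(carry[2] * frame_rate)
    actions <- action_table(lift0, lift1, "both", fy = -3.5, grasp = 4)
  } else if (scenario == "screw_task") {
    hold <- smooth_pulse(t, 0.1 * duration, 0.9 * duration)
    for (s in c("R")) {
      ang[[paste0("arm_", s, "_Rx")]] <- -60 * hold
      ang[[paste0("forearm_", s, "_Rx")]] <- 70 * hold
      ang[[paste0("hand_", s, "_Ry")]] <- 25 * hold * sin(2 * pi * 3 * t)
    }
    s0 <- round(0.25 * duration * frame_rate)
    s1 <- round(0.75 * duration * frame_rate)
    actions <- action_table(s0, s1, "right", tz = -0.2, grasp = 1)
  }
  # static_stand: leave all rotations at zero

  df <- if (length(ang)) as.data.frame(ang) else
    as.data.frame(matrix(0, nf, 1, dimnames = list(NULL, "pelvis_Rx")))
  series <- capture_series(df, frame_rate = frame_rate)
  list(series = series, actions = actions, supports = support_table())
}
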