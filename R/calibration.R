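# Derivation of effort/acceleration threshold tables from capture sets:
# 99th-percentile maxima, static-standing minima, side averaging and
# percentile coefficients, plus the 0.2-s stop rule for accelerations.

#' Maximum stress of a capture set
#'
#' 99th percentile (linear-interpolation definition) of the pooled
#' per-frame load moduli, the statistic defining each joint's maximum
#' effort threshold.
#'
#' @param x numeric vector of per-frame force or torque moduli (pooled
#'   over captures).
#' @param probs percentile, default 0.99.
#' @return scalar threshold.
#' @export
max_stress <- function(x, probs = 0.99) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

#' Angular speed to acceleration threshold
#'
#' Converts an angular-speed threshold into an acceleration threshold
#' under the rule that a joint moving at that speed stops in 0.2 s (12
#' frames at 60 fps).
#'
#' @param speed angular speed, deg/s.
#' @param stop_time stopping time in seconds.
#' @return angular acceleration, deg/s^2.
#' @export
speed_to_acceleration <- function(speed, stop_time = 0.2) {
  if (stop_time <= 0) stop("stop_time must be > 0")
  speed / stop_time
}

#' Derive an effort threshold table from percentile maxima/minima
#'
#' Applies the table-construction arithmetic: bilateral joints are
#' averaged across right/left sides, the P05/P95 transformation
#' coefficients are the ratios of the P05/P95 maxima to the P50 maximum
#' (reported to two decimals, half-up), and the static minima - measured
#' for the 50th percentile only - are transported to other percentiles by
#' those same coefficients.
#'
#' @param maxima data.frame with columns `joint` (sided names allowed,
#'   e.g. `shoulder_R`), `percentile` (`P05`, `P50`, `P95`) and `value`.
#' @param minima data.frame with columns `joint` and `value` (P50 static
#'   captures).
#' @return data.frame with columns `joint`, `min`, `max`, `coef_p05`,
#'   `coef_p95`.
#' @export
derive_threshold_table <- function(maxima, minima) {
  need <- c("P05", "P50", "P95")
  if (!all(need %in% maxima$percentile)) {
    stop("maxima must cover percentiles ", paste(need, collapse = ", "))
  }
  maxima$joint <- sub("_(R|L)$", "", maxima$joint)
  minima$joint <- sub("_(R|L)$", "", minima$joint)
  joints <- unique(maxima$joint)
  rows <- lapply(joints, function(j) {
    m <- maxima[maxima$joint == j, ]
    avg <- vapply(need, function(p) mean(m$value[m$percentile == p]), numeric(1))
    if (any(is.na(avg))) stop("missing percentile column for joint ", j)
    mn <- minima$value[minima$joint == j]
    data.frame(joint = j,
               min = if (length(mn)) round_half_up(mean(mn), 2) else NA_real_,
               max = round_half_up(avg[["P50"]], 2),
               coef_p05 = round_half_up(avg[["P05"]] / avg[["P50"]], 2),
               coef_p95 = round_half_up(avg[["P95"]] / avg[["P50"]], 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate the threshold-calibration protocol
#'
#' Exercises the calibration arithmetic end-to-end without human
#' subjects: generates wide-arc synthetic joint trajectories, attaches
#' the constant (0, -8, 0) kgf both-hands load used to emulate maximum
#' handling, runs the kinetics pipeline for each percentile model, pools
#' the per-frame moduli, and derives the threshold table together with a
#' static standing capture for the minima.
#'
#' @param sex `"male"` or `"female"`.
#' @param seed integer seed controlling the synthetic trajectories.
#' @param duration capture duration in seconds.
#' @param frame_rate sampling rate, Hz.
#' @return list with `force` and `torque` threshold tables (see
#'   [derive_threshold_table()]) and the raw pooled `maxima`/`minima`.
#' @export
simulate_calibration_protocol <- function(sex = "male", seed = 1,
                                          duration = 3, frame_rate = 30) {
  base <- build_human_model(default_height(sex), sex)
  pcts <- c("P05", "P50", "P95")
  syn <- generate_synthetic_capture("wide_arcs", duration = duration,
                                    frame_rate = frame_rate, seed = seed)
  hold <- action_table(0, n_frames(syn$series) - 1, "both", fy = -8)
  static <- generate_synthetic_capture("static_stand", duration = 1,
                                       frame_rate = frame_rate, seed = seed)
  sided <- c("lumbar", "cervical", paste0(rep(c("shoulder", "elbow", "wrist", "knee"),
                                              each = 2), c("_R", "_L")))
  collect <- function(loads, stat) {
    do.call(rbind, lapply(sided, function(j) {
      bone <- RISK_JOINT_BONE[[j]]
      data.frame(joint = j,
                 force = stat(loads$force_mod[, bone]),
                 torque = stat(loads$torque_mod[, bone]),
                 stringsAsFactors = FALSE)
    }))
  }
  maxima <- minima <- NULL
  for (p in pcts) {
    model <- scale_to_percentile(base, sex, p)
    dyn <- run_inverse_dynamics(model, syn$series, actions = hold)
    mx <- collect(dyn, max_stress)
    mx$percentile <- p
    maxima <- rbind(maxima, mx)
    if (p == "P50") {
      st <- run_inverse_dynamics(model, static$series)
      minima <- collect(st, mean)
    }
  }
  force <- derive_threshold_table(
    data.frame(joint = maxima$joint, percentile = maxima$percentile, value = maxima$force),
    data.frame(joint = minima$joint, value = minima$force))
  torque <- derive_threshold_table(
    data.frame(joint = maxima$joint, percentile = maxima$percentile, value = maxima$torque),
    data.frame(joint = minima$joint, value = minima$torque))
  list(force = force, torque = torque, maxima = maxima, minima = minima)
}
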