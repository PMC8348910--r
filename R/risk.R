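# Per-posture factor scores, per-minute risk aggregation and risk levels.

RISK_JOINTS <- c("lumbar", "cervical", "shoulder_R", "elbow_R", "wrist_R",
                 "knee_R", "shoulder_L", "elbow_L", "wrist_L", "knee_L")

# assessed joint -> bone whose origin is that joint
RISK_JOINT_BONE <- c(lumbar = "lumbar", cervical = "head",
                     shoulder_R = "arm_R", elbow_R = "forearm_R",
                     wrist_R = "hand_R", knee_R = "shin_R",
                     shoulder_L = "arm_L", elbow_L = "forearm_L",
                     wrist_L = "hand_L", knee_L = "shin_L")

risk_joint_kind <- function(joint) sub("_(R|L)$", "", joint)

#' Posture (angle) score
#'
#' Piecewise-linear lookup of each rotation axis in the joint's angle
#' graph; the returned score is the worst (maximum) axis. Values are
#' interpolated between breakpoints, never stepped, and saturate at the
#' graph ends. The shoulder uses a two-input interpolated table over
#' elevation and antero-posterior rotation because of its range of
#' motion.
#'
#' The breakpoint graphs shipped with the package are editable defaults
#' (REBA/RULA/ISO 11226-inspired band edges); site-calibrated graphs can
#' be supplied via `graphs`/`shoulder_grid`.
#'
#' @param joint joint kind (`"lumbar"`, `"cervical"`, `"shoulder"`,
#'   `"elbow"`, `"wrist"`, `"knee"`) or a sided name like `"wrist_R"`.
#' @param rx,ry,rz joint rotations in degrees.
#' @param graphs breakpoint table (columns `joint`, `axis`, `angle_deg`,
#'   `score`).
#' @param shoulder_grid two-input grid for the shoulder (columns
#'   `elevation`, `anteroposterior`, `score`).
#' @return score in [1, 2] (wrist capped at 1.6).
#' @export
angle_score <- function(joint, rx, ry = 0, rz = 0, graphs = NULL,
                        shoulder_grid = NULL) {
  kind <- risk_joint_kind(joint)
  maxima <- factor_maxima()
  if (!kind %in% maxima$joint) stop("no angle graph for joint: ", joint)
  cap <- maxima$angle_max[maxima$joint == kind]
  if (kind == "shoulder") {
    s <- shoulder_angle_score(rx, rz, shoulder_grid)
    return(min(max(s, 1), cap))
  }
  g <- graphs %||% angle_graph_table()
  g <- g[g$joint == kind, , drop = FALSE]
  if (!nrow(g)) stop("no angle graph for joint: ", joint)
  ang <- c(Rx = unname(rx), Ry = unname(ry), Rz = unname(rz))
  sc <- 1
  for (ax in unique(g$axis)) {
    ga <- g[g$axis == ax, ]
    sc <- max(sc, stats::approx(ga$angle_deg, ga$score, xout = ang[[ax]], rule = 2)$y)
  }
  min(max(sc, 1), cap)
}

shoulder_angle_score <- function(rx, rz, grid = NULL) {
  grid <- grid %||% shoulder_grid_table()
  # elevation: angle between the arm axis and the hanging (downward)
  # direction implied by flexion rx and abduction rz
  elev <- rad2deg(acos(pmin(1, pmax(-1, cos(deg2rad(rx)) * cos(deg2rad(rz))))))
  ap <- rx
  es <- sort(unique(grid$elevation))
  as_ <- sort(unique(grid$anteroposterior))
  elev <- min(max(elev, min(es)), max(es))
  ap <- min(max(ap, min(as_)), max(as_))
  e0 <- max(es[es <= elev]); e1 <- min(es[es >= elev])
  a0 <- max(as_[as_ <= ap]); a1 <- min(as_[as_ >= ap])
  gv <- function(e, a) grid$score[grid$elevation == e & grid$anteroposterior == a]
  te <- if (e1 > e0) (elev - e0) / (e1 - e0) else 0
  ta <- if (a1 > a0) (ap - a0) / (a1 - a0) else 0
  (1 - te) * ((1 - ta) * gv(e0, a0) + ta * gv(e0, a1)) +
    te * ((1 - ta) * gv(e1, a0) + ta * gv(e1, a1))
}

#' Angular-acceleration score
#'
#' 1 at or below the joint's slow-acceleration threshold, 1.5 at or above
#' its maximum, linear in between.
#'
#' @param joint joint kind or sided name.
#' @param acc modulus of the relative angular acceleration, deg/s^2.
#' @param table threshold table (see [acceleration_thresholds()]).
#' @return score in [1, 1.5].
#' @export
angular_acceleration_score <- function(joint, acc, table = NULL) {
  tab <- table %||% acceleration_thresholds()
  row <- tab[tab$joint == risk_joint_kind(joint), ]
  if (!nrow(row)) stop("no acceleration thresholds for joint: ", joint)
  pmin(1.5, pmax(1, 1 + 0.5 * (acc - row$slow_accel) / (row$max_accel - row$slow_accel)))
}

prep_coef <- function(preparation) c(`0` = 0.9, `1` = 1.0, `2` = 1.1, `3` = 1.2)[[as.character(preparation)]]

# thresholds interpolated on height between the P05/P50/P95 anchors,
# maxima scaled by the worker-preparation coefficient
resolve_effort_thresholds <- function(joint, sex, height, preparation = 1,
                                      kind = c("force", "torque")) {
  kind <- match.arg(kind)
  tab <- effort_thresholds(kind)
  row <- tab[tab$joint == risk_joint_kind(joint) & tab$sex == sex, ]
  if (!nrow(row)) stop("no ", kind, " thresholds for joint: ", joint)
  anchors <- stature_percentiles()
  anchors <- anchors[anchors$sex == sex, ]
  h <- anchors$height_m[match(c("P05", "P50", "P95"), anchors$percentile)]
  coef <- lin_interp(h, c(row$coef_p05, 1, row$coef_p95), height)
  list(min = row$min * coef, max = row$max * coef * prep_coef(preparation))
}

#' Internal-force score
#'
#' 1 at or below the joint's minimum force threshold (the static standing
#' load), 2 at or above the maximum, linear in between. Thresholds are
#' interpolated on worker height between the percentile columns and the
#' maximum is scaled by the worker-preparation coefficient (0.9, 1.0,
#' 1.1, 1.2).
#'
#' @param joint joint kind or sided name.
#' @param force force modulus, kgf.
#' @param sex,height worker sex and stature (m).
#' @param preparation preparation level 0-3.
#' @return score in [1, 2].
#' @export
force_score <- function(joint, force, sex = "male", height = NULL,
                        preparation = 1) {
  height <- height %||% default_height(sex)
  th <- resolve_effort_thresholds(joint, sex, height, preparation, "force")
  pmin(2, pmax(1, 1 + (force - th$min) / (th$max - th$min)))
}

#' Torque score
#'
#' As [force_score()] with the torque threshold table and a ceiling of
#' 2.5.
#'
#' @inheritParams force_score
#' @param torque torque modulus, kg m.
#' @return score in [1, 2.5].
#' @export
torque_score <- function(joint, torque, sex = "male", height = NULL,
                         preparation = 1) {
  height <- height %||% default_height(sex)
  th <- resolve_effort_thresholds(joint, sex, height, preparation, "torque")
  pmin(2.5, pmax(1, 1 + 1.5 * (torque - th$min) / (th$max - th$min)))
}

default_height <- function(sex) {
  tab <- stature_percentiles()
  tab$height_m[tab$sex == sex & tab$percentile == "P50"]
}

#' Grip score
#'
#' Table lookup of the grasp-type code (0-9); applies to the wrist only.
#'
#' @param grasp integer code 0-9.
#' @return score in [1, 2].
#' @export
grip_score <- function(grasp) {
  tab <- grip_table()
  if (!all(grasp %in% tab$code)) stop("grasp codes must be in 0..9")
  tab$score[match(grasp, tab$code)]
}

#' Factor product for one posture
#'
#' Product of the five per-posture factor scores minus one; zero means a
#' risk-free posture.
#'
#' @param angle,acceleration,force,torque,grip the component scores
#'   (each >= 1; grip is 1 for non-wrist joints). Alternatively pass a
#'   single numeric vector of the five scores as `angle`.
#' @return non-negative factor value.
#' @export
factors_per_posture <- function(angle, acceleration = 1, force = 1,
                                torque = 1, grip = 1) {
  if (length(angle) == 5 && missing(acceleration)) {
    sc <- angle
  } else {
    sc <- c(angle, acceleration, force, torque, grip)
  }
  if (any(sc < 1)) stop("factor scores must all be >= 1")
  prod(sc) - 1
}

#' Maximum achievable factor product for a joint
#'
#' Product of the per-factor maxima minus one: 23 for the wrist, 14 for
#' every other assessed joint.
#'
#' @param joint joint kind or sided name.
#' @return numeric constant.
#' @export
max_factors_per_posture <- function(joint) {
  m <- factor_maxima()
  row <- m[m$joint == risk_joint_kind(joint), ]
  if (!nrow(row)) stop("unknown joint: ", joint)
  row$angle_max * row$accel_max * row$force_max * row$torque_max * row$grip_max - 1
}

#' Risk percentage of one posture
#'
#' @param factors factor value(s) from [factors_per_posture()].
#' @param joint joint kind or sided name (sets the normalising maximum).
#' @return percentage in [0, 100].
#' @export
risk_per_posture <- function(factors, joint) {
  100 * factors / max_factors_per_posture(joint)
}

#' Repetitiveness weighting of high-risk postures
#'
#' Nondecreasing piecewise-linear weight (>= 1) applied to each frame's
#' factor value before summation, penalising frames with a high
#' per-posture risk. The default curve rises linearly from 1 at 0\% to 2
#' at 100\% and is fully configurable.
#'
#' @param risk_pct per-posture risk percentage in [0, 100].
#' @param curve two-column matrix/data.frame of (risk \%, weight)
#'   anchors.
#' @return multiplier >= 1.
#' @export
repetitiveness_factor <- function(risk_pct, curve = NULL) {
  if (is.null(curve)) curve <- cbind(c(0, 100), c(1, 2))
  curve <- as.matrix(curve)
  pmax(1, stats::approx(curve[, 1], curve[, 2], xout = risk_pct, rule = 2)$y)
}

#' Workstation context parameters
#'
#' Organisational inputs entering the per-minute risk: granted cycle
#' time, non-recovery hours, micro-pause reduction, repetitive hours per
#' workday and the proportion of the cycle with additional risk factors.
#'
#' @param cycle_time granted cycle time in seconds (`NULL`: the selected
#'   frame span's duration).
#' @param nonrecovery_hours whole hours without recovery (>= 0).
#' @param micropauses micro-pause reduction factor in [0.7, 1].
#' @param repetitive_hours decimal hours of repetitive activity in
#'   (0, 16].
#' @param additional proportion of the cycle with additional factors,
#'   [0, 1].
#' @param preparation worker preparation level 0-3.
#' @param frame_range optional inclusive 0-based `c(first, last)` frame
#'   selection.
#' @return object of class `workstation_context`.
#' @export
workstation_context <- function(cycle_time = NULL, nonrecovery_hours = 0,
                                micropauses = 1, repetitive_hours = 8,
                                additional = 0, preparation = 1,
                                frame_range = NULL) {
  if (!is.null(cycle_time) && cycle_time <= 0) stop("cycle_time must be > 0")
  if (nonrecovery_hours < 0) stop("nonrecovery_hours must be >= 0")
  if (micropauses < 0.7 || micropauses > 1) stop("micropauses must be in [0.7, 1]")
  if (repetitive_hours <= 0 || repetitive_hours > 16) {
    stop("repetitive_hours must be in (0, 16]")
  }
  if (additional < 0 || additional > 1) stop("additional must be in [0, 1]")
  structure(list(cycle_time = cycle_time,
                 nonrecovery_hours = nonrecovery_hours,
                 micropauses = micropauses,
                 repetitive_hours = repetitive_hours,
                 additional = additional, preparation = preparation,
                 frame_range = frame_range),
            class = "workstation_context")
}

recovery_factor <- function(hours) pmin(2.6, 1 + 0.2 * hours)

duration_factor <- function(hours) {
  stats::approx(c(0, 8, 16), c(0.5, 1.1, 2.0), xout = hours, rule = 2)$y
}

additional_factor <- function(proportion) 1 + 0.18 * proportion

#' General (organisational) risk multiplier
#'
#' Product of the recovery factor (1 to 2.6, rising with non-recovery
#' hours), the user-entered micro-pauses factor (0.7 to 1), the duration
#' factor (0.5 to 2 with 8 h of repetitive work mapping to 1.1) and the
#' additional-conditions factor (1 to 1.18).
#'
#' @param ctx a `workstation_context`.
#' @return positive multiplier.
#' @export
general_factors <- function(ctx) {
  recovery_factor(ctx$nonrecovery_hours) * ctx$micropauses *
    duration_factor(ctx$repetitive_hours) * additional_factor(ctx$additional)
}

#' Per-minute risk for one joint
#'
#' Repetitiveness-weighted sum of the per-frame factor values, scaled to
#' one minute by `60 / cycle_time`, normalised by the maximum factor
#' attainable in one minute (the per-posture maximum times frames
#' processed per minute; 3600 postures at 60 Hz) and multiplied by the
#' general factors.
#'
#' @param factors per-frame factor values (from [factors_per_posture()]).
#' @param joint joint kind or sided name.
#' @param ctx a `workstation_context` (its `cycle_time` defaults to the
#'   series duration).
#' @param frame_rate capture rate, Hz.
#' @param rep_curve optional repetitiveness curve (see
#'   [repetitiveness_factor()]).
#' @return risk percentage (>= 0, unbounded above 100 in pathological
#'   overload).
#' @export
risk_per_minute <- function(factors, joint, ctx, frame_rate = 60,
                            rep_curve = NULL) {
  cycle <- ctx$cycle_time %||% (length(factors) / frame_rate)
  if (cycle <= 0) stop("cycle_time must be > 0")
  rpp <- risk_per_posture(factors, joint)
  w <- repetitiveness_factor(rpp, rep_curve)
  max_per_minute <- max_factors_per_posture(joint) * frame_rate * 60
  100 * sum(factors * w) * (60 / cycle) / max_per_minute * general_factors(ctx)
}

#' Risk level, valuation and colour band
#'
#' Maps a per-minute risk percentage onto the 0-5 continuous level scale
#' by linear interpolation within the banding table, with the band's
#' valuation, interpretation and display colour.
#'
#' @param rpm risk-per-minute percentage(s).
#' @return data.frame with columns `risk_per_minute`, `level`,
#'   `valuation`, `interpretation`, `color`.
#' @export
risk_level <- function(rpm) {
  bands <- risk_level_bands()
  out <- lapply(rpm, function(r) {
    i <- which(r > bands$rpm_lo & r <= bands$rpm_hi)
    if (r <= 0) i <- 1L
    if (!length(i)) i <- nrow(bands)
    b <- bands[i[1], ]
    lvl <- if (is.finite(b$rpm_hi)) {
      b$level_lo + (r - b$rpm_lo) / (b$rpm_hi - b$rpm_lo) * (b$level_hi - b$level_lo)
    } else {
      # beyond the last closed band the level keeps the previous slope
      b$level_lo + (r - b$rpm_lo) / 30
    }
    data.frame(risk_per_minute = r, level = max(0, lvl),
               valuation = b$valuation, interpretation = b$interpretation,
               color = b$color, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# grip score per frame for a wrist joint from the active actions
frame_grip_scores <- function(actions, side, nf) {
  g <- rep(1, nf)
  if (is.null(actions) || !nrow(actions)) return(g)
  want <- c("both", if (side == "R") "right" else "left")
  act <- actions[actions$hand %in% want, , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    rng <- (act$frame_start[i]:act$frame_end[i]) + 1L
    rng <- rng[rng >= 1 & rng <= nf]
    g[rng] <- pmax(g[rng], grip_score(act$grasp[i]))
  }
  g
}

#' Assess musculoskeletal risk for a capture
#'
#' Full scoring pipeline: inverse dynamics, per-frame factor scores for
#' the ten assessed joints (lumbar, cervical and sided shoulder, elbow,
#' wrist, knee), per-posture risk series, per-minute risk and risk
#' levels.
#'
#' @param model a `human_model`.
#' @param series a `capture_series`.
#' @param actions optional `action_table`.
#' @param supports optional `support_table`.
#' @param ctx a `workstation_context`.
#' @param loads optional precomputed `joint_load_series` (skips the
#'   inverse-dynamics solve).
#' @param rep_curve optional repetitiveness curve.
#' @return object of class `risk_profile`: `summary` data frame (one row
#'   per joint: risk per minute, level, valuation, interpretation,
#'   colour), `risk_per_posture` matrix (frames x joints, \%), the
#'   per-frame `factors` and the underlying `loads`.
#' @export
assess_risk <- function(model, series, actions = NULL, supports = NULL,
                        ctx = workstation_context(), loads = NULL,
                        rep_curve = NULL) {
  loads <- loads %||% run_inverse_dynamics(model, series, actions, supports)
  kin <- loads$kinematics
  ser <- kin$series
  nf <- dim(loads$force)[1]
  sel <- seq_len(nf)
  if (!is.null(ctx$frame_range)) {
    sel <- (ctx$frame_range[1]:ctx$frame_range[2]) + 1L
    sel <- sel[sel >= 1 & sel <= nf]
  }
  frame_rate <- ser$frame_rate
  factors <- matrix(0, length(sel), length(RISK_JOINTS),
                    dimnames = list(NULL, RISK_JOINTS))
  for (j in RISK_JOINTS) {
    bone <- RISK_JOINT_BONE[[j]]
    ang <- series_angles(ser, bone)[sel, , drop = FALSE]
    acc <- sqrt(rowSums(ser$ang_acc[sel, paste0(bone, c("_Rx", "_Ry", "_Rz")), drop = FALSE]^2))
    fmod <- loads$force_mod[sel, bone]
    tmod <- loads$torque_mod[sel, bone]
    grip <- if (risk_joint_kind(j) == "wrist") {
      frame_grip_scores(actions, sub("^.*_", "", j), nf)[sel]
    } else rep(1, length(sel))
    a_sc <- vapply(seq_along(sel), function(i) {
      angle_score(j, ang[i, 1], ang[i, 2], ang[i, 3])
    }, numeric(1))
    acc_sc <- angular_acceleration_score(j, acc)
    f_sc <- force_score(j, fmod, model$sex, model$height, ctx$preparation)
    t_sc <- torque_score(j, tmod, model$sex, model$height, ctx$preparation)
    factors[, j] <- a_sc * acc_sc * f_sc * t_sc * grip - 1
  }
  rpp <- sweep(factors, 2, vapply(RISK_JOINTS, max_factors_per_posture,
                                  numeric(1)), "/") * 100
  rpm <- vapply(RISK_JOINTS, function(j) {
    risk_per_minute(factors[, j], j, ctx, frame_rate, rep_curve)
  }, numeric(1))
  lv <- risk_level(rpm)
  summary <- cbind(data.frame(joint = RISK_JOINTS, stringsAsFactors = FALSE),
                   lv)
  rownames(summary) <- NULL
  structure(list(summary = summary, risk_per_posture = rpp,
                 factors = factors, loads = loads, context = ctx),
            class = "risk_profile")
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile>\n")
  s <- x$summary
  s$risk_per_minute <- round_half_up(s$risk_per_minute, 1)
  s$level <- round_half_up(s$level, 2)
  print(s[, c("joint", "risk_per_minute", "level", "valuation", "interpretation")],
        row.names = FALSE)
  invisible(x)
}

#' Per-frame risk curves
#'
#' Plots the per-posture risk series of every assessed joint.
#'
#' @param x a `risk_profile`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.risk_profile <- function(x, ...) {
  graphics::matplot(x$risk_per_posture, type = "l", lty = 1,
                    xlab = "frame", ylab = "risk per posture (%)", ...)
  graphics::legend("topright", legend = colnames(x$risk_per_posture),
                   col = seq_len(ncol(x$risk_per_posture)), lty = 1, cex = 0.6)
}
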