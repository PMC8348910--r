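# Two-stage inverse dynamics in kilogram-force units: whole-body support
# reactions first, then distal-to-proximal propagation of force and torque
# vectors along each kinematic chain.

#' External hand-action table
#'
#' Declares the forces/torques the worker exerts with the hands over
#' frame ranges. Vectors are expressed in the pelvis-linked frame (y
#' vertical, x/z parallel to the ground, rotating with pelvis yaw) and
#' carry the sign of the load perceived in the hands.
#'
#' @param frame_start,frame_end inclusive 0-based frame indices.
#' @param hand `"right"`, `"left"` or `"both"` (a both-hands vector is
#'   split 50/50 between hands).
#' @param fx,fy,fz force components, kgf.
#' @param tx,ty,tz torque components, kg m.
#' @param grasp grasp-type code 0-9.
#' @return data.frame of class `action_table`.
#' @export
action_table <- function(frame_start = integer(), frame_end = integer(),
                         hand = character(), fx = 0, fy = 0, fz = 0,
                         tx = 0, ty = 0, tz = 0, grasp = 0) {
  n <- length(frame_start)
  rep_n <- function(x) rep_len(x, n)
  tab <- data.frame(frame_start = as.integer(frame_start),
                    frame_end = as.integer(rep_n(frame_end)),
                    hand = as.character(rep_n(hand)),
                    fx = rep_n(fx), fy = rep_n(fy), fz = rep_n(fz),
                    tx = rep_n(tx), ty = rep_n(ty), tz = rep_n(tz),
                    grasp = as.integer(rep_n(grasp)), stringsAsFactors = FALSE)
  validate_actions(tab)
  class(tab) <- c("action_table", "data.frame")
  tab
}

validate_actions <- function(tab) {
  if (!nrow(tab)) return(invisible(tab))
  if (any(tab$frame_start > tab$frame_end)) stop("frame_start > frame_end in action table")
  if (any(tab$frame_start < 0)) stop("negative frame index in action table")
  if (!all(tab$hand %in% c("right", "left", "both"))) {
    stop("hand must be one of 'right', 'left', 'both'")
  }
  if (!all(tab$grasp %in% 0:9)) stop("grasp codes must be in 0..9")
  invisible(tab)
}

#' Support-declaration table
#'
#' Frame ranges during which the worker is seated or has a hand
#' supported. These declarations override automatic foot-support
#' detection within their range.
#'
#' @param frame_start,frame_end inclusive 0-based frame indices.
#' @param kind `"seated"`, `"hand_L"` or `"hand_R"`.
#' @return data.frame of class `support_table`.
#' @export
support_table <- function(frame_start = integer(), frame_end = integer(),
                          kind = character()) {
  tab <- data.frame(frame_start = as.integer(frame_start),
                    frame_end = as.integer(frame_end),
                    kind = as.character(kind), stringsAsFactors = FALSE)
  if (nrow(tab)) {
    if (any(tab$frame_start > tab$frame_end)) stop("frame_start > frame_end in support table")
    if (!all(tab$kind %in% c("seated", "hand_L", "hand_R"))) {
      stop("kind must be one of 'seated', 'hand_L', 'hand_R'")
    }
  }
  class(tab) <- c("support_table", "data.frame")
  tab
}

#' Detect per-frame support state
#'
#' A foot counts as supported when its ankle height above the frame's
#' lowest foot point stays below `height_threshold` and its linear speed
#' below `speed_threshold`. Declared seated / hand-support ranges
#' override the detection; a frame with no detected support falls back to
#' both feet with a warning.
#'
#' @param kin a `capture_kinematics`.
#' @param declared optional `support_table`.
#' @param height_threshold metres above the frame minimum.
#' @param speed_threshold metres per second.
#' @return data.frame per frame with logical columns `foot_R`, `foot_L`,
#'   `seated`, `hand_R`, `hand_L` (class `support_state`).
#' @export
detect_foot_support <- function(kin, declared = NULL,
                                height_threshold = 0.05,
                                speed_threshold = 0.3) {
  stopifnot(inherits(kin, "capture_kinematics"))
  nf <- dim(kin$joints)[1]
  hr <- kin$joints[, "foot_R", "y"]
  hl <- kin$joints[, "foot_L", "y"]
  base <- pmin(hr, hl)
  spd <- function(b) sqrt(rowSums(kin$joint_vel[, b, , drop = FALSE]^2, dims = 1))
  sr <- spd("foot_R"); sl <- spd("foot_L")
  st <- data.frame(
    foot_R = (hr - base) < height_threshold & sr < speed_threshold,
    foot_L = (hl - base) < height_threshold & sl < speed_threshold,
    seated = FALSE, hand_R = FALSE, hand_L = FALSE
  )
  if (!is.null(declared) && nrow(declared)) {
    for (i in seq_len(nrow(declared))) {
      rng <- (declared$frame_start[i]:declared$frame_end[i]) + 1L
      rng <- rng[rng >= 1 & rng <= nf]
      col <- switch(declared$kind[i], seated = "seated",
                    hand_L = "hand_L", hand_R = "hand_R")
      st[rng, col] <- TRUE
      if (declared$kind[i] == "seated") st[rng, c("foot_R", "foot_L")] <- FALSE
    }
  }
  none <- !st$foot_R & !st$foot_L & !st$seated & !st$hand_R & !st$hand_L
  if (any(none)) {
    warning(sum(none), " frame(s) with no detected support; assuming both feet")
    st[none, c("foot_R", "foot_L")] <- TRUE
  }
  class(st) <- c("support_state", "data.frame")
  st
}

# pelvis yaw angle (rotation about the vertical) for the action frame
pelvis_yaw <- function(kin, frame) {
  r <- kin$rot[frame, "pelvis", , ]
  ant <- r %*% c(0, 0, 1)
  atan2(ant[1], ant[3])
}

# resolve declared actions for one frame: list of per-hand global-frame
# force/torque vectors (kgf, kg m)
resolve_actions <- function(kin, actions, frame) {
  out <- list(hand_R = list(force = c(0, 0, 0), torque = c(0, 0, 0)),
              hand_L = list(force = c(0, 0, 0), torque = c(0, 0, 0)))
  if (is.null(actions) || !nrow(actions)) return(out)
  idx0 <- frame - 1L  # action ranges are 0-based
  act <- actions[actions$frame_start <= idx0 & actions$frame_end >= idx0, , drop = FALSE]
  if (!nrow(act)) return(out)
  ry <- rot_y(pelvis_yaw(kin, frame))
  for (i in seq_len(nrow(act))) {
    f <- as.numeric(ry %*% c(act$fx[i], act$fy[i], act$fz[i]))
    tq <- as.numeric(ry %*% c(act$tx[i], act$ty[i], act$tz[i]))
    hands <- switch(act$hand[i], right = "hand_R", left = "hand_L",
                    both = c("hand_R", "hand_L"))
    w <- if (length(hands) == 2) 0.5 else 1
    for (h in hands) {
      out[[h]]$force <- out[[h]]$force + w * f
      out[[h]]$torque <- out[[h]]$torque + w * tq
    }
  }
  out
}

# Distribute the whole-body reaction among active support points.
# Weights minimise the distance between the weighted support centroid and
# the horizontal projection of the global CG (exact clamped lever rule for
# two supports), solved by active-set enumeration over the simplex.
distribute_supports <- function(points_xz, cg_xz) {
  n <- nrow(points_xz)
  if (n == 1) return(1)
  obj <- function(w) {
    d <- colSums(w * points_xz) - cg_xz
    sum(d * d)
  }
  best_w <- rep(1 / n, n)
  best <- obj(best_w)
  for (k in seq_len(n)) {
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      p <- points_xz[sub, , drop = FALSE]
      # least squares for centroid == cg on the affine hull of the subset
      if (length(sub) == 1) {
        w_sub <- 1
      } else {
        a <- rbind(t(p), 1)
        b <- c(cg_xz, 1)
        w_sub <- tryCatch(qr.solve(a, b, tol = 1e-12), error = function(e) NULL)
        if (is.null(w_sub)) w_sub <- rep(1 / length(sub), length(sub))
      }
      if (any(w_sub < -1e-9)) next
      w_sub <- pmax(w_sub, 0)
      if (sum(w_sub) <= 0) next
      w_sub <- w_sub / sum(w_sub)
      w <- rep(0, n); w[sub] <- w_sub
      val <- obj(w)
      if (val < best - 1e-12) { best <- val; best_w <- w }
    }
  }
  best_w
}

# per-frame gravity, inertial and external loads for every bone (kgf)
frame_loads <- function(kin, frame, actions, gravity = GRAVITY) {
  model <- kin$model
  seg <- model$segments
  g_scale <- gravity / GRAVITY  # allows switching gravity off in analyses
  w <- -outer(seg$weight_fraction * model$body_weight * g_scale, c(0, 1, 0))
  rownames(w) <- BONES
  acc <- kin$cg_acc[frame, , ]
  inert <- -(seg$weight_fraction * model$body_weight) * acc / GRAVITY
  ext <- resolve_actions(kin, actions, frame)
  list(weight = w, inertial = inert, external = ext)
}

# support contact points for one frame (attached to their carrying bone)
support_points <- function(kin, frame, st) {
  pts <- list()
  if (st$foot_R[frame]) pts$foot_R <- kin$joints[frame, "foot_R", ]
  if (st$foot_L[frame]) pts$foot_L <- kin$joints[frame, "foot_L", ]
  if (st$seated[frame]) pts$pelvis <- kin$joints[frame, "pelvis", ]
  if (st$hand_R[frame]) pts$hand_R <- kin$cg[frame, "hand_R", ]
  if (st$hand_L[frame]) pts$hand_L <- kin$cg[frame, "hand_L", ]
  pts
}

#' Whole-body support reactions for one frame
#'
#' Balances segment weights, inertial forces and external hand loads so
#' the net force on the body is zero; with several supports the load is
#' shared by the lever rule on the horizontal projection of the global
#' centre of gravity between the support points (clamped to the segment).
#'
#' @param kin a `capture_kinematics`.
#' @param frame 1-based frame index.
#' @param actions optional `action_table`.
#' @param supports a `support_state` (see [detect_foot_support()]).
#' @param gravity gravitational acceleration, m/s^2.
#' @return named list of reaction 3-vectors (kgf), one per support point.
#' @export
support_reactions <- function(kin, frame, actions = NULL, supports,
                              gravity = GRAVITY) {
  pts <- support_points(kin, frame, supports)
  if (!length(pts)) stop("no active support at frame ", frame)
  ld <- frame_loads(kin, frame, actions, gravity)
  total <- colSums(ld$weight) + colSums(ld$inertial) +
    ld$external$hand_R$force + ld$external$hand_L$force
  r_total <- -total
  seg <- kin$model$segments
  mass <- seg$weight_fraction
  cg_xz <- c(sum(mass * kin$cg[frame, , "x"]), sum(mass * kin$cg[frame, , "z"])) / sum(mass)
  p <- do.call(rbind, lapply(pts, function(v) v[c(1, 3)]))
  w <- distribute_supports(p, cg_xz)
  stats::setNames(lapply(seq_along(pts), function(i) w[i] * r_total), names(pts))
}

# children lookup for the recursion
skeleton_children <- function(sk) {
  lapply(stats::setNames(sk$bone, sk$bone), function(b) sk$bone[!is.na(sk$parent) & sk$parent == b])
}

# Solve one frame: force and torque at every bone-origin joint.
solve_frame <- function(kin, frame, actions = NULL, supports = NULL,
                        reactions = NULL, gravity = GRAVITY) {
  model <- kin$model
  sk <- model$skeleton
  seg <- model$segments
  if (is.null(reactions)) {
    reactions <- support_reactions(kin, frame, actions, supports, gravity)
  }
  ld <- frame_loads(kin, frame, actions, gravity)
  children <- skeleton_children(sk)
  order <- skeleton_postorder(sk)
  f <- t <- matrix(0, length(BONES), 3, dimnames = list(BONES, c("x", "y", "z")))
  jp <- kin$joints[frame, , ]
  cgp <- kin$cg[frame, , ]
  for (b in order) {
    wb <- ld$weight[b, ] + ld$inertial[b, ]
    fb <- wb
    lcg <- cgp[b, ] - jp[b, ]
    tens <- as.numeric(seg[b, c("i_x", "i_y", "i_z")])
    om <- kin$omega[frame, b, ]
    al <- kin$alpha[frame, b, ]
    it <- -(tens * al + cross3(om, tens * om)) / GRAVITY
    tb <- cross3(lcg, wb) + it
    if (b %in% c("hand_R", "hand_L")) {
      ef <- ld$external[[b]]$force
      et <- ld$external[[b]]$torque
      fb <- fb + ef
      tb <- tb + cross3(lcg, ef) + et  # force applied at the hand CG
    }
    rn <- reactions[[b]]
    if (!is.null(rn)) {
      # contact point: bone origin for feet/pelvis, CG for supported hands
      pt <- if (b %in% c("hand_R", "hand_L")) cgp[b, ] else jp[b, ]
      fb <- fb + rn
      tb <- tb + cross3(pt - jp[b, ], rn)
    }
    for (ch in children[[b]]) {
      fb <- fb + f[ch, ]
      tb <- tb + cross3(jp[ch, ] - jp[b, ], f[ch, ]) + t[ch, ]
    }
    f[b, ] <- fb
    t[b, ] <- tb
  }
  list(force = f, torque = t, reactions = reactions)
}

#' Force supported by a joint in one frame
#'
#' Isolates the kinematic chain distal to the joint (the bone whose
#' origin is the joint plus everything it carries) and sums segment
#' weights, inertial forces, external hand forces and support reactions.
#'
#' @inheritParams support_reactions
#' @param joint bone name identifying the joint at the bone's origin
#'   (e.g. `"hand_R"` for the right wrist, `"lumbar"` for the
#'   lumbosacral joint).
#' @param reactions optional precomputed reactions from
#'   [support_reactions()]; computed when omitted.
#' @return force 3-vector in kgf.
#' @export
joint_force <- function(kin, frame, joint, actions = NULL, supports = NULL,
                        reactions = NULL, gravity = GRAVITY) {
  if (!joint %in% BONES) stop("unknown joint: ", joint)
  solve_frame(kin, frame, actions, supports, reactions, gravity)$force[joint, ]
}

#' Torque supported by a joint in one frame
#'
#' Moments of all distal loads about the joint centre plus inertial
#' torques (tensor times angular acceleration plus the gyroscopic term)
#' and external hand torques.
#'
#' @inheritParams joint_force
#' @return torque 3-vector in kg m.
#' @export
joint_torque <- function(kin, frame, joint, actions = NULL, supports = NULL,
                         reactions = NULL, gravity = GRAVITY) {
  if (!joint %in% BONES) stop("unknown joint: ", joint)
  solve_frame(kin, frame, actions, supports, reactions, gravity)$torque[joint, ]
}

#' Run inverse dynamics over a capture
#'
#' Per-frame two-stage solve: support reactions for the whole body, then
#' the distal-to-proximal recursion from wrists and ankles towards the
#' pelvis, for every frame of the capture.
#'
#' @param model a `human_model`.
#' @param series a `capture_series` (or a precomputed
#'   `capture_kinematics`).
#' @param actions optional `action_table`.
#' @param supports optional `support_table` of declared seated/hand
#'   ranges; foot support is detected automatically.
#' @param gravity gravitational acceleration, m/s^2 (set 0 to isolate
#'   inertial effects).
#' @return object of class `joint_load_series` with arrays `force`,
#'   `torque` (frames x bones x 3, kgf / kg m), matrices `force_mod`,
#'   `torque_mod`, the per-frame `reactions`, the `support` state and the
#'   embedded kinematics.
#' @export
run_inverse_dynamics <- function(model, series, actions = NULL,
                                 supports = NULL, gravity = GRAVITY) {
  kin <- if (inherits(series, "capture_kinematics")) series
         else compute_kinematics(model, series)
  if (!is.null(actions)) {
    validate_actions(actions)
    nf <- dim(kin$joints)[1]
    if (any(actions$frame_end > nf - 1)) {
      stop("action frame range exceeds capture length")
    }
  }
  st <- detect_foot_support(kin, declared = supports)
  nf <- dim(kin$joints)[1]
  force <- torque <- array(0, c(nf, length(BONES), 3),
                           dimnames = list(NULL, BONES, c("x", "y", "z")))
  reactions <- vector("list", nf)
  for (i in seq_len(nf)) {
    sol <- tryCatch(
      solve_frame(kin, i, actions, st, gravity = gravity),
      error = function(e) stop("frame ", i, ": ", conditionMessage(e))
    )
    force[i, , ] <- sol$force
    torque[i, , ] <- sol$torque
    reactions[[i]] <- sol$reactions
  }
  structure(list(model = model, kinematics = kin, support = st,
                 force = force, torque = torque,
                 force_mod = sqrt(rowSums(force^2, dims = 2)),
                 torque_mod = sqrt(rowSums(torque^2, dims = 2)),
                 reactions = reactions, actions = actions,
                 gravity = gravity),
            class = "joint_load_series")
}

#' @export
print.joint_load_series <- function(x, ...) {
  cat(sprintf("<joint_load_series> %d frames x %d joints\n",
              dim(x$force)[1], dim(x$force)[2]))
  cat("  mean |f| (kgf): lumbar", round(mean(x$force_mod[, "lumbar"]), 2),
      "| cervical", round(mean(x$force_mod[, "head"]), 2), "\n")
  invisible(x)
}
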