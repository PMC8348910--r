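# Kinematics: capture container, forward kinematics along the chain, and
# numerical differentiation of angle and position series.

#' Create a capture series
#'
#' A capture series holds per-frame joint rotations in degrees (right-hand
#' rule, relative to the neutral standing pose) for each bone of the
#' model, sampled uniformly.
#'
#' @param angles data.frame or matrix with one row per frame and columns
#'   named `<bone>_<Rx|Ry|Rz>` (e.g. `lumbar_Rx`). Missing columns are
#'   filled with zeros.
#' @param frame_rate sampling rate in Hz.
#' @return object of class `capture_series`.
#' @export
capture_series <- function(angles, frame_rate = 60) {
  angles <- as.data.frame(angles)
  if (nrow(angles) < 3) stop("a capture needs at least 3 frames")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  full <- as.vector(outer(BONES, c("Rx", "Ry", "Rz"), paste, sep = "_"))
  bad <- setdiff(names(angles), full)
  if (length(bad)) stop("unknown angle columns: ", paste(bad, collapse = ", "))
  m <- matrix(0, nrow(angles), length(full), dimnames = list(NULL, full))
  m[, names(angles)] <- as.matrix(angles)
  if (any(!is.finite(m))) stop("capture contains non-finite angles")
  structure(list(frame_rate = frame_rate, angles = m),
            class = "capture_series")
}

#' @export
print.capture_series <- function(x, ...) {
  cat(sprintf("<capture_series> %d frames at %g Hz (%.2f s)\n",
              nrow(x$angles), x$frame_rate, nrow(x$angles) / x$frame_rate))
  invisible(x)
}

n_frames <- function(series) nrow(series$angles)

series_angles <- function(series, bone) {
  series$angles[, paste0(bone, c("_Rx", "_Ry", "_Rz")), drop = FALSE]
}

#' Forward kinematics for one frame
#'
#' Composes the per-joint rotations along the chain from the pelvis using
#' the model bone lengths, returning global joint-centre and segment-CG
#' positions (m; y vertical up) plus each bone's global rotation matrix.
#'
#' @param model a `human_model`.
#' @param rotations named list or vector source of per-bone `(Rx, Ry, Rz)`
#'   degrees: either a named numeric vector with `<bone>_<axis>` names or
#'   a one-row slice of a capture's angle matrix. All chain bones must be
#'   present (zeros allowed).
#' @return list with `joints` (16 x 3 matrix of joint-centre positions),
#'   `tips` (bone distal ends), `cg` (segment centres of gravity) and
#'   `rot` (list of 3 x 3 global rotation matrices).
#' @export
forward_kinematics <- function(model, rotations) {
  if (is.list(rotations) && !is.data.frame(rotations)) {
    rotations <- unlist(rotations)
  }
  need <- as.vector(outer(BONES, c("Rx", "Ry", "Rz"), paste, sep = "_"))
  missing <- setdiff(need, names(rotations))
  if (length(missing)) {
    miss_bones <- unique(sub("_(Rx|Ry|Rz)$", "", missing))
    stop("missing rotations for joint(s): ", paste(miss_bones, collapse = ", "))
  }
  sk <- model$skeleton
  seg <- model$segments
  joints <- tips <- cg <- matrix(NA_real_, length(BONES), 3,
                                 dimnames = list(BONES, c("x", "y", "z")))
  rot <- vector("list", length(BONES)); names(rot) <- BONES
  for (b in BONES) {
    r <- euler_xyz(rotations[[paste0(b, "_Rx")]],
                   rotations[[paste0(b, "_Ry")]],
                   rotations[[paste0(b, "_Rz")]])
    p <- sk[b, "parent"]
    off <- as.numeric(sk[b, c("off_x", "off_y", "off_z")])
    if (is.na(p)) {
      rot[[b]] <- r
      joints[b, ] <- off
    } else {
      rot[[b]] <- rot[[p]] %*% r
      joints[b, ] <- joints[p, ] + as.numeric(rot[[p]] %*% off)
    }
    bv <- as.numeric(rot[[b]] %*% (as.numeric(sk[b, c("dir_x", "dir_y", "dir_z")]) * sk[b, "length"]))
    tips[b, ] <- joints[b, ] + bv
    cg[b, ] <- joints[b, ] + seg[b, "cg_fraction"] * bv
  }
  list(joints = joints, tips = tips, cg = cg, rot = rot)
}

# finite differences on a column matrix; interior central, endpoints one-sided
fd_velocity <- function(x, dt) {
  n <- nrow(x)
  v <- x * 0
  if (n >= 3) v[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  v[1, ] <- (x[2, ] - x[1, ]) / dt
  v[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  v
}

fd_acceleration <- function(x, dt) {
  n <- nrow(x)
  a <- x * 0
  if (n >= 3) {
    a[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - 2 * x[2:(n - 1), , drop = FALSE] +
                         x[1:(n - 2), , drop = FALSE]) / dt^2
    a[1, ] <- a[2, ]
    a[n, ] <- a[n - 1, ]
  }
  a
}

#' Differentiate a capture series
#'
#' First and second numerical derivatives of every joint-angle curve:
#' central differences in the interior, one-sided at the endpoints.
#' Optionally applies Savitzky-Golay smoothing to the angles before
#' differencing (off by default; the effort calibration tables were
#' derived from unsmoothed series).
#'
#' @param series a `capture_series`.
#' @param smooth_window odd window length for Savitzky-Golay smoothing,
#'   or `NULL` for none.
#' @param smooth_order polynomial order for the smoother.
#' @return the series with matrices `ang_vel` (deg/s) and `ang_acc`
#'   (deg/s^2) attached.
#' @export
differentiate <- function(series, smooth_window = NULL, smooth_order = 3) {
  stopifnot(inherits(series, "capture_series"))
  if (n_frames(series) < 3) stop("need at least 3 frames to differentiate")
  x <- series$angles
  if (!is.null(smooth_window)) {
    x <- apply(x, 2, function(col) signal::sgolayfilt(col, p = smooth_order, n = smooth_window))
  }
  dt <- 1 / series$frame_rate
  series$ang_vel <- fd_velocity(x, dt)
  series$ang_acc <- fd_acceleration(x, dt)
  series
}

#' Full kinematics of a capture
#'
#' Runs forward kinematics on every frame and differentiates: joint and
#' CG positions, relative angular velocity/acceleration per joint (deg/s,
#' deg/s^2), global angular velocity/acceleration per bone (rad/s,
#' rad/s^2, extracted from the rotation-matrix time series) and linear
#' velocity/acceleration of joints and segment CGs (m/s, m/s^2).
#'
#' @param model a `human_model`.
#' @param series a `capture_series`.
#' @inheritParams differentiate
#' @return object of class `capture_kinematics`.
#' @export
compute_kinematics <- function(model, series, smooth_window = NULL) {
  series <- differentiate(series, smooth_window = smooth_window)
  nf <- n_frames(series)
  nb <- length(BONES)
  dt <- 1 / series$frame_rate
  joints <- tips <- cg <- array(NA_real_, c(nf, nb, 3),
                                dimnames = list(NULL, BONES, c("x", "y", "z")))
  rots <- array(NA_real_, c(nf, nb, 3, 3), dimnames = list(NULL, BONES, NULL, NULL))
  for (i in seq_len(nf)) {
    fk <- forward_kinematics(model, series$angles[i, ])
    joints[i, , ] <- fk$joints
    tips[i, , ] <- fk$tips
    cg[i, , ] <- fk$cg
    for (b in seq_len(nb)) rots[i, b, , ] <- fk$rot[[b]]
  }
  flat <- function(a) matrix(a, nf, nb * 3)  # frame-major view for differencing
  unflat <- function(m) array(m, c(nf, nb, 3), dimnames = dimnames(joints))
  cg_vel <- unflat(fd_velocity(flat(cg), dt))
  cg_acc <- unflat(fd_acceleration(flat(cg), dt))
  joint_vel <- unflat(fd_velocity(flat(joints), dt))

  # global angular velocity from Rdot R^T, then differentiate for alpha
  omega <- array(0, c(nf, nb, 3), dimnames = dimnames(joints))
  for (b in seq_len(nb)) {
    for (i in seq_len(nf)) {
      i0 <- max(1, i - 1); i1 <- min(nf, i + 1)
      rdot <- (rots[i1, b, , ] - rots[i0, b, , ]) / ((i1 - i0) * dt)
      omega[i, b, ] <- unskew(rdot %*% t(rots[i, b, , ]))
    }
  }
  alpha <- unflat(fd_velocity(flat(omega), dt))

  structure(list(model = model, series = series,
                 joints = joints, tips = tips, cg = cg,
                 rot = rots, cg_vel = cg_vel, cg_acc = cg_acc,
                 joint_vel = joint_vel, omega = omega, alpha = alpha),
            class = "capture_kinematics")
}

#' @export
print.capture_kinematics <- function(x, ...) {
  cat(sprintf("<capture_kinematics> %d frames, %d bones\n",
              dim(x$joints)[1], dim(x$joints)[2]))
  invisible(x)
}
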