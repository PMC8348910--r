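# Shared fixtures and independent oracles for the test suite.

male_p50 <- function() build_human_model(1.759, "male")

# a capture with every joint at a fixed rotation, n frames
constant_capture <- function(angles = list(), n = 60, frame_rate = 60) {
  df <- if (length(angles)) {
    as.data.frame(lapply(angles, rep_len, n))
  } else {
    data.frame(pelvis_Rx = numeric(n))
  }
  capture_series(df, frame_rate = frame_rate)
}

# direction of a bone hanging down after a rotation about the global x axis
hang_dir <- function(theta_rad) c(0, -cos(theta_rad), -sin(theta_rad))

# Closed-form planar two-link oracle for the right arm chain
# (shoulder/elbow flexion about the global x axis, wrist fixed), computing
# joint torques by direct summation of moments of gravity + inertial
# loads about the joint, with analytic positions and accelerations.
# Independent of the package's FK/recursion code path.
planar_arm_oracle <- function(model, t, th1, th1d, th1dd, th2, th2d, th2dd,
                              gravity = 9.81) {
  seg <- model$segments
  sk <- model$skeleton
  L1 <- sk["arm_R", "length"]; L2 <- sk["forearm_R", "length"]
  L3 <- sk["hand_R", "length"]
  c1 <- seg["arm_R", "cg_fraction"]; c2 <- seg["forearm_R", "cg_fraction"]
  c3 <- seg["hand_R", "cg_fraction"]
  m <- seg$weight_fraction * model$body_weight
  names(m) <- seg$bone
  g2 <- th1 + th2; g2d <- th1d + th2d; g2dd <- th1dd + th2dd
  d <- function(th) c(0, -cos(th), -sin(th))
  dp <- function(th) c(0, sin(th), -cos(th))
  # acceleration of a point at distance r along a link with global angle th
  acc <- function(r, th, thd, thdd) r * (dp(th) * thdd - d(th) * thd^2)
  p_sh <- c(0, 0, 0)  # torques only need relative levers
  p_el <- p_sh + L1 * d(th1)
  p_wr <- p_el + L2 * d(g2)
  cg_arm <- p_sh + c1 * L1 * d(th1)
  cg_fa <- p_el + c2 * L2 * d(g2)
  cg_h <- p_wr + c3 * L3 * d(g2)
  a_arm <- acc(c1 * L1, th1, th1d, th1dd)
  a_fa <- acc(L1, th1, th1d, th1dd) + acc(c2 * L2, g2, g2d, g2dd)
  a_h <- acc(L1, th1, th1d, th1dd) + acc(L2 + c3 * L3, g2, g2d, g2dd)
  load <- function(mb, a) c(0, -mb, 0) - mb * a / gravity  # kgf
  it_x <- function(bone, thdd) -seg[bone, "i_x"] * thdd / gravity
  mom_x <- function(lever, f) lever[2] * f[3] - lever[3] * f[2]
  tau <- function(p_joint, bodies) {
    s <- 0
    for (b in bodies) {
      s <- s + mom_x(b$cg - p_joint, b$f) + b$it
    }
    s
  }
  arm <- list(cg = cg_arm, f = load(m[["arm_R"]], a_arm), it = it_x("arm_R", th1dd))
  fa <- list(cg = cg_fa, f = load(m[["forearm_R"]], a_fa), it = it_x("forearm_R", g2dd))
  h <- list(cg = cg_h, f = load(m[["hand_R"]], a_h), it = it_x("hand_R", g2dd))
  list(shoulder = tau(p_sh, list(arm, fa, h)),
       elbow = tau(p_el, list(fa, h)),
       wrist = tau(p_wr, list(h)))
}

# Published per-workstation per-minute risk rows, used as combination-
# arithmetic inputs: three captured variants of one workstation and a
# five-station risk map with an equal-time rotation.
p003_rows <- function() {
  data.frame(
    label = c("P003_Medium", "P003_Low", "P003_Top"),
    lumbar = c(22.9, 34.2, 21.8), cervical = c(22.6, 24.1, 20.7),
    shoulder_R = c(8.8, 8.6, 14.1), elbow_R = c(16.2, 21.7, 24.0),
    wrist_R = c(15.4, 14.9, 16.3), knee_R = c(20.5, 19.6, 15.2),
    shoulder_L = c(9.1, 8.6, 12.8), elbow_L = c(26.9, 27.3, 29.7),
    wrist_L = c(14.2, 12.4, 13.1), knee_L = c(14.7, 24.7, 18.2),
    stringsAsFactors = FALSE
  )
}

station_rows <- function() {
  data.frame(
    label = c("P001", "P002", "P003_COMBI", "P004", "P005"),
    lumbar = c(6.8, 18.2, 25.8, 13.6, 30.4),
    cervical = c(25.4, 16.7, 22.5, 44.4, 12.6),
    shoulder_R = c(4.6, 7.9, 10.3, 22.4, 7.9),
    elbow_R = c(11.4, 15.7, 20.0, 40.8, 8.9),
    wrist_R = c(5.0, 5.9, 15.5, 36.4, 4.9),
    knee_R = c(4.5, 5.3, 18.7, 17.2, 0.0),
    shoulder_L = c(4.2, 11.7, 10.0, 24.4, 9.4),
    elbow_L = c(10.3, 18.7, 27.8, 35.7, 10.8),
    wrist_L = c(7.3, 8.1, 13.4, 37.4, 8.4),
    knee_L = c(4.7, 4.3, 18.6, 6.1, 0.4),
    stringsAsFactors = FALSE
  )
}

# whole-body force-balance residual per frame, recomputed from the raw
# kinematics arrays (masses, CG accelerations, declared actions)
equilibrium_residuals <- function(loads) {
  kin <- loads$kinematics
  model <- loads$model
  nf <- dim(loads$force)[1]
  mass <- model$segments$weight_fraction * model$body_weight
  vapply(seq_len(nf), function(i) {
    w <- c(0, -sum(mass), 0)
    inert <- -colSums(mass * kin$cg_acc[i, , ]) / 9.81
    ext <- ergoforces:::resolve_actions(kin, loads$actions, i)
    tot <- w + inert + ext$hand_R$force + ext$hand_L$force +
      Reduce(`+`, loads$reactions[[i]])
    max(abs(tot))
  }, numeric(1))
}
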