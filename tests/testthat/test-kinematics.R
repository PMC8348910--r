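test_that("forward kinematics matches a hand-computed two-link chain", {
  m <- male_p50()
  # 90 deg elbow flexion only: wrist displaced by the forearm geometry
  rot <- stats::setNames(rep(0, 48),
                         as.vector(outer(ergoforces:::BONES, c("Rx", "Ry", "Rz"),
                                         paste, sep = "_")))
  fk0 <- forward_kinematics(m, rot)
  rot[["forearm_R_Rx"]] <- 90
  fk <- forward_kinematics(m, rot)
  L2 <- m$skeleton["forearm_R", "length"]
  L3 <- m$skeleton["hand_R", "length"]
  p_el <- fk0$joints["forearm_R", ]
  expect_equal(unname(fk$joints["hand_R", ]),
               unname(p_el + L2 * hang_dir(pi / 2)), tolerance = 1e-12)
  expect_equal(unname(fk$tips["hand_R", ]),
               unname(p_el + (L2 + L3) * hang_dir(pi / 2)), tolerance = 1e-12)
  # head CG sits at 30% of the head bone from its origin
  expect_equal(fk0$cg["head", "y"] - fk0$joints["head", "y"],
               0.30 * m$skeleton["head", "length"])
})

test_that("missing joint rotations are rejected by name", {
  m <- male_p50()
  expect_error(forward_kinematics(m, c(pelvis_Rx = 0)), "head")
})

test_that("consecutive joint centres stay one bone length apart", {
  m <- male_p50()
  set.seed(42)
  pairs <- list(c("arm_R", "forearm_R"), c("forearm_R", "hand_R"),
                c("thigh_L", "shin_L"), c("shin_L", "foot_L"),
                c("lumbar", "thorax"), c("thorax", "head"))
  for (rep in 1:5) {
    rot <- stats::setNames(stats::runif(48, -60, 60),
                           as.vector(outer(ergoforces:::BONES, c("Rx", "Ry", "Rz"),
                                           paste, sep = "_")))
    fk <- forward_kinematics(m, rot)
    for (p in pairs) {
      expect_equal(sqrt(sum((fk$joints[p[2], ] - fk$joints[p[1], ])^2)),
                   m$skeleton[p[1], "length"], tolerance = 1e-9)
    }
  }
})

test_that("differentiation recovers analytic derivatives", {
  fr <- 60
  n <- 240
  t <- (seq_len(n) - 1) / fr
  # constant series: zero velocity and acceleration
  cs <- constant_capture(list(lumbar_Rx = 12), n = n)
  d <- differentiate(cs)
  expect_true(all(abs(d$ang_vel) < 1e-12))
  expect_true(all(abs(d$ang_acc) < 1e-12))
  # linear ramp: constant velocity, zero interior acceleration
  ramp <- capture_series(data.frame(lumbar_Rx = 7 * t), frame_rate = fr)
  dr <- differentiate(ramp)
  expect_equal(unname(dr$ang_vel[2:(n - 1), "lumbar_Rx"]), rep(7, n - 2))
  expect_true(all(abs(dr$ang_acc[2:(n - 1), "lumbar_Rx"]) < 1e-9))
  # sinusoid: peak angular speed within 1% of A*omega for omega <= 2*pi
  for (f in c(0.5, 1)) {
    A <- 30
    sine <- capture_series(data.frame(hand_R_Rx = A * sin(2 * pi * f * t)),
                           frame_rate = fr)
    ds <- differentiate(sine)
    expect_equal(max(abs(ds$ang_vel[, "hand_R_Rx"])), A * 2 * pi * f,
                 tolerance = 0.01)
  }
})

test_that("differentiation is linear in the series", {
  fr <- 60
  t <- (0:99) / fr
  a1 <- data.frame(lumbar_Rx = 20 * sin(2 * pi * t), head_Ry = 5 * t)
  a2 <- data.frame(lumbar_Rx = cos(3 * t), head_Ry = t^2)
  s1 <- capture_series(a1, fr); s2 <- capture_series(a2, fr)
  s12 <- capture_series(2 * a1 + 3 * a2, fr)
  d1 <- differentiate(s1); d2 <- differentiate(s2); d12 <- differentiate(s12)
  expect_equal(d12$ang_vel, 2 * d1$ang_vel + 3 * d2$ang_vel, tolerance = 1e-9)
  expect_equal(d12$ang_acc, 2 * d1$ang_acc + 3 * d2$ang_acc, tolerance = 1e-9)
})

test_that("too-short captures are rejected", {
  expect_error(capture_series(data.frame(lumbar_Rx = c(0, 1))), "3 frames")
})
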