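test_that("static standing support reactions balance body weight", {
  m <- male_p50()
  ld <- run_inverse_dynamics(m, constant_capture(n = 20))
  r <- ld$reactions[[10]]
  total <- Reduce(`+`, r)
  expect_equal(total, c(x = 0, y = 80.50, z = 0), tolerance = 1e-9)
  # symmetric stance: each foot carries half
  expect_equal(unname(r$foot_R[2]), 40.25, tolerance = 1e-6)
  expect_equal(unname(r$foot_L[2]), 40.25, tolerance = 1e-6)
  # holding 8 kgf down in each hand adds 16 to the vertical reaction
  acts <- action_table(c(0, 0), c(19, 19), c("right", "left"), fy = -8)
  ld2 <- run_inverse_dynamics(m, constant_capture(n = 20), actions = acts)
  expect_equal(unname(Reduce(`+`, ld2$reactions[[10]])[2]), 80.50 + 16,
               tolerance = 1e-9)
})

test_that("static standing joint forces reproduce the tabulated minima", {
  m <- male_p50()
  ld <- run_inverse_dynamics(m, constant_capture(n = 20))
  fm <- colMeans(ld$force_mod)
  expect_equal(unname(fm["lumbar"]), 44.6, tolerance = 0.15)
  expect_equal(unname(fm["head"]), 6.8, tolerance = 0.15)
  expect_equal(unname(fm["arm_R"]), 4.2, tolerance = 0.15)
  expect_equal(unname(fm["arm_L"]), 4.2, tolerance = 0.15)
  expect_equal(unname(fm["forearm_R"]), 1.9, tolerance = 0.15)
  expect_equal(unname(fm["hand_R"]), 0.5, tolerance = 0.15)
  # female P50 static minima
  f <- scale_to_percentile(m, "female", "P50")
  ldf <- run_inverse_dynamics(f, constant_capture(n = 20))
  fmf <- colMeans(ldf$force_mod)
  expect_equal(unname(fmf["lumbar"]), 27.7, tolerance = 0.15)
  expect_equal(unname(fmf["head"]), 5.5, tolerance = 0.15)
  expect_equal(unname(fmf["arm_R"]), 3.1, tolerance = 0.15)
  expect_equal(unname(fmf["hand_L"]), 0.4, tolerance = 0.15)
  # an idealized symmetric stance cannot exceed the measured static torques
  tq <- effort_thresholds("torque")
  tq <- tq[tq$sex == "male", ]
  tm <- colMeans(ld$torque_mod)
  bone_of <- c(lumbar = "lumbar", cervical = "head", shoulder = "arm_R",
               elbow = "forearm_R", wrist = "hand_R", knee = "shin_R")
  for (j in names(bone_of)) {
    expect_lte(tm[[bone_of[[j]]]], tq$min[tq$joint == j] + 0.15)
  }
})

test_that("zero gravity and zero motion produce zero joint loads", {
  m <- male_p50()
  ld <- run_inverse_dynamics(m, constant_capture(n = 10), gravity = 0)
  expect_true(all(abs(ld$force) < 1e-9))
  expect_true(all(abs(ld$torque) < 1e-9))
})

test_that("whole-body force equilibrium holds at every frame", {
  m <- male_p50()
  for (sc in c("static_stand", "wide_arcs", "lift_place", "screw_task")) {
    syn <- generate_synthetic_capture(sc, duration = 1.5, frame_rate = 30,
                                      seed = 7)
    ld <- run_inverse_dynamics(m, syn$series, actions = syn$actions)
    expect_lt(max(equilibrium_residuals(ld)), 1e-6)
  }
})

test_that("a horizontally outstretched arm loads the shoulder by the lever sum", {
  m <- male_p50()
  cs <- constant_capture(list(arm_R_Rx = -90), n = 12)
  ld <- run_inverse_dynamics(m, cs)
  seg <- m$segments
  sk <- m$skeleton
  W <- m$body_weight
  lever <- seg["arm_R", "weight_fraction"] * W * seg["arm_R", "cg_fraction"] * sk["arm_R", "length"] +
    seg["forearm_R", "weight_fraction"] * W * (sk["arm_R", "length"] + seg["forearm_R", "cg_fraction"] * sk["forearm_R", "length"]) +
    seg["hand_R", "weight_fraction"] * W * (sk["arm_R", "length"] + sk["forearm_R", "length"] + seg["hand_R", "cg_fraction"] * sk["hand_R", "length"])
  expect_equal(unname(ld$torque_mod[6, "arm_R"]), lever, tolerance = 1e-9)
  # the hanging arm carries essentially no shoulder torque
  ld0 <- run_inverse_dynamics(m, constant_capture(n = 12))
  expect_lt(ld0$torque_mod[6, "arm_R"], 1e-9)
})

test_that("an external hand torque propagates unchanged to the static wrist", {
  m <- male_p50()
  acts <- action_table(0, 11, "right", tz = -0.2, grasp = 1)
  ld <- run_inverse_dynamics(m, constant_capture(n = 12), actions = acts)
  expect_equal(unname(ld$torque[6, "hand_R", ]), c(0, 0, -0.2),
               tolerance = 1e-9)
})

test_that("inertial loads scale with acceleration when gravity is off", {
  m <- male_p50()
  ang <- data.frame(arm_R_Rx = 15 * sin(2 * pi * (0:59) / 60))
  # identical samples at twice the frame rate: every acceleration exactly
  # quadruples, so with gravity off all inertial loads quadruple
  ld1 <- run_inverse_dynamics(m, capture_series(ang, 30), gravity = 0)
  ld2 <- run_inverse_dynamics(m, capture_series(ang, 60), gravity = 0)
  expect_equal(ld2$force_mod, 4 * ld1$force_mod, tolerance = 1e-9)
  expect_equal(ld2$torque_mod, 4 * ld1$torque_mod, tolerance = 1e-9)
})

test_that("planar two-link torques match the closed-form rigid-body oracle", {
  m <- male_p50()
  fr <- 60
  n <- 121
  t <- (seq_len(n) - 1) / fr
  w1 <- 2 * pi * 0.5; w2 <- 2 * pi * 0.5
  A1 <- 45; A2 <- 30
  th1 <- A1 * pi / 180 * sin(w1 * t)
  th2 <- A2 * pi / 180 * sin(w2 * t + pi / 4)
  cs <- capture_series(data.frame(arm_R_Rx = th1 * 180 / pi,
                                  forearm_R_Rx = th2 * 180 / pi), fr)
  ld <- run_inverse_dynamics(m, cs)
  oracle_sh <- oracle_el <- numeric(n)
  for (i in seq_len(n)) {
    o <- planar_arm_oracle(
      m, t[i],
      th1[i], A1 * pi / 180 * w1 * cos(w1 * t[i]),
      -A1 * pi / 180 * w1^2 * sin(w1 * t[i]),
      th2[i], A2 * pi / 180 * w2 * cos(w2 * t[i] + pi / 4),
      -A2 * pi / 180 * w2^2 * sin(w2 * t[i] + pi / 4))
    oracle_sh[i] <- abs(o$shoulder)
    oracle_el[i] <- abs(o$elbow)
  }
  interior <- 5:(n - 4)  # skip one-sided endpoint differences
  # per-frame agreement within 1% of the cycle's peak torque
  expect_lt(max(abs(ld$torque_mod[interior, "arm_R"] - oracle_sh[interior])),
            0.01 * max(oracle_sh))
  expect_lt(max(abs(ld$torque_mod[interior, "forearm_R"] - oracle_el[interior])),
            0.01 * max(oracle_el))
})

test_that("foot support detection separates grounded and raised feet", {
  m <- male_p50()
  # static neutral: both feet supported everywhere
  kin <- compute_kinematics(m, constant_capture(n = 10))
  st <- detect_foot_support(kin)
  expect_true(all(st$foot_R) && all(st$foot_L))
  # one leg raised by hip flexion: only the grounded foot supports
  kin1 <- compute_kinematics(m, constant_capture(list(thigh_R_Rx = -50), n = 10))
  st1 <- detect_foot_support(kin1)
  expect_true(all(st1$foot_L))
  expect_false(any(st1$foot_R))
  # declared seated range overrides foot detection
  dec <- support_table(2, 5, "seated")
  st2 <- detect_foot_support(kin, declared = dec)
  expect_true(all(st2$seated[3:6]))
  expect_false(any(st2$foot_R[3:6]))
  expect_true(all(st2$foot_R[c(1:2, 7:10)]))
})

test_that("action and support tables are validated", {
  expect_error(action_table(5, 2, "right"), "frame_start")
  expect_error(action_table(0, 5, "middle"), "hand")
  expect_error(action_table(0, 5, "right", grasp = 12), "grasp")
  expect_error(support_table(0, 5, "kneeling"), "kind")
  m <- male_p50()
  expect_error(run_inverse_dynamics(m, constant_capture(n = 5),
                                    actions = action_table(0, 99, "both")),
               "exceeds capture length")
})
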