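test_that("angle score interpolates between breakpoints and saturates", {
  expect_equal(angle_score("lumbar", 0, 0, 0), 1.0)
  expect_equal(angle_score("lumbar", 100), 2.0)   # beyond the extreme
  expect_equal(angle_score("lumbar", 40), 1.5)    # halfway 20..60
  expect_equal(angle_score("lumbar", 0, 0, 20), 1.5)
  expect_equal(angle_score("wrist_R", 45), 1.6)   # wrist cap
  expect_equal(angle_score("shoulder_L", 0, 0, 0), 1.0)
  expect_gt(angle_score("shoulder_L", 0, 0, 90), 1.4)
  expect_error(angle_score("hip", 0), "no angle graph")
})

test_that("angular acceleration score follows the threshold table", {
  expect_equal(angular_acceleration_score("lumbar", 50), 1.0)
  expect_equal(angular_acceleration_score("lumbar", 255), 1.5)
  expect_equal(angular_acceleration_score("lumbar", 152.5), 1.25)
  expect_equal(angular_acceleration_score("lumbar", 0), 1.0)
  expect_equal(angular_acceleration_score("wrist_R", 1e6), 1.5)
})

test_that("force and torque scores use percentile thresholds and preparation", {
  expect_equal(force_score("lumbar", 44.6, "male", 1.759), 1.0)
  expect_equal(force_score("lumbar", 65.1, "male", 1.759), 2.0)
  expect_equal(force_score("lumbar", 54.85, "male", 1.759), 1.5)
  # a specially trained worker raises the maximum to 65.1 * 1.2
  expect_lt(force_score("lumbar", 65.1, "male", 1.759, preparation = 3), 2.0)
  expect_equal(torque_score("lumbar", 1.81, "male", 1.759), 1.0)
  expect_equal(torque_score("lumbar", 22.95, "male", 1.759), 2.5)
  expect_equal(torque_score("lumbar", (1.81 + 22.95) / 2, "male", 1.759), 1.75)
  expect_equal(torque_score("lumbar", 0, "male", 1.759), 1.0)
  # height interpolation: P05 stature scales thresholds by coef_p05
  expect_equal(force_score("lumbar", 44.6 * 0.87, "male", 1.649), 1.0)
  expect_equal(force_score("lumbar", 65.1 * 0.87, "male", 1.649), 2.0)
})

test_that("grip scores look up the grasp table", {
  expect_equal(grip_score(0), 1.0)
  expect_equal(grip_score(4), 1.6)
  expect_equal(grip_score(9), 2.0)
  expect_error(grip_score(11), "grasp")
})

test_that("factor products and per-posture risk follow the scoring formula", {
  expect_equal(factors_per_posture(c(1, 1, 1, 1, 1)), 0)
  expect_equal(factors_per_posture(c(1.6, 1.5, 2, 2.5, 2)), 23)
  expect_equal(factors_per_posture(c(2, 1.5, 2, 2.5, 1)), 14)
  expect_equal(factors_per_posture(1.5, 1.2, 1.3, 1.4, 1),
               1.5 * 1.2 * 1.3 * 1.4 - 1)
  expect_error(factors_per_posture(c(0.9, 1, 1, 1, 1)), ">= 1")
  expect_equal(max_factors_per_posture("wrist_L"), 23)
  expect_equal(max_factors_per_posture("knee"), 14)
  expect_equal(risk_per_posture(0, "lumbar"), 0)
  expect_equal(risk_per_posture(14, "lumbar"), 100)
  expect_equal(risk_per_posture(7, "lumbar"), 50)
})

test_that("repetitiveness weighting is monotone with unit floor", {
  expect_equal(repetitiveness_factor(0), 1.0)
  expect_equal(repetitiveness_factor(100), 2.0)
  x <- seq(0, 100, by = 5)
  w <- repetitiveness_factor(x)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w >= 1))
})

test_that("general factors multiply the organisational components", {
  base <- workstation_context(nonrecovery_hours = 0, micropauses = 1,
                              repetitive_hours = 8, additional = 0)
  expect_equal(general_factors(base), 1.1)  # 8 h maps to 1.1
  full_add <- workstation_context(repetitive_hours = 8, additional = 1)
  expect_equal(general_factors(full_add), 1.1 * 1.18)
  # component floors: no recovery need, deepest micro-pauses, minimal duration
  floor_ctx <- workstation_context(nonrecovery_hours = 0, micropauses = 0.7,
                                   repetitive_hours = 1e-9, additional = 0)
  expect_equal(general_factors(floor_ctx), 0.7 * 0.5, tolerance = 1e-6)
  # recovery factor saturates at 2.6
  long <- workstation_context(nonrecovery_hours = 12, repetitive_hours = 8)
  expect_equal(general_factors(long), 2.6 * 1.1)
  expect_error(workstation_context(cycle_time = 0), "cycle_time")
  expect_error(workstation_context(micropauses = 0.5), "micropauses")
})

test_that("risk per minute collapses correctly for constant postures", {
  fr <- 60
  n <- 180  # 3 s capture
  f <- rep(3, n)
  ctx <- workstation_context(cycle_time = n / fr, repetitive_hours = 8,
                             micropauses = 1)
  # with repetitiveness forced to 1 and general factors divided out, the
  # per-minute risk of a constant posture equals its per-posture risk
  flat <- cbind(c(0, 100), c(1, 1))
  gf <- general_factors(ctx)
  expect_equal(risk_per_minute(f, "lumbar", ctx, fr, rep_curve = flat) / gf,
               100 * 3 / 14)
  # halving cycle time doubles the risk
  ctx2 <- workstation_context(cycle_time = n / fr / 2)
  expect_equal(risk_per_minute(f, "lumbar", ctx2, fr),
               2 * risk_per_minute(f, "lumbar", ctx, fr))
  expect_equal(risk_per_minute(rep(0, n), "lumbar", ctx, fr), 0)
})

test_that("duplicating the capture with doubled cycle time leaves risk unchanged", {
  fr <- 60
  f <- runif(120, 0, 5)
  ctx1 <- workstation_context(cycle_time = 2)
  ctx2 <- workstation_context(cycle_time = 4)
  expect_equal(risk_per_minute(c(f, f), "wrist", ctx2, fr),
               risk_per_minute(f, "wrist", ctx1, fr))
})

test_that("risk level bands interpolate and classify", {
  lv <- risk_level(26.9)
  expect_equal(lv$interpretation, "Conditional")
  expect_equal(risk_level(10)$level, 1)
  expect_equal(risk_level(10)$valuation, "No risk")
  expect_equal(risk_level(55)$level, 4.5)
  expect_equal(risk_level(44.4)$interpretation, "Unacceptable")
  expect_equal(risk_level(0)$level, 0)
  expect_gt(risk_level(90)$level, 5)
})

test_that("each factor input is nondecreasing in the per-minute risk", {
  ctx <- workstation_context(cycle_time = 1)
  fr <- 60
  rpm_of <- function(a = 1, acc = 1, f = 1, tq = 1, g = 1, joint = "wrist") {
    risk_per_minute(rep(a * acc * f * tq * g - 1, 60), joint, ctx, fr)
  }
  grids <- list(
    angle = vapply(seq(1, 1.6, 0.1), function(v) rpm_of(a = v), numeric(1)),
    accel = vapply(seq(1, 1.5, 0.1), function(v) rpm_of(acc = v), numeric(1)),
    force = vapply(seq(1, 2, 0.2), function(v) rpm_of(f = v), numeric(1)),
    torque = vapply(seq(1, 2.5, 0.25), function(v) rpm_of(tq = v), numeric(1)),
    grip = vapply(seq(1, 2, 0.2), function(v) rpm_of(g = v), numeric(1))
  )
  for (g in grids) expect_true(all(diff(g) >= 0))
  # raw inputs through the score functions are monotone too
  fs <- vapply(seq(0, 90, 5), function(v) force_score("lumbar", v), numeric(1))
  ts <- vapply(seq(0, 30, 2), function(v) torque_score("lumbar", v), numeric(1))
  as_ <- vapply(seq(0, 2000, 100),
                function(v) angular_acceleration_score("elbow", v), numeric(1))
  an <- vapply(seq(0, 80, 5), function(v) angle_score("lumbar", v), numeric(1))
  gr <- grip_score(c(0, 1, 4, 5, 9))
  for (g in list(fs, ts, as_, an)) expect_true(all(diff(g) >= 0))
  expect_true(all(diff(gr[c(1, 2, 3, 4, 5)]) >= 0))
  # organisational inputs
  hrs <- vapply(0:10, function(h) general_factors(
    workstation_context(nonrecovery_hours = h)), numeric(1))
  add <- vapply(seq(0, 1, 0.1), function(p) general_factors(
    workstation_context(additional = p)), numeric(1))
  expect_true(all(diff(hrs) >= 0))
  expect_true(all(diff(add) >= 0))
})

test_that("the full assessment pipeline scores a benign static stand as acceptable", {
  m <- male_p50()
  syn <- generate_synthetic_capture("static_stand", duration = 1,
                                    frame_rate = 30)
  ctx <- workstation_context(nonrecovery_hours = 0, micropauses = 1,
                             repetitive_hours = 8, additional = 0)
  prof <- assess_risk(m, syn$series, ctx = ctx)
  expect_s3_class(prof, "risk_profile")
  expect_true(all(prof$summary$interpretation == "Acceptable"))
  expect_true(all(prof$risk_per_posture >= 0 & prof$risk_per_posture <= 100))
  # lifting raises the peak lumbar per-posture risk above static standing
  lift <- generate_synthetic_capture("lift_place", duration = 2,
                                     frame_rate = 30)
  prof_l <- assess_risk(m, lift$series, actions = lift$actions, ctx = ctx)
  expect_gt(max(prof_l$risk_per_posture[, "lumbar"]),
            max(prof$risk_per_posture[, "lumbar"]))
  # grip scoring engages the wrists during the declared action frames
  act_rows <- lift$actions
  in_lift <- (act_rows$frame_start[1]:act_rows$frame_end[1]) + 1
  expect_gt(max(prof_l$factors[in_lift, "wrist_R"]), 0)
})
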