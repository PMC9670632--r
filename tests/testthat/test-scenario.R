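cyclic_switch_layout <- function() {
  # each patient: robot i for steps 1-6, robot i+1 (mod 5) for steps 8-12
  schedule(patient = rep(1:5, each = 2),
           robot = c(t(cbind(1:5, c(2:5, 1)))),
           start = rep(c(1L, 8L), 5),
           end = rep(c(6L, 12L), 5))
}

test_that("feasibility checking accepts valid layouts", {
  scn <- scn_5p5r12e()
  expect_true(validate_schedule(scn, empty_schedule())$feasible)
  rep <- validate_schedule(scn, cyclic_switch_layout())
  expect_true(rep$feasible)
  expect_equal(total_gain(scn, cyclic_switch_layout()),
               5 * (eq_gain(6) + eq_gain(5)), tolerance = 1e-9)
})

test_that("violations are tagged by constraint", {
  scn <- gym_scenario(2, 2, G = 12)
  # same robot, steps 1-4 and 4-6: step 4 double-booked
  bad <- schedule(patient = 1:2, robot = 1, start = c(1, 4), end = c(4, 6))
  expect_false(validate_schedule(scn, bad)$feasible)
  expect_true("robot_overlap" %in% validate_schedule(scn, bad)$violations$tag)

  scn_h <- gym_scenario(1, 1, G = 12, H = 6)
  late <- schedule(1, 1, 7, 8)
  expect_true("last_start" %in%
                validate_schedule(scn_h, late)$violations$tag)

  out <- schedule(1, 1, 1, 13)
  expect_true("bounds" %in% validate_schedule(scn, out)$violations$tag)

  dup <- schedule(patient = c(1, 1), robot = c(1, 1), start = c(1, 6),
                  end = c(2, 7))
  expect_true("duplicate_pair" %in%
                validate_schedule(scn, dup)$violations$tag)

  scn_e <- gym_scenario(2, data.frame(id = 1:2, exit_time = 1), G = 12)
  gap_r <- schedule(patient = 1:2, robot = 1, start = c(1, 5), end = c(4, 9))
  expect_true("robot_exit_gap" %in%
                validate_schedule(scn_e, gap_r)$violations$tag)
  gap_p <- schedule(patient = 1, robot = 1:2, start = c(1, 5), end = c(4, 9))
  expect_true("patient_exit_gap" %in%
                validate_schedule(scn_e, gap_p)$violations$tag)
})

test_that("out-of-range indices are a structural error, not infeasibility", {
  scn <- gym_scenario(2, 2, G = 5)
  expect_error(validate_schedule(scn, schedule(3, 1, 1, 2)), "outside")
  expect_error(validate_schedule(scn, schedule(1, 9, 1, 2)), "outside")
})

test_that("feasibility is invariant to block insertion order", {
  scn <- scn_5p5r12e()
  base <- as.data.frame(cyclic_switch_layout())
  set.seed(42)
  for (k in 1:5) {
    shuffled <- schedule(base[sample.int(nrow(base)), ])
    expect_true(validate_schedule(scn, shuffled)$feasible)
  }
})

test_that("gains depend on durations, not positions", {
  scn <- gym_scenario(1, 1, G = 10)
  for (s in 2:4)
    expect_equal(total_gain(scn, schedule(1, 1, s, s + 3)),
                 total_gain(scn, schedule(1, 1, s + 1, s + 4)))
})

test_that("total and per-patient gains reproduce the printed baselines", {
  scn <- scn_5p5r7()
  br <- best_robot_schedule(scn)
  expect_equal(total_gain(scn, br), 153.5, tolerance = 0.05 / 153.5)
  expect_equal(total_gain(scn, empty_schedule()), 0)

  scn6 <- gym_scenario(6, 5, G = 7)
  g <- per_patient_gains(scn6, best_robot_schedule(scn6))
  expect_equal(sum(g == 0), 1)
  expect_equal(sort(g, decreasing = TRUE)[1:5], rep(eq_gain(7), 5),
               tolerance = 1e-9)
  expect_equal(sum(g), total_gain(scn6, best_robot_schedule(scn6)))
  expect_equal(per_patient_gains(scn6, empty_schedule()), numeric(6))
})

test_that("trajectory is cumulative, nondecreasing and ends at the total", {
  scn <- scn_5p5r7()
  br <- best_robot_schedule(scn)
  tr <- gain_trajectory(scn, br)
  expect_length(tr, 7)
  expect_equal(tr[1], 5 * eq_gain(1), tolerance = 1e-9)
  expect_equal(tr[7], total_gain(scn, br), tolerance = 1e-9)
  expect_true(all(diff(tr) >= -1e-12))
  expect_equal(gain_trajectory(scn, empty_schedule()), numeric(7))
})

test_that("group objectives reduce to total gain in the expected limits", {
  scn <- scn_5p5r7()
  br <- best_robot_schedule(scn)
  tot <- total_gain(scn, br)
  expect_equal(objective_value(scn, br, objective_total()), tot)
  expect_equal(objective_value(scn, br, objective_variance_penalized(0)),
               tot)
  # equal curves + symmetric schedule: zero variance for any m
  expect_equal(objective_value(scn, br, objective_variance_penalized(50)),
               tot, tolerance = 1e-9)
  # unequal gains are penalised
  scn2 <- gym_scenario(2, 1, G = 4)
  sch <- schedule(patient = 1:2, robot = 1, start = c(1, 4), end = c(3, 4))
  g <- per_patient_gains(scn2, sch)
  expect_equal(objective_value(scn2, sch, objective_variance_penalized(2)),
               sum(g) - 2 * mean((g - mean(g))^2), tolerance = 1e-12)
})

test_that("relative-to-max objective vanishes penalty at the maximum", {
  scn <- gym_scenario(1, 1, G = 5)
  best <- schedule(1, 1, 1, 5)   # the single patient's individual optimum
  tot <- total_gain(scn, best)
  expect_equal(objective_value(scn, best, objective_relative_to_max(3)),
               tot, tolerance = 1e-9)
  # zero maximum with a positive penalty coefficient is a domain error
  scn0 <- gym_scenario(1, 1, G = 5,
                       curves = skill_curve(c4 = 0))
  expect_error(objective_value(scn0, empty_schedule(),
                               objective_relative_to_max(1)),
               "zero maximum")
})
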