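test_that("repair pulls blocks forward and extends into idle time", {
  scn <- gym_scenario(1, 1, G = 5)
  fixed <- repair_schedule(scn, schedule(1, 1, 2, 3))
  expect_equal(as.data.frame(fixed),
               data.frame(patient = 1L, robot = 1L, start = 1L, end = 5L))
  expect_equal(total_gain(scn, fixed), eq_gain(5), tolerance = 1e-9)
  # fixed points stay fixed
  expect_equal(as.data.frame(repair_schedule(scn, fixed)),
               as.data.frame(fixed))
  full <- schedule(1, 1, 1, 5)
  expect_equal(as.data.frame(repair_schedule(scn, full)),
               as.data.frame(full))
})

test_that("repair is monotone, feasible and idempotent on random schedules", {
  for (seed in 1:10) {
    scn <- random_scenario(seed)
    sch <- random_feasible_schedule(scn, seed + 30)
    rep1 <- repair_schedule(scn, sch)
    expect_true(validate_schedule(scn, rep1)$feasible)
    expect_gte(total_gain(scn, rep1), total_gain(scn, sch) - 1e-9)
    expect_equal(as.data.frame(repair_schedule(scn, rep1)),
                 as.data.frame(rep1))
  }
})

test_that("individual maxima match exhaustive reasoning on equal curves", {
  # 5 robots, G=7, no exit: optimal split 2+2+1+1+1 across robots
  expect_equal(max_individual_gain(gym_scenario(1, 5, G = 7), 1),
               2 * eq_gain(2) + 3 * eq_gain(1), tolerance = 1e-9)
  # 5 robots, G=12, exit 1: optimal is 3 robots at 4+3+3 (2 exits consumed)
  expect_equal(max_individual_gain(gym_scenario(1, rep(1, 5), G = 12), 1),
               eq_gain(4) + 2 * eq_gain(3), tolerance = 1e-9)
  # single robot: no choice but the full session
  expect_equal(max_individual_gain(gym_scenario(1, 1, G = 7), 1),
               eq_gain(7), tolerance = 1e-9)
})

test_that("upper bound dominates every feasible schedule", {
  scn1 <- gym_scenario(1, 3, G = 6)
  expect_equal(upper_bound(scn1), max_individual_gain(scn1, 1),
               tolerance = 1e-9)
  expect_equal(upper_bound(scn_5p5r7()),
               5 * (2 * eq_gain(2) + 3 * eq_gain(1)), tolerance = 1e-9)
  for (seed in 1:8) {
    scn <- random_scenario(seed)
    ub <- upper_bound(scn)
    sch <- random_feasible_schedule(scn, seed + 70)
    expect_gte(ub, total_gain(scn, sch) - 1e-9)
  }
})

test_that("brute force recovers hand-checkable optima", {
  r1 <- brute_force_optimal(gym_scenario(1, 1, G = 3))
  expect_equal(r1$value, eq_gain(3), tolerance = 1e-9)
  expect_equal(r1$bound, r1$value)
  expect_equal(as.data.frame(r1$schedule),
               data.frame(patient = 1L, robot = 1L, start = 1L, end = 3L))

  # two patients share one robot over 3 steps: splitting 2+1 beats 3+0
  r2 <- brute_force_optimal(gym_scenario(2, 1, G = 3))
  expect_equal(r2$value, eq_gain(2) + eq_gain(1), tolerance = 1e-9)
  expect_gt(r2$value, eq_gain(3))
  expect_true(validate_schedule(gym_scenario(2, 1, G = 3),
                                r2$schedule)$feasible)
})

test_that("brute force refuses oversized instances", {
  expect_error(brute_force_optimal(scn_5p5r12(), cap = 1e6),
               "optimize_schedule")
})

test_that("optimizer matches the brute-force oracle on small instances", {
  insts <- list(gym_scenario(1, 1, G = 3),
                gym_scenario(2, 1, G = 3),
                gym_scenario(2, 2, G = 4),
                gym_scenario(3, 3, G = 4),
                gym_scenario(2, data.frame(id = 1:2, exit_time = 1), G = 5))
  for (scn in insts) {
    opt <- brute_force_optimal(scn)$value
    for (m in c("disjunctive", "time_indexed")) {
      res <- optimize_schedule(scn, method = m, budget = 80, seed = 11)
      expect_equal(res$value, opt, tolerance = 1e-9,
                   label = paste(m, scn$M, "P", scn$N, "R", scn$G, "G"))
    }
  }
})

test_that("zero budget returns the better baseline", {
  for (seed in 1:4) {
    scn <- random_scenario(seed)
    base_best <- max(total_gain(scn, best_robot_schedule(scn)),
                     total_gain(scn, switch_halfway_schedule(scn)))
    res <- optimize_schedule(scn, budget = 0, seed = 1)
    expect_equal(res$value, base_best, tolerance = 1e-12)
    expect_equal(res$iterations_used, 0L)
  }
})

test_that("value is nondecreasing in budget and never above the bound", {
  scn <- random_scenario(3)
  vals <- vapply(c(0, 2, 10, 40), function(b)
    optimize_schedule(scn, budget = b, seed = 9)$value, numeric(1))
  expect_true(all(diff(vals) >= -1e-12))
  for (seed in 1:6) {
    scn <- random_scenario(seed)
    res <- optimize_schedule(scn, budget = 25, seed = seed)
    expect_lte(res$value, res$bound + 1e-9)
    expect_true(validate_schedule(scn, res$schedule)$feasible)
    expect_true(all(diff(res$improvement_log$value) > 0))
  }
})

test_that("optimization is deterministic given a seed", {
  scn <- random_scenario(5)
  a <- optimize_schedule(scn, budget = 30, seed = 21)
  b <- optimize_schedule(scn, budget = 30, seed = 21)
  expect_identical(as.data.frame(a$schedule), as.data.frame(b$schedule))
  expect_identical(a$improvement_log, b$improvement_log)
})

test_that("optimizer honours alternative objectives", {
  scn <- gym_scenario(2, 1, G = 4)
  # a large variance penalty prefers even splits over lopsided ones
  res <- optimize_schedule(scn, objective_variance_penalized(5),
                           budget = 60, seed = 2)
  g <- per_patient_gains(scn, res$schedule)
  expect_lte(abs(diff(g)), eq_gain(2))
  bf <- brute_force_optimal(scn, objective_variance_penalized(5))
  expect_equal(res$value, bf$value, tolerance = 1e-9)

  res_rel <- optimize_schedule(scn, objective_relative_to_max(c(1, 1)),
                               budget = 60, seed = 2)
  bf_rel <- brute_force_optimal(scn, objective_relative_to_max(c(1, 1)))
  expect_equal(res_rel$value, bf_rel$value, tolerance = 1e-9)
})
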