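# printed reference totals for the nine equal-curve scenarios
table1_baselines <- data.frame(
  scenario = c("5P 5R 7T", "5P 5R 12T", "5P 5R 12T e1",
               "6P 5R 7T", "6P 5R 12T", "6P 5R 12T e1",
               "5P 7R 7T", "5P 7R 12T", "5P 7R 12T e1"),
  best_robot = c(153.5, 208.3, 208.3, 153.5, 208.3, 208.3,
                 153.5, 208.3, 208.3),
  switch_halfway = c(187.5, 277.8, 261.4, 187.5, 277.8, 261.4,
                     187.5, 277.8, 261.4))

test_that("both baselines reproduce the printed equal-curve totals", {
  scns <- equal_curve_scenarios()
  for (i in seq_len(nrow(table1_baselines))) {
    scn <- scns[[table1_baselines$scenario[i]]]
    expect_equal(total_gain(scn, best_robot_schedule(scn)),
                 table1_baselines$best_robot[i], tolerance = 0.05 / 100,
                 label = paste("best robot", table1_baselines$scenario[i]))
    expect_equal(total_gain(scn, switch_halfway_schedule(scn)),
                 table1_baselines$switch_halfway[i], tolerance = 0.05 / 100,
                 label = paste("switch halfway",
                               table1_baselines$scenario[i]))
  }
})

test_that("best robot assigns min(M, N) patients for the whole session", {
  for (dims in list(c(5, 5), c(6, 5), c(5, 7), c(2, 4))) {
    scn <- gym_scenario(dims[1], dims[2], G = 7)
    sch <- best_robot_schedule(scn)
    expect_equal(nrow(sch), min(dims))
    expect_true(all(sch$start == 1 & sch$end == 7))
    expect_true(validate_schedule(scn, sch)$feasible)
  }
  scn1 <- gym_scenario(1, 1, G = 3)
  expect_equal(as.data.frame(best_robot_schedule(scn1)),
               data.frame(patient = 1L, robot = 1L, start = 1L, end = 3L))
})

test_that("switch halfway splits the session as ceil/floor around the exit", {
  scn <- scn_5p5r7()
  sch <- switch_halfway_schedule(scn)
  durs <- tapply(sch$end - sch$start + 1, sch$patient, function(x)
    paste(sort(x, decreasing = TRUE), collapse = "+"))
  expect_true(all(durs == "4+3"))

  sch_e <- switch_halfway_schedule(scn_5p5r12e())
  durs_e <- tapply(sch_e$end - sch_e$start + 1, sch_e$patient, function(x)
    paste(sort(x, decreasing = TRUE), collapse = "+"))
  expect_true(all(durs_e == "6+5"))
  # second block waits out the exit window
  for (p in 1:5) {
    bl <- sch_e[sch_e$patient == p, ]
    expect_equal(bl$start[2], bl$end[1] + 1 + 1)
  }
})

test_that("baselines are feasible on randomized scenarios", {
  for (seed in 1:8) {
    scn <- random_scenario(seed)
    expect_true(validate_schedule(scn, best_robot_schedule(scn))$feasible)
    expect_true(validate_schedule(scn,
                                  switch_halfway_schedule(scn))$feasible)
  }
})

test_that("greedy conflict resolution favours the larger gain", {
  # patient 1 gains much more on robot 1; patient 2 must take robot 2
  crv <- list(c1 = matrix(100, 2, 2),
              c2 = matrix(1, 2, 2),
              c3 = matrix(c(5, 500, 100, 100), 2, 2),
              c4 = matrix(1, 2, 2), u = matrix(1, 2, 2))
  scn <- gym_scenario(2, 2, G = 6, curves = crv)
  sch <- best_robot_schedule(scn)
  expect_equal(sch$robot[sch$patient == 1], 1L)
  expect_equal(sch$robot[sch$patient == 2], 2L)
})

test_that("switching halfway beats staying put under diminishing returns", {
  for (nm in names(equal_curve_scenarios())) {
    scn <- equal_curve_scenarios()[[nm]]
    expect_gt(total_gain(scn, switch_halfway_schedule(scn)),
              total_gain(scn, best_robot_schedule(scn)))
  }
})
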