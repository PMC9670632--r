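test_that("group generation is deterministic and respects the ranges", {
  spec <- group_spec()
  g1 <- generate_group(spec, 5, 5, seed = 7)
  g2 <- generate_group(spec, 5, 5, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_group(spec, 5, 5, seed = 8)))
  expect_true(all(g1$c2 >= 0.01 & g1$c2 <= 100))
  expect_true(all(g1$c3 >= 5 & g1$c3 <= 1000))
  expect_true(all(g1$c1 == 100) && all(g1$c4 == 1) && all(g1$u == 1))
})

test_that("degenerate ranges collapse to the equal-curve scenario", {
  spec <- group_spec(c2_range = c(1, 1), c3_range = c(10, 10))
  g <- generate_group(spec, 3, 3, seed = 1)
  scn <- gym_scenario(3, 3, G = 7, curves = g)
  expect_equal(total_gain(scn, best_robot_schedule(scn)), 3 * eq_gain(7),
               tolerance = 1e-9)
})

test_that("a pool smaller than M*N is rejected", {
  expect_error(generate_group(group_spec(n_curves = 10), 5, 5), "too small")
})

test_that("the nine equal-curve scenarios carry the intended dimensions", {
  scns <- equal_curve_scenarios()
  expect_length(scns, 9)
  expect_equal(scns[["5P 5R 12T e1"]]$exit, rep(1L, 5))
  expect_equal(scns[["5P 7R 7T"]]$N, 7L)
  expect_equal(scns[["6P 5R 12T"]]$M, 6L)
  expect_true(all(vapply(scns, function(s) s$H == s$G, logical(1))))
})

test_that("suite baseline columns reproduce the printed table", {
  suite <- run_suite(schedule_types = c("best_robot", "switch_halfway"))
  expect_equal(suite$table$best_robot,
               c(153.5, 208.3, 208.3, 153.5, 208.3, 208.3,
                 153.5, 208.3, 208.3), tolerance = 0.05 / 100)
  expect_equal(suite$table$switch_halfway,
               c(187.5, 277.8, 261.4, 187.5, 277.8, 261.4,
                 187.5, 277.8, 261.4), tolerance = 0.05 / 100)
  det <- suite$details[["5P 5R 7T | best_robot"]]
  expect_equal(sum(det$per_patient), suite$table$best_robot[1],
               tolerance = 1e-9)
  expect_equal(det$trajectory[length(det$trajectory)],
               suite$table$best_robot[1], tolerance = 1e-9)
})

test_that("optimized suite cells dominate the baselines", {
  scns <- equal_curve_scenarios()[c("5P 5R 7T", "6P 5R 12T e1")]
  suite <- run_suite(scns, budget = 40, seed = 3)
  for (i in seq_len(nrow(suite$table))) {
    expect_gte(suite$table$disjunctive[i],
               suite$table$best_robot[i] - 1e-9)
    expect_gte(suite$table$disjunctive[i],
               suite$table$switch_halfway[i] - 1e-9)
    expect_gte(suite$table$time_indexed[i],
               suite$table$switch_halfway[i] - 1e-9)
  }
})

test_that("random groups preserve the ordering property", {
  for (gseed in 1:3) {
    crv <- generate_group(group_spec(), 5, 5, seed = gseed)
    scn <- gym_scenario(5, 5, G = 7, curves = crv)
    res <- optimize_schedule(scn, budget = 40, seed = gseed + 10)
    expect_gte(res$value,
               total_gain(scn, best_robot_schedule(scn)) - 1e-9)
    expect_gte(res$value,
               total_gain(scn, switch_halfway_schedule(scn)) - 1e-9)
  }
})

test_that("scaling experiment collapses to known single-axis optima", {
  tab <- scaling_experiment("patients", 1, budget = 5, seed = 1)
  expect_equal(tab$gain,
               max_individual_gain(gym_scenario(1, 5, G = 5), 1),
               tolerance = 1e-9)
  tab_t <- scaling_experiment("time_steps", 1, budget = 5, seed = 1)
  expect_equal(tab_t$gain, 5 * eq_gain(1), tolerance = 1e-9)
  expect_true(all(c("axis", "value", "seconds", "gain") %in% names(tab)))
})
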