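# shared fixtures, all built in code

# equal-curve gain oracle: direct evaluation of the simplified hyperbola
# (written out independently of skill_gain)
eq_gain <- function(d, c2 = 1, c3 = 10) {
  100 * (c2 + 1 + d) / (c2 + 1 + d + c3) - 100 * (c2 + 1) / (c2 + 1 + c3)
}

scn_5p5r7 <- function() gym_scenario(5, 5, G = 7)
scn_5p5r12 <- function() gym_scenario(5, 5, G = 12)
scn_5p5r12e <- function() gym_scenario(5, rep(1, 5), G = 12)

# small random scenario with varied curves and exit times
random_scenario <- function(seed) {
  set.seed(seed)
  M <- sample(2:4, 1)
  N <- sample(2:4, 1)
  G <- sample(3:8, 1)
  ex <- sample(0:2, N, replace = TRUE)
  crv <- generate_group(group_spec(n_curves = 2L * M * N,
                                   c2_range = c(0.1, 50),
                                   c3_range = c(5, 200)),
                        M, N, seed = seed + 1000L)
  gym_scenario(M, ex, G = G, curves = crv)
}

# random feasible schedule: shuffled pairs, random placements, keep the
# blocks that validate
random_feasible_schedule <- function(scenario, seed) {
  set.seed(seed)
  pairs <- expand.grid(p = seq_len(scenario$M), r = seq_len(scenario$N))
  pairs <- pairs[sample.int(nrow(pairs)), ]
  acc <- data.frame(patient = integer(), robot = integer(),
                    start = integer(), end = integer())
  for (i in seq_len(nrow(pairs))) {
    if (stats::runif(1) < 0.3) next
    s <- sample.int(scenario$H, 1)
    d <- sample.int(scenario$G - s + 1L, 1)
    cand <- rbind(acc, data.frame(patient = pairs$p[i], robot = pairs$r[i],
                                  start = s, end = s + d - 1L))
    if (validate_schedule(scenario, schedule(cand))$feasible) acc <- cand
  }
  schedule(acc)
}

# random block set with at most one block per (patient, robot) pair; not
# necessarily feasible (bounds always respected, overlaps/gaps not)
random_block_set <- function(scenario, seed) {
  set.seed(seed)
  pairs <- expand.grid(p = seq_len(scenario$M), r = seq_len(scenario$N))
  keep <- stats::runif(nrow(pairs)) < 0.5
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty_schedule())
  s <- vapply(seq_len(nrow(pairs)), function(i) sample.int(scenario$H, 1),
              integer(1))
  d <- vapply(seq_len(nrow(pairs)), function(i)
    sample.int(scenario$G - s[i] + 1L, 1), integer(1))
  schedule(patient = pairs$p, robot = pairs$r, start = s, end = s + d - 1L)
}

# raw-variable builders that transcribe any block set (one block per pair)
# WITHOUT a feasibility gate, so the checkers can be exercised on
# infeasible inputs too
raw_time_indexed <- function(scenario, sched) {
  N <- scenario$N; M <- scenario$M; H <- scenario$H
  x <- array(0L, dim = c(N, M, H))
  d <- matrix(0L, N, M)
  s <- matrix(NA_integer_, N, M)
  for (i in seq_len(nrow(sched))) {
    b <- sched[i, ]
    x[b$robot, b$patient, b$start] <- 1L
    d[b$robot, b$patient] <- b$end - b$start + 1L
    s[b$robot, b$patient] <- b$start
  }
  structure(list(x = x, d = d, s = s, N = N, M = M, G = scenario$G, H = H),
            class = "gym_time_indexed")
}

raw_disjunctive <- function(scenario, sched) {
  N <- scenario$N; M <- scenario$M
  x <- matrix(0L, N, M); y <- matrix(0L, N, M); z <- matrix(0L, N, M)
  for (i in seq_len(nrow(sched))) {
    b <- sched[i, ]
    x[b$robot, b$patient] <- b$start
    y[b$robot, b$patient] <- b$end
    z[b$robot, b$patient] <- 1L
  }
  a <- array(0L, dim = c(N, M, M))
  for (r in seq_len(N)) for (pa in seq_len(M)) for (pb in seq_len(M))
    if (pa != pb && z[r, pa] == 1L && z[r, pb] == 1L && x[r, pa] < x[r, pb])
      a[r, pa, pb] <- 1L
  b <- array(0L, dim = c(N, N, M))
  for (p in seq_len(M)) for (ra in seq_len(N)) for (rb in seq_len(N))
    if (ra != rb && z[ra, p] == 1L && z[rb, p] == 1L && x[ra, p] < x[rb, p])
      b[ra, rb, p] <- 1L
  structure(list(x = x, y = y, z = z, a = a, b = b,
                 V = scenario$G + max(scenario$exit) + 1L,
                 N = N, M = M, G = scenario$G, H = scenario$H),
            class = "gym_disjunctive")
}
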