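# Checkable variable encodings of a schedule.
#
# The same feasible set is expressed two ways, mirroring the two classic
# scheduling formulations:
#  * time-indexed: a Boolean start indicator per (robot, patient, step <= H)
#    plus a nonnegative integer duration per (robot, patient);
#  * disjunctive: integer start/end per (robot, patient), Boolean activation,
#    and Boolean precedence indicators deactivated through a big multiplier V.
# Both carry a "+1" in the exit-gap inequalities: with inclusive interval
# ends, a successor on the same robot (or the same patient) may start no
# earlier than predecessor_end + exit + 1, which forbids same-step overlap
# even at exit time 0. Encoding then decoding reproduces the schedule, and
# the disjunctive objective (gain at duration 1 + y - x) equals total_gain.

#' Encode a feasible schedule in time-indexed variables
#'
#' @param scenario A [gym_scenario()].
#' @param sched A feasible [schedule()].
#' @return An object of class `gym_time_indexed` with `x` (N x M x H 0/1
#'   start indicators), `d` (N x M integer durations) and `s` (N x M start
#'   steps, `NA` where a pair is unused).
#' @seealso [decode_time_indexed()], [check_time_indexed()]
#' @export
encode_time_indexed <- function(scenario, sched) {
  sched <- schedule(sched)
  assert_feasible(scenario, sched)
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

#' @rdname encode_time_indexed
#' @param vars A `gym_time_indexed` object.
#' @export
decode_time_indexed <- function(scenario, vars) {
  stopifnot(inherits(vars, "gym_time_indexed"))
  idx <- which(!is.na(vars$s), arr.ind = TRUE)
  if (!nrow(idx)) return(empty_schedule())
  st <- vars$s[idx]
  schedule(patient = idx[, 2], robot = idx[, 1], start = st,
           end = st + vars$d[idx] - 1L)
}

#' Check time-indexed variables against the scheduling constraints
#'
#' Verifies, on the raw variables: at most one start per robot per step and
#' per patient per step; no training past step G; durations positive exactly
#' where a start indicator is set; at most one start per (robot, patient)
#' pair; and the interval no-overlap / exit-gap conditions for blocks sharing
#' a robot or a patient.
#'
#' @param scenario A [gym_scenario()].
#' @param vars A `gym_time_indexed` object.
#' @return List with `ok` (flag) and `violations` (character vector).
#' @export
check_time_indexed <- function(scenario, vars) {
  stopifnot(inherits(vars, "gym_time_indexed"))
  v <- character()
  N <- vars$N; M <- vars$M; G <- vars$G; H <- vars$H
  for (r in seq_len(N)) for (t in seq_len(H))
    if (sum(vars$x[r, , t]) > 1L)
      v <- c(v, sprintf("robot %d: multiple starts at step %d", r, t))
  for (p in seq_len(M)) for (t in seq_len(H))
    if (sum(vars$x[, p, t]) > 1L)
      v <- c(v, sprintf("patient %d: multiple starts at step %d", p, t))
  for (r in seq_len(N)) for (p in seq_len(M)) {
    started <- sum(vars$x[r, p, ])
    if (started > 1L)
      v <- c(v, sprintf("pair (r%d,p%d): more than one start", r, p))
    if (started == 0L && vars$d[r, p] > 0L)
      v <- c(v, sprintf("pair (r%d,p%d): duration without a start", r, p))
    if (started == 1L) {
      if (vars$d[r, p] < 1L)
        v <- c(v, sprintf("pair (r%d,p%d): start without duration", r, p))
      st <- which(vars$x[r, p, ] == 1L)[1]
      if (st + vars$d[r, p] - 1L > G)
        v <- c(v, sprintf("pair (r%d,p%d): trains past step G", r, p))
    }
  }
  # interval semantics (overlap and exit gaps) via the decoded blocks
  sched <- decode_time_indexed(scenario, vars)
  rep <- validate_schedule(scenario, sched)
  if (!rep$feasible)
    v <- c(v, paste(rep$violations$tag, rep$violations$detail))
  list(ok = length(v) == 0L, violations = v)
}

#' Encode a feasible schedule in disjunctive variables
#'
#' @param scenario A [gym_scenario()].
#' @param sched A feasible [schedule()].
#' @return An object of class `gym_disjunctive` with `x`/`y` (N x M integer
#'   start/end steps, 0 where inactive), `z` (N x M 0/1 activation), `a`
#'   (N x M x M patient-precedence indicators on each robot), `b`
#'   (N x N x M robot-precedence indicators for each patient) and the big
#'   multiplier `V = G + max(exit) + 1`, the smallest value that deactivates
#'   a disjunct over the variable ranges.
#' @seealso [decode_disjunctive()], [check_disjunctive()],
#'   [disjunctive_objective()]
#' @export
encode_disjunctive <- function(scenario, sched) {
  sched <- schedule(sched)
  assert_feasible(scenario, sched)
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
    if (pa != pb && z[r, pa] == 1L && z[r, pb] == 1L &&
        x[r, pa] < x[r, pb])
      a[r, pa, pb] <- 1L
  b <- array(0L, dim = c(N, N, M))
  for (p in seq_len(M)) for (ra in seq_len(N)) for (rb in seq_len(N))
    if (ra != rb && z[ra, p] == 1L && z[rb, p] == 1L &&
        x[ra, p] < x[rb, p])
      b[ra, rb, p] <- 1L
  structure(list(x = x, y = y, z = z, a = a, b = b,
                 V = scenario$G + max(scenario$exit) + 1L,
                 N = N, M = M, G = scenario$G, H = scenario$H),
            class = "gym_disjunctive")
}

#' @rdname encode_disjunctive
#' @param vars A `gym_disjunctive` object.
#' @export
decode_disjunctive <- function(scenario, vars) {
  stopifnot(inherits(vars, "gym_disjunctive"))
  idx <- which(vars$z == 1L, arr.ind = TRUE)
  if (!nrow(idx)) return(empty_schedule())
  schedule(patient = idx[, 2], robot = idx[, 1],
           start = vars$x[idx], end = vars$y[idx])
}

#' Check disjunctive variables against the scheduling constraints
#'
#' Verifies, on the raw variables: `1 <= x <= y <= G` and `x <= H` for every
#' active pair, and the four families of big-V disjunctive inequalities (two
#' patients on one robot; one patient on two robots), each requiring the
#' successor to start at predecessor end + exit + 1 or later when the
#' corresponding precedence indicator selects it.
#'
#' @param scenario A [gym_scenario()].
#' @param vars A `gym_disjunctive` object.
#' @return List with `ok` (flag) and `violations` (character vector).
#' @export
check_disjunctive <- function(scenario, vars) {
  stopifnot(inherits(vars, "gym_disjunctive"))
  v <- character()
  N <- vars$N; M <- vars$M; G <- vars$G; V <- vars$V
  e <- scenario$exit
  for (r in seq_len(N)) for (p in seq_len(M)) if (vars$z[r, p] == 1L) {
    if (vars$x[r, p] < 1L || vars$x[r, p] > vars$y[r, p] || vars$y[r, p] > G)
      v <- c(v, sprintf("pair (r%d,p%d): start/end outside 1..G", r, p))
    if (vars$x[r, p] > vars$H)
      v <- c(v, sprintf("pair (r%d,p%d): starts after H", r, p))
  }
  for (r in seq_len(N)) for (pa in seq_len(M)) for (pb in seq_len(M)) {
    if (pa == pb || vars$z[r, pa] == 0L || vars$z[r, pb] == 0L) next
    lhs1 <- vars$x[r, pa] - (vars$y[r, pb] + e[r] + 1L - V * vars$a[r, pa, pb])
    if (lhs1 < 0L)
      v <- c(v, sprintf("robot %d: patients %d,%d violate exit disjunct",
                        r, pa, pb))
  }
  for (p in seq_len(M)) for (ra in seq_len(N)) for (rb in seq_len(N)) {
    if (ra == rb || vars$z[ra, p] == 0L || vars$z[rb, p] == 0L) next
    lhs1 <- vars$x[ra, p] - (vars$y[rb, p] + e[rb] + 1L - V * vars$b[ra, rb, p])
    if (lhs1 < 0L)
      v <- c(v, sprintf("patient %d: robots %d,%d violate exit disjunct",
                        p, ra, rb))
  }
  # precedence indicators must be consistent (exactly one direction active)
  for (r in seq_len(N)) for (pa in seq_len(M)) for (pb in seq_len(M))
    if (pa < pb && vars$z[r, pa] == 1L && vars$z[r, pb] == 1L &&
        vars$a[r, pa, pb] + vars$a[r, pb, pa] != 1L)
      v <- c(v, sprintf("robot %d: inconsistent precedence for %d,%d",
                        r, pa, pb))
  list(ok = length(v) == 0L, violations = v)
}

#' Objective value computed from disjunctive variables
#'
#' Sums, over active pairs, the curve gain at duration `1 + y - x`. For any
#' feasible schedule this equals [total_gain()] of the decoded schedule (the
#' two formulations share one objective).
#'
#' @param scenario A [gym_scenario()].
#' @param vars A `gym_disjunctive` object.
#' @return Total gain in skill units.
#' @export
disjunctive_objective <- function(scenario, vars) {
  stopifnot(inherits(vars, "gym_disjunctive"))
  idx <- which(vars$z == 1L, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  sum(pair_gain(scenario, idx[, 2], idx[, 1],
                1L + vars$y[idx] - vars$x[idx]))
}
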