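#' Define a rehabilitation gym scenario
#'
#' A scenario is M patients sharing N single-skill robots over a session of G
#' discrete time steps. Each robot trains exactly one skill (N = K), carries a
#' nonnegative integer exit time, and each (patient, robot) pair has its own
#' hyperbolic [skill_curve()]. `H` is the last step at which a training block
#' may start (the study keeps `H = G`).
#'
#' @param patients Number of patients M (>= 1).
#' @param robots One of: an integer N (robots with exit time 0), a numeric
#'   vector of per-robot exit times, or a data.frame with columns `id` and
#'   `exit_time` (optional `skill_id`, defaults to the robot index).
#' @param G Session horizon in time steps (>= 1).
#' @param H Last allowed start step, `1 <= H <= G`. Default `G`.
#' @param curves `"equal"` for the equal-curves preset (c1=100, c2=1, c3=10,
#'   c4=1, u=1 for every pair), a single [skill_curve()] recycled to all
#'   pairs, a list of M x N parameter matrices named c1, c2, c3, c4, u (the
#'   format produced by [generate_group()]), or an M x N list-matrix of
#'   [skill_curve()] objects. Row = patient, column = robot.
#'
#' @return An object of class `gym_scenario` with elements `M`, `N`, `G`,
#'   `H`, `robots` (data.frame), `exit` (numeric length N) and `curves` (list
#'   of five M x N matrices).
#' @examples
#' scn <- gym_scenario(5, 5, G = 7)
#' scn
#' @export
gym_scenario <- function(patients, robots, G, H = G, curves = "equal") {
  M <- patients
  if (!is.numeric(M) || length(M) != 1L || M != floor(M) || M < 1)
    stop("patients must be a positive integer", call. = FALSE)
  M <- as.integer(M)

  if (is.data.frame(robots)) {
    rb <- robots
    if (is.null(rb$id)) rb$id <- seq_len(nrow(rb))
    if (is.null(rb$exit_time)) rb$exit_time <- 0L
    if (is.null(rb$skill_id)) rb$skill_id <- rb$id
  } else if (is.numeric(robots) && length(robots) == 1L &&
             robots == floor(robots)) {
    rb <- data.frame(id = seq_len(robots), exit_time = 0L,
                     skill_id = seq_len(robots))
  } else if (is.numeric(robots)) {
    rb <- data.frame(id = seq_along(robots), exit_time = robots,
                     skill_id = seq_along(robots))
  } else stop("robots must be a count, an exit-time vector or a data.frame",
              call. = FALSE)
  N <- nrow(rb)
  if (N < 1) stop("at least one robot is required", call. = FALSE)
  if (any(rb$exit_time < 0) || any(rb$exit_time != floor(rb$exit_time)))
    stop("robot exit times must be nonnegative integers", call. = FALSE)
  if (anyDuplicated(rb$skill_id))
    stop("each robot must train a distinct skill (skill_id unique)",
         call. = FALSE)
  rb$exit_time <- as.integer(rb$exit_time)

  if (!is.numeric(G) || length(G) != 1L || G != floor(G) || G < 1)
    stop("G must be a positive integer", call. = FALSE)
  if (!is.numeric(H) || length(H) != 1L || H != floor(H) || H < 1 || H > G)
    stop("H must be an integer with 1 <= H <= G", call. = FALSE)

  cm <- build_curve_matrices(curves, M, N)

  structure(list(M = M, N = N, G = as.integer(G), H = as.integer(H),
                 robots = rb, exit = rb$exit_time, curves = cm),
            class = "gym_scenario")
}

build_curve_matrices <- function(curves, M, N) {
  mk <- function(v) matrix(v, nrow = M, ncol = N)
  if (is.character(curves) && length(curves) == 1L) {
    if (curves != "equal")
      stop("unknown curve preset '", curves, "' (only \"equal\")",
           call. = FALSE)
    crv <- skill_curve()
    return(lapply(crv, mk))
  }
  if (inherits(curves, "skill_curve")) return(lapply(curves, mk))
  if (is.list(curves) && all(c("c1", "c2", "c3", "c4", "u") %in% names(curves))) {
    cm <- lapply(curves[c("c1", "c2", "c3", "c4", "u")], function(x) {
      x <- as.matrix(x)
      if (!all(dim(x) == c(M, N)) && length(x) == 1L) x <- mk(x[1])
      if (!all(dim(x) == c(M, N)))
        stop("curve parameter matrices must be M x N", call. = FALSE)
      x
    })
    # validate every pair through the constructor
    for (p in seq_len(M)) for (r in seq_len(N))
      skill_curve(cm$c1[p, r], cm$c2[p, r], cm$c3[p, r], cm$c4[p, r],
                  cm$u[p, r])
    return(cm)
  }
  if (is.matrix(curves) && is.list(curves)) {
    if (!all(dim(curves) == c(M, N)))
      stop("curve list-matrix must be M x N", call. = FALSE)
    cm <- lapply(c("c1", "c2", "c3", "c4", "u"), function(nm)
      mk(vapply(seq_along(curves),
                function(i) as_skill_curve(curves[[i]])[[nm]], numeric(1))))
    names(cm) <- c("c1", "c2", "c3", "c4", "u")
    return(cm)
  }
  stop("cannot interpret 'curves'", call. = FALSE)
}

#' @export
print.gym_scenario <- function(x, ...) {
  cat(sprintf("<gym_scenario> %d patients, %d robots, G=%d, H=%d\n",
              x$M, x$N, x$G, x$H))
  cat("  exit times:", paste(x$exit, collapse = " "), "\n")
  eq <- all(vapply(x$curves, function(m) length(unique(c(m))) == 1L, logical(1)))
  cat("  curves:", if (eq) sprintf(
    "identical for all pairs (c1=%g c2=%g c3=%g c4=%g u=%g)",
    x$curves$c1[1], x$curves$c2[1], x$curves$c3[1], x$curves$c4[1],
    x$curves$u[1]) else "per-pair matrix", "\n")
  invisible(x)
}

#' Extract the skill curve of one patient-robot pair
#'
#' @param scenario A [gym_scenario()].
#' @param patient,robot 1-based indices.
#' @return A [skill_curve()].
#' @export
curve_at <- function(scenario, patient, robot) {
  stopifnot(inherits(scenario, "gym_scenario"))
  cm <- scenario$curves
  skill_curve(cm$c1[patient, robot], cm$c2[patient, robot],
              cm$c3[patient, robot], cm$c4[patient, robot],
              cm$u[patient, robot])
}

# gain for pair (p, r) after d steps, vectorised over p/r/d of equal length
pair_gain <- function(scenario, p, r, d) {
  cm <- scenario$curves
  i <- cbind(p, r)
  c1 <- cm$c1[i]; c2 <- cm$c2[i]; c3 <- cm$c3[i]; c4 <- cm$c4[i]
  u <- cm$u[i]
  skill_value_raw(c1, c2, c3, c4, u, d) - skill_value_raw(c1, c2, c3, c4, u, 0)
}

#' Build a schedule from training blocks
#'
#' A schedule is a set of training blocks, each assigning one patient to one
#' robot for an inclusive 1-based interval `[start, end]` of time steps.
#' Blocks are stored canonically ordered by (patient, start).
#'
#' @param patient,robot,start,end Equal-length vectors describing the blocks.
#'   May also be given as a single data.frame in `patient`.
#' @return An object of class `gym_schedule`: a data.frame with columns
#'   `patient`, `robot`, `start`, `end`.
#' @examples
#' schedule(patient = 1:2, robot = c(1, 2), start = 1, end = 7)
#' empty_schedule()
#' @export
schedule <- function(patient = integer(), robot = integer(),
                     start = integer(), end = integer()) {
  if (is.data.frame(patient)) {
    df <- patient
    if (!all(c("patient", "robot", "start", "end") %in% names(df)))
      stop("schedule data.frame needs columns patient, robot, start, end",
           call. = FALSE)
    df <- df[c("patient", "robot", "start", "end")]
  } else {
    df <- data.frame(patient = patient, robot = robot,
                     start = start, end = end)
  }
  for (cl in names(df)) {
    if (nrow(df) && (any(!is.finite(df[[cl]])) || any(df[[cl]] != floor(df[[cl]]))))
      stop("schedule column '", cl, "' must be whole numbers", call. = FALSE)
    df[[cl]] <- as.integer(df[[cl]])
  }
  df <- df[order(df$patient, df$start, df$robot), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gym_schedule", "data.frame")
  df
}

#' @rdname schedule
#' @export
empty_schedule <- function() schedule()

#' @export
print.gym_schedule <- function(x, ...) {
  cat(sprintf("<gym_schedule> %d block(s), 1-based inclusive steps\n", nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

block_duration <- function(sched) sched$end - sched$start + 1L

#' Check a schedule against the gym's feasibility constraints
#'
#' Verifies every constraint of the scheduling model: interval bounds within
#' `[1, G]`, starts no later than `H`, at most one block per (patient, robot)
#' pair, no overlap of blocks sharing a robot or a patient, and exit-time
#' gaps: after a block on robot r ends at step y, neither that robot nor that
#' patient may start a new block before step `y + exit_time(r) + 1`.
#'
#' @param scenario A [gym_scenario()].
#' @param sched A [schedule()]. Blocks referencing patients or robots outside
#'   the scenario raise an error (a structural problem, not an infeasibility).
#' @return A list of class `gym_feasibility` with `feasible` (flag) and
#'   `violations`, a data.frame with columns `tag` (one of `bounds`,
#'   `last_start`, `duplicate_pair`, `robot_overlap`, `patient_overlap`,
#'   `robot_exit_gap`, `patient_exit_gap`) and `detail`.
#' @export
validate_schedule <- function(scenario, sched) {
  stopifnot(inherits(scenario, "gym_scenario"))
  sched <- schedule(sched)
  if (nrow(sched) &&
      (any(sched$patient < 1L) || any(sched$patient > scenario$M) ||
       any(sched$robot < 1L) || any(sched$robot > scenario$N)))
    stop("schedule references a patient or robot outside the scenario",
         call. = FALSE)

  tags <- character(); details <- character()
  note <- function(tag, detail) {
    tags <<- c(tags, tag); details <<- c(details, detail)
  }
  blk_str <- function(b)
    sprintf("p%d/r%d[%d-%d]", b$patient, b$robot, b$start, b$end)

  for (i in seq_len(nrow(sched))) {
    b <- sched[i, ]
    if (b$start < 1L || b$end > scenario$G || b$start > b$end)
      note("bounds", blk_str(b))
    if (b$start > scenario$H) note("last_start", blk_str(b))
  }
  dup <- duplicated(sched[c("patient", "robot")])
  for (i in which(dup)) note("duplicate_pair", blk_str(sched[i, ]))

  check_line <- function(rows, over_tag, gap_tag, exit_of) {
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) < 2L) return(invisible())
    for (k in seq_len(nrow(rows) - 1L)) {
      a <- rows[k, ]; b <- rows[k + 1L, ]
      pair <- paste(blk_str(a), blk_str(b))
      if (b$start <= a$end) note(over_tag, pair)
      else if (b$start < a$end + exit_of(a) + 1L) note(gap_tag, pair)
    }
  }
  for (r in unique(sched$robot))
    check_line(sched[sched$robot == r, ], "robot_overlap", "robot_exit_gap",
               function(a) scenario$exit[a$robot])
  for (p in unique(sched$patient))
    check_line(sched[sched$patient == p, ], "patient_overlap",
               "patient_exit_gap", function(a) scenario$exit[a$robot])

  structure(list(feasible = length(tags) == 0L,
                 violations = data.frame(tag = tags, detail = details)),
            class = "gym_feasibility")
}

#' @export
print.gym_feasibility <- function(x, ...) {
  if (x$feasible) cat("<gym_feasibility> feasible\n")
  else {
    cat(sprintf("<gym_feasibility> INFEASIBLE (%d violation(s))\n",
                nrow(x$violations)))
    print.data.frame(x$violations)
  }
  invisible(x)
}

assert_feasible <- function(scenario, sched) {
  rep <- validate_schedule(scenario, sched)
  if (!rep$feasible) {
    msg <- paste0("schedule is infeasible: ",
                  paste(rep$violations$tag, rep$violations$detail,
                        collapse = "; "))
    cond <- structure(class = c("gym_infeasible", "error", "condition"),
                      list(message = msg, call = sys.call(-1), report = rep))
    stop(cond)
  }
  invisible(rep)
}

#' Total group skill gain of a schedule
#'
#' Sum over all training blocks of the block's curve gain at the block's
#' duration. Identical under the time-indexed and disjunctive encodings
#' (duration is `end - start + 1` either way).
#'
#' @param scenario A [gym_scenario()].
#' @param sched A feasible [schedule()]; infeasible schedules are rejected
#'   with their feasibility report attached to the error.
#' @param check Set `FALSE` to skip revalidation (internal hot paths).
#' @return Total gain in skill units.
#' @export
total_gain <- function(scenario, sched, check = TRUE) {
  sched <- schedule(sched)
  if (check) assert_feasible(scenario, sched)
  if (!nrow(sched)) return(0)
  sum(pair_gain(scenario, sched$patient, sched$robot, block_duration(sched)))
}

#' Per-patient skill gains
#'
#' @inheritParams total_gain
#' @return Numeric vector of length M; entry j is patient j's summed gain
#'   (0 for unassigned patients). Sums to [total_gain()].
#' @export
per_patient_gains <- function(scenario, sched, check = TRUE) {
  sched <- schedule(sched)
  if (check) assert_feasible(scenario, sched)
  out <- numeric(scenario$M)
  if (!nrow(sched)) return(out)
  g <- pair_gain(scenario, sched$patient, sched$robot, block_duration(sched))
  for (i in seq_along(g)) out[sched$patient[i]] <- out[sched$patient[i]] + g[i]
  out
}

#' Cumulative group gain trajectory
#'
#' Group gain accrued by the end of each time step: at step t each block
#' contributes its curve's gain at `min(max(t - start + 1, 0), duration)`
#' steps. Nondecreasing; the final entry equals [total_gain()]. By
#' convention the trajectory starts after the first step (gain at "t = 0"
#' is 0 and is not part of the vector).
#'
#' @inheritParams total_gain
#' @return Numeric vector of length G.
#' @export
gain_trajectory <- function(scenario, sched, check = TRUE) {
  sched <- schedule(sched)
  if (check) assert_feasible(scenario, sched)
  out <- numeric(scenario$G)
  if (!nrow(sched)) return(out)
  dur <- block_duration(sched)
  for (t in seq_len(scenario$G)) {
    d <- pmin(pmax(t - sched$start + 1L, 0L), dur)
    out[t] <- sum(pair_gain(scenario, sched$patient, sched$robot, d))
  }
  out
}

#' Group objectives for schedule optimization
#'
#' Three ways to score a feasible schedule:
#' * `objective_total()`: total skill gain across patients (the default goal).
#' * `objective_variance_penalized(m)`: total gain minus `m` times the
#'   variance of per-patient gains, encouraging even improvement across the
#'   group. The variance is the population variance (divide by M) by default;
#'   set `var_type = "sample"` for the n-1 divisor.
#' * `objective_relative_to_max(m_p, max_gains)`: `sum_j [g_j - m_p[j] *
#'   (1 - g_j / max_gains[j])]`, scoring each patient's gain relative to the
#'   most that patient could gain alone in the gym. `max_gains` defaults to
#'   [max_individual_gain()] computed per patient when the objective is
#'   evaluated.
#'
#' @param m Nonnegative variance penalty coefficient.
#' @param m_p Nonnegative per-patient penalty coefficients (length M or 1).
#' @param max_gains Optional per-patient maximum attainable gains; computed
#'   from the scenario when omitted.
#' @param var_type `"population"` (default) or `"sample"`.
#' @return An object of class `gym_objective`.
#' @export
objective_total <- function() {
  structure(list(kind = "total"), class = "gym_objective")
}

#' @rdname objective_total
#' @export
objective_variance_penalized <- function(m, var_type = c("population", "sample")) {
  stopifnot(is.numeric(m), length(m) == 1L, m >= 0)
  structure(list(kind = "variance_penalized", m = m,
                 var_type = match.arg(var_type)),
            class = "gym_objective")
}

#' @rdname objective_total
#' @export
objective_relative_to_max <- function(m_p, max_gains = NULL) {
  stopifnot(is.numeric(m_p), all(m_p >= 0))
  structure(list(kind = "relative_to_max", m_p = m_p, max_gains = max_gains),
            class = "gym_objective")
}

# fill in per-patient maxima once so repeated evaluations are cheap
resolve_objective <- function(scenario, objective) {
  if (is.null(objective)) return(objective_total())
  stopifnot(inherits(objective, "gym_objective"))
  if (objective$kind == "relative_to_max") {
    if (is.null(objective$max_gains))
      objective$max_gains <- vapply(seq_len(scenario$M), function(p)
        max_individual_gain(scenario, p), numeric(1))
    m_p <- rep_len(objective$m_p, scenario$M)
    if (any(objective$max_gains == 0 & m_p > 0))
      stop("relative_to_max objective: patient with zero maximum gain but ",
           "positive penalty coefficient", call. = FALSE)
    objective$m_p <- m_p
  }
  objective
}

#' Evaluate a group objective on a schedule
#'
#' @inheritParams total_gain
#' @param objective A `gym_objective` from [objective_total()] and friends.
#' @return Objective value (skill units for `total`; objective units
#'   otherwise).
#' @export
objective_value <- function(scenario, sched, objective = objective_total(),
                            check = TRUE) {
  objective <- resolve_objective(scenario, objective)
  sched <- schedule(sched)
  if (check) assert_feasible(scenario, sched)
  g <- per_patient_gains(scenario, sched, check = FALSE)
  switch(objective$kind,
    total = sum(g),
    variance_penalized = {
      v <- if (identical(objective$var_type, "sample") && scenario$M > 1L)
        stats::var(g)
      else mean((g - mean(g))^2)
      sum(g) - objective$m * v
    },
    relative_to_max = {
      mx <- objective$max_gains
      pen <- ifelse(mx > 0, objective$m_p * (1 - g / mx), 0)
      sum(g - pen)
    },
    stop("unknown objective kind", call. = FALSE))
}
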