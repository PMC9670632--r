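#' Specification of a random patient group
#'
#' Describes a pool of randomly drawn skill curves from which a patient
#' group's M x N curve matrix is filled. Curve shape parameters `c2` and
#' `c3` are sampled within their ranges (log-uniformly by default, since
#' both ranges span several decades); `c1`, `c4` and `u` are held fixed.
#'
#' @param n_curves Pool size (default 42).
#' @param c2_range,c3_range Two-element ranges, `0 < low < high`. Defaults
#'   `c(0.01, 100)` and `c(5, 1000)`.
#' @param c1,c4,u Fixed parameters of every curve (defaults 100, 1, 1).
#' @param sampling `"log_uniform"` (default) or `"uniform"`.
#' @return An object of class `gym_group_spec`.
#' @seealso [generate_group()]
#' @export
group_spec <- function(n_curves = 42L, c2_range = c(0.01, 100),
                       c3_range = c(5, 1000), c1 = 100, c4 = 1, u = 1,
                       sampling = c("log_uniform", "uniform")) {
  stopifnot(n_curves >= 1, length(c2_range) == 2L, length(c3_range) == 2L,
            all(c2_range > 0), all(c3_range > 0),
            c2_range[1] <= c2_range[2], c3_range[1] <= c3_range[2])
  structure(list(n_curves = as.integer(n_curves), c2_range = c2_range,
                 c3_range = c3_range, c1 = c1, c4 = c4, u = u,
                 sampling = match.arg(sampling)),
            class = "gym_group_spec")
}

#' Draw a random curve matrix for a patient group
#'
#' Draws `n_curves` skill curves with `c2` and `c3` sampled within the
#' spec's ranges, then assigns `M * N` of them to patient-robot pairs
#' without replacement. Deterministic for a given seed.
#'
#' @param spec A [group_spec()].
#' @param M,N Numbers of patients and robots; requires `n_curves >= M * N`.
#' @param seed Integer seed.
#' @return A list of five M x N parameter matrices (`c1`, `c2`, `c3`, `c4`,
#'   `u`), directly usable as the `curves` argument of [gym_scenario()].
#' @export
generate_group <- function(spec, M, N, seed = 1L) {
  stopifnot(inherits(spec, "gym_group_spec"))
  if (spec$n_curves < M * N)
    stop("curve pool too small: n_curves = ", spec$n_curves, " < M*N = ",
         M * N, call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  draw <- function(rng) {
    if (spec$sampling == "log_uniform")
      exp(stats::runif(spec$n_curves, log(rng[1]), log(rng[2])))
    else stats::runif(spec$n_curves, rng[1], rng[2])
  }
  c2 <- draw(spec$c2_range)
  c3 <- draw(spec$c3_range)
  take <- sample.int(spec$n_curves, M * N)
  mk <- function(v) matrix(v, nrow = M, ncol = N)
  list(c1 = mk(spec$c1), c2 = mk(c2[take]), c3 = mk(c3[take]),
       c4 = mk(spec$c4), u = mk(spec$u))
}

#' The nine equal-curve evaluation scenarios
#'
#' Three gym sizes (5 patients/5 robots, 6/5, 5/7) crossed with three time
#' variants (7 steps no exit time, 12 steps no exit time, 12 steps with
#' 1-step exit time), all with the equal-curves preset.
#'
#' @return A named list of nine [gym_scenario()] objects, in the standard
#'   reporting order.
#' @export
equal_curve_scenarios <- function() {
  sizes <- list(c(5L, 5L), c(6L, 5L), c(5L, 7L))
  variants <- list(list(G = 7L, e = 0L, lab = "7T"),
                   list(G = 12L, e = 0L, lab = "12T"),
                   list(G = 12L, e = 1L, lab = "12T e1"))
  out <- list()
  for (sz in sizes) for (vr in variants) {
    nm <- sprintf("%dP %dR %s", sz[1], sz[2], vr$lab)
    out[[nm]] <- gym_scenario(sz[1], rep(vr$e, sz[2]), G = vr$G)
  }
  out
}

#' Run a suite of scenarios under several schedule types
#'
#' Evaluates each (scenario, schedule type) cell and collects total gains,
#' per-patient gains, trajectories and optimizer metadata. Baseline types
#' are deterministic; optimizer types run [optimize_schedule()] with the
#' given budget and a per-cell seed derived from `seed`, so optimized cells
#' are never below the baselines of the same row.
#'
#' @param scenarios Named list of [gym_scenario()] objects (default the nine
#'   equal-curve scenarios).
#' @param schedule_types Subset of `best_robot`, `switch_halfway`,
#'   `disjunctive`, `time_indexed` (the latter two are optimizer runs on the
#'   corresponding encoding).
#' @param budget Optimizer iteration budget per cell.
#' @param seed Base integer seed.
#' @param objective A `gym_objective` for the optimizer cells.
#' @return An object of class `gym_suite`: `table` (data.frame, one row per
#'   scenario, one column per schedule type) and `details` (per-cell list of
#'   schedule, per-patient gains, trajectory, optimizer metadata).
#' @examples
#' \donttest{
#' suite <- run_suite(budget = 50, seed = 1)
#' suite$table
#' }
#' @export
run_suite <- function(scenarios = equal_curve_scenarios(),
                      schedule_types = c("disjunctive", "time_indexed",
                                         "best_robot", "switch_halfway"),
                      budget = 300L, seed = 1L,
                      objective = objective_total()) {
  schedule_types <- match.arg(schedule_types, several.ok = TRUE)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste("scenario", seq_along(scenarios))
  tab <- data.frame(scenario = names(scenarios))
  details <- list()
  cell <- 0L
  for (ty in schedule_types) tab[[ty]] <- NA_real_
  for (si in seq_along(scenarios)) {
    scn <- scenarios[[si]]
    for (ty in schedule_types) {
      cell <- cell + 1L
      meta <- NULL
      if (ty == "best_robot") sch <- best_robot_schedule(scn)
      else if (ty == "switch_halfway") sch <- switch_halfway_schedule(scn)
      else {
        res <- optimize_schedule(scn, objective = objective, method = ty,
                                 budget = budget,
                                 seed = (seed + 131L * cell) %% .Machine$integer.max)
        sch <- res$schedule
        meta <- list(budget = budget, seed = res$seed,
                     iterations_used = res$iterations_used,
                     bound = res$bound,
                     improvement_log = res$improvement_log)
      }
      stopifnot(validate_schedule(scn, sch)$feasible)
      tab[[ty]][si] <- total_gain(scn, sch, check = FALSE)
      details[[paste(names(scenarios)[si], ty, sep = " | ")]] <-
        list(scenario = names(scenarios)[si], type = ty, schedule = sch,
             per_patient = per_patient_gains(scn, sch, check = FALSE),
             trajectory = gain_trajectory(scn, sch, check = FALSE),
             optimizer = meta)
    }
  }
  structure(list(table = tab, details = details, budget = budget,
                 seed = seed),
            class = "gym_suite")
}

#' @export
print.gym_suite <- function(x, ...) {
  cat("<gym_suite> total skill gain by scenario and schedule type\n")
  tab <- x$table
  for (cl in setdiff(names(tab), "scenario")) tab[[cl]] <- round(tab[[cl]], 1)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Scaling experiment: optimization effort versus problem size
#'
#' Re-runs the optimizer while growing one axis of the problem (time steps,
#' patients or robots) and records the wall-clock duration and achieved
#' gain. Durations are informational only (they depend on hardware); the
#' achieved gain is the substantive output.
#'
#' @param axis One of `"time_steps"`, `"patients"`, `"robots"`.
#' @param values Positive integers to sweep over.
#' @param base Named list giving the fixed dimensions: `patients`, `robots`,
#'   `G`, `exit` (scalar exit time). Defaults to the 5-patient, 5-robot,
#'   5-step equal-curve gym.
#' @param budget,seed,method Passed to [optimize_schedule()].
#' @return data.frame with columns `axis`, `value`, `seconds`, `gain`.
#' @export
scaling_experiment <- function(axis = c("time_steps", "patients", "robots"),
                               values,
                               base = list(patients = 5L, robots = 5L,
                                           G = 5L, exit = 0L),
                               budget = 100L, seed = 1L,
                               method = "disjunctive") {
  axis <- match.arg(axis)
  stopifnot(is.numeric(values), all(values >= 1),
            all(values == floor(values)))
  out <- data.frame(axis = character(), value = integer(),
                    seconds = numeric(), gain = numeric())
  for (v in as.integer(values)) {
    dims <- base
    if (axis == "time_steps") dims$G <- v
    if (axis == "patients") dims$patients <- v
    if (axis == "robots") dims$robots <- v
    scn <- gym_scenario(dims$patients, rep(dims$exit, dims$robots),
                        G = dims$G)
    secs <- system.time(
      res <- optimize_schedule(scn, method = method, budget = budget,
                               seed = seed))[["elapsed"]]
    out <- rbind(out, data.frame(axis = axis, value = v, seconds = secs,
                                 gain = res$value))
  }
  out
}
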