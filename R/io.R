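#' Read a gym scenario from a configuration file
#'
#' Accepts YAML or JSON with fields `patients`, `robots` (a count or a list
#' of records with `id` and `exit_time`), `G`, optional `H` (defaults to G),
#' and `curves`: either the string `"equal"`, a mapping of the five
#' parameter matrices (`c1`..`u`, each a list of per-patient rows), or a
#' `group` mapping (`n_curves`, `c2_range`, `c3_range`, `seed`, optional
#' `sampling`) from which a random group is generated.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return A [gym_scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$patients) || is.null(cfg$robots) || is.null(cfg$G))
    stop("scenario config needs fields patients, robots, G", call. = FALSE)

  robots <- cfg$robots
  if (is.list(robots) && !is.data.frame(robots))
    robots <- do.call(rbind, lapply(robots, function(r)
      data.frame(id = r$id, exit_time = r$exit_time %||% 0L)))

  curves <- cfg$curves %||% "equal"
  if (is.list(curves) && !is.null(curves$group)) {
    g <- curves$group
    spec <- group_spec(n_curves = g$n_curves %||% 42L,
                       c2_range = unlist(g$c2_range %||% c(0.01, 100)),
                       c3_range = unlist(g$c3_range %||% c(5, 1000)),
                       sampling = g$sampling %||% "log_uniform")
    N <- if (is.data.frame(robots)) nrow(robots) else
      if (length(robots) == 1L) robots else length(robots)
    curves <- generate_group(spec, cfg$patients, N, seed = g$seed %||% 1L)
  } else if (is.list(curves) && !is.null(curves$c1)) {
    curves <- lapply(curves[c("c1", "c2", "c3", "c4", "u")], function(m)
      if (is.list(m)) do.call(rbind, m) else m)
  }
  gym_scenario(cfg$patients, robots, G = cfg$G, H = cfg$H %||% cfg$G,
               curves = curves)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read schedules as CSV
#'
#' The CSV has columns `patient`, `robot`, `start`, `end`; steps are 1-based
#' and intervals inclusive (stated in a comment header line).
#'
#' @param sched A [schedule()].
#' @param path Output file path.
#' @return `write_schedule_csv` returns `path` invisibly;
#'   `read_schedule_csv` returns a [schedule()].
#' @export
write_schedule_csv <- function(sched, path) {
  sched <- schedule(sched)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_base: 1-based inclusive steps", con)
  utils::write.csv(as.data.frame(sched), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  schedule(utils::read.csv(path, comment.char = "#"))
}

#' Write a schedule with its evaluation as JSON
#'
#' Embeds the blocks together with the per-patient gains, the cumulative
#' gain trajectory and the total gain, plus the interval convention.
#'
#' @param scenario A [gym_scenario()].
#' @param sched A feasible [schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(scenario, sched, path) {
  sched <- schedule(sched)
  assert_feasible(scenario, sched)
  out <- list(
    time_base = "1-based inclusive steps",
    blocks = as.data.frame(sched),
    per_patient_gains = per_patient_gains(scenario, sched, check = FALSE),
    trajectory = gain_trajectory(scenario, sched, check = FALSE),
    total_gain = total_gain(scenario, sched, check = FALSE))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a suite result table as CSV
#'
#' One row per scenario, one column per schedule type, mirroring the layout
#' of the equal-curve results table.
#'
#' @param suite A `gym_suite` from [run_suite()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_suite_csv <- function(suite, path) {
  stopifnot(inherits(suite, "gym_suite"))
  utils::write.csv(suite$table, path, row.names = FALSE)
  invisible(path)
}
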