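#' Hyperbolic skill curve for one patient-robot pairing
#'
#' A skill curve maps cumulative training time on one robot to the skill a
#' patient holds in the skill that robot trains. The curve is a modified
#' hyperbola with diminishing returns: skill after `d` training steps is
#' `c1 * (c2 + c4*(d + u)) / (c2 + c4*(d + u) + c3)`, so rapid early gains
#' flatten out as training accumulates and skill never reaches the ceiling
#' `c1` in finite time (for `c4 > 0`).
#'
#' @param c1 Maximum attainable skill (ceiling of the hyperbola), in skill
#'   units, e.g. the maximum score of a clinical assessment scale. Must be
#'   >= 0. Default 100.
#' @param c2 Shape offset, dimensionless, >= 0. Default 1.
#' @param c3 Shape divisor, dimensionless, strictly positive; larger values
#'   flatten the curve (slower learner). Default 10.
#' @param c4 Advance rate: how far along the curve one time step of training
#'   moves the patient. >= 0; 0 gives a flat curve (no learning). Default 1.
#' @param u Prior-training calibration term: number of steps trained in
#'   previous sessions plus one. >= 0. Default 1 (no previous training).
#'
#' @return An object of class `skill_curve` (a named list of the five
#'   parameters).
#'
#' @details The defaults `c1 = 100, c2 = 1, c3 = 10, c4 = 1, u = 1` are the
#'   "equal curves" preset used throughout the evaluation suite. The combined
#'   offset `c2 + c4*u` must be >= 0 so both hyperbola denominators are
#'   strictly positive.
#'
#' @examples
#' crv <- skill_curve()          # equal-curves preset
#' initial_skill(crv)            # 16.667: skill before the session
#' skill_gain(crv, 7)            # gain after 7 uninterrupted steps
#' marginal_gain(crv, 1:7)       # diminishing per-step returns
#' @export
skill_curve <- function(c1 = 100, c2 = 1, c3 = 10, c4 = 1, u = 1) {
  for (nm in c("c1", "c2", "c3", "c4", "u")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("skill curve parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (c1 < 0) stop("invalid skill curve: c1 must be >= 0 (got ", c1, ")",
                   call. = FALSE)
  if (c2 < 0) stop("invalid skill curve: c2 must be >= 0 (got ", c2, ")",
                   call. = FALSE)
  if (c3 <= 0) stop("invalid skill curve: c3 must be > 0 (got ", c3, ")",
                    call. = FALSE)
  if (c4 < 0) stop("invalid skill curve: c4 must be >= 0 (got ", c4, ")",
                   call. = FALSE)
  if (u < 0) stop("invalid skill curve: u must be >= 0 (got ", u, ")",
                  call. = FALSE)
  if (c2 + c4 * u < 0)
    stop("invalid skill curve: c2 + c4*u must be >= 0", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, u = u),
            class = "skill_curve")
}

#' @export
print.skill_curve <- function(x, ...) {
  cat(sprintf(
    "<skill_curve> c1=%g c2=%g c3=%g c4=%g u=%g (initial skill %.4f)\n",
    x$c1, x$c2, x$c3, x$c4, x$u, initial_skill(x)))
  invisible(x)
}

as_skill_curve <- function(x) {
  if (inherits(x, "skill_curve")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(do.call(skill_curve, x[intersect(names(x),
                                            c("c1", "c2", "c3", "c4", "u"))]))
  }
  stop("cannot interpret object as a skill curve", call. = FALSE)
}

# raw hyperbola: skill value after d cumulative steps (vectorised over d)
skill_value_raw <- function(c1, c2, c3, c4, u, d) {
  a <- c2 + c4 * (d + u)
  c1 * a / (a + c3)
}

#' Initial skill value of a curve
#'
#' Skill held before the current session starts, i.e. the hyperbola evaluated
#' at zero additional training: `c1*(c2 + c4*u) / (c2 + c4*u + c3)`.
#'
#' @param curve A [skill_curve()].
#' @return Skill value in skill units, in `[0, c1]`.
#' @export
initial_skill <- function(curve) {
  curve <- as_skill_curve(curve)
  skill_value_raw(curve$c1, curve$c2, curve$c3, curve$c4, curve$u, 0)
}

check_duration <- function(d, least = 0L) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d != floor(d)))
    stop("training duration must be a whole number of time steps",
         call. = FALSE)
  if (any(d < least))
    stop("training duration must be >= ", least, call. = FALSE)
  invisible(as.integer(d))
}

#' Skill gain from uninterrupted training
#'
#' Gain accrued by training `d` consecutive steps on the robot, i.e. skill
#' after `d` steps minus [initial_skill()]. Vectorised over `d`.
#'
#' @param curve A [skill_curve()].
#' @param d Integer number of training steps, >= 0.
#' @return Gain in skill units; 0 at `d = 0`, strictly increasing and concave
#'   in `d` when `c4 > 0`, bounded above by `c1 - initial_skill(curve)`.
#' @export
skill_gain <- function(curve, d) {
  curve <- as_skill_curve(curve)
  check_duration(d, 0L)
  skill_value_raw(curve$c1, curve$c2, curve$c3, curve$c4, curve$u, d) -
    initial_skill(curve)
}

#' Marginal gain of one more training step
#'
#' `skill_gain(curve, d) - skill_gain(curve, d - 1)`: the extra skill bought
#' by the `d`-th consecutive step. Strictly positive and strictly decreasing
#' in `d` when `c4 > 0` (diminishing returns). Vectorised over `d`.
#'
#' @param curve A [skill_curve()].
#' @param d Integer step index, >= 1.
#' @return Gain of the `d`-th step in skill units.
#' @export
marginal_gain <- function(curve, d) {
  curve <- as_skill_curve(curve)
  check_duration(d, 1L)
  skill_gain(curve, d) - skill_gain(curve, d - 1L)
}
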