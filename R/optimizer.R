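# placement feasibility of one block against fixed other blocks, with the
# "+1" exit-gap semantics on both the robot line and the patient line
placement_ok <- function(scenario, others, p, r, s, y) {
  e_r <- scenario$exit[r]
  ob <- others[others$robot == r, , drop = FALSE]
  for (i in seq_len(nrow(ob)))
    if (!(y + e_r + 1L <= ob$start[i] || s >= ob$end[i] + e_r + 1L))
      return(FALSE)
  pb <- others[others$patient == p, , drop = FALSE]
  for (i in seq_len(nrow(pb))) {
    e_o <- scenario$exit[pb$robot[i]]
    if (!(y + e_r + 1L <= pb$start[i] || s >= pb$end[i] + e_o + 1L))
      return(FALSE)
  }
  TRUE
}

#' Repair a schedule by removing obvious weaknesses
#'
#' Iterates two improving moves to a fixed point:
#' * pull forward: if a block's robot is already available earlier (and the
#'   patient is idle), the block is shifted to the earliest feasible start,
#'   keeping its duration;
#' * extend: if both the patient and the robot are idle after a block ends,
#'   the block is lengthened as far as the horizon and the neighbouring
#'   blocks' exit windows allow.
#'
#' Neither move can reduce total gain (gain is nondecreasing in duration and
#' independent of position), the result is feasible, and the operation is
#' idempotent.
#'
#' @param scenario A [gym_scenario()].
#' @param sched A feasible [schedule()].
#' @return The repaired, feasible [schedule()].
#' @examples
#' scn <- gym_scenario(1, 1, G = 5)
#' repair_schedule(scn, schedule(1, 1, 2, 3))   # becomes the block [1, 5]
#' @export
repair_schedule <- function(scenario, sched) {
  sched <- schedule(sched)
  assert_feasible(scenario, sched)
  if (!nrow(sched)) return(sched)
  df <- as.data.frame(sched)
  repeat {
    changed <- FALSE
    # pull forward, earliest blocks first
    for (i in order(df$start)) {
      dur <- df$end[i] - df$start[i] + 1L
      others <- df[-i, , drop = FALSE]
      for (s in seq_len(df$start[i] - 1L)) {
        if (s > scenario$H) break
        if (placement_ok(scenario, others, df$patient[i], df$robot[i],
                         s, s + dur - 1L)) {
          df$start[i] <- s
          df$end[i] <- s + dur - 1L
          changed <- TRUE
          break
        }
      }
    }
    # extend block ends into free time
    for (i in seq_len(nrow(df))) {
      others <- df[-i, , drop = FALSE]
      y <- df$end[i]
      while (y + 1L <= scenario$G &&
             placement_ok(scenario, others, df$patient[i], df$robot[i],
                          df$start[i], y + 1L))
        y <- y + 1L
      if (y > df$end[i]) { df$end[i] <- y; changed <- TRUE }
    }
    if (!changed) break
  }
  schedule(df)
}

#' Upper bound on the optimal total gain
#'
#' Minimum of two relaxations, each provably at least the optimal total gain:
#' * the contention-free bound: the sum over patients of
#'   [max_individual_gain()] (every patient scheduled as if alone);
#' * the robot-capacity bound: each robot has G trainable time units; by
#'   concavity the gain a robot can hand out is at most the sum of the G
#'   largest per-step marginal gains available on that robot across patients
#'   (exit times and patient-side contention ignored).
#'
#' Used by the optimizer to stop early once an incumbent attains the bound.
#'
#' @param scenario A [gym_scenario()].
#' @return A value greater than or equal to the optimal total gain.
#' @export
upper_bound <- function(scenario) {
  stopifnot(inherits(scenario, "gym_scenario"))
  b1 <- sum(vapply(seq_len(scenario$M), function(p)
    max_individual_gain(scenario, p), numeric(1)))
  b2 <- 0
  G <- scenario$G
  for (r in seq_len(scenario$N)) {
    mg <- unlist(lapply(seq_len(scenario$M), function(p) {
      g <- pair_gain(scenario, rep(p, G), rep(r, G), seq_len(G))
      diff(c(0, g))
    }))
    mg <- sort(mg, decreasing = TRUE)
    b2 <- b2 + sum(mg[seq_len(min(G, length(mg)))])
  }
  min(b1, b2)
}

# count the timed plans of one patient without materialising them, by
# memoised recursion over (next start time, robot subset); used by the
# brute-force size guard before any enumeration happens
count_patient_plans <- function(scenario) {
  G <- scenario$G; H <- scenario$H; N <- scenario$N; ex <- scenario$exit
  memo <- new.env(hash = TRUE)
  cnt <- function(t, used) {
    if (t > H) return(1)
    k <- paste0(t, ".", used)
    got <- memo[[k]]
    if (!is.null(got)) return(got)
    tot <- 1
    for (r in seq_len(N)) {
      bit <- bitwShiftL(1L, r - 1L)
      if (bitwAnd(used, bit) != 0L) next
      for (s in t:H) for (d in seq_len(G - s + 1L))
        tot <- tot + cnt(s + d + ex[r], bitwOr(used, bit))
    }
    memo[[k]] <- tot
    tot
  }
  cnt(1L, 0L)
}

# enumerate every timed plan of one patient: ordered blocks on distinct
# robots with explicit starts (all waiting positions included).
# Returns list of data.frames (possibly empty schedule).
enumerate_patient_plans <- function(scenario, p) {
  G <- scenario$G; H <- scenario$H; N <- scenario$N; ex <- scenario$exit
  plans <- list()
  grow <- function(t, used, blocks) {
    plans[[length(plans) + 1L]] <<- blocks
    if (t > H) return(invisible())
    for (r in seq_len(N)) {
      bit <- bitwShiftL(1L, r - 1L)
      if (bitwAnd(used, bit) != 0L) next
      for (s in t:H) for (d in seq_len(G - s + 1L))
        grow(s + d + ex[r], bitwOr(used, bit),
             rbind(blocks, data.frame(patient = p, robot = r,
                                      start = s, end = s + d - 1L)))
    }
  }
  grow(1L, 0L, data.frame(patient = integer(), robot = integer(),
                          start = integer(), end = integer()))
  plans
}

#' Exhaustive brute-force optimum for small instances
#'
#' Enumerates, per patient, every ordered sequence of blocks on distinct
#' robots with explicit start times, then searches the cross product
#' depth-first, keeping only combinations whose blocks are mutually feasible
#' on every robot line. For the total-gain objective, branches are pruned
#' when the partial gain plus the remaining patients' individual maxima
#' cannot beat the incumbent. Intended for instances around 3 patients, 3
#' robots, G <= 6; a size guard rejects anything whose estimated enumeration
#' exceeds `cap`.
#'
#' @param scenario A [gym_scenario()].
#' @param objective A `gym_objective`; bound pruning applies only to
#'   [objective_total()].
#' @param cap Maximum estimated enumeration size (product over patients of
#'   per-patient plan counts) before the instance is rejected with advice to
#'   use [optimize_schedule()].
#' @return A `gym_optimizer_result`: the globally optimal `schedule`, its
#'   `value`, `bound` (equal to `value`), `iterations_used` (search nodes)
#'   and `improvement_log`.
#' @examples
#' scn <- gym_scenario(2, 1, G = 3)
#' brute_force_optimal(scn)$value   # 18.315: split the robot 2 + 1 steps
#' @export
brute_force_optimal <- function(scenario, objective = objective_total(),
                                cap = 5e9) {
  stopifnot(inherits(scenario, "gym_scenario"))
  objective <- resolve_objective(scenario, objective)
  M <- scenario$M

  est <- count_patient_plans(scenario)^M
  if (!is.finite(est) || est > cap)
    stop("instance too large for brute force (estimated ", format(est),
         " combinations > cap ", format(cap),
         "); use optimize_schedule() instead", call. = FALSE)
  plans1 <- enumerate_patient_plans(scenario, 1L)

  plan_sets <- vector("list", M)
  plan_sets[[1L]] <- plans1
  if (M > 1L) for (p in 2L:M) plan_sets[[p]] <- lapply(plans1, function(b) {
    if (nrow(b)) b$patient <- p
    b
  })
  gains <- lapply(plan_sets, function(ps) vapply(ps, function(b)
    if (nrow(b)) sum(pair_gain(scenario, b$patient, b$robot,
                               b$end - b$start + 1L)) else 0, numeric(1)))
  ords <- lapply(gains, order, decreasing = TRUE)

  use_bound <- objective$kind == "total"
  maxind <- vapply(seq_len(M), function(p) max_individual_gain(scenario, p),
                   numeric(1))
  bound_rem <- rev(cumsum(rev(c(maxind[-1L], 0))))

  best_val <- -Inf; best_sched <- empty_schedule(); nodes <- 0L

  # all blocks of a candidate plan must be robot-line compatible with the
  # accumulated blocks (patient lines were enforced during enumeration)
  compatible <- function(acc, b) {
    for (i in seq_len(nrow(b)))
      if (!placement_ok(scenario, acc, b$patient[i], b$robot[i],
                        b$start[i], b$end[i]))
        return(FALSE)
    TRUE
  }

  dfs <- function(p, acc, tot) {
    nodes <<- nodes + 1L
    if (p > M) {
      val <- if (use_bound) tot
      else objective_value(scenario, schedule(acc), objective, check = FALSE)
      if (val > best_val + 1e-12) {
        best_val <<- val
        best_sched <<- schedule(acc)
      }
      return(invisible())
    }
    for (k in ords[[p]]) {
      g <- gains[[p]][k]
      if (use_bound && tot + g + bound_rem[p] <= best_val + 1e-12) break
      b <- plan_sets[[p]][[k]]
      if (!nrow(b) || compatible(acc, b))
        dfs(p + 1L, rbind(acc, b), tot + g)
    }
  }
  dfs(1L, data.frame(patient = integer(), robot = integer(),
                     start = integer(), end = integer()), 0)

  structure(list(schedule = best_sched, value = best_val, bound = best_val,
                 iterations_used = nodes,
                 improvement_log = data.frame(iteration = 0L,
                                              value = best_val),
                 method = "brute_force"),
            class = "gym_optimizer_result")
}

#' @export
print.gym_optimizer_result <- function(x, ...) {
  cat(sprintf(
    "<gym_optimizer_result> method=%s value=%.4f bound=%.4f iterations=%d\n",
    x$method, x$value, x$bound, x$iterations_used))
  invisible(x)
}

# encoding-native random move proposal; returns a schedule or NULL
propose_move <- function(scenario, df, method) {
  G <- scenario$G; H <- scenario$H
  nb <- nrow(df)
  add_pair <- function() {
    # activate an unused (patient, robot) pair at a random start, duration 1
    p <- sample.int(scenario$M, 1L)
    used_r <- df$robot[df$patient == p]
    free_r <- setdiff(seq_len(scenario$N), used_r)
    if (!length(free_r)) return(NULL)
    r <- free_r[sample.int(length(free_r), 1L)]
    s <- sample.int(H, 1L)
    rbind(df, data.frame(patient = p, robot = r, start = s, end = s))
  }
  if (nb == 0L) return(add_pair())
  if (method == "disjunctive") {
    op <- sample.int(4L, 1L)
    if (op == 4L) return(add_pair())
    i <- sample.int(nb, 1L)
    delta <- sample(c(-1L, 1L), 1L)
    out <- df
    if (op == 1L) {                       # shift the whole block
      out$start[i] <- out$start[i] + delta
      out$end[i] <- out$end[i] + delta
    } else if (op == 2L) {                # move the end
      out$end[i] <- out$end[i] + delta
    } else {                              # deactivate
      out <- out[-i, , drop = FALSE]
    }
    if (nrow(out) && (any(out$start < 1L) || any(out$end > G) ||
                      any(out$start > out$end) || any(out$start > H)))
      return(NULL)
    return(out)
  }
  # time-indexed: toggle start indicators / adjust durations
  op <- sample.int(4L, 1L)
  if (op == 4L) return(add_pair())
  i <- sample.int(nb, 1L)
  out <- df
  if (op == 1L) {                         # move the start indicator, keep d
    delta <- sample(c(-1L, 1L), 1L)
    out$start[i] <- out$start[i] + delta
    out$end[i] <- out$end[i] + delta
  } else if (op == 2L) {                  # adjust the duration integer
    out$end[i] <- out$end[i] + sample(c(-1L, 1L), 1L)
  } else {                                # toggle the indicator off
    out <- out[-i, , drop = FALSE]
  }
  if (nrow(out) && (any(out$start < 1L) || any(out$end > G) ||
                    any(out$start > out$end) || any(out$start > H)))
    return(NULL)
  out
}

#' Anytime schedule optimization
#'
#' Deterministic, seeded anytime search for a high-quality feasible schedule.
#' The incumbent is initialised from the better of the two baseline
#' schedules ([best_robot_schedule()], [switch_halfway_schedule()]), so the
#' result is never worse than either baseline at any budget. Each iteration
#' evaluates one candidate schedule, obtained either by greedy block-insertion
#' construction (patients inserted one at a time in a seeded order, each via
#' the exact single-patient best-response over robot subsets and free
#' windows), by a ruin-and-recreate move (remove one or two patients from the
#' incumbent and reinsert them optimally), or by a small encoding-native move
#' — for the disjunctive encoding a change to a block's start/end integers or
#' activation, for the time-indexed encoding a start-indicator toggle or
#' duration adjustment. Every candidate passes through [repair_schedule()];
#' candidates that improve the objective replace the incumbent. The search
#' stops early once the incumbent reaches [upper_bound()].
#'
#' @param scenario A [gym_scenario()].
#' @param objective A `gym_objective`; default [objective_total()].
#' @param method `"disjunctive"` or `"time_indexed"`: which encoding's move
#'   space drives the local moves. Both reach the same optima given budget;
#'   disjunctive moves perturb start/end integers directly and tend to need
#'   fewer iterations.
#' @param budget Number of candidate evaluations (0 returns the better
#'   baseline).
#' @param seed Integer seed; the search is a deterministic function of
#'   (scenario, objective, method, budget, seed), and for a fixed seed the
#'   value is nondecreasing in budget.
#' @return A `gym_optimizer_result` with `schedule`, `value`, `bound`
#'   (always >= value), `iterations_used` and `improvement_log` (data.frame
#'   of accepted improvements: iteration, value).
#' @examples
#' scn <- gym_scenario(2, 1, G = 3)
#' optimize_schedule(scn, budget = 50)$value    # 18.315, the true optimum
#' @export
optimize_schedule <- function(scenario, objective = objective_total(),
                              method = c("disjunctive", "time_indexed"),
                              budget = 1000L, seed = 1L) {
  stopifnot(inherits(scenario, "gym_scenario"), budget >= 0)
  method <- match.arg(method)
  objective <- resolve_objective(scenario, objective)
  obj <- function(s) objective_value(scenario, s, objective, check = FALSE)

  base1 <- best_robot_schedule(scenario)
  base2 <- switch_halfway_schedule(scenario)
  v1 <- obj(base1); v2 <- obj(base2)
  inc <- if (v1 >= v2) base1 else base2
  inc_val <- max(v1, v2)
  bound <- upper_bound(scenario)
  log <- data.frame(iteration = 0L, value = inc_val)

  result <- function(it) structure(
    list(schedule = inc, value = inc_val, bound = bound,
         iterations_used = it, improvement_log = log, method = method,
         seed = seed),
    class = "gym_optimizer_result")
  if (budget == 0L) return(result(0L))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  consider <- function(cand, it) {
    v <- obj(cand)
    if (v > inc_val + 1e-9) {
      inc <<- cand; inc_val <<- v
      log <<- rbind(log, data.frame(iteration = it, value = v))
    }
  }
  # Insert patients one at a time, each via the exact best response. The
  # robot tie-break order is staggered per patient (cyclic rotation, or a
  # random permutation when `shuffle_ties`), so symmetric groups spread over
  # robots instead of blocking each other.
  rebuild <- function(order_p, base_blocks, shuffle_ties = FALSE) {
    acc <- base_blocks
    for (p in order_p) {
      ro <- if (shuffle_ties) sample.int(scenario$N)
      else ((seq_len(scenario$N) + p - 2L) %% scenario$N) + 1L
      br <- patient_best_response(scenario, p, others = schedule(acc),
                                  robot_order = ro)
      acc <- rbind(acc, as.data.frame(br$blocks))
    }
    repair_schedule(scenario, schedule(acc))
  }

  it <- 0L
  n_constr <- min(budget, max(4L, min(2L * scenario$M, 10L)))
  orders <- c(list(seq_len(scenario$M), rev(seq_len(scenario$M))),
              lapply(seq_len(max(0L, n_constr - 2L)),
                     function(k) sample.int(scenario$M)))
  for (k in seq_len(n_constr)) {
    it <- it + 1L
    consider(rebuild(orders[[k]], empty_schedule(), shuffle_ties = k > 2L),
             it)
    if (inc_val >= bound - 1e-9) return(result(it))
  }

  while (it < budget) {
    it <- it + 1L
    if (stats::runif(1) < 0.25) {
      # ruin and recreate around the incumbent
      k <- sample.int(min(2L, scenario$M), 1L)
      victims <- sample.int(scenario$M, k)
      keep <- as.data.frame(inc)[!(inc$patient %in% victims), , drop = FALSE]
      cand <- rebuild(victims[sample.int(length(victims))], keep,
                      shuffle_ties = TRUE)
      consider(cand, it)
    } else {
      prop <- propose_move(scenario, as.data.frame(inc), method)
      if (!is.null(prop)) {
        prop <- schedule(prop)
        if (validate_schedule(scenario, prop)$feasible)
          consider(repair_schedule(scenario, prop), it)
      }
    }
    if (inc_val >= bound - 1e-9) break
  }
  result(it)
}
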