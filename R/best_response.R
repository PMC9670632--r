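# Exact single-patient best response.
#
# Given the other patients' blocks held fixed, the best schedule for one
# patient is an optimal walk over robot subsets: choose which robots to
# visit, in what order, when, and for how long, where a block [s, s+d-1] on
# robot r must fit a free window of r's timeline and the next block may start
# no earlier than s + d + exit(r). Solved exactly by memoised recursion over
# (earliest allowed start time, set of robots already used); within a free
# window only the earliest admissible start need be considered, since gains
# depend on duration alone and delaying a start can never help.
#
# This doubles as the single-patient optimum ([max_individual_gain]) when
# `others` is empty, and as the block-insertion engine of the optimizer.

# free windows [a, b] on robot r once `others`' blocks (with exit margins)
# are carved out of [1, G]
robot_free_windows <- function(scenario, r, others) {
  G <- scenario$G; e <- scenario$exit[r]
  ob <- others[others$robot == r, , drop = FALSE]
  if (!nrow(ob)) return(list(c(1L, G)))
  ob <- ob[order(ob$start), , drop = FALSE]
  wins <- list(); lo <- 1L
  for (i in seq_len(nrow(ob))) {
    hi <- ob$start[i] - e - 1L
    if (hi >= lo) wins[[length(wins) + 1L]] <- c(lo, hi)
    lo <- max(lo, ob$end[i] + e + 1L)
  }
  if (lo <= G) wins[[length(wins) + 1L]] <- c(lo, G)
  wins
}

# Returns list(gain, blocks) for patient `p` against fixed blocks `others`
# (a schedule-like data.frame that must not contain blocks of `p`).
# `robot_order` permutes the exploration order of robots, which controls
# only how ties between equally good responses break (the value is exact
# either way); staggering it across patients steers equal-curve groups into
# rotation patterns instead of mutually blocking choices.
patient_best_response <- function(scenario, p, others = empty_schedule(),
                                  robot_order = seq_len(scenario$N)) {
  stopifnot(inherits(scenario, "gym_scenario"))
  N <- scenario$N; G <- scenario$G; H <- scenario$H
  ex <- scenario$exit
  windows <- lapply(seq_len(N), robot_free_windows, scenario = scenario,
                    others = others)
  gains <- lapply(seq_len(N), function(r)
    pair_gain(scenario, rep(p, G), rep(r, G), seq_len(G)))

  n_t <- G + 2L                       # times clamp to G+1 ("session over")
  memo <- rep(NA_real_, n_t * bitwShiftL(1L, N))
  choice <- vector("list", n_t * bitwShiftL(1L, N))
  key <- function(t, used) (min(t, G + 1L) - 1L) * bitwShiftL(1L, N) + used + 1L

  solve <- function(t, used) {
    if (t > G) return(0)
    k <- key(t, used)
    if (!is.na(memo[k])) return(memo[k])
    best <- 0; best_ch <- NULL
    for (r in robot_order) {
      bit <- bitwShiftL(1L, r - 1L)
      if (bitwAnd(used, bit) != 0L) next
      for (w in windows[[r]]) {
        s <- max(t, w[1])
        if (s > w[2] || s > H) next
        gr <- gains[[r]]
        for (d in seq_len(w[2] - s + 1L)) {
          v <- gr[d] + solve(s + d + ex[r], bitwOr(used, bit))
          if (v > best + 1e-12) {
            best <- v
            best_ch <- c(r, s, s + d - 1L)
          }
        }
      }
    }
    memo[k] <<- best
    choice[k] <<- list(best_ch)   # list() wrapper keeps NULL as an element
    best
  }

  g <- solve(1L, 0L)
  # reconstruct
  blocks <- list(); t <- 1L; used <- 0L
  repeat {
    ch <- choice[[key(t, used)]]
    if (is.null(ch)) break
    blocks[[length(blocks) + 1L]] <- ch
    t <- ch[3] + ex[ch[1]] + 1L
    used <- bitwOr(used, bitwShiftL(1L, ch[1] - 1L))
    if (t > G) break
  }
  if (length(blocks)) {
    m <- do.call(rbind, blocks)
    sch <- schedule(patient = rep(p, nrow(m)), robot = m[, 1],
                    start = m[, 2], end = m[, 3])
  } else sch <- empty_schedule()
  list(gain = g, blocks = sch)
}

#' Maximum gain a patient could achieve alone in the gym
#'
#' The exact best total gain for one patient with no contention: an optimal
#' choice of robot subset, visiting order, start times and integer durations,
#' where moving on from robot r costs that robot's exit time before the next
#' block may start. Computed by exact dynamic programming over robot subsets.
#' Used as a per-patient component of [upper_bound()] and as the reference
#' maximum of [objective_relative_to_max()].
#'
#' @param scenario A [gym_scenario()].
#' @param patient Patient index in `1..M`.
#' @return Maximum attainable gain in skill units.
#' @examples
#' scn <- gym_scenario(1, 5, G = 7)
#' max_individual_gain(scn, 1)   # 43.04 for equal curves
#' @export
max_individual_gain <- function(scenario, patient) {
  stopifnot(inherits(scenario, "gym_scenario"),
            patient >= 1L, patient <= scenario$M)
  patient_best_response(scenario, patient)$gain
}
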