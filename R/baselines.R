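# Greedy pick of (patient, robot) pairs by descending gain with deterministic
# tie-breaks: higher gain first, then lower patient index, then lower robot.
# `allowed` is an M x N logical matrix of admissible pairs; each patient and
# each robot is used at most once. Returns an integer vector robot-of-patient
# (NA where unassigned).
greedy_assign <- function(gain, allowed) {
  M <- nrow(gain); N <- ncol(gain)
  pick <- rep(NA_integer_, M)
  free_r <- rep(TRUE, N); free_p <- rep(TRUE, M)
  repeat {
    best <- -Inf; bp <- 0L; br <- 0L
    for (p in seq_len(M)) {
      if (!free_p[p]) next
      for (r in seq_len(N)) {
        if (!free_r[r] || !allowed[p, r]) next
        if (gain[p, r] > best + 1e-12) { best <- gain[p, r]; bp <- p; br <- r }
      }
    }
    if (bp == 0L) break
    pick[bp] <- br; free_p[bp] <- FALSE; free_r[br] <- FALSE
  }
  pick
}

#' "Best robot only" baseline schedule
#'
#' Each patient is assigned to a single robot for the whole session (steps 1
#' to G). Robots are handed out greedily: repeatedly give the still-free
#' robot to the still-unassigned patient with the largest full-session gain,
#' so when two patients want the same robot the one who would gain more wins
#' and the other falls back to their next-best free robot. Ties break by
#' lower patient index, then lower robot index. With more patients than
#' robots, `M - N` patients stay idle.
#'
#' @param scenario A [gym_scenario()].
#' @return A feasible [schedule()] with exactly `min(M, N)` blocks.
#' @examples
#' scn <- gym_scenario(5, 5, G = 7)
#' total_gain(scn, best_robot_schedule(scn))   # 153.5 for equal curves
#' @export
best_robot_schedule <- function(scenario) {
  stopifnot(inherits(scenario, "gym_scenario"))
  idx <- expand.grid(p = seq_len(scenario$M), r = seq_len(scenario$N))
  g <- matrix(pair_gain(scenario, idx$p, idx$r, scenario$G),
              scenario$M, scenario$N)
  pick <- greedy_assign(g, matrix(TRUE, scenario$M, scenario$N))
  got <- which(!is.na(pick))
  schedule(patient = got, robot = pick[got], start = rep(1L, length(got)),
           end = rep(scenario$G, length(got)))
}

#' "Switch halfway" baseline schedule
#'
#' Each patient trains on one robot for the first half of the session and on
#' a second robot for the second half, exploiting the diminishing returns of
#' the skill curves. For a first-half robot with exit time `e` the split is
#' `d1 = ceiling((G - e) / 2)` steps starting at step 1, then `d2 = G - e -
#' d1` steps starting at `d1 + e + 1` (the longer segment first). Robots are
#' chosen by the same greedy highest-gain conflict resolution as
#' [best_robot_schedule()], applied once per half; in the second half a
#' patient may not reuse their first-half robot and must respect every exit
#' window. A patient who cannot obtain a robot in a half idles that half; a
#' patient whose only option is their first-half robot keeps it for the whole
#' session (single block).
#'
#' @param scenario A [gym_scenario()].
#' @return A feasible [schedule()].
#' @examples
#' scn <- gym_scenario(5, 5, G = 7)
#' total_gain(scn, switch_halfway_schedule(scn))   # 187.5 for equal curves
#' @export
switch_halfway_schedule <- function(scenario) {
  stopifnot(inherits(scenario, "gym_scenario"))
  M <- scenario$M; N <- scenario$N; G <- scenario$G
  e <- scenario$exit

  # first half: duration depends on the robot's own exit time
  d1r <- ceiling((G - e) / 2)
  g1 <- matrix(0, M, N); ok1 <- matrix(FALSE, M, N)
  for (r in seq_len(N)) if (d1r[r] >= 1) {
    ok1[, r] <- TRUE
    g1[, r] <- pair_gain(scenario, seq_len(M), rep(r, M), rep(d1r[r], M))
  }
  first <- greedy_assign(g1, ok1)

  first_end <- ifelse(is.na(first), NA_integer_, d1r[first])
  # second half: per-pair feasible start = max(patient ready, robot free)
  start2 <- matrix(NA_integer_, M, N); g2 <- matrix(-Inf, M, N)
  ok2 <- matrix(FALSE, M, N)
  r_used_by <- match(seq_len(N), first)          # patient holding robot r, or NA
  for (p in seq_len(M)) {
    p_ready <- if (is.na(first[p])) 1L else first_end[p] + e[first[p]] + 1L
    for (r in seq_len(N)) {
      if (!is.na(first[p]) && first[p] == r) next
      r_free <- if (is.na(r_used_by[r])) 1L else d1r[r] + e[r] + 1L
      s <- max(p_ready, r_free)
      d2 <- G - s + 1L
      if (d2 >= 1L && s <= scenario$H) {
        ok2[p, r] <- TRUE
        start2[p, r] <- s
        g2[p, r] <- pair_gain(scenario, p, r, d2)
      }
    }
  }
  second <- greedy_assign(ifelse(ok2, g2, 0), ok2)

  # Plain greedy can strand a patient whose only admissible robots were
  # handed to others (e.g. a 2-cycle among earlier patients). Complete the
  # assignment with deterministic augmenting paths, accepted only when the
  # reshuffle increases total second-half gain.
  holder <- match(seq_len(N), second)
  for (p in seq_len(M)) {
    if (!is.na(second[p]) || !any(ok2[p, ])) next
    snap_second <- second; snap_holder <- holder
    visited <- rep(FALSE, N)
    augment <- function(q) {
      for (r in seq_len(N)) {
        if (!ok2[q, r] || visited[r]) next
        visited[r] <<- TRUE
        h <- holder[r]
        if (is.na(h) || augment(h)) {
          holder[r] <<- q; second[q] <<- r
          return(TRUE)
        }
      }
      FALSE
    }
    if (augment(p)) {
      delta <- sum(g2[cbind(which(!is.na(second)),
                            second[!is.na(second)])]) -
        sum(g2[cbind(which(!is.na(snap_second)),
                     snap_second[!is.na(snap_second)])])
      if (delta <= 1e-9) { second <- snap_second; holder <- snap_holder }
    } else { second <- snap_second; holder <- snap_holder }
  }

  pts <- integer(); rbs <- integer(); sts <- integer(); ens <- integer()
  for (p in seq_len(M)) {
    if (!is.na(first[p])) {
      en1 <- first_end[p]
      # lone-robot fallback: no second-half robot and nobody takes ours later
      if (is.na(second[p]) && !(first[p] %in% second))
        en1 <- G
      pts <- c(pts, p); rbs <- c(rbs, first[p]); sts <- c(sts, 1L)
      ens <- c(ens, en1)
    }
    if (!is.na(second[p])) {
      pts <- c(pts, p); rbs <- c(rbs, second[p])
      sts <- c(sts, start2[p, second[p]]); ens <- c(ens, G)
    }
  }
  schedule(patient = pts, robot = rbs, start = sts, end = ens)
}
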