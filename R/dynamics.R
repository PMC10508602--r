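#' Simulation parameters for the urn process
#'
#' Bundles the behavioural probabilities of one decision event:
#' social influence `ps` (imitate a decided group-mate), conformity `pc`
#' (adopt the group norm when not imitating), the norm-assignment rate
#' `delta1` (probability a hyperedge's purpose is RED), and the personal
#' preference `qs` (probability of choosing RED when neither imitating nor
#' conforming). The shipped experiment designs all use `qs = 1`: RED is the
#' intrinsically preferred, quality-1 choice and BLUE the quality-0 one.
#'
#' @param ps,pc,delta1,qs Probabilities in `[0, 1]`.
#' @return A list of class `urn_params`.
#' @export
urn_params <- function(ps, pc, delta1 = 0.5, qs = 1) {
  structure(list(ps = check_prob(ps, "ps"),
                 pc = check_prob(pc, "pc"),
                 delta1 = check_prob(delta1, "delta1"),
                 qs = check_prob(qs, "qs")),
            class = "urn_params")
}

#' @export
print.urn_params <- function(x, ...) {
  cat(sprintf("<urn_params> ps=%g pc=%g delta1=%g qs=%g\n",
              x$ps, x$pc, x$delta1, x$qs))
  invisible(x)
}

#' Start conditions: the initial urn
#'
#' The process is seeded by placing `red + blue` balls in the global urn on
#' as many randomly chosen nodes. The three named conditions follow the
#' standard designs: a *false* start (1 red, 9 blue) that contradicts the
#' RED preference, an *equal* start (5, 5), and a *correct* start (9, 1).
#'
#' @param condition `"false"`, `"equal"`, `"correct"`, or `"custom"`.
#' @param red,blue Seed counts, used when `condition = "custom"`.
#' @return A list of class `urn_start` with fields `red` and `blue`.
#' @export
start_condition <- function(condition = c("false", "equal", "correct",
                                          "custom"),
                            red = NULL, blue = NULL) {
  condition <- match.arg(condition)
  counts <- switch(condition,
                   false = c(1L, 9L), equal = c(5L, 5L), correct = c(9L, 1L),
                   custom = c(check_count(red, "red"),
                              check_count(blue, "blue")))
  structure(list(condition = condition, red = counts[1], blue = counts[2]),
            class = "urn_start")
}

as_start <- function(start) {
  if (inherits(start, "urn_start")) start
  else if (is.character(start)) start_condition(start)
  else if (is.numeric(start) && length(start) == 2L)
    start_condition("custom", red = start[1], blue = start[2])
  else abort("`start` must be an urn_start, a condition name, or c(red, blue).",
             class = "hyperurn_invalid_config")
}

new_trajectory <- function(hn, params, start, node, color, step) {
  color_chr <- URN_COLORS[color]
  red_cum <- cumsum(color == 1L)
  blue_cum <- cumsum(color == 2L)
  decisions <- tibble(step = step, node = node, color = color_chr,
                      n_red = red_cum, n_blue = blue_cum)
  state <- rep(NA_character_, hn$node_count)
  state[node] <- color_chr
  structure(list(hn = hn, params = params, start = start,
                 decisions = decisions, state = state),
            class = "urn_trajectory")
}

#' Seed the urn process
#'
#' Chooses `red + blue` distinct nodes uniformly at random and assigns them
#' their seed colours (RED seeds first) as completed decisions at step 0,
#' so that the global urn starts at the seed counts.
#'
#' @param hn A `hypernetwork` with assigned purposes (unassigned purposes
#'   are only allowed when `pc = 0`, where norms are never consulted).
#' @param params An [urn_params()] object.
#' @param start A start condition (see [start_condition()]).
#' @param seed Optional integer seed for the draw.
#' @return An `urn_trajectory` containing only the seed decisions.
#' @export
initialize_state <- function(hn, params, start, seed = NULL) {
  start <- as_start(start)
  ns <- start$red + start$blue
  if (ns > hn$node_count)
    abort(sprintf("%d seed balls but only %d nodes.", ns, hn$node_count),
          class = "hyperurn_invalid_config")
  if (is.null(hn$purposes) && params$pc > 0)
    abort("Hypernetwork purposes are unassigned; call assign_purposes().",
          class = "hyperurn_invalid_config")
  nodes <- with_opt_seed(seed, {
    if (ns == 0L) integer(0) else sample.int(hn$node_count, ns)
  })
  new_trajectory(hn, params, start, nodes,
                 rep(c(1L, 2L), c(start$red, start$blue)),
                 rep.int(0L, ns))
}

#' Local urn of a node
#'
#' The information available to an undecided individual: one ball of colour
#' `c` for every *decided* neighbour that chose `c` (one ball per distinct
#' neighbour, regardless of how many hyperedges they share).
#'
#' @param traj An `urn_trajectory`.
#' @param node A node id.
#' @return Named integer vector `c(RED = , BLUE = )`.
#' @export
local_urn <- function(traj, node) {
  nb <- hn_neighbors(traj$hn, node)
  cols <- traj$state[nb]
  c(RED = sum(cols == "RED", na.rm = TRUE),
    BLUE = sum(cols == "BLUE", na.rm = TRUE))
}

# Pure-R reference implementation of one decision event; the compiled
# engine implements the same rule. Operates in the ambient RNG stream.
draw_color <- function(traj, l, social_ok) {
  p <- traj$params
  hn <- traj$hn
  if (social_ok) {
    nb <- hn_neighbors(hn, l)
    decided <- nb[!is.na(traj$state[nb])]
    k <- decided[sample.int(length(decided), 1L)]
    if (runif(1) <= p$ps) return(traj$state[k])
  }
  own <- which(vapply(hn$hyperedges, function(e) l %in% e, logical(1)))
  if (length(own) > 0L && runif(1) < p$pc) {
    e <- own[sample.int(length(own), 1L)]
    return(hn$purposes[e])
  }
  if (runif(1) <= p$qs) "RED" else "BLUE"
}

#' Advance the urn process by one decision
#'
#' Selects one undecided individual and decides its colour: uniformly among
#' the undecided individuals whose local urn is non-empty, imitate a
#' uniformly drawn decided neighbour with probability `ps`, otherwise adopt
#' the purpose of a uniformly drawn own hyperedge with probability `pc`,
#' otherwise choose RED with probability `qs`. If *no* undecided individual
#' has a decided neighbour, a uniformly drawn undecided individual decides
#' through the non-social branch alone (the same rule the first mover in an
#' empty market follows). This is the slow reference stepper; use
#' [run_simulation()] for whole runs.
#'
#' @inheritParams local_urn
#' @return The trajectory with one more decision appended.
#' @export
decide_one <- function(traj) {
  undec <- which(is.na(traj$state))
  if (length(undec) == 0L)
    abort("All individuals have already decided.",
          class = "hyperurn_invalid_config")
  has_nb <- vapply(undec, function(v) sum(local_urn(traj, v)) > 0, logical(1))
  cand <- undec[has_nb]
  if (length(cand) > 0L) {
    l <- cand[sample.int(length(cand), 1L)]
    col <- draw_color(traj, l, social_ok = TRUE)
  } else {
    l <- undec[sample.int(length(undec), 1L)]
    col <- draw_color(traj, l, social_ok = FALSE)
  }
  last <- traj$decisions[nrow(traj$decisions), ]
  traj$decisions <- dplyr::bind_rows(
    traj$decisions,
    tibble(step = max(traj$decisions$step, 0L) + 1L, node = l, color = col,
           n_red = (last$n_red %||% 0L) + (col == "RED"),
           n_blue = (last$n_blue %||% 0L) + (col == "BLUE")))
  traj$state[l] <- col
  traj
}

#' Run the urn process until every individual has decided
#'
#' @inheritParams initialize_state
#' @param engine `"compiled"` (default, C++ inner loop) or `"reference"`
#'   (pure-R [decide_one()] iterated; identical decision rule, much slower).
#'   Both draw from R's RNG, so runs are reproducible given `seed`, but the
#'   two engines consume the stream differently and produce different —
#'   identically distributed — trajectories from the same seed.
#' @return A complete `urn_trajectory`; its `decisions` tibble has columns
#'   `step` (0 for seeds), `node`, `color`, and running urn counts `n_red`,
#'   `n_blue`.
#' @export
#' @examples
#' hn <- generate_uniform_hypernetwork(100, 15, 10, seed = 1) |>
#'   assign_purposes(delta1 = 0.5, seed = 2)
#' traj <- run_simulation(hn, urn_params(ps = 0.5, pc = 0.5), "false",
#'                        seed = 3)
#' final_shares(traj)
run_simulation <- function(hn, params, start, seed = NULL,
                           engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  start <- as_start(start)
  with_opt_seed(seed, {
    if (engine == "reference") {
      traj <- initialize_state(hn, params, start)
      while (anyNA(traj$state)) traj <- decide_one(traj)
      traj
    } else {
      ns <- start$red + start$blue
      if (ns > hn$node_count)
        abort(sprintf("%d seed balls but only %d nodes.", ns, hn$node_count),
              class = "hyperurn_invalid_config")
      if (is.null(hn$purposes) && params$pc > 0)
        abort("Hypernetwork purposes are unassigned; call assign_purposes().",
              class = "hyperurn_invalid_config")
      seeds <- if (ns == 0L) integer(0) else sample.int(hn$node_count, ns)
      res <- .urn_engine(hn$node_count, hn$hyperedges, node_edge_index(hn),
                         hn$purposes == "RED",
                         params$ps, params$pc, params$qs, seeds, start$red)
      new_trajectory(hn, params, start, res$node, res$color, res$step)
    }
  })
}

#' @export
print.urn_trajectory <- function(x, ...) {
  n <- nrow(x$decisions)
  cat(sprintf("<urn_trajectory> %d/%d decided", n, x$hn$node_count))
  if (n > 0) {
    last <- x$decisions[n, ]
    cat(sprintf("; urn [RED %d, BLUE %d]", last$n_red, last$n_blue))
  }
  cat("\n")
  invisible(x)
}

#' Final market shares of a trajectory
#'
#' @param traj A complete `urn_trajectory`.
#' @return A tibble with columns `color`, `count`, `share` (share of
#'   `node_count`, seeds included).
#' @export
final_shares <- function(traj) {
  last <- traj$decisions[nrow(traj$decisions), ]
  market_share(c(RED = last$n_red, BLUE = last$n_blue), traj$hn$node_count)
}

#' Run an ensemble of independent simulations
#'
#' Executes `runs` independent realisations. Run `w` is seeded
#' `base_seed + w - 1`, and within its substream the hypernetwork factory
#' (if given) is called first, then seed nodes are drawn, then the dynamics
#' run — so seed-node selection and (with a factory) purpose assignment are
#' fresh every run.
#'
#' @param hn A `hypernetwork`, or a zero-argument function returning one
#'   (a factory; called once per run inside the run's RNG substream, e.g.
#'   to redraw purposes).
#' @param params An [urn_params()] object.
#' @param start A start condition.
#' @param runs Number of independent runs `W`.
#' @param base_seed Integer seed of the first run.
#' @param record_time Keep per-run share trajectories on the common
#'   decision-index grid (index 0 = post-seed state)? Needed by
#'   [time_resolved_unpredictability()].
#' @return An `urn_ensemble`: field `shares` is a tibble (`run`, `seed`,
#'   `red`, `blue`) of final shares; `time_red` (when recorded) is a
#'   `runs x (decisions + 1)` matrix of running RED counts.
#' @export
run_ensemble <- function(hn, params, start, runs = 500, base_seed = 1,
                         record_time = FALSE) {
  runs <- check_count(runs, "runs", 1L)
  base_seed <- check_count(base_seed, "base_seed")
  start <- as_start(start)
  factory <- if (is.function(hn)) hn else function() hn
  m <- NULL
  red <- numeric(runs)
  time_red <- NULL
  for (w in seq_len(runs)) {
    seed_w <- base_seed + w - 1L
    traj <- withr::with_seed(seed_w, {
      run_simulation(factory(), params, start)
    })
    m <- traj$hn$node_count
    last <- traj$decisions[nrow(traj$decisions), ]
    red[w] <- last$n_red / m
    if (record_time) {
      ns <- start$red + start$blue
      tr <- traj$decisions$n_red[ns:nrow(traj$decisions)]
      if (ns == 0L) tr <- c(0L, traj$decisions$n_red)
      if (is.null(time_red)) time_red <- matrix(0L, runs, length(tr))
      time_red[w, ] <- tr
    }
  }
  structure(list(
    shares = tibble(run = seq_len(runs),
                    seed = base_seed + seq_len(runs) - 1L,
                    red = red, blue = 1 - red),
    time_red = time_red, runs = runs, node_count = m,
    n_seeds = start$red + start$blue,
    params = params, start = start, base_seed = base_seed),
    class = "urn_ensemble")
}

#' @export
print.urn_ensemble <- function(x, ...) {
  cat(sprintf(
    "<urn_ensemble> %d runs on %d nodes; mean RED share %.3f (sd %.3f)\n",
    x$runs, x$node_count, mean(x$shares$red), sd(x$shares$red)))
  invisible(x)
}

#' Export a trajectory or ensemble to CSV
#'
#' `write_trajectory_csv()` writes the per-decision table (`step`, `node`,
#' `color`, `n_red`, `n_blue`); `write_ensemble_csv()` writes the per-run
#' summary (`run`, `seed`, `red`, `blue` final shares).
#'
#' @param x An `urn_trajectory` or `urn_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(x, path) {
  write.csv(x$decisions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_ensemble_csv <- function(x, path) {
  write.csv(x$shares, path, row.names = FALSE)
  invisible(path)
}
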