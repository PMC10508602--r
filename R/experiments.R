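#' Specify a parameter sweep
#'
#' Collects everything a sweep needs: the `ps`/`pc` grid, norm-assignment
#' rates `delta1`, start conditions, ensemble size, network shape and the
#' base seed. Defaults mirror the standard experimental design: an 11x11
#' grid over `[0, 1]`, 500 runs per cell, and a 100-node uniform
#' hypernetwork of 15 hyperedges with 10 members each in which a node has a
#' 50% chance of multiple memberships.
#'
#' @param ps,pc Numeric vectors of grid values in `[0, 1]`.
#' @param delta1 Numeric vector of norm-assignment rates.
#' @param starts Character vector of start conditions.
#' @param runs Runs per cell (`W`).
#' @param nodes,edges,edge_size Hypernetwork dimensions.
#' @param network `"hyper"` (uniform overlapping hypernetwork) or `"full"`
#'   (single hyperedge over all nodes).
#' @param multi_membership_prob Marginal multi-membership rate of the
#'   generated structure.
#' @param qs Personal preference for RED.
#' @param edge_counts Integer vector for [sweep_hyperedge_count()].
#' @param base_seed Integer; cell `i` uses run seeds
#'   `base_seed + (i - 1) * runs + (0..runs-1)`, and the structure is drawn
#'   once from `base_seed`.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(ps = seq(0, 1, by = 0.1), pc = seq(0, 1, by = 0.1),
                       delta1 = 0.5, starts = c("false", "equal", "correct"),
                       runs = 500, nodes = 100, edges = 15, edge_size = 10,
                       network = c("hyper", "full"),
                       multi_membership_prob = 0.5, qs = 1,
                       edge_counts = NULL, base_seed = 1) {
  for (v in ps) check_prob(v, "ps")
  for (v in pc) check_prob(v, "pc")
  for (v in delta1) check_prob(v, "delta1")
  structure(list(ps = ps, pc = pc, delta1 = delta1,
                 starts = match.arg(starts, several.ok = TRUE,
                                    choices = c("false", "equal", "correct")),
                 runs = check_count(runs, "runs", 1L),
                 nodes = check_count(nodes, "nodes", 1L),
                 edges = check_count(edges, "edges", 1L),
                 edge_size = check_count(edge_size, "edge_size", 1L),
                 network = match.arg(network),
                 multi_membership_prob =
                   check_prob(multi_membership_prob, "multi_membership_prob"),
                 qs = check_prob(qs, "qs"),
                 edge_counts = edge_counts,
                 base_seed = check_count(base_seed, "base_seed")),
            class = "sweep_spec")
}

# structure for one sweep (drawn once, purposes redrawn per run)
sweep_structure <- function(spec) {
  if (spec$network == "full") fully_connected_hypernetwork(spec$nodes)
  else generate_overlapping_hypernetwork(
    spec$nodes, spec$edges, spec$edge_size, spec$multi_membership_prob,
    seed = spec$base_seed)
}

run_one_cell <- function(struct, ps, pc, delta1, start, qs, runs, seed0,
                         record_time = FALSE) {
  params <- urn_params(ps = ps, pc = pc, delta1 = delta1, qs = qs)
  factory <- function() assign_purposes(struct, delta1)
  run_ensemble(factory, params, start, runs = runs, base_seed = seed0,
               record_time = record_time)
}

#' Run a full parameter sweep
#'
#' One ensemble per grid cell `(ps, pc, delta1, start)`; purposes are
#' redrawn each run, seed nodes are redrawn each run, the structure is
#' fixed across the sweep. Returns every per-cell statistic; the
#' `sweep_share_heatmap()`, `sweep_unpredictability()` and
#' `sweep_inequality()` wrappers select the view matching each canonical
#' figure-style summary.
#'
#' @param spec A [sweep_spec()].
#' @return A tibble of class `urn_sweep`: the grid columns plus the
#'   [ensemble_stats()] columns.
#' @export
run_sweep <- function(spec) {
  grid <- tidyr::expand_grid(ps = spec$ps, pc = spec$pc,
                             delta1 = spec$delta1, start = spec$starts)
  struct <- sweep_structure(spec)
  out <- purrr::pmap_dfr(
    c(grid, list(idx = seq_len(nrow(grid)))),
    function(ps, pc, delta1, start, idx) {
      ens <- run_one_cell(struct, ps, pc, delta1, start, spec$qs, spec$runs,
                          seed0 = spec$base_seed + (idx - 1L) * spec$runs)
      dplyr::bind_cols(tibble(ps = ps, pc = pc, delta1 = delta1,
                              start = start), ensemble_stats(ens))
    })
  attr(out, "spec") <- spec
  class(out) <- c("urn_sweep", class(out))
  out
}

#' @rdname run_sweep
#' @export
sweep_share_heatmap <- function(spec) {
  out <- run_sweep(spec)
  attr(out, "statistic") <- "mean_red"
  out
}

#' @rdname run_sweep
#' @export
sweep_unpredictability <- function(spec) {
  out <- run_sweep(spec)
  attr(out, "statistic") <- "U"
  out
}

#' @rdname run_sweep
#' @export
sweep_inequality <- function(spec) {
  out <- run_sweep(spec)
  attr(out, "statistic") <- "mean_G"
  out
}

#' Sweep over the number of hyperedges
#'
#' Holds the population at `spec$nodes` and varies the number of uniform
#' hyperedges, keeping the membership-slot density at the base structure's
#' 1.5 slots per node: `edge_size = min(nodes, ceiling(1.5 * nodes /
#' edge_count))`. An edge count of 1 therefore degenerates to the
#' fully-connected single hyperedge. Each count draws its own structure
#' (seeded from the spec), and each cell runs a full ensemble.
#'
#' @param spec A [sweep_spec()] whose `edge_counts` is a non-empty integer
#'   vector.
#' @return A tibble of class `urn_sweep` with columns `edge_count`,
#'   `edge_size`, the grid columns and the per-cell statistics.
#' @export
sweep_hyperedge_count <- function(spec) {
  if (is.null(spec$edge_counts) || length(spec$edge_counts) == 0L)
    abort("`spec$edge_counts` must list the hyperedge counts to sweep.",
          class = "hyperurn_invalid_config")
  grid <- tidyr::expand_grid(edge_count = as.integer(spec$edge_counts),
                             ps = spec$ps, pc = spec$pc,
                             delta1 = spec$delta1, start = spec$starts)
  out <- purrr::pmap_dfr(
    c(grid, list(idx = seq_len(nrow(grid)))),
    function(edge_count, ps, pc, delta1, start, idx) {
      k <- min(spec$nodes, as.integer(ceiling(1.5 * spec$nodes / edge_count)))
      struct <- if (edge_count == 1L)
        fully_connected_hypernetwork(spec$nodes)
      else generate_overlapping_hypernetwork(
        spec$nodes, edge_count, k, spec$multi_membership_prob,
        seed = spec$base_seed + edge_count)
      ens <- run_one_cell(struct, ps, pc, delta1, start, spec$qs, spec$runs,
                          seed0 = spec$base_seed + (idx - 1L) * spec$runs)
      dplyr::bind_cols(tibble(edge_count = edge_count, edge_size = k,
                              ps = ps, pc = pc, delta1 = delta1,
                              start = start), ensemble_stats(ens))
    })
  attr(out, "spec") <- spec
  class(out) <- c("urn_sweep", class(out))
  out
}

#' Compare the analytic recursion with simulation on one hyperedge
#'
#' On the fully-connected single-hyperedge network the simulator and the
#' mean-field recursion describe the same process, so the simulated
#' ensemble-mean final share should sit within Monte-Carlo error of the
#' analytic expectation at every grid point. Two purpose conventions are
#' supported: `"redraw"` draws the hyperedge's norm RED with probability
#' `delta1` afresh each run and compares against the recursion with
#' `delta = delta1` (exact by linearity of the expectation in `delta`);
#' `"fixed-red"` pins the norm to RED and uses `delta = 1`.
#'
#' @param delta1 Numeric vector of norm-assignment rates (the sweep axis).
#' @param ps,pc,qs Scalar probabilities.
#' @param nodes Population size.
#' @param start Start condition.
#' @param runs Runs per grid point.
#' @param base_seed Integer seed; point `i` uses
#'   `base_seed + (i - 1) * runs` onward.
#' @param purpose Purpose convention (see above).
#' @return A tibble of class `urn_comparison`: `delta1`, `analytic`,
#'   `simulated`, `se`, `z` (difference in SE units).
#' @export
compare_numeric_vs_simulation <- function(delta1, ps, pc, qs = 1, nodes = 100,
                                          start = "false", runs = 500,
                                          base_seed = 1,
                                          purpose = c("redraw", "fixed-red")) {
  purpose <- match.arg(purpose)
  start <- as_start(start)
  B <- start$red + start$blue
  out <- purrr::imap_dfr(as.numeric(delta1), function(d1, i) {
    struct <- fully_connected_hypernetwork(nodes)
    params <- urn_params(ps = ps, pc = pc, delta1 = d1, qs = qs)
    factory <- if (purpose == "redraw")
      function() assign_purposes(struct, d1)
    else function() { struct$purposes <- "RED"; struct }
    ens <- run_ensemble(factory, params, start, runs = runs,
                        base_seed = base_seed + (i - 1L) * runs)
    ana <- analytic_params(ps = ps, pc = pc,
                           delta = if (purpose == "redraw") d1 else 1,
                           q = qs)
    exp_share <- expected_share_recursion(nodes - B, B, start$red, ana)
    analytic <- exp_share$expected_share[nrow(exp_share)]
    st <- ensemble_stats(ens)
    tibble(delta1 = d1, analytic = analytic, simulated = st$mean_red,
           se = st$se_red, z = (st$mean_red - analytic) / st$se_red)
  })
  class(out) <- c("urn_comparison", class(out))
  out
}
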