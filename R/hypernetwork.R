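#' Construct a hypernetwork
#'
#' A hypernetwork represents a population of individuals (nodes) organised
#' into groups (hyperedges): each hyperedge is a set of node ids and may
#' carry a *purpose* — the group norm colour that conforming members adopt.
#' Nodes are 1-based contiguous integers `1..node_count`.
#'
#' @param node_count Number of individuals (positive integer).
#' @param hyperedges List of integer vectors; each vector is one hyperedge's
#'   distinct member node ids.
#' @param purposes Optional character vector, one of `"RED"`/`"BLUE"` per
#'   hyperedge; `NULL` while norms have not been assigned yet (see
#'   [assign_purposes()]).
#' @param uniform_size Optional integer; when set, every hyperedge must have
#'   exactly this many members (a *uniform* hypernetwork).
#'
#' @return An object of class `hypernetwork`.
#' @seealso [generate_uniform_hypernetwork()], [assign_purposes()],
#'   [hn_neighbors()], [read_hypernetwork()]
#' @export
#' @examples
#' hn <- hypernetwork(5, list(c(1, 2, 3), c(3, 4, 5)), c("RED", "BLUE"))
#' hn_neighbors(hn, 3)
hypernetwork <- function(node_count, hyperedges, purposes = NULL,
                         uniform_size = NULL) {
  node_count <- check_count(node_count, "node_count", min = 1L)
  if (!is.list(hyperedges) || length(hyperedges) == 0L) {
    abort("`hyperedges` must be a non-empty list of integer vectors.",
          class = "hyperurn_invalid_hypernetwork")
  }
  hyperedges <- lapply(hyperedges, function(e) as.integer(e))
  hn <- structure(
    list(node_count = node_count,
         hyperedges = hyperedges,
         purposes = purposes,
         uniform_size = if (!is.null(uniform_size))
           check_count(uniform_size, "uniform_size", 1L) else NULL),
    class = "hypernetwork")
  validate_hypernetwork(hn)
}

#' Validate hypernetwork invariants
#'
#' Checks that every hyperedge is a non-empty set of distinct in-range node
#' ids, that `purposes` (when present) has one colour label per hyperedge,
#' and that a declared `uniform_size` is respected. Nodes left uncovered by
#' every hyperedge are allowed but trigger a warning: such individuals have
#' no neighbours and no group norm, so they can only decide by preference.
#'
#' @param hn A `hypernetwork`.
#' @return `hn`, invisibly unchanged, or an error of class
#'   `hyperurn_invalid_hypernetwork`.
#' @export
validate_hypernetwork <- function(hn) {
  m <- hn$node_count
  for (i in seq_along(hn$hyperedges)) {
    e <- hn$hyperedges[[i]]
    if (length(e) == 0L)
      abort(sprintf("Hyperedge %d is empty.", i),
            class = "hyperurn_invalid_hypernetwork")
    if (anyNA(e) || any(e < 1L) || any(e > m))
      abort(sprintf("Hyperedge %d has node ids outside 1..%d.", i, m),
            class = "hyperurn_invalid_hypernetwork")
    if (anyDuplicated(e))
      abort(sprintf("Hyperedge %d contains duplicate node ids.", i),
            class = "hyperurn_invalid_hypernetwork")
    if (!is.null(hn$uniform_size) && length(e) != hn$uniform_size)
      abort(sprintf("Hyperedge %d has %d members but uniform_size is %d.",
                    i, length(e), hn$uniform_size),
            class = "hyperurn_invalid_hypernetwork")
  }
  if (!is.null(hn$purposes)) {
    if (length(hn$purposes) != length(hn$hyperedges))
      abort("`purposes` must have one entry per hyperedge.",
            class = "hyperurn_invalid_hypernetwork")
    if (!all(hn$purposes %in% URN_COLORS))
      abort("`purposes` entries must be \"RED\" or \"BLUE\".",
            class = "hyperurn_invalid_hypernetwork")
  }
  uncovered <- setdiff(seq_len(m), unique(unlist(hn$hyperedges)))
  if (length(uncovered) > 0L)
    warn(sprintf("%d node(s) belong to no hyperedge (e.g. node %d).",
                 length(uncovered), uncovered[1]))
  invisible(hn)
}

#' @export
print.hypernetwork <- function(x, ...) {
  sizes <- lengths(x$hyperedges)
  cat(sprintf("<hypernetwork> %d nodes, %d hyperedge(s), sizes %s\n",
              x$node_count, length(x$hyperedges),
              if (length(unique(sizes)) == 1L) paste0("all ", sizes[1])
              else paste0(min(sizes), "-", max(sizes))))
  if (!is.null(x$purposes))
    cat(sprintf("  purposes: %d RED / %d BLUE\n",
                sum(x$purposes == "RED"), sum(x$purposes == "BLUE")))
  else cat("  purposes: unassigned\n")
  invisible(x)
}

#' Tidy membership table of a hypernetwork
#'
#' @param x A `hypernetwork`.
#' @param ... Unused.
#' @return A tibble with one row per (hyperedge, member) pair: columns
#'   `edge`, `node`, and `purpose` (`NA` when norms are unassigned).
#' @export
as_tibble.hypernetwork <- function(x, ...) {
  tibble(
    edge = rep.int(seq_along(x$hyperedges), lengths(x$hyperedges)),
    node = unlist(x$hyperedges, use.names = FALSE),
    purpose = if (is.null(x$purposes)) NA_character_
              else rep.int(x$purposes, lengths(x$hyperedges)))
}

#' Neighbours of a node in a hypernetwork
#'
#' The neighbourhood of `node` is the union of all hyperedges containing it,
#' minus the node itself; a neighbour sharing several hyperedges with `node`
#' appears once.
#'
#' @param hn A `hypernetwork`.
#' @param node A single node id.
#' @return Sorted integer vector of neighbour ids (possibly empty).
#' @export
hn_neighbors <- function(hn, node) {
  node <- check_count(node, "node", 1L)
  if (node > hn$node_count)
    abort(sprintf("Unknown node id %d (node_count is %d).",
                  node, hn$node_count), class = "hyperurn_invalid_config")
  own <- hn$hyperedges[vapply(hn$hyperedges, function(e) node %in% e, logical(1))]
  sort(setdiff(unique(unlist(own)), node))
}

# per-node list of hyperedge ids (1-based); used by the engines
node_edge_index <- function(hn) {
  ne <- length(hn$hyperedges)
  idx <- vector("list", hn$node_count)
  for (e in seq_len(ne))
    for (v in hn$hyperedges[[e]]) idx[[v]] <- c(idx[[v]], e)
  lapply(idx, function(v) as.integer(v %||% integer(0)))
}

check_feasible_sizes <- function(node_count, edge_count, edge_size) {
  node_count <- check_count(node_count, "node_count", 1L)
  edge_count <- check_count(edge_count, "edge_count", 1L)
  edge_size <- check_count(edge_size, "edge_size", 1L)
  if (edge_size > node_count)
    abort(sprintf("edge_size (%d) exceeds node_count (%d).",
                  edge_size, node_count), class = "hyperurn_invalid_config")
  if (edge_count * edge_size < node_count)
    abort(sprintf(
      "Cannot cover %d nodes with %d hyperedge(s) of size %d.",
      node_count, edge_count, edge_size), class = "hyperurn_invalid_config")
  invisible(list(m = node_count, ne = edge_count, k = edge_size))
}

#' Generate a random uniform hypernetwork
#'
#' Draws a hypernetwork in which every hyperedge has exactly `edge_size`
#' distinct members and every node belongs to at least one hyperedge.
#' Membership is sampled in two passes: each node (in random order) first
#' claims one slot in a uniformly chosen hyperedge with spare capacity, then
#' the remaining slots of each hyperedge are filled uniformly at random from
#' the nodes not yet in it. This guarantees full coverage and the uniform
#' edge size while imposing as little extra structure as possible.
#'
#' @inheritParams hypernetwork
#' @param edge_count Number of hyperedges.
#' @param edge_size Members per hyperedge.
#' @param seed Optional integer; when given the draw is made under this seed
#'   (and is reproducible), leaving the ambient RNG state untouched.
#' @return A uniform `hypernetwork` with unassigned purposes.
#' @export
#' @examples
#' hn <- generate_uniform_hypernetwork(100, 15, 10, seed = 1)
#' hn
generate_uniform_hypernetwork <- function(node_count, edge_count, edge_size,
                                          seed = NULL) {
  sz <- check_feasible_sizes(node_count, edge_count, edge_size)
  with_opt_seed(seed, {
    slots <- rep.int(sz$k, sz$ne)
    members <- replicate(sz$ne, integer(0), simplify = FALSE)
    for (v in sample.int(sz$m)) {
      open <- which(slots > 0L)
      e <- open[sample.int(length(open), 1L)]
      members[[e]] <- c(members[[e]], v)
      slots[e] <- slots[e] - 1L
    }
    for (e in seq_len(sz$ne)) {
      if (slots[e] > 0L) {
        pool <- setdiff(seq_len(sz$m), members[[e]])
        members[[e]] <- c(members[[e]],
                          pool[sample.int(length(pool), slots[e])])
      }
    }
    hypernetwork(sz$m, members, uniform_size = sz$k)
  })
}

#' Generate a random uniform hypernetwork with controlled overlap
#'
#' Like [generate_uniform_hypernetwork()] but with an explicit marginal
#' multi-membership rate: every node is covered once, and each node is
#' independently flagged with probability `multi_membership_prob`; flagged
#' nodes are then used preferentially to fill the extra membership slots, so
#' that (slots permitting) a node ends up in two or more hyperedges with
#' approximately that probability. With `multi_membership_prob = 0` and
#' `edge_count * edge_size == node_count` the result is a partition.
#'
#' @inheritParams generate_uniform_hypernetwork
#' @param multi_membership_prob Probability in `[0, 1]` that a node belongs
#'   to two or more hyperedges (marginally; default 0.5).
#' @return A uniform `hypernetwork` with unassigned purposes.
#' @export
generate_overlapping_hypernetwork <- function(node_count, edge_count,
                                              edge_size,
                                              multi_membership_prob = 0.5,
                                              seed = NULL) {
  sz <- check_feasible_sizes(node_count, edge_count, edge_size)
  p_multi <- check_prob(multi_membership_prob, "multi_membership_prob")
  with_opt_seed(seed, {
    slots <- rep.int(sz$k, sz$ne)
    members <- replicate(sz$ne, integer(0), simplify = FALSE)
    # pass 1: coverage
    for (v in sample.int(sz$m)) {
      open <- which(slots > 0L)
      e <- open[sample.int(length(open), 1L)]
      members[[e]] <- c(members[[e]], v)
      slots[e] <- slots[e] - 1L
    }
    flagged <- which(runif(sz$m) < p_multi)
    # pass 2a: one extra membership per flagged node while slots remain
    for (v in sample(flagged)) {
      open <- which(slots > 0L &
                    !vapply(members, function(mm) v %in% mm, logical(1)))
      if (length(open) == 0L) next
      e <- open[sample.int(length(open), 1L)]
      members[[e]] <- c(members[[e]], v)
      slots[e] <- slots[e] - 1L
    }
    # pass 2b: leftover slots, flagged nodes first, then anyone eligible
    for (e in seq_len(sz$ne)) {
      while (slots[e] > 0L) {
        pool <- setdiff(flagged, members[[e]])
        if (length(pool) == 0L) pool <- setdiff(seq_len(sz$m), members[[e]])
        v <- pool[sample.int(length(pool), 1L)]
        members[[e]] <- c(members[[e]], v)
        slots[e] <- slots[e] - 1L
      }
    }
    hypernetwork(sz$m, members, uniform_size = sz$k)
  })
}

#' The fully-connected comparison network
#'
#' A single hyperedge containing every node: the mean-field case in which
#' each individual can observe all decided individuals and there is one
#' group norm for the whole population.
#'
#' @inheritParams hypernetwork
#' @param purpose Optional single colour for the one hyperedge.
#' @return A `hypernetwork` with one hyperedge of all nodes.
#' @export
fully_connected_hypernetwork <- function(node_count, purpose = NULL) {
  node_count <- check_count(node_count, "node_count", 1L)
  hypernetwork(node_count, list(seq_len(node_count)),
               purposes = purpose, uniform_size = node_count)
}

#' Assign group norms to hyperedges
#'
#' Each hyperedge independently receives purpose `"RED"` with probability
#' `delta1` and `"BLUE"` otherwise.
#'
#' @param hn A `hypernetwork`.
#' @param delta1 Probability in `[0, 1]` that a hyperedge's norm is RED.
#' @inheritParams generate_uniform_hypernetwork
#' @return `hn` with its `purposes` field replaced by a fresh draw.
#' @export
assign_purposes <- function(hn, delta1, seed = NULL) {
  delta1 <- check_prob(delta1, "delta1")
  hn$purposes <- with_opt_seed(seed, {
    ifelse(runif(length(hn$hyperedges)) < delta1, "RED", "BLUE")
  })
  hn
}

#' Read / write a hypernetwork in the package JSON dialect
#'
#' The on-disk dialect is
#' `{"node_count": n, "hyperedges": [[...], ...], "purposes": [...]}` with
#' 0-based node ids and order-preserving arrays; `purposes` may be absent.
#' In-memory objects use 1-based ids; the shift happens here.
#'
#' @param path File path.
#' @return `read_hypernetwork()` returns a validated `hypernetwork`;
#'   `write_hypernetwork()` returns `path` invisibly.
#' @export
read_hypernetwork <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$node_count) || is.null(doc$hyperedges))
    abort("File is not in the hypernetwork JSON dialect.",
          class = "hyperurn_invalid_hypernetwork")
  hypernetwork(
    node_count = doc$node_count,
    hyperedges = lapply(doc$hyperedges,
                        function(e) as.integer(unlist(e)) + 1L),
    purposes = if (!is.null(doc$purposes))
      as.character(unlist(doc$purposes)) else NULL)
}

#' @param hn A `hypernetwork`.
#' @rdname read_hypernetwork
#' @export
write_hypernetwork <- function(hn, path) {
  validate_hypernetwork(hn)
  doc <- list(node_count = jsonlite::unbox(hn$node_count),
              hyperedges = lapply(hn$hyperedges, function(e) e - 1L))
  if (!is.null(hn$purposes)) doc$purposes <- hn$purposes
  jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
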