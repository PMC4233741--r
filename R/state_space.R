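# State space of the mutant-invasion Markov chain. A configuration is the
# set of mutant-occupied nodes, encoded as a bit mask (bit i = node i). The
# empty and the full configuration are the two absorbing states; everything
# else is transient. The space can be collapsed by graph-automorphism orbits
# (configurations related by a symmetry of the graph are dynamically
# equivalent) and restricted to states reachable from single-mutant starts.

popcount <- function(masks) {
  counts <- integer(length(masks))
  x <- as.integer(masks)
  while (any(x > 0L)) {
    counts <- counts + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  counts
}

mask_nodes <- function(mask, n) which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L) - 1L

nodes_mask <- function(nodes) {
  if (!length(nodes)) return(0L)
  sum(bitwShiftL(1L, as.integer(nodes)))
}

# image of a configuration mask under a 0-based node permutation
permute_mask <- function(mask, perm) {
  n <- length(perm)
  bits <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
  nodes_mask(perm[bits])
}

#' The automorphism group of a small graph
#'
#' Brute force over all `n!` node permutations, keeping those that map the
#' edge set onto itself. The identity is always included. These symmetries
#' justify collapsing mutant configurations into orbit states: dynamics from
#' two configurations related by an automorphism are identical.
#'
#' @param graph An [evograph()] object with at most 8 nodes.
#' @return List of 0-based permutation vectors (`perm[i + 1]` is the image
#'   of node `i`).
#' @examples
#' length(graph_automorphisms(make_named_graph("diamond")))  # 4
#' @export
graph_automorphisms <- function(graph) {
  n <- graph$n_nodes
  if (n > 8L) stop("brute-force automorphism search is limited to n <= 8")
  key <- edge_key(graph$edges, n)
  keep <- list()
  for (p in all_permutations(n)) {
    perm <- p - 1L
    if (identical(edge_key(permute_edges(graph$edges, perm), n), key)) {
      keep[[length(keep) + 1L]] <- perm
    }
  }
  keep
}

new_state_space <- function(graph, states, reduced, pruned) {
  reps <- vapply(states, min, integer(1))
  counts <- popcount(reps)
  # canonical order: ascending mutant count, then ascending representative
  # mask, transient states first, absorbing (extinction, fixation) last
  full <- bitwShiftL(1L, graph$n_nodes) - 1L
  absorbing <- reps %in% c(0L, full)
  ord <- order(absorbing, counts, reps)
  states <- states[ord]
  reps <- reps[ord]
  counts <- counts[ord]
  state_of <- rep(NA_integer_, bitwShiftL(1L, graph$n_nodes))
  for (i in seq_along(states)) state_of[states[[i]] + 1L] <- i
  structure(
    list(graph = graph, states = states, reps = reps,
         orbit_sizes = lengths(states), mutant_counts = counts,
         n_states = length(states), t = length(states) - 2L, a = 2L,
         state_of = state_of, reduced = reduced, pruned = pruned),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf(
    "state_space on %d-node graph: %d states (%d transient, %d absorbing)%s%s\n",
    x$graph$n_nodes, x$n_states, x$t, x$a,
    if (x$reduced) ", symmetry-reduced" else "",
    if (x$pruned) ", reachability-pruned" else ""))
  print(state_table(x))
  invisible(x)
}

#' Tabulate the states of a state space
#'
#' @param space A [full_state_space()] (possibly reduced/pruned) object.
#' @return A data frame with one row per state: representative occupancy
#'   (mutant node labels), mutant count, orbit size, and whether the state
#'   is absorbing.
#' @export
state_table <- function(space) {
  n <- space$graph$n_nodes
  full <- bitwShiftL(1L, n) - 1L
  data.frame(
    state = seq_len(space$n_states),
    occupancy = vapply(space$reps, function(m) {
      paste(mask_nodes(m, n), collapse = ",")
    }, character(1)),
    mutants = space$mutant_counts,
    orbit_size = space$orbit_sizes,
    absorbing = space$reps %in% c(0L, full)
  )
}

#' Enumerate all mutant configurations of a graph
#'
#' All `2^n` subsets of nodes, ordered by ascending mutant count then
#' ascending bit-mask value, with the two absorbing configurations
#' (all-wild-type extinction, all-mutant fixation) last, in that order.
#'
#' @param graph An [evograph()] object.
#' @param max_nodes Refuse graphs larger than this (the state space grows as
#'   `2^n`); default 16.
#' @return A `state_space` object with `reduced = FALSE`, `pruned = FALSE`.
#' @export
full_state_space <- function(graph, max_nodes = 16L) {
  n <- graph$n_nodes
  if (n > max_nodes) {
    stop("full state space has 2^", n, " configurations; raise max_nodes ",
         "only if you mean it")
  }
  masks <- 0:(bitwShiftL(1L, n) - 1L)
  new_state_space(graph, as.list(masks), reduced = FALSE, pruned = FALSE)
}

#' Collapse a state space by graph-automorphism orbits
#'
#' Configurations related by an automorphism of the graph form one orbit
#' state; the orbit's representative is its lexicographically smallest
#' configuration. On the four-node diamond this reduces 16 configurations
#' to 9 orbit states (7 transient), because only the hub/degree-2
#' distinction matters.
#'
#' @param space An unreduced `state_space`.
#' @param graph Optional graph (defaults to the one stored in `space`).
#' @return A `state_space` with `reduced = TRUE`.
#' @export
reduce_state_space <- function(space, graph = space$graph) {
  if (space$reduced) return(space)
  auts <- graph_automorphisms(graph)
  masks <- unlist(space$states)
  canon <- vapply(masks, function(m) {
    min(vapply(auts, function(p) permute_mask(m, p), integer(1)))
  }, integer(1))
  orbits <- split(masks, canon)
  orbits <- lapply(orbits, function(v) sort(as.integer(v)))
  new_state_space(graph, unname(orbits), reduced = TRUE, pruned = space$pruned)
}

#' Drop states unreachable from single-mutant starts
#'
#' Keeps the states reachable (with positive probability for some r > 0)
#' from at least one single-mutant configuration, plus both absorbing
#' states. Because the zero pattern of the transition probabilities does not
#' depend on r for r > 0, reachability is assessed at r = 1. On the ring of
#' four, the two-mutant configuration with the mutants on opposite nodes is
#' unreachable -- invading mutants form a contiguous cluster -- so pruning
#' takes the ring's 6 orbit states down to 5.
#'
#' @param space A `state_space` (reduced or not).
#' @return A `state_space` with `pruned = TRUE`.
#' @export
prune_unreachable <- function(space) {
  graph <- space$graph
  n <- graph$n_nodes
  full <- bitwShiftL(1L, n) - 1L
  start_idx <- unique(space$state_of[bitwShiftL(1L, 0:(n - 1L)) + 1L])
  reach <- logical(space$n_states)
  queue <- start_idx
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    rep_mask <- space$reps[i]
    if (rep_mask %in% c(0L, full)) next
    succ <- step_distribution(graph, rep_mask, r = 1)
    for (j in unique(space$state_of[succ$masks + 1L])) {
      if (!reach[j]) {
        reach[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  reach[space$reps %in% c(0L, full)] <- TRUE
  new_state_space(graph, space$states[reach], reduced = space$reduced,
                  pruned = TRUE)
}

#' Build the working state space of a graph in one call
#'
#' Convenience wrapper: full enumeration, then symmetry reduction, then
#' reachability pruning -- the representation used by all downstream exact
#' calculations.
#'
#' @param graph An [evograph()] object.
#' @param reduce Collapse by automorphism orbits?
#' @param prune Drop states unreachable from single-mutant starts?
#' @return A `state_space`.
#' @examples
#' moran_state_space(make_named_graph("ring"))$n_states     # 5
#' moran_state_space(make_named_graph("diamond"))$n_states  # 9
#' @export
moran_state_space <- function(graph, reduce = TRUE, prune = TRUE) {
  space <- full_state_space(graph)
  if (reduce) space <- reduce_state_space(space)
  if (prune) space <- prune_unreachable(space)
  space
}

#' Indices of the single-mutant states of a space
#'
#' @param space A `state_space`.
#' @return Integer vector of state indices whose representative has exactly
#'   one mutant.
#' @export
single_mutant_states <- function(space) {
  which(space$mutant_counts == 1L & !(space$reps %in%
    c(0L, bitwShiftL(1L, space$graph$n_nodes) - 1L)))
}
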