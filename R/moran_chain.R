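# Exact one-step transition probabilities of the birth-death Moran process
# on a graph, and assembly of the canonical-form transition matrix blocks
# [Q | R] over a (possibly orbit-reduced) state space.
#
# Update rule: one individual is chosen for birth with probability
# proportional to its fitness (mutants have fitness r, wild-types 1); its
# offspring replaces a uniformly chosen neighbour. Replacement of like by
# like leaves the configuration unchanged, so the chain has a positive
# staying probability in every transient state.

#' One-step successor distribution of a mutant configuration
#'
#' With mutant set S of size m on an n-node graph, total fitness is
#' W = r m + (n - m). A wild-type node j becomes mutant with probability
#' sum over its mutant neighbours k of (r / W) (1 / deg(k)); a mutant node v
#' is lost with probability sum over its wild-type neighbours k of
#' (1 / W) (1 / deg(k)). The residual probability is spent staying put.
#' The two absorbing configurations map to themselves with probability 1.
#'
#' @param graph An [evograph()] object.
#' @param config Mutant configuration as a bit mask (bit i = node i mutant),
#'   or a vector of mutant node labels via [nodes_to_config()].
#' @param r Mutant relative fitness, r > 0.
#' @return A list with `masks` (successor configuration masks, the current
#'   one included when the staying probability is positive) and `probs`
#'   (matching probabilities, summing to 1).
#' @export
step_distribution <- function(graph, config, r) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("r must be > 0")
  n <- graph$n_nodes
  mask <- as.integer(config)
  full <- bitwShiftL(1L, n) - 1L
  if (mask == 0L || mask == full) {
    return(list(masks = mask, probs = 1))
  }
  is_mut <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L
  m <- sum(is_mut)
  W <- r * m + (n - m)
  deg <- graph$degree
  masks <- integer(0); probs <- numeric(0)
  for (v in 0:(n - 1L)) {
    nb <- graph$adj[[v + 1L]]
    if (is_mut[v + 1L]) {
      # mutant v is lost when a wild-type neighbour reproduces into it
      wild_nb <- nb[!is_mut[nb + 1L]]
      if (length(wild_nb)) {
        p <- sum(1 / (W * deg[wild_nb + 1L]))
        masks <- c(masks, bitwAnd(mask, bitwNot(bitwShiftL(1L, v))))
        probs <- c(probs, p)
      }
    } else {
      # wild-type v is gained when a mutant neighbour reproduces into it
      mut_nb <- nb[is_mut[nb + 1L]]
      if (length(mut_nb)) {
        p <- sum(r / (W * deg[mut_nb + 1L]))
        masks <- c(masks, bitwOr(mask, bitwShiftL(1L, v)))
        probs <- c(probs, p)
      }
    }
  }
  stay <- 1 - sum(probs)
  list(masks = c(masks, mask), probs = c(probs, stay))
}

#' Convert mutant node labels to a configuration mask
#'
#' @param nodes Vector of 0-based mutant node labels (may be empty).
#' @return Integer bit mask.
#' @export
nodes_to_config <- function(nodes) nodes_mask(nodes)

#' Canonical-form transition blocks of the Moran chain
#'
#' Orders the chain's states transient-first and returns the transient-to-
#' transient block `Q` (t x t) and the transient-to-absorbing block `R`
#' (t x 2, columns extinction then fixation), so that the full transition
#' matrix is `[Q R; 0 I]`. On a reduced space the probability from orbit A
#' to orbit B is the total step probability from a representative of A into
#' all members of B; by construction this is representative-independent
#' (the orbits are lumpable), which is verified when `check = TRUE`.
#'
#' @param graph An [evograph()] object.
#' @param space A `state_space` for `graph` (any combination of reduced /
#'   pruned); defaults to [moran_state_space()].
#' @param r Mutant relative fitness, r > 0.
#' @param check Verify row-stochasticity and, on reduced spaces, that every
#'   orbit member yields the same aggregated row (tolerance 1e-12).
#' @return A `canonical_chain` object: list with `Q`, `R`, `space`, `r`;
#'   `R`'s columns are named `extinction` and `fixation`.
#' @examples
#' ch <- build_canonical_chain(make_named_graph("ring"), r = 2)
#' ch$Q  # 3 x 3; staying probability in the two-mutant state is 1/2
#' @export
build_canonical_chain <- function(graph, space = moran_state_space(graph), r,
                                  check = TRUE) {
  t_n <- space$t
  Q <- matrix(0, t_n, t_n)
  R <- matrix(0, t_n, 2L, dimnames = list(NULL, c("extinction", "fixation")))
  full <- bitwShiftL(1L, graph$n_nodes) - 1L
  # absorbing states sit at indices t+1 (extinction) and t+2 (fixation)
  stopifnot(space$reps[t_n + 1L] == 0L, space$reps[t_n + 2L] == full)
  row_from_mask <- function(mask) {
    sd <- step_distribution(graph, mask, r)
    idx <- space$state_of[sd$masks + 1L]
    if (anyNA(idx)) {
      stop("transition into a state missing from the space; the space was ",
           "pruned against a different chain")
    }
    qrow <- numeric(t_n); rrow <- numeric(2L)
    for (k in seq_along(idx)) {
      j <- idx[k]
      if (j <= t_n) qrow[j] <- qrow[j] + sd$probs[k]
      else rrow[j - t_n] <- rrow[j - t_n] + sd$probs[k]
    }
    list(q = qrow, r = rrow)
  }
  for (i in seq_len(t_n)) {
    row <- row_from_mask(space$reps[i])
    Q[i, ] <- row$q
    R[i, ] <- row$r
    if (check && space$orbit_sizes[i] > 1L) {
      for (member in setdiff(space$states[[i]], space$reps[i])) {
        alt <- row_from_mask(member)
        if (max(abs(alt$q - row$q)) > 1e-12 ||
            max(abs(alt$r - row$r)) > 1e-12) {
          stop("orbit aggregation is representative-dependent (state ", i,
               "): the reduction is not lumpable")
        }
      }
    }
  }
  if (check) {
    rs <- rowSums(Q) + rowSums(R)
    if (max(abs(rs - 1)) > 1e-12) stop("rows of [Q | R] do not sum to 1")
  }
  structure(list(Q = Q, R = R, space = space, r = r),
            class = "canonical_chain")
}

#' @export
print.canonical_chain <- function(x, ...) {
  cat(sprintf("canonical_chain: %d transient states, r = %g\n",
              nrow(x$Q), x$r))
  invisible(x)
}

#' Well-mixed Moran transition probabilities
#'
#' For i mutants among N individuals the probability to go up one is
#' `r i / (r i + N - i) * (N - i) / (N - 1)` and to go down one is
#' `(N - i) / (r i + N - i) * i / (N - 1)`; their ratio is 1/r at every
#' interior state. The boundaries i = 0 and i = N are absorbing (both
#' probabilities 0). The 1/(N - 1) factor reflects that the offspring
#' replaces one of the parent's N - 1 neighbours on the complete graph,
#' never the parent itself, so these formulas coincide exactly with
#' [step_distribution()] on the complete network.
#'
#' @param N Population size, `N >= 2`.
#' @param i Current number of mutants, `0 <= i <= N`.
#' @param r Mutant relative fitness, r > 0.
#' @return Named numeric vector `c(up = , down = )`.
#' @export
wellmixed_transitions <- function(N, i, r) {
  if (!is.numeric(r) || r <= 0) stop("r must be > 0")
  if (i < 0 || i > N) stop("i must lie in 0..N")
  if (i == 0 || i == N) return(c(up = 0, down = 0))
  W <- r * i + (N - i)
  c(up = (r * i / W) * ((N - i) / (N - 1)),
    down = ((N - i) / W) * (i / (N - 1)))
}
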