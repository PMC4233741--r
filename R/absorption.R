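# Solving the absorbing Markov chain. With the canonical blocks Q and R,
# the fundamental matrix F = (I - Q)^-1 holds the expected unconditional
# sojourn times F[i, j] (time spent in transient state j starting from i);
# Phi = F R gives the absorption probabilities; summing row i of F gives the
# unconditional fixation time. The conditional sojourn times, given that
# the mutants eventually fixate, follow from the unconditional ones as
# T_cond[i, j] = F[i, j] * Phi[j, fix] / Phi[i, fix], and their row sums are
# the conditional fixation times.

#' Solve an absorbing Moran chain
#'
#' Computes the fundamental matrix, the absorption (extinction/fixation)
#' probabilities, and unconditional and conditional fixation and sojourn
#' times for every transient starting state. The linear system
#' `(I - Q) F = I` is solved by a single LU factorisation, never by forming
#' the inverse explicitly being the point -- `solve()` with a matrix
#' right-hand side.
#'
#' @param chain A [build_canonical_chain()] object.
#' @return An `absorption_result`: list with `F` (unconditional sojourn
#'   times), `Phi` (t x 2, columns extinction/fixation), `tau_unc`,
#'   `T_cond` (conditional sojourn times given fixation), `tau_cond`,
#'   `space`, and `r`.
#' @examples
#' ch <- build_canonical_chain(make_named_graph("complete"), r = 1)
#' solve_chain(ch)$tau_cond[1]  # 9 steps from a single mutant
#' @export
solve_chain <- function(chain) {
  Q <- chain$Q
  t_n <- nrow(Q)
  Fm <- tryCatch(solve(diag(t_n) - Q),
                 error = function(e) {
                   stop("(I - Q) is singular: absorption is not certain, ",
                        "the chain is malformed")
                 })
  Phi <- Fm %*% chain$R
  colnames(Phi) <- c("extinction", "fixation")
  tau_unc <- rowSums(Fm)
  pfix <- Phi[, "fixation"]
  if (any(pfix <= 0)) {
    stop("zero fixation probability from a transient state; the graph is ",
         "not connected or r <= 0")
  }
  T_cond <- Fm * rep(pfix, each = t_n) / pfix  # F[i,j] phi_j / phi_i
  tau_cond <- rowSums(T_cond)
  structure(
    list(F = Fm, Phi = Phi, tau_unc = tau_unc,
         T_cond = T_cond, tau_cond = tau_cond,
         space = chain$space, r = chain$r),
    class = "absorption_result"
  )
}

#' @export
print.absorption_result <- function(x, ...) {
  cat(sprintf("absorption_result: %d transient states, r = %g\n",
              nrow(x$F), x$r))
  sm <- single_mutant_states(x$space)
  cat("single-mutant starts:\n")
  print(data.frame(state = sm,
                   fixation_prob = x$Phi[sm, "fixation"],
                   tau_unconditional = x$tau_unc[sm],
                   tau_conditional = x$tau_cond[sm]))
  invisible(x)
}

#' Closed-form fixation probability in a well-mixed population
#'
#' For i mutants of relative fitness r among N individuals,
#' `phi = (1 - r^-i) / (1 - r^-N)`, with the continuous extension
#' `phi = i / N` at r = 1. This is the standard birth-death result and the
#' exact value on the complete graph (and, by the isothermal theorem, on
#' every regular graph).
#'
#' @param N Population size.
#' @param r Mutant relative fitness, r > 0 (vectorised).
#' @param i Initial number of mutants (default 1).
#' @return Fixation probability (vectorised over `r`).
#' @export
fixation_probability_wellmixed <- function(N, r, i = 1) {
  if (any(r <= 0)) stop("r must be > 0")
  if (any(i < 1) || any(i > N)) stop("i must lie in 1..N")
  k <- max(length(r), length(i))
  r <- rep_len(r, k); i <- rep_len(i, k)
  ifelse(abs(r - 1) < 1e-12, i / N, (1 - r^(-i)) / (1 - r^(-N)))
}

#' Closed-form conditional fixation time in a well-mixed population
#'
#' Expected number of birth-death steps for a single mutant to fixate,
#' conditioned on fixation, in the well-mixed (complete-graph) Moran
#' process. Uses the standard one-dimensional birth-death chain sum over
#' the up/down transition probabilities -- an independent route from the
#' matrix machinery of [solve_chain()], against which it agrees to
#' numerical precision.
#'
#' @param N Population size.
#' @param r Mutant relative fitness, r > 0.
#' @return Conditional fixation time in steps.
#' @export
conditional_time_wellmixed <- function(N, r) {
  if (r <= 0) stop("r must be > 0")
  up <- vapply(1:(N - 1), function(i) wellmixed_transitions(N, i, r)["up"],
               numeric(1))
  phi <- fixation_probability_wellmixed(N, r, i = 1:(N - 1))
  gamma <- 1 / r  # down/up ratio, constant over interior states
  total <- 0
  for (k in 1:(N - 1)) {
    for (l in 1:k) {
      total <- total + (phi[l] / up[l]) * gamma^(k - l)
    }
  }
  total
}

#' Average absorption quantities over a uniform single-mutant start
#'
#' The first mutant arises on a uniformly chosen node, so each single-mutant
#' orbit is weighted by its orbit size divided by n (on the diamond: 1/2 on
#' the hub orbit, 1/2 on the degree-2 orbit; on the star with n = 4: 1/4
#' centre, 3/4 leaf).
#'
#' @param result An [solve_chain()] result on a reduced space.
#' @return List with `weights` (named by state index), `fixation_prob`,
#'   `tau_unc`, `tau_cond` (start-averaged; the conditional time is the
#'   weighted mean of the per-start conditional times), and
#'   `sojourn_cond` (start-averaged conditional sojourn time per transient
#'   state).
#' @export
start_averaged <- function(result) {
  space <- result$space
  sm <- single_mutant_states(space)
  w <- space$orbit_sizes[sm] / space$graph$n_nodes
  stopifnot(abs(sum(w) - 1) < 1e-12)
  list(
    weights = stats::setNames(w, sm),
    fixation_prob = sum(w * result$Phi[sm, "fixation"]),
    tau_unc = sum(w * result$tau_unc[sm]),
    tau_cond = sum(w * result$tau_cond[sm]),
    sojourn_cond = colSums(w * result$T_cond[sm, , drop = FALSE])
  )
}

#' Conditional sojourn times aggregated by mutant count
#'
#' Sums the start-averaged conditional sojourn times over all transient
#' states with the same number of mutants -- the decomposition that reveals
#' where an additional link delays fixation.
#'
#' @param result An [solve_chain()] result.
#' @return Named numeric vector indexed by mutant count `1..n-1`.
#' @export
sojourn_by_count <- function(result) {
  space <- result$space
  soj <- start_averaged(result)$sojourn_cond
  counts <- space$mutant_counts[seq_len(space$t)]
  out <- vapply(1:(space$graph$n_nodes - 1L),
                function(k) sum(soj[counts == k]), numeric(1))
  stats::setNames(out, 1:(space$graph$n_nodes - 1L))
}

#' Numerical strong-selection limit of an absorption-derived quantity
#'
#' Evaluates `quantity(r)` along an increasing fitness sequence and reports
#' the last value together with a convergence flag (successive differences
#' below `tol`). Used for the r -> Inf sojourn-time limits, where e.g. the
#' complete graph's per-count conditional sojourns approach
#' (1, 3/2, 3, ...) = (N-1)/(N-i).
#'
#' @param quantity Function of r returning a numeric scalar or vector.
#' @param r_sequence Increasing fitness values; default `10^(2:6)`.
#' @param tol Convergence tolerance on the successive difference.
#' @return List with `value` (at the largest r), `converged`, `history`.
#' @export
strong_selection_limit <- function(quantity, r_sequence = 10^(2:6),
                                   tol = 1e-4) {
  vals <- lapply(r_sequence, quantity)
  k <- length(vals)
  diff_last <- max(abs(vals[[k]] - vals[[k - 1L]]))
  list(value = vals[[k]], converged = diff_last < tol, history = vals)
}

#' Exact fixation analysis of a graph in one call
#'
#' Builds the reduced, pruned state space and the canonical chain at
#' fitness `r`, solves it, and returns the start-averaged summary alongside
#' the full per-state result.
#'
#' @param graph An [evograph()] object.
#' @param r Mutant relative fitness.
#' @param space Optional precomputed `state_space` (reuse across r values).
#' @return List with `result` (the [solve_chain()] output) and `summary`
#'   (the [start_averaged()] output).
#' @export
fixation_analysis <- function(graph, r, space = moran_state_space(graph)) {
  result <- solve_chain(build_canonical_chain(graph, space, r))
  list(result = result, summary = start_averaged(result))
}
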