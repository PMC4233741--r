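# Monte Carlo realisation of the birth-death Moran process. The inner loop
# lives in C++ (src/simulator.cpp) and draws from R's RNG, so set.seed /
# the `seed` argument make every estimate reproducible.

graph_csr <- function(graph) {
  deg <- graph$degree
  list(adj = as.integer(unlist(graph$adj)),
       adj_start = as.integer(c(0L, cumsum(deg))))
}

#' Simulate the Moran process once
#'
#' Runs a single realisation from one mutant on `start_node` until the
#' mutants fixate or go extinct. Every elementary birth-death event counts
#' one step, whether or not the configuration changes, matching the
#' discrete-time chain the exact solver models.
#'
#' @param graph An [evograph()] object.
#' @param r Mutant relative fitness, r > 0.
#' @param start_node 0-based node carrying the initial mutant.
#' @return List with `fixed` (logical) and `steps` (numeric).
#' @export
run_once <- function(graph, r, start_node) {
  if (r <= 0) stop("r must be > 0")
  if (start_node < 0 || start_node >= graph$n_nodes) stop("invalid start node")
  csr <- graph_csr(graph)
  out <- sim_moran_cpp(csr$adj, csr$adj_start, r, as.integer(start_node))
  list(fixed = out$fixed[1], steps = out$steps[1])
}

#' Monte Carlo estimate of fixation probability and fixation times
#'
#' Repeats the process `replicates` times and summarises: fixation
#' frequency, mean conditional fixation time (over fixation runs only),
#' mean unconditional absorption time, each with its standard error from
#' the sample variance of per-run times.
#'
#' @param graph An [evograph()] object.
#' @param r Mutant relative fitness, r > 0.
#' @param replicates Number of independent realisations.
#' @param start Either `"uniform"` (initial mutant on a uniformly random
#'   node, the default) or a single 0-based node label.
#' @param seed Optional integer seed; with the same seed (and arguments)
#'   the result is identical.
#' @return A `sim_result`: list with counts (`replicates`, `fixations`,
#'   `extinctions`), `fixation_prob` and `fixation_prob_se`, `tau_cond` and
#'   `tau_cond_se` (NA with `tau_cond_defined = FALSE` if no run fixated),
#'   `tau_unc` and `tau_unc_se`, plus `r`, `seed` and the graph descriptor.
#' @examples
#' simulate_fixation(make_named_graph("complete"), r = 2,
#'                   replicates = 2000, seed = 1)$fixation_prob
#' @export
simulate_fixation <- function(graph, r, replicates, start = "uniform",
                              seed = NULL) {
  if (r <= 0) stop("r must be > 0")
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n_nodes
  if (identical(start, "uniform")) {
    starts <- sample.int(n, replicates, replace = TRUE) - 1L
  } else {
    start <- as.integer(start)
    if (start < 0L || start >= n) stop("invalid start node")
    starts <- rep(start, replicates)
  }
  csr <- graph_csr(graph)
  out <- sim_moran_cpp(csr$adj, csr$adj_start, r, starts)
  fix <- out$fixed
  nf <- sum(fix)
  phat <- nf / replicates
  se_mean <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  structure(
    list(replicates = replicates, fixations = nf,
         extinctions = replicates - nf,
         fixation_prob = phat,
         fixation_prob_se = sqrt(phat * (1 - phat) / replicates),
         tau_cond = if (nf > 0L) mean(out$steps[fix]) else NA_real_,
         tau_cond_se = if (nf > 0L) se_mean(out$steps[fix]) else NA_real_,
         tau_cond_defined = nf > 0L,
         tau_unc = mean(out$steps),
         tau_unc_se = se_mean(out$steps),
         r = r, seed = seed,
         graph = if (is.null(graph$name)) "graph" else graph$name),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "sim_result [%s, r = %g, %d reps%s]\n  fixation prob %.4f (SE %.4f)\n  conditional time %s (SE %s)\n",
    x$graph, x$r, x$replicates,
    if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed),
    x$fixation_prob, x$fixation_prob_se,
    if (x$tau_cond_defined) sprintf("%.2f", x$tau_cond) else "undefined",
    if (x$tau_cond_defined) sprintf("%.3f", x$tau_cond_se) else "-"))
  invisible(x)
}
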