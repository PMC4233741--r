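# High-level analyses: amplifier classification, the fixation-time ordering
# under link removal, the diamond's sojourn-time and initial-placement
# crossovers, and the lattice simulation study.

default_r_grid <- function() c(0.25, 0.5, 0.8, 1.25, 2, 4)

#' Classify networks as amplifiers or suppressors of selection
#'
#' Compares the exact single-mutant fixation probability (uniform initial
#' placement) with the well-mixed value over a grid of fitness values
#' spanning both sides of neutrality. A graph is an amplifier if it is
#' strictly above the well-mixed value at every grid r > 1 and strictly
#' below at every r < 1, a suppressor for the reverse pattern, equivalent
#' if it matches everywhere to `tol` (the isothermal case), and `"none"`
#' otherwise.
#'
#' @param graphs Named list of [evograph()] objects.
#' @param r_grid Fitness grid excluding 1; default
#'   `c(0.25, 0.5, 0.8, 1.25, 2, 4)`.
#' @param tol Equality tolerance against the well-mixed value.
#' @return Data frame with one row per graph: `graph`, `class`, and the
#'   maximum deviation from the well-mixed probability.
#' @export
classify_amplifiers <- function(graphs, r_grid = default_r_grid(),
                                tol = 1e-9) {
  stopifnot(length(r_grid) > 0, all(r_grid > 0), all(abs(r_grid - 1) > tol))
  rows <- lapply(names(graphs), function(nm) {
    g <- graphs[[nm]]
    space <- moran_state_space(g)
    dev <- vapply(r_grid, function(r) {
      phi <- fixation_analysis(g, r, space)$summary$fixation_prob
      phi - fixation_probability_wellmixed(g$n_nodes, r)
    }, numeric(1))
    above <- dev > tol
    below <- dev < -tol
    hi <- r_grid > 1
    cls <- if (all(abs(dev) <= tol)) "equivalent"
    else if (all(above[hi]) && all(below[!hi])) "amplifier"
    else if (all(below[hi]) && all(above[!hi])) "suppressor"
    else "none"
    data.frame(graph = nm, class = cls, max_abs_deviation = max(abs(dev)))
  })
  do.call(rbind, rows)
}

#' Start-averaged conditional fixation times across graphs and fitness
#'
#' @param graphs Named list of [evograph()] objects.
#' @param r_grid Fitness values.
#' @return Data frame with columns `graph`, `r`, `fixation_prob`,
#'   `tau_cond` (uniform single-mutant start).
#' @export
fixation_time_table <- function(graphs, r_grid = default_r_grid()) {
  rows <- lapply(names(graphs), function(nm) {
    g <- graphs[[nm]]
    space <- moran_state_space(g)
    do.call(rbind, lapply(r_grid, function(r) {
      s <- fixation_analysis(g, r, space)$summary
      data.frame(graph = nm, r = r, fixation_prob = s$fixation_prob,
                 tau_cond = s$tau_cond)
    }))
  })
  do.call(rbind, rows)
}

# structural identification of the diamond's distinguished orbit states
diamond_states <- function(space) {
  g <- space$graph
  n <- g$n_nodes
  full <- bitwShiftL(1L, n) - 1L
  deg_of_rep_nodes <- function(mask) g$degree[mask_nodes(mask, n) + 1L]
  sm <- single_mutant_states(space)
  sm_deg <- vapply(space$reps[sm], function(m) deg_of_rep_nodes(m)[1],
                   numeric(1))
  three <- which(space$mutant_counts == 3L &
                   !(space$reps %in% c(0L, full)))
  wild_deg <- vapply(space$reps[three], function(m) {
    g$degree[mask_nodes(bitwAnd(bitwNot(m), full), n) + 1L]
  }, numeric(1))
  list(
    start_hub = sm[which.max(sm_deg)],        # one mutant on a degree-3 hub
    start_deg2 = sm[which.min(sm_deg)],       # one mutant on a degree-2 node
    three_wild_deg2 = three[which.min(wild_deg)],  # wild-type left on deg-2
    three_wild_hub = three[which.max(wild_deg)]
  )
}

find_crossover <- function(f, bracket, tol = 1e-8, label = c("a", "b")) {
  fa <- f(bracket[1]); fb <- f(bracket[2])
  if (sign(fa) == sign(fb)) {
    stop("no sign change of the curve difference in the bracket (",
         bracket[1], ", ", bracket[2], ")")
  }
  root <- stats::uniroot(f, bracket, tol = tol)
  structure(list(r_star = root$root, residual = root$f.root,
                 bracket = bracket, curves = label),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf("crossover of %s vs %s at r* = %.4f (residual %.2e)\n",
              x$curves[1], x$curves[2], x$r_star, x$residual))
  invisible(x)
}

#' Fitness at which the diamond's dominant sojourn state switches
#'
#' On the diamond, for neutral and weakly advantageous mutants the chain
#' spends most conditional sojourn time in a two-mutant state; for strongly
#' advantageous mutants the maximum moves to the three-mutant state whose
#' remaining wild-type sits on a degree-2 node (that wild-type is connected
#' to only two of the three mutants, so the mutants keep replacing each
#' other). This function identifies the neutral argmax state, verifies the
#' large-r argmax is the wild-on-degree-2 state, and locates the fitness at
#' which their start-averaged conditional sojourn curves cross.
#'
#' @param bracket Search interval for the crossover; default `c(1, 3)`.
#' @return A `crossover_result` with `r_star` (about 1.65), plus
#'   `argmax_neutral` and `argmax_high` (state indices) and the
#'   `state_table` of the diamond space.
#' @export
sojourn_crossover_diamond <- function(bracket = c(1, 3)) {
  g <- make_named_graph("diamond")
  space <- moran_state_space(g)
  ds <- diamond_states(space)
  soj <- function(r) fixation_analysis(g, r, space)$summary$sojourn_cond
  s_neutral <- soj(1)
  argmax_neutral <- which.max(s_neutral)
  stopifnot(space$mutant_counts[argmax_neutral] == 2L)
  s_high <- soj(bracket[2])
  argmax_high <- which.max(s_high)
  stopifnot(argmax_high == ds$three_wild_deg2)
  out <- find_crossover(
    function(r) {
      s <- soj(r)
      s[ds$three_wild_deg2] - s[argmax_neutral]
    },
    bracket,
    label = c("sojourn(3 mutants, wild-type on degree-2 node)",
              "sojourn(neutral argmax, a two-mutant state)")
  )
  out$argmax_neutral <- argmax_neutral
  out$argmax_high <- argmax_high
  out$state_table <- state_table(space)
  out
}

#' Fitness at which the best initial node of the diamond switches
#'
#' The diamond's two node classes give two single-mutant starting states.
#' For small r, a mutant starting on a degree-2 node takes longer to fixate
#' than one starting on a degree-3 hub; beyond a crossover fitness the
#' ordering flips and the hub start is (slightly) slower. Locates that
#' crossover of the two conditional fixation-time curves.
#'
#' @param bracket Search interval; default `c(2, 10)`.
#' @return A `crossover_result` with `r_star` (about 5.8) and the two
#'   per-start conditional times at a few reference fitness values.
#' @export
placement_crossover_diamond <- function(bracket = c(2, 10)) {
  g <- make_named_graph("diamond")
  space <- moran_state_space(g)
  ds <- diamond_states(space)
  times <- function(r) {
    res <- fixation_analysis(g, r, space)$result
    c(hub = res$tau_cond[ds$start_hub], deg2 = res$tau_cond[ds$start_deg2])
  }
  t1 <- times(1)
  stopifnot(t1["deg2"] > t1["hub"])  # deg-2 start slower for small r
  out <- find_crossover(
    function(r) { tt <- times(r); tt["deg2"] - tt["hub"] },
    bracket,
    label = c("tau_cond(start at degree-2 node)",
              "tau_cond(start at degree-3 hub)")
  )
  out$reference_times <- rbind(r1 = t1, r_star = times(out$r_star))
  out
}

#' Lattice simulation study: fixation time vs boundary conditions and links
#'
#' Simulates the conditional fixation time of a single mutant (uniform
#' start, fitness `r`) on three lattice variants per boundary type -- plain
#' square lattice, lattice with one diagonal per cell (the diamond-motif
#' tiling: a ring plus one chord), and lattice with both diagonals (Moore
#' neighbourhood) -- open and periodic, plus the complete graph of the same
#' size. Then checks, wherever the separation exceeds 3 pooled standard
#' errors: (i) each periodic lattice fixes faster than its open
#' counterpart; (ii) among the periodic (isothermal) lattices, dropping
#' links increases the fixation time (both diagonals < one diagonal <
#' plain, in time); (iii) among open lattices, *adding* one diagonal per
#' cell increases the fixation time even though it adds links -- the
#' counterintuitive effect, the large-lattice analogue of the
#' diamond-vs-ring comparison; (iv) every lattice is slower than the
#' complete graph. Comparisons without sufficient separation are reported
#' as `NA` with a warning rather than failed.
#'
#' @param sides Lattice side lengths; default `4:7` (populations 16..49).
#' @param r Mutant fitness; default 2.
#' @param replicates Realisations per network; default `10000`.
#' @param seed Integer seed for reproducibility.
#' @return List with `table` (one row per network and size: estimates and
#'   standard errors) and `assertions` (one row per ordering check:
#'   `side`, `check`, `holds`, `separation_se`).
#' @export
lattice_experiment <- function(sides = 4:7, r = 2, replicates = 10000,
                               seed = NULL) {
  stopifnot(all(sides >= 3))
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); asserts <- list()
  for (side in sides) {
    n <- side * side
    nets <- list(
      open = make_lattice(side),
      open_diag1 = make_lattice(side, diagonals = "single"),
      open_diag2 = make_lattice(side, diagonals = "both"),
      periodic = make_lattice(side, periodic = TRUE),
      periodic_diag1 = make_lattice(side, periodic = TRUE,
                                    diagonals = "single"),
      periodic_diag2 = make_lattice(side, periodic = TRUE,
                                    diagonals = "both"),
      complete = make_named_graph("complete", n)
    )
    est <- lapply(nets, simulate_fixation, r = r, replicates = replicates)
    for (nm in names(est)) {
      e <- est[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, n = n, network = nm, replicates = e$replicates,
        fixation_prob = e$fixation_prob,
        fixation_prob_se = e$fixation_prob_se,
        tau_cond = e$tau_cond, tau_cond_se = e$tau_cond_se)
    }
    cmp <- function(check, slower, faster) {
      d <- est[[slower]]$tau_cond - est[[faster]]$tau_cond
      se <- sqrt(est[[slower]]$tau_cond_se^2 + est[[faster]]$tau_cond_se^2)
      holds <- if (abs(d) > 3 * se) d > 0 else NA
      if (is.na(holds)) {
        warning(sprintf(
          "side %d, %s: separation %.2f below 3 pooled SE (%.2f); not assessed",
          side, check, d, 3 * se), call. = FALSE)
      }
      asserts[[length(asserts) + 1L]] <<- data.frame(
        side = side, check = check, holds = holds, separation_se = d / se)
    }
    cmp("periodic faster than open (plain)", "open", "periodic")
    cmp("periodic faster than open (one diagonal)",
        "open_diag1", "periodic_diag1")
    cmp("periodic faster than open (both diagonals)",
        "open_diag2", "periodic_diag2")
    cmp("dropping diagonals slows periodic lattices",
        "periodic", "periodic_diag1")
    cmp("dropping more links slows periodic lattices further",
        "periodic_diag1", "periodic_diag2")
    cmp("adding one diagonal per cell slows open lattices",
        "open_diag1", "open")
    for (nm in setdiff(names(nets), "complete")) {
      cmp(sprintf("%s lattice slower than complete", nm), nm, "complete")
    }
  }
  list(table = do.call(rbind, rows), assertions = do.call(rbind, asserts))
}
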