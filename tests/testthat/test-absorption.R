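solve_graph <- function(name, r, n = 4) {
  g <- make_named_graph(name, n)
  solve_chain(build_canonical_chain(g, moran_state_space(g), r))
}

test_that("neutral conditional times and sojourns on complete graph and ring", {
  resc <- solve_graph("complete", 1)
  expect_equal(resc$tau_cond[1], 9, tolerance = 1e-10)
  expect_equal(unname(sojourn_by_count(resc)), c(3, 3, 3), tolerance = 1e-10)

  resr <- solve_graph("ring", 1)
  expect_equal(resr$tau_cond[1], 10, tolerance = 1e-10)
  sojr <- sojourn_by_count(resr)
  # the ring prolongs only the two-mutant sojourn, by exactly one step
  expect_equal(unname(sojr), c(3, 4, 3), tolerance = 1e-10)
})

test_that("absorption probabilities behave like probabilities", {
  for (name in c("complete", "ring", "diamond", "star", "shovel", "line")) {
    for (r in c(0.3, 1, 2)) {
      res <- solve_graph(name, r)
      expect_equal(unname(rowSums(res$Phi)), rep(1, nrow(res$Phi)),
                   tolerance = 1e-12)
      expect_true(all(res$Phi >= 0))
      expect_true(all(res$F >= 0))
      expect_true(all(is.finite(res$tau_cond)))
    }
  }
})

test_that("neutral fixation probability is 1/n on regular graphs", {
  for (g in list(make_named_graph("complete"), make_named_graph("ring", 5),
                 make_lattice(3, periodic = TRUE))) {
    res <- solve_chain(build_canonical_chain(
      g, moran_state_space(g, reduce = g$n_nodes <= 8), 1))
    sm <- single_mutant_states(res$space)
    expect_equal(unname(res$Phi[sm, "fixation"]),
                 rep(1 / g$n_nodes, length(sm)), tolerance = 1e-12)
  }
})

test_that("closed-form well-mixed fixation probability matches the matrix solve", {
  expect_equal(fixation_probability_wellmixed(4, 1), 0.25)
  expect_equal(fixation_probability_wellmixed(4, 2), 8 / 15, tolerance = 1e-12)
  for (N in 3:6) {
    sp <- moran_state_space(make_named_graph("complete", N))
    for (r in c(0.25, 0.8, 1, 1.3, 4)) {
      res <- solve_graph("complete", r, n = N)
      expect_equal(unname(res$Phi[1, "fixation"]),
                   fixation_probability_wellmixed(N, r), tolerance = 1e-9)
    }
  }
  expect_error(fixation_probability_wellmixed(4, -1), "r must")
})

test_that("closed-form conditional time matches the matrix solve to 1e-9", {
  for (N in c(3, 4, 6)) {
    for (r in c(0.25, 0.5, 1, 2, 5, 10)) {
      expect_equal(conditional_time_wellmixed(N, r),
                   solve_graph("complete", r, n = N)$tau_cond[1],
                   tolerance = 1e-9)
    }
  }
  expect_equal(conditional_time_wellmixed(4, 1), 9, tolerance = 1e-12)
  # strong-selection limit: sum over i of (N-1)/(N-i) = 1 + 3/2 + 3
  expect_equal(conditional_time_wellmixed(4, 1e7), 5.5, tolerance = 1e-5)
})

test_that("independent value-iteration oracle confirms fixation probabilities", {
  set.seed(5)
  for (g in c(list(make_named_graph("diamond"), make_named_graph("shovel")),
              list(random_connected_graph(5)))) {
    sp <- moran_state_space(g)
    for (r in c(0.5, 2)) {
      res <- solve_chain(build_canonical_chain(g, sp, r))
      sm <- single_mutant_states(sp)
      for (i in sm) {
        expect_equal(unname(res$Phi[i, "fixation"]),
                     fixation_prob_oracle(g, r, sp$reps[i]),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("full and symmetry-reduced chains agree (lumpability)", {
  set.seed(9)
  graphs <- c(all_named_motifs(),
              list(rand5 = random_connected_graph(5),
                   rand6 = random_connected_graph(6)))
  for (g in graphs) {
    full_sp <- prune_unreachable(full_state_space(g))
    red_sp <- moran_state_space(g)
    for (r in c(0.5, 1, 2)) {
      res_f <- solve_chain(build_canonical_chain(g, full_sp, r))
      res_r <- solve_chain(build_canonical_chain(g, red_sp, r))
      # per-config quantities equal their orbit's
      for (i in single_mutant_states(red_sp)) {
        members <- red_sp$states[[i]]
        idx <- full_sp$state_of[members + 1L]
        expect_equal(unname(res_f$Phi[idx, "fixation"]),
                     rep(unname(res_r$Phi[i, "fixation"]), length(idx)),
                     tolerance = 1e-10)
        expect_equal(unname(res_f$tau_cond[idx]),
                     rep(res_r$tau_cond[i], length(idx)), tolerance = 1e-8)
      }
      expect_equal(start_averaged(res_f)$tau_cond,
                   start_averaged(res_r)$tau_cond, tolerance = 1e-8)
    }
  }
})

test_that("isothermal theorem: ring and complete graph have equal fixation probabilities", {
  spc <- moran_state_space(make_named_graph("complete"))
  spr <- moran_state_space(make_named_graph("ring"))
  for (r in c(0.1, 0.5, 1, 2, 10)) {
    pc <- solve_chain(build_canonical_chain(make_named_graph("complete"), spc, r))
    pr <- solve_chain(build_canonical_chain(make_named_graph("ring"), spr, r))
    expect_equal(unname(pr$Phi[1, "fixation"]), unname(pc$Phi[1, "fixation"]),
                 tolerance = 1e-12)
  }
})

test_that("fixation probability increases with fitness on every motif", {
  rs <- c(0.25, 0.5, 1, 2, 4, 8)
  for (g in all_named_motifs()) {
    sp <- moran_state_space(g)
    phi <- vapply(rs, function(r) {
      start_averaged(solve_chain(build_canonical_chain(g, sp, r)))$fixation_prob
    }, numeric(1))
    expect_true(all(diff(phi) > 0), info = g$name)
  }
})

test_that("start averaging weights orbits by size", {
  star <- make_named_graph("star")
  sp <- moran_state_space(star)
  res <- solve_chain(build_canonical_chain(star, sp, 2))
  sa <- start_averaged(res)
  expect_equal(sort(unname(sa$weights)), c(1 / 4, 3 / 4))
  sm <- single_mutant_states(sp)
  expect_equal(sa$tau_cond, sum(sa$weights * res$tau_cond[sm]))

  diamond <- make_named_graph("diamond")
  spd <- moran_state_space(diamond)
  sad <- start_averaged(solve_chain(build_canonical_chain(diamond, spd, 2)))
  expect_equal(unname(sad$weights), c(1 / 2, 1 / 2))
})

test_that("strong-selection sojourn limits match the known values", {
  per_count <- function(g) {
    sp <- moran_state_space(g)
    function(r) sojourn_by_count(solve_chain(build_canonical_chain(g, sp, r)))
  }
  limc <- strong_selection_limit(per_count(make_named_graph("complete")))
  expect_true(limc$converged)
  expect_equal(unname(limc$value), c(1, 3 / 2, 3), tolerance = 1e-3)

  limr <- strong_selection_limit(per_count(make_named_graph("ring")))
  expect_true(limr$converged)
  # one- and three-mutant sojourns equal the complete graph's under strong
  # selection; only the two-mutant state differs
  expect_equal(unname(limr$value[c(1, 3)]), c(1, 3), tolerance = 1e-3)
  expect_gt(limr$value[2], limc$value[2])

  # diamond: strong selection spends more time in the three-mutant states
  # than neutrality does
  gd <- make_named_graph("diamond")
  spd <- moran_state_space(gd)
  f <- per_count(gd)
  limd <- strong_selection_limit(f)
  expect_true(limd$converged)
  expect_gt(limd$value[3], f(1)[3])
})

test_that("a malformed chain is reported, not silently inverted", {
  g <- make_named_graph("ring")
  ch <- build_canonical_chain(g, moran_state_space(g), 1)
  ch$Q <- diag(nrow(ch$Q))  # absorption impossible
  expect_error(solve_chain(ch), "singular|certain")
})
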