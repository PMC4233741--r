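r_grid <- c(0.1, 0.25, 0.5, 1, 1.65, 2, 4, 10)

test_that("step distribution matches exhaustive event enumeration", {
  set.seed(1)
  for (g in all_named_motifs()) {
    masks <- sample(0:(2^g$n_nodes - 1L), 8)
    for (mask in masks) {
      for (r in c(0.5, 1, 3)) {
        expect_same_distribution(step_distribution(g, mask, r),
                                 step_distribution_oracle(g, mask, r))
      }
    }
  }
  # and on a couple of random larger graphs
  for (k in 1:3) {
    g <- random_connected_graph(6)
    mask <- sample(1:62, 1)
    expect_same_distribution(step_distribution(g, mask, 2),
                             step_distribution_oracle(g, mask, 2))
  }
})

test_that("absorbing configurations are fixed points", {
  g <- make_named_graph("diamond")
  for (mask in c(0L, 15L)) {
    sd <- step_distribution(g, mask, 2)
    expect_equal(sd$masks, mask)
    expect_equal(sd$probs, 1)
  }
})

test_that("two-mutant staying probability is 1/2 on the ring, 1/3 on the complete graph, for every r", {
  ring <- make_named_graph("ring")
  complete <- make_named_graph("complete")
  sp_r <- moran_state_space(ring)
  sp_c <- moran_state_space(complete)
  for (r in r_grid) {
    Qr <- build_canonical_chain(ring, sp_r, r)$Q
    Qc <- build_canonical_chain(complete, sp_c, r)$Q
    i2r <- which(sp_r$mutant_counts[1:3] == 2L)
    i2c <- which(sp_c$mutant_counts[1:3] == 2L)
    expect_equal(Qr[i2r, i2r], 1 / 2, tolerance = 1e-12)
    expect_equal(Qc[i2c, i2c], 1 / 3, tolerance = 1e-12)
  }
})

test_that("a lone mutant in the star centre reproduces with probability r/(r+3)", {
  star <- make_named_graph("star")
  for (r in r_grid) {
    sd <- step_distribution(star, nodes_to_config(0), r)
    gain <- sum(sd$probs[moranet:::popcount(sd$masks) == 2L])
    expect_equal(gain, r / (r + 3), tolerance = 1e-12)
    # every neighbour is wild-type, so the centre cannot fail to expand;
    # the only other event is losing the centre to a leaf birth
    loss <- sum(sd$probs[sd$masks == 0L])
    expect_equal(loss, 3 / (r + 3), tolerance = 1e-12)
  }
})

test_that("well-mixed transitions have the birth-death structure", {
  for (N in c(3, 4, 6)) {
    for (r in r_grid) {
      for (i in 1:(N - 1)) {
        tr <- wellmixed_transitions(N, i, r)
        expect_equal(tr[["down"]] / tr[["up"]], 1 / r, tolerance = 1e-12)
      }
      expect_equal(wellmixed_transitions(N, 0, r), c(up = 0, down = 0))
      expect_equal(wellmixed_transitions(N, N, r), c(up = 0, down = 0))
    }
  }
  # N = 4, i = 2: up + down = 2/3, so the staying probability is 1/3
  tr <- wellmixed_transitions(4, 2, 1.7)
  expect_equal(tr[["up"]] + tr[["down"]], 2 / 3, tolerance = 1e-12)
})

test_that("the complete graph realises the well-mixed process exactly", {
  for (N in 3:6) {
    g <- make_named_graph("complete", N)
    sp <- moran_state_space(g)
    for (r in c(0.5, 1, 2.5)) {
      ch <- build_canonical_chain(g, sp, r)
      for (i in 1:(N - 1)) {
        tr <- wellmixed_transitions(N, i, r)
        up <- unname(if (i < N - 1) ch$Q[i, i + 1] else ch$R[i, "fixation"])
        down <- unname(if (i > 1) ch$Q[i, i - 1] else ch$R[i, "extinction"])
        expect_equal(up, tr[["up"]], tolerance = 1e-12)
        expect_equal(down, tr[["down"]], tolerance = 1e-12)
      }
    }
  }
})

test_that("canonical chains are row-stochastic with an r-independent zero pattern", {
  for (g in all_named_motifs()) {
    sp <- moran_state_space(g)
    zero_pattern <- NULL
    for (r in c(0.2, 1, 6)) {
      ch <- build_canonical_chain(g, sp, r)
      expect_equal(rowSums(ch$Q) + rowSums(ch$R), rep(1, sp$t),
                   tolerance = 1e-12)
      expect_true(all(ch$Q >= 0 & ch$Q <= 1))
      pat <- cbind(ch$Q, ch$R) > 0
      if (is.null(zero_pattern)) zero_pattern <- pat
      expect_equal(pat, zero_pattern)
    }
  }
})

test_that("diamond chain has the two structural zeros among transient states", {
  g <- make_named_graph("diamond")
  sp <- moran_state_space(g)
  ch <- build_canonical_chain(g, sp, 2)
  reps <- sp$reps
  hub1 <- which(reps == nodes_to_config(0))            # one mutant on a hub
  both_deg2 <- which(reps == nodes_to_config(c(2, 3))) # mutants on both deg-2
  wild_deg2 <- which(reps == nodes_to_config(c(0, 1, 2))) # wild on deg-2
  both_hubs <- which(reps == nodes_to_config(c(0, 1)))
  # a hub mutant cannot create the both-degree-2 pair in one step
  expect_equal(ch$Q[hub1, both_deg2], 0)
  # losing a mutant from the wild-on-degree-2 state cannot leave both hubs
  expect_equal(ch$Q[wild_deg2, both_hubs], 0)
})

test_that("on regular graphs the per-config down/up ratio is 1/r", {
  for (g in list(make_named_graph("ring", 5),
                 make_lattice(3, periodic = TRUE))) {
    n <- g$n_nodes
    set.seed(2)
    for (r in c(0.5, 2, 5)) {
      for (mask in sample(1:(2^n - 2L), 10)) {
        sd <- step_distribution(g, mask, r)
        counts <- moranet:::popcount(sd$masks)
        m0 <- moranet:::popcount(mask)
        up <- sum(sd$probs[counts == m0 + 1L])
        down <- sum(sd$probs[counts == m0 - 1L])
        expect_equal(down / up, 1 / r, tolerance = 1e-12)
      }
    }
  }
})

test_that("chain construction rejects invalid fitness", {
  expect_error(step_distribution(make_named_graph("ring"), 1L, 0), "r must")
  expect_error(wellmixed_transitions(4, 2, -1), "r must")
  expect_error(wellmixed_transitions(4, 5, 1), "0..N")
})
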