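# Independent oracles used across the test files. Deliberately written as
# direct enumerations / first-principles recursions so they share no code
# path with the package implementation they check.

# One-step distribution by exhaustive enumeration of (birth node, replaced
# neighbour) events: node k reproduces with probability fitness_k / W and
# its offspring lands on each neighbour with probability 1 / deg(k).
step_distribution_oracle <- function(graph, mask, r) {
  n <- graph$n_nodes
  full <- bitwShiftL(1L, n) - 1L
  if (mask == 0L || mask == full) {
    return(list(masks = mask, probs = 1))
  }
  is_mut <- bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L
  W <- sum(ifelse(is_mut, r, 1))
  acc <- new.env()
  add <- function(m, p) {
    key <- as.character(m)
    assign(key, p + if (exists(key, acc)) get(key, acc) else 0, acc)
  }
  for (k in 0:(n - 1L)) {
    fit <- if (is_mut[k + 1L]) r else 1
    nb <- graph$adj[[k + 1L]]
    for (j in nb) {
      succ <- if (is_mut[k + 1L]) bitwOr(mask, bitwShiftL(1L, j))
              else bitwAnd(mask, bitwNot(bitwShiftL(1L, j)))
      add(succ, (fit / W) / length(nb))
    }
  }
  keys <- ls(acc)
  list(masks = as.integer(keys),
       probs = vapply(keys, get, numeric(1), envir = acc))
}

expect_same_distribution <- function(a, b, tol = 1e-12) {
  oa <- order(a$masks); ob <- order(b$masks)
  pa <- a$probs[oa][a$probs[oa] > tol]
  pb <- b$probs[ob][b$probs[ob] > tol]
  ma <- a$masks[oa][a$probs[oa] > tol]
  mb <- b$masks[ob][b$probs[ob] > tol]
  expect_equal(ma, mb)
  expect_equal(pa, pb, tolerance = tol, ignore_attr = TRUE)
}

# Fixation probabilities on the full 2^n configuration chain by first-step
# value iteration (no matrices, no state reduction).
fixation_prob_oracle <- function(graph, r, start_mask, tol = 1e-13) {
  n <- graph$n_nodes
  full <- bitwShiftL(1L, n) - 1L
  phi <- rep(0.5, full + 1L)
  phi[1L] <- 0; phi[full + 1L] <- 1
  sds <- lapply(0:full, function(m) step_distribution_oracle(graph, m, r))
  repeat {
    new <- vapply(0:full, function(m) {
      if (m == 0L || m == full) return(phi[m + 1L])
      sd <- sds[[m + 1L]]
      sum(sd$probs * phi[sd$masks + 1L])
    }, numeric(1))
    if (max(abs(new - phi)) < tol) break
    phi <- new
  }
  phi[start_mask + 1L]
}

all_named_motifs <- function() {
  nms <- c("complete", "ring", "line", "star", "shovel", "diamond")
  stats::setNames(lapply(nms, make_named_graph), nms)
}

# random connected simple graph via rejection sampling
random_connected_graph <- function(n, p = 0.5) {
  pairs <- t(utils::combn(0:(n - 1L), 2L))
  repeat {
    keep <- stats::runif(nrow(pairs)) < p
    if (sum(keep) < n - 1L) next
    g <- tryCatch(evograph(n, pairs[keep, , drop = FALSE]),
                  error = function(e) NULL)
    if (!is.null(g)) return(g)
  }
}

as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges + 1L, directed = FALSE)
}
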