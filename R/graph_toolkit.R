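# Construction, validation and I/O for the small undirected networks on
# which the Moran process is analysed. Nodes are labelled 0..n-1 throughout,
# including in edge-list files.

#' Construct an evograph object from an edge list
#'
#' Low-level constructor for the undirected, simple, connected graphs used
#' throughout the package. Most users will call [make_named_graph()],
#' [make_lattice()] or [read_edge_list()] instead.
#'
#' @param n_nodes Number of nodes; nodes are labelled `0..n_nodes-1`.
#' @param edges Two-column integer matrix of 0-based endpoints, one row per
#'   undirected edge.
#' @param name Optional descriptive label carried along in printouts.
#' @return An object of class `evograph`: a list with elements `n_nodes`,
#'   `edges` (canonically sorted), `adj` (adjacency list; `adj[[i+1]]` holds
#'   the neighbours of node `i`), `degree`, and `name`.
#' @examples
#' g <- evograph(3, rbind(c(0, 1), c(1, 2), c(2, 0)), name = "triangle")
#' degree(g)
#' @export
evograph <- function(n_nodes, edges, name = NULL) {
  n <- as.integer(n_nodes)
  if (is.na(n) || n < 2L) stop("a graph needs at least 2 nodes")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (anyNA(edges)) stop("non-integer node labels in edge list")
  if (any(edges < 0L) || any(edges >= n)) {
    stop("edge endpoints must be node labels in 0..", n - 1L)
  }
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  # canonical order: smaller endpoint first, rows sorted, duplicates rejected
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  key <- edges[, 1L] * n + edges[, 2L]
  if (anyDuplicated(key)) stop("multi-edges are not allowed")
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a + 1L]] <- c(adj[[a + 1L]], b)
    adj[[b + 1L]] <- c(adj[[b + 1L]], a)
  }
  adj <- lapply(adj, function(v) if (is.null(v)) integer(0) else sort(v))
  deg <- vapply(adj, length, integer(1))
  g <- structure(
    list(n_nodes = n, edges = edges, adj = adj, degree = deg, name = name),
    class = "evograph"
  )
  if (!is_connected(g)) stop("graph must be connected")
  g
}

#' @export
print.evograph <- function(x, ...) {
  cat(sprintf("evograph%s: %d nodes, %d edges, degrees [%s]\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              x$n_nodes, nrow(x$edges),
              paste(x$degree, collapse = " ")))
  invisible(x)
}

#' Node degrees of an evograph
#'
#' @param graph An [evograph()] object.
#' @return Integer vector of degrees, indexed by node label + 1.
#' @export
degree <- function(graph) graph$degree

is_connected <- function(graph) {
  n <- graph$n_nodes
  seen <- logical(n)
  queue <- 0L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in graph$adj[[v + 1L]]) {
      if (!seen[w + 1L]) {
        seen[w + 1L] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}

#' Build one of the named small network families
#'
#' The six connected four-node motifs (complete, ring, line, star, shovel,
#' diamond) plus the generalisations of the first four to other sizes.
#' The diamond is the complete graph on four nodes minus one edge: nodes 0
#' and 1 are the degree-3 hubs, nodes 2 and 3 the non-adjacent degree-2
#' nodes. The shovel is a triangle with a pendant node attached to one
#' triangle vertex (degrees 1, 2, 2, 3).
#'
#' @param name One of `"complete"`, `"ring"`, `"line"`, `"star"`,
#'   `"shovel"`, `"diamond"`.
#' @param n Number of nodes. `shovel` and `diamond` are defined only for
#'   `n = 4`; `ring` requires `n >= 3`; the others accept any `n >= 2`.
#' @return An [evograph()] object.
#' @examples
#' make_named_graph("diamond")
#' make_named_graph("star", n = 5)
#' @export
make_named_graph <- function(name = c("complete", "ring", "line", "star",
                                      "shovel", "diamond"),
                             n = 4L) {
  name <- match.arg(name)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  edges <- switch(
    name,
    complete = t(utils::combn(0:(n - 1L), 2L)),
    ring = {
      if (n < 3L) stop("a ring needs n >= 3")
      cbind(0:(n - 1L), c(1:(n - 1L), 0L))
    },
    line = cbind(0:(n - 2L), 1:(n - 1L)),
    star = cbind(0L, 1:(n - 1L)),
    shovel = {
      if (n != 4L) stop("the shovel is defined only for n = 4")
      rbind(c(0L, 1L), c(0L, 2L), c(1L, 2L), c(2L, 3L))
    },
    diamond = {
      if (n != 4L) stop("the diamond is defined only for n = 4")
      rbind(c(0L, 1L), c(0L, 2L), c(0L, 3L), c(1L, 2L), c(1L, 3L))
    }
  )
  evograph(n, edges, name = if (n == 4L) name else sprintf("%s-%d", name, n))
}

#' Build a square lattice network
#'
#' A `side` x `side` square lattice. With `periodic = TRUE` both boundaries
#' wrap, giving a torus on which every node has the same degree -- an
#' isothermal network. `diagonals` controls the links beyond the
#' von-Neumann neighbourhood: `"none"` (or `FALSE`) is the plain square
#' lattice (degree 4 in the interior), `"single"` additionally links each
#' cell to one diagonal neighbour, the same corner everywhere (degree 6; the
#' tiling of the four-node diamond motif, a ring plus one chord per cell),
#' and `"both"` (or `TRUE`) links both diagonals (degree 8, the Moore
#' neighbourhood). Node `(row, col)` gets label `row * side + col`.
#'
#' @param side Lattice side length; the population size is `side^2`.
#'   Open lattices need `side >= 2`; periodic ones `side >= 3` (a periodic
#'   2x2 lattice would create multi-edges).
#' @param periodic Wrap both boundaries (torus)?
#' @param diagonals `"none"`, `"single"`, or `"both"`; `FALSE`/`TRUE` are
#'   accepted as aliases for `"none"`/`"both"`.
#' @return An [evograph()] object.
#' @examples
#' make_lattice(3, periodic = TRUE)   # 9-node torus, 4-regular
#' make_lattice(2)                    # degenerates to the ring of 4
#' @export
make_lattice <- function(side, periodic = FALSE, diagonals = "none") {
  side <- as.integer(side)
  if (is.na(side) || side < 2L) stop("side must be an integer >= 2")
  if (periodic && side < 3L) stop("periodic lattices need side >= 3")
  if (is.logical(diagonals)) diagonals <- if (diagonals) "both" else "none"
  diagonals <- match.arg(diagonals, c("none", "single", "both"))
  id <- function(r, c) ((r %% side) * side + (c %% side))
  from <- integer(0); to <- integer(0)
  steps <- list(c(0L, 1L), c(1L, 0L))
  if (diagonals == "single") steps <- c(steps, list(c(1L, 1L)))
  if (diagonals == "both") steps <- c(steps, list(c(1L, 1L), c(1L, -1L)))
  for (r in 0:(side - 1L)) {
    for (cc in 0:(side - 1L)) {
      for (s in steps) {
        r2 <- r + s[1L]; c2 <- cc + s[2L]
        if (!periodic && (r2 < 0L || r2 >= side || c2 < 0L || c2 >= side)) next
        if (periodic || (c2 >= 0L && c2 < side)) {
          from <- c(from, id(r, cc)); to <- c(to, id(r2, c2))
        }
      }
    }
  }
  keep <- from != to
  tag <- sprintf("lattice-%d%s%s", side,
                 if (periodic) "-periodic" else "-open",
                 switch(diagonals, none = "", single = "-diag1",
                        both = "-diag2"))
  evograph(side * side, cbind(from[keep], to[keep]), name = tag)
}

# all permutations of 1..n as a list of integer vectors
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos)
    }
  }
  out
}

edge_key <- function(edges, n) sort(edges[, 1L] * n + edges[, 2L])

# permute node labels of an edge matrix; perm is 0-based image vector
permute_edges <- function(edges, perm) {
  a <- perm[edges[, 1L] + 1L]; b <- perm[edges[, 2L] + 1L]
  cbind(pmin(a, b), pmax(a, b))
}

#' Test two small graphs for isomorphism by brute force
#'
#' Tries all `n!` node relabellings; intended for the package's small-graph
#' regime (`n <= 8`).
#'
#' @param g1,g2 [evograph()] objects.
#' @return `TRUE` if some node permutation maps the edge set of `g1` onto
#'   that of `g2`.
#' @export
is_isomorphic <- function(g1, g2) {
  n <- g1$n_nodes
  if (n != g2$n_nodes || nrow(g1$edges) != nrow(g2$edges)) return(FALSE)
  if (!identical(sort(g1$degree), sort(g2$degree))) return(FALSE)
  if (n > 8L) stop("brute-force isomorphism is limited to n <= 8")
  key2 <- edge_key(g2$edges, n)
  for (p in all_permutations(n)) {
    perm <- p - 1L
    if (identical(edge_key(permute_edges(g1$edges, perm), n), key2)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Enumerate all connected graphs on n nodes up to isomorphism
#'
#' Brute force over all edge subsets with isomorphism rejection; one
#' representative per isomorphism class. There are, e.g., exactly six
#' connected undirected graphs on four nodes.
#'
#' @param n Number of nodes, `2 <= n <= 6` (the brute-force bound).
#' @return List of [evograph()] objects, one per isomorphism class.
#' @examples
#' length(enumerate_connected_graphs(4))  # 6
#' @export
enumerate_connected_graphs <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L || n > 6L) {
    stop("enumeration by brute force is limited to 2 <= n <= 6")
  }
  pairs <- t(utils::combn(0:(n - 1L), 2L))
  m <- nrow(pairs)
  reps <- list()
  for (mask in 1:(2^m - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 1L))) != 0L)
    if (length(sel) < n - 1L) next  # too few edges to connect
    g <- tryCatch(evograph(n, pairs[sel, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(g)) next
    if (!any(vapply(reps, is_isomorphic, logical(1), g2 = g))) {
      reps[[length(reps) + 1L]] <- g
    }
  }
  reps
}

#' Read a graph from a plain-text edge list
#'
#' One whitespace-separated pair of 0-based node labels per line; `#` starts
#' a comment. The node count is taken as `max(label) + 1` unless given.
#' Disconnected input and self-loops are rejected.
#'
#' @param path File to read.
#' @param n_nodes Optional explicit node count.
#' @return An [evograph()] object.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no edges in ", path)
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) != 2L)) {
    stop("each line must hold exactly two node labels")
  }
  ends <- suppressWarnings(matrix(as.integer(unlist(toks)),
                                  ncol = 2L, byrow = TRUE))
  if (anyNA(ends)) stop("non-integer node label in ", path)
  if (is.null(n_nodes)) n_nodes <- max(ends) + 1L
  evograph(n_nodes, ends, name = basename(path))
}

#' Write a graph as a plain-text edge list
#'
#' Inverse of [read_edge_list()]: writing then reading reproduces the same
#' edge set.
#'
#' @param graph An [evograph()] object.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  writeLines(sprintf("%d %d", graph$edges[, 1L], graph$edges[, 2L]), path)
  invisible(path)
}
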