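#' Synthetic social topologies
#'
#' Three generators produce the synthetic topologies used in the reference
#' experiments. All return a simple undirected [igraph::igraph] graph with
#' character vertex names `"1" .. "n"` in insertion order, so downstream
#' tie-breaking is reproducible.
#'
#' `gen_preferential_attachment()` grows the graph one node at a time;
#' each arriving node adds a single link to an existing node chosen with
#' probability proportional to its in-degree (links received from later
#' arrivals) plus one -- the classic cumulative-advantage (Price) rule,
#' with the +1 smoothing giving nodes that have received no links a
#' non-zero attachment probability. Edges are stored undirected. The
#' result is a tree with `n - 1` edges and a heavy-tailed degree
#' distribution.
#'
#' @param n number of nodes (`n >= 2`).
#' @param rng_seed optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return an undirected simple `igraph` graph.
#' @examples
#' g <- gen_preferential_attachment(100, rng_seed = 1)
#' igraph::ecount(g)  # 99
#' @seealso [read_edge_list()], [influence_weight()]
#' @export
gen_preferential_attachment <- function(n, rng_seed = NULL) {
  if (!is.numeric(n) || n < 2) stop_invalid("n must be at least 2")
  n <- as.integer(n)
  with_seed(rng_seed, {
    indeg <- integer(n)
    from <- integer(n - 1L)
    to <- integer(n - 1L)
    for (v in 2:n) {
      tgt <- sample.int(v - 1L, 1L, prob = indeg[seq_len(v - 1L)] + 1)
      from[v - 1L] <- v
      to[v - 1L] <- tgt
      indeg[tgt] <- indeg[tgt] + 1L
    }
    graph_from_edges(cbind(from, to), n)
  })
}

#' @rdname gen_preferential_attachment
#'
#' @details
#' `gen_small_world()` starts from a regular ring lattice in which every
#' node is linked to its `lattice_k / 2` nearest neighbors on each side,
#' then rewires each lattice edge independently with probability
#' `p_rewire`: the far endpoint is replaced by a uniformly random target
#' that creates neither a self-loop nor a parallel edge. The edge count is
#' preserved. The defaults (`lattice_k = 2`, `p_rewire = 0.2`) follow the
#' reference configuration, where the lattice is a plain cycle.
#'
#' @param lattice_k even number of lattice neighbors per node
#'   (`2 <= lattice_k < n`).
#' @param p_rewire probability of rewiring each lattice edge.
#' @export
gen_small_world <- function(n, lattice_k = 2, p_rewire = 0.2,
                            rng_seed = NULL) {
  if (!is.numeric(n) || !is.numeric(lattice_k) || n <= lattice_k ||
      lattice_k < 2 || lattice_k %% 2 != 0) {
    stop_invalid("need n > lattice_k >= 2 with lattice_k even")
  }
  if (p_rewire < 0 || p_rewire > 1) {
    stop_invalid("p_rewire must be a probability")
  }
  n <- as.integer(n)
  half <- as.integer(lattice_k / 2)
  with_seed(rng_seed, {
    from <- integer(0)
    to <- integer(0)
    for (o in seq_len(half)) {
      from <- c(from, seq_len(n))
      to <- c(to, (seq_len(n) + o - 1L) %% n + 1L)
    }
    # adjacency sets maintained during rewiring to rule out duplicates
    nbr <- vector("list", n)
    for (e in seq_along(from)) {
      nbr[[from[e]]] <- c(nbr[[from[e]]], to[e])
      nbr[[to[e]]] <- c(nbr[[to[e]]], from[e])
    }
    for (e in seq_along(from)) {
      if (stats::runif(1) >= p_rewire) next
      u <- from[e]
      old <- to[e]
      if (length(nbr[[u]]) >= n - 1L) next  # no legal target remains
      repeat {
        w <- sample.int(n, 1L)
        if (w != u && !(w %in% nbr[[u]])) break
      }
      nbr[[u]] <- c(setdiff(nbr[[u]], old), w)
      nbr[[old]] <- setdiff(nbr[[old]], u)
      nbr[[w]] <- c(nbr[[w]], u)
      to[e] <- w
    }
    graph_from_edges(cbind(from, to), n)
  })
}

#' @rdname gen_preferential_attachment
#'
#' @details
#' `gen_spatially_clustered()` places `n` nodes uniformly at random in the
#' unit square and links the spatially closest pairs, in increasing order
#' of distance, until the mean degree first reaches `avg_degree`
#' (`ceiling(n * avg_degree / 2)` edges). Proximity-based linking yields
#' the high clustering characteristic of spatial social networks.
#'
#' @param avg_degree target mean degree (`1 <= avg_degree < n - 1`).
#' @export
gen_spatially_clustered <- function(n, avg_degree = 10, rng_seed = NULL) {
  if (!is.numeric(n) || !is.numeric(avg_degree) || n <= avg_degree ||
      avg_degree < 1) {
    stop_invalid("need n > avg_degree >= 1")
  }
  if (avg_degree > n - 1) {
    stop_invalid("avg_degree %.3g is infeasible for %d nodes", avg_degree, n)
  }
  n <- as.integer(n)
  with_seed(rng_seed, {
    x <- stats::runif(n)
    y <- stats::runif(n)
    d <- as.matrix(stats::dist(cbind(x, y)))
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    ord <- order(d[upper.tri(d)])
    m <- ceiling(n * avg_degree / 2)
    sel <- pairs[ord[seq_len(m)], , drop = FALSE]
    graph_from_edges(sel, n)
  })
}

# build a named simple undirected igraph from an integer edge matrix
graph_from_edges <- function(edges, n) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- as.character(seq_len(n))
  stopifnot(igraph::is_simple(g))
  g
}

#' Read and write whitespace-delimited edge lists
#'
#' Reads a SNAP-dialect edge list: one whitespace-separated node pair per
#' line, lines starting with `#` ignored. Duplicate lines and reversed
#' duplicates collapse to a single undirected edge; self-loops are dropped
#' with a warning. Node identifiers are kept verbatim, in order of first
#' appearance.
#'
#' @param path path to the edge-list file.
#' @return an undirected simple `igraph` graph with character vertex
#'   names.
#' @examples
#' f <- tempfile()
#' writeLines(c("# comment", "a b", "b a", "b c"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)  # 3
#' igraph::ecount(g)  # 2
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  tokens <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(tokens) != 2L)
  if (length(bad) > 0L) {
    stop_invalid("malformed edge at line %d of %s: expected two node tokens",
                 idx[bad[1]], path)
  }
  if (length(tokens) == 0L) stop_invalid("no edges in %s", path)
  ends <- do.call(rbind, tokens)
  loops <- ends[, 1] == ends[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s) while reading %s",
                    sum(loops), path), call. = FALSE)
    ends <- ends[!loops, , drop = FALSE]
  }
  ids <- unique(as.vector(t(ends)))  # first-appearance order
  a <- match(ends[, 1], ids)
  b <- match(ends[, 2], ids)
  key <- paste(pmin(a, b), pmax(a, b))
  dup <- duplicated(key)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::add_edges(g, rbind(a[!dup], b[!dup]))
  igraph::V(g)$name <- ids
  g
}

#' @rdname read_edge_list
#' @param graph graph to write.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(c(sprintf("# %d nodes, %d edges", igraph::vcount(graph),
                       igraph::ecount(graph)),
               paste(el[, 1], el[, 2])), path)
  invisible(path)
}

#' Influence weight exerted on a node by a neighbor
#'
#' Every neighbor of `v` exerts the same influence weight `1/|N(v)|`, so
#' the incoming weights of a non-isolated node sum to one.
#'
#' @param graph an `igraph` graph.
#' @param v,w vertex names or indices; `w` must be a neighbor of `v`.
#' @return the influence weight `1/|N(v)|`.
#' @export
influence_weight <- function(graph, v, w) {
  nb <- igraph::neighbors(graph, v)
  if (!(igraph::as_ids(igraph::V(graph)[w]) %in% igraph::as_ids(nb))) {
    stop_invalid("influence weight is defined only for neighbors of v")
  }
  1 / length(nb)
}

#' Topology generator closure
#'
#' Wraps one of the synthetic generators (or a fixed edge-list file) into
#' a zero-argument closure drawing a fresh topology from the current RNG
#' stream. The network-average estimation regime requires such a
#' generator.
#'
#' @param model one of `"pa"`, `"sw"`, `"sc"`.
#' @param n number of nodes.
#' @param ... passed to the underlying generator
#'   (e.g. `p_rewire`, `avg_degree`).
#' @return a function `function()` returning a fresh `igraph` graph.
#' @examples
#' gen <- graph_generator("pa", 50)
#' set.seed(1); g <- gen()
#' @export
graph_generator <- function(model = c("pa", "sw", "sc"), n, ...) {
  model <- match.arg(model)
  fn <- switch(model,
    pa = function() gen_preferential_attachment(n, ...),
    sw = function() gen_small_world(n, ...),
    sc = function() gen_spatially_clustered(n, ...)
  )
  fn
}

# 0-based adjacency list for the C++ engine
adj0 <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"),
         function(x) as.integer(x) - 1L)
}
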