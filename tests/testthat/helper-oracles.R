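# Fixtures and independent oracles used across the suite. Everything here
# is deliberately written in plain base R / igraph, independent of the
# package's own diffusion machinery.

path_graph <- function(n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

star_graph <- function(leaves) {
  g <- igraph::make_empty_graph(leaves + 1L, directed = FALSE)
  g <- igraph::add_edges(g, rbind(rep(1L, leaves), seq_len(leaves) + 1L))
  igraph::V(g)$name <- as.character(seq_len(leaves + 1L))
  g
}

cycle_graph <- function(n) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L)))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

adj_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

# Independent synchronous Linear Threshold simulator: node v activates
# when the fraction of active neighbors reaches theta[v]. Deterministic
# given thresholds. Returns the logical activation vector.
lt_oracle <- function(g, theta, seeds) {
  adj <- adj_list(g)
  n <- length(adj)
  active <- logical(n)
  active[seeds] <- TRUE
  repeat {
    frac <- vapply(adj, function(nb) {
      if (length(nb) == 0L) 0 else mean(active[nb])
    }, numeric(1))
    nxt <- active | (lengths(adj) > 0L & frac >= theta - 1e-12)
    if (identical(nxt, active)) break
    active <- nxt
  }
  unname(active)
}

# Exact expected participation for the single-behavior sticky process by
# exhaustive enumeration of live-edge configurations: each eligible node
# (r >= cost) independently picks one neighbor uniformly as its live
# edge; a node activates iff it is eligible and reachable from a seed
# through live edges. Feasible only when prod(deg) is small.
exact_sigma_k1 <- function(g, seeds, eligible = NULL) {
  adj <- adj_list(g)
  n <- length(adj)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  free <- which(eligible & lengths(adj) > 0L & !(seq_len(n) %in% seeds))
  choices <- lapply(free, function(v) adj[[v]])
  total <- prod(lengths(choices))
  stopifnot(total <= 2e5)
  idx <- rep(1L, length(free))
  sizes <- lengths(choices)
  sigma <- 0
  for (cfg in seq_len(total)) {
    live <- integer(n)
    for (t in seq_along(free)) live[free[t]] <- choices[[t]][idx[t]]
    active <- logical(n)
    active[seeds] <- TRUE
    repeat {
      nxt <- active
      for (v in free) if (!nxt[v] && active[live[v]]) nxt[v] <- TRUE
      if (identical(nxt, active)) break
      active <- nxt
    }
    sigma <- sigma + sum(active)
    # odometer increment
    for (t in seq_along(idx)) {
      idx[t] <- idx[t] + 1L
      if (idx[t] <= sizes[t]) break
      idx[t] <- 1L
    }
  }
  sigma / total
}

# single-behavior seed assignment helper
seeds_k1 <- function(nodes, n, variant = "S-T") {
  seed_assignment(list(nodes), n, variant)
}

# small deterministic endowment
flat_endowment <- function(n, k, r = 1, theta = 1) {
  endowment(rep(r, n), matrix(theta, n, k))
}
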