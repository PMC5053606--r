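#' Sample node endowments
#'
#' Draws the per-node resource `r(v) ~ U(0, 1)` and the per-node,
#' per-behavior adoption thresholds `theta_i(v) ~ U(0, 1)`, all
#' independent. Thresholds are private and unknown to the seeding
#' algorithms; resources are treated as known.
#'
#' @param graph an `igraph` graph (only its node count is used).
#' @param k number of behaviors.
#' @param rng_seed optional integer seed.
#' @return An object of class `endowment`: a list with `r` (length-`n`
#'   numeric) and `theta` (`n x k` matrix).
#' @export
sample_endowments <- function(graph, k, rng_seed = NULL) {
  if (k < 1) stop_invalid("k must be at least 1")
  n <- igraph::vcount(graph)
  with_seed(rng_seed, {
    endowment(r = stats::runif(n),
              theta = matrix(stats::runif(n * k), nrow = n, ncol = k))
  })
}

#' @rdname sample_endowments
#' @param r resource vector.
#' @param theta `n x k` threshold matrix.
#' @export
endowment <- function(r, theta) {
  theta <- as.matrix(theta)
  if (nrow(theta) != length(r)) {
    stop_invalid("theta must have one row per node")
  }
  if (any(r < 0 | r > 1) || any(theta < 0 | theta > 1)) {
    stop_invalid("resources and thresholds must lie in [0, 1]")
  }
  structure(list(r = as.numeric(r), theta = theta), class = "endowment")
}
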