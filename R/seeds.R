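#' Seed assignments
#'
#' A seed assignment records, for each behavior, which nodes are installed
#' as its early adopters at epoch 0, plus any resource top-up granted to
#' seeds that could not otherwise afford their assigned behavior.
#'
#' Four variants are distinguished (`variant`): `"S"`eeds carry a single
#' behavior vs `"M"`ultiple behaviors, crossed with `"T"`op-up (a seed
#' short of resource has `r(v)` raised to exactly the assigned cost) vs
#' `"NT"` (only nodes that can already afford a behavior are assigned it).
#'
#' @param sets list of `k` integer vectors of vertex indices, one per
#'   behavior.
#' @param n number of nodes in the graph.
#' @param variant one of `"S-T"`, `"S-NT"`, `"M-T"`, `"M-NT"`.
#' @param topped_up numeric length-`n` vector of resource amounts added to
#'   seeds (zero everywhere in NT variants).
#' @return an object of class `seed_assignment`.
#' @export
seed_assignment <- function(sets, n, variant = "S-T",
                            topped_up = numeric(n)) {
  variant <- match.arg(variant, c("S-T", "S-NT", "M-T", "M-NT"))
  sets <- lapply(sets, function(s) sort(unique(as.integer(s))))
  all_idx <- unlist(sets)
  if (length(all_idx) > 0L && (min(all_idx) < 1L || max(all_idx) > n)) {
    stop_invalid("seed indices out of range")
  }
  if (startsWith(variant, "S") && anyDuplicated(all_idx)) {
    stop_invalid("single-behavior variants allow each node in one seed set only")
  }
  if (endsWith(variant, "NT") && any(topped_up > 0)) {
    stop_invalid("no-top-up variants cannot carry top-up amounts")
  }
  structure(list(sets = sets, n = n, variant = variant,
                 topped_up = as.numeric(topped_up)),
            class = "seed_assignment")
}

#' @rdname seed_assignment
#' @param k number of behaviors.
#' @export
empty_assignment <- function(k, n, variant = "S-T") {
  seed_assignment(rep(list(integer(0)), k), n, variant)
}

#' @export
print.seed_assignment <- function(x, ...) {
  cat(sprintf("Seed assignment (%s): %d seed slot(s) over %d behavior(s)\n",
              x$variant, sum(lengths(x$sets)), length(x$sets)))
  for (i in seq_along(x$sets)) {
    cat(sprintf("  behavior %d: %d seed(s)\n", i, length(x$sets[[i]])))
  }
  tu <- sum(x$topped_up > 0)
  if (tu > 0) {
    cat(sprintf("  %d seed(s) topped up by %.3f in total\n", tu,
                sum(x$topped_up)))
  }
  invisible(x)
}

# per-node bitmask of pinned behaviors
pinned_masks <- function(seeds) {
  m <- integer(seeds$n)
  for (i in seq_along(seeds$sets)) {
    m[seeds$sets[[i]]] <- bitwOr(m[seeds$sets[[i]]], bitwShiftL(1L, i - 1L))
  }
  m
}

# resources after applying the assignment's top-ups
r_effective <- function(endow_r, seeds) {
  if (is.null(seeds)) endow_r else endow_r + seeds$topped_up
}

mask_cost <- function(mask, behaviors) {
  k <- n_behaviors(behaviors)
  vapply(mask, function(m) {
    sum(behaviors$cost[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L])
  }, numeric(1))
}

mask_to_sets <- function(mask, k) {
  lapply(mask, function(m) which(bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L))
}
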