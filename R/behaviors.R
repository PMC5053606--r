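#' Define a set of behaviors
#'
#' A behavior set holds the `k` behaviors to be spread through the network.
#' Each behavior `i` has an adoption cost `c_i` and an intrinsic utility
#' `u_i`, both in `[0, 1]` and intrinsic to the behavior (identical for
#' every individual). Behaviors are indexed in non-decreasing order of
#' cost; the constructor sorts cost/utility pairs accordingly.
#'
#' @param cost numeric vector of adoption costs in `[0, 1]`.
#' @param utility numeric vector of utilities in `[0, 1]`, same length as
#'   `cost`. Defaults to `cost` (utility proportional to cost, the
#'   configuration used throughout the reference experiments).
#' @return An object of class `behavior_set`: a data frame with columns
#'   `cost` and `utility`, one row per behavior, sorted by cost.
#' @examples
#' behavior_set(c(0.2, 0.5, 0.7))
#' @export
behavior_set <- function(cost, utility = cost) {
  if (length(cost) < 1L) stop_invalid("a behavior set needs at least one behavior")
  if (length(utility) != length(cost)) {
    stop_invalid("cost and utility must have the same length")
  }
  if (any(!is.finite(cost)) || any(cost < 0) || any(cost > 1)) {
    stop_invalid("costs must lie in [0, 1]")
  }
  if (any(!is.finite(utility)) || any(utility < 0) || any(utility > 1)) {
    stop_invalid("utilities must lie in [0, 1]")
  }
  ord <- order(cost)
  out <- data.frame(cost = cost[ord], utility = utility[ord])
  class(out) <- c("behavior_set", "data.frame")
  out
}

#' @export
print.behavior_set <- function(x, ...) {
  cat(sprintf("Behavior set with %d behavior(s):\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

n_behaviors <- function(behaviors) nrow(behaviors)

#' Number of affordable behaviors
#'
#' `kappa(v)` is the largest behavior index `j` such that `c_j <= r(v)`,
#' i.e. the number of behaviors the individual could afford one at a time
#' (costs are sorted ascending). Returns 0 when no behavior is affordable.
#'
#' @param behaviors a [behavior_set()].
#' @param r resource value(s) in `[0, 1]`; vectorized.
#' @return integer vector of the same length as `r`.
#' @examples
#' b <- behavior_set(c(0.2, 0.5, 0.7))
#' kappa(b, c(0.1, 0.5, 1))
#' @export
kappa <- function(behaviors, r) {
  vapply(r, function(ri) sum(behaviors$cost <= ri + 1e-12), integer(1))
}

#' Adoption payoff of a behavior
#'
#' The payoff blends intrinsic intent and social signal:
#' `p_i(v) = w * u_i + (1 - w) * l_i(v)`.
#'
#' @param behaviors a [behavior_set()].
#' @param i behavior index.
#' @param l social signal strength in `[0, 1]` (see [social_signal()]).
#' @param w relative weight of the intrinsic utility, in `[0, 1]`.
#' @return payoff value in `[0, 1]`.
#' @export
payoff <- function(behaviors, i, l, w) {
  stopifnot(i >= 1L, i <= n_behaviors(behaviors))
  if (any(l < -1e-12) || any(l > 1 + 1e-12)) {
    stop_invalid("social signal must lie in [0, 1]")
  }
  if (w < 0 || w > 1) stop_invalid("payoff weight w must lie in [0, 1]")
  w * behaviors$utility[i] + (1 - w) * l
}

#' Knapsack selection of behaviors
#'
#' Exhaustively searches the subsets of a candidate behavior set and
#' returns the feasible subset (total cost within budget) with maximal
#' total payoff. Ties are broken by lower total cost, then by the
#' lexicographically smallest index set. The empty set (payoff 0) is
#' always feasible.
#'
#' @param candidates integer vector of candidate behavior indices.
#' @param payoffs numeric vector of per-behavior payoffs, length `k`
#'   (indexed by behavior, not by candidate position).
#' @param behaviors a [behavior_set()].
#' @param budget available resource.
#' @return integer vector of selected behavior indices (sorted).
#' @examples
#' b <- behavior_set(c(0.2, 0.5, 0.7))
#' knapsack_select(1:3, c(0.4, 0.5, 0.6), b, budget = 0.7)  # {1, 2}
#' @export
knapsack_select <- function(candidates, payoffs, behaviors, budget) {
  k <- n_behaviors(behaviors)
  stopifnot(length(payoffs) == k, budget >= 0)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1L | candidates > k)) {
    stop_invalid("candidate indices must lie in 1..k")
  }
  best <- integer(0)
  best_pay <- 0
  best_cost <- 0
  nc <- length(candidates)
  if (nc == 0L) return(best)
  for (m in seq_len(2^nc) - 1L) {
    sel <- candidates[bitwAnd(m, 2^(seq_len(nc) - 1L)) > 0L]
    cc <- sum(behaviors$cost[sel])
    if (cc > budget + 1e-12) next
    cp <- sum(payoffs[sel])
    take <- FALSE
    if (cp > best_pay + 1e-12) {
      take <- TRUE
    } else if (cp > best_pay - 1e-12) {
      if (cc < best_cost - 1e-12) {
        take <- TRUE
      } else if (cc < best_cost + 1e-12 && lex_smaller_set(sel, best)) {
        take <- TRUE
      }
    }
    if (take) {
      best <- sel
      best_pay <- cp
      best_cost <- cc
    }
  }
  best
}

# TRUE if sorted index set a precedes sorted index set b lexicographically
# (a shorter prefix wins: {1} < {1,2}; the empty set precedes everything)
lex_smaller_set <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- min(la, lb)
  if (n > 0L) {
    for (t in seq_len(n)) {
      if (a[t] < b[t]) return(TRUE)
      if (a[t] > b[t]) return(FALSE)
    }
  }
  la < lb
}
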