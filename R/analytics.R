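#' Full utilization points of a behavior cost vector
#'
#' An individual with resource exactly equal to an achievable subset-sum
#' of the behavior costs can spend their resource fully. The set of these
#' "full utilization points" is the sorted distinct nonzero subset-sums
#' of the costs not exceeding 1 (duplicates within `1e-12` merged, so
#' e.g. costs (0.2, 0.5, 0.7) give the four points 0.2, 0.5, 0.7, 0.9).
#'
#' @param behaviors a [behavior_set()].
#' @return numeric vector of class `utilization_points`, strictly
#'   increasing in `(0, 1]`.
#' @examples
#' utilization_points(behavior_set(c(0.2, 0.5, 0.7)))
#' @export
utilization_points <- function(behaviors) {
  cost <- behaviors$cost
  k <- length(cost)
  sums <- vapply(seq_len(2^k) - 1L, function(m) {
    sum(cost[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0L])
  }, numeric(1))
  sums <- sums[sums > 1e-12 & sums <= 1 + 1e-12]
  sums <- sort(sums)
  if (length(sums) == 0L) {
    stop_invalid("no achievable utilization point lies in (0, 1]")
  }
  pts <- sums[c(TRUE, diff(sums) > 1e-12)]
  structure(pmin(pts, 1), class = "utilization_points")
}

#' Closed-form maximum resource utilization
#'
#' For utilization points `0 < mu_1 < ... < mu_n <= 1` and resources
#' uniform on `(0, 1)`, an individual with resource `r` can spend at most
#' the largest point below `r`, so the expected spend is a staircase
#' integral and the maximum expected utilization is
#' `2 * (mu_1 mu_2 + ... + mu_{n-1} mu_n + mu_n) - 2 * (mu_1^2 + ... + mu_n^2)`.
#'
#' @param points a [utilization_points()] vector (any strictly increasing
#'   numeric vector in `(0, 1]` is accepted).
#' @return the maximum expected utilization, in `[0, 1]`.
#' @examples
#' max_utilization(utilization_points(behavior_set(c(0.2, 0.5, 0.7))))  # 0.78
#' @export
max_utilization <- function(points) {
  mu <- as.numeric(points)
  if (length(mu) == 0L || any(diff(mu) <= 0) || mu[1] <= 0 ||
      mu[length(mu)] > 1 + 1e-12) {
    stop_invalid("points must be strictly increasing in (0, 1]")
  }
  n <- length(mu)
  adjacent <- if (n > 1) sum(mu[-n] * mu[-1]) else 0
  2 * (adjacent + mu[n]) - 2 * sum(mu^2)
}

#' Optimal utilization points
#'
#' Setting the partial derivatives of the closed-form utilization to zero
#' shows the optimal `n` points are uniformly spaced, `mu_i = i/(n+1)`,
#' achieving utilization `n/(n+1)`.
#'
#' @param n number of utilization points.
#' @return list with `points` (the uniformly spaced optimum) and `value`
#'   (`n/(n+1)`).
#' @examples
#' optimal_points(3)  # points 0.25 0.50 0.75, value 0.75
#' @export
optimal_points <- function(n) {
  if (n < 1) stop_invalid("n must be at least 1")
  pts <- seq_len(n) / (n + 1)
  list(points = structure(pts, class = "utilization_points"),
       value = n / (n + 1))
}
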