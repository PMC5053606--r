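b3 <- behavior_set(c(0.2, 0.5, 0.7))

test_that("endowment sampling is reproducible, uniform and independent", {
  g <- gen_preferential_attachment(100, rng_seed = 1)
  e1 <- sample_endowments(g, 3, rng_seed = 5)
  e2 <- sample_endowments(g, 3, rng_seed = 5)
  expect_identical(e1, e2)

  gbig <- gen_small_world(10000, 2, 0.2, rng_seed = 1)
  e <- sample_endowments(gbig, 3, rng_seed = 6)
  expect_lt(abs(mean(e$r) - 0.5), 0.02)
  expect_lt(abs(cor(e$theta[, 1], e$theta[, 2])), 0.03)
  expect_lt(abs(cor(e$theta[, 2], e$theta[, 3])), 0.03)
})

test_that("social signal sums adopting neighbors' influence weights", {
  g <- star_graph(4)  # hub "1" with 4 leaves
  adopted <- rep(list(integer(0)), 5)
  expect_equal(social_signal(g, adopted, "1", 1), 0)
  adopted[c(2, 3)] <- list(1L, 1L)
  expect_equal(social_signal(g, adopted, "1", 1), 0.5)
  adopted[c(4, 5)] <- list(1L, 1L)
  expect_equal(social_signal(g, adopted, "1", 1), 1)
  expect_equal(social_signal(g, adopted, "2", 2), 0)
})

test_that("candidate sets respect thresholds, budget and prior adoption", {
  g <- star_graph(4)
  n <- 5
  # leaves 2,3 adopted 1; leaves 4,5 adopted 3 -> hub signals (0.5, 0, 0.5)
  adopted <- list(integer(0), 1L, 1L, 3L, 3L)
  e <- endowment(rep(1, n), matrix(0.5, n, 3))
  expect_identical(candidate_set(g, adopted, e, b3, "1", budget = 0.6), 1L)
  expect_identical(candidate_set(g, adopted, e, b3, "1", budget = 1), c(1L, 3L))
  # all thresholds 1, partial signals -> nothing qualifies
  e1 <- endowment(rep(1, n), matrix(1, n, 3))
  expect_identical(candidate_set(g, adopted, e1, b3, "1", 1), integer(0))
  # zero thresholds, nothing adopted: all behaviors qualify
  e0 <- endowment(rep(1, n), matrix(0, n, 3))
  expect_identical(candidate_set(g, rep(list(integer(0)), n), e0, b3,
                                 "1", 1), 1:3)
})

test_that("diffusion with no seeds stays empty", {
  g <- gen_preferential_attachment(50, rng_seed = 3)
  e <- sample_endowments(g, 3, rng_seed = 4)
  out <- run_diffusion(g, e, b3, NULL, mode = "sticky")
  expect_equal(out$result$participation, 0)
  expect_equal(out$result$utilization, 0)
  expect_true(out$result$converged)
})

test_that("path-graph expected participation matches the exact value", {
  # path a-b-c, one behavior of cost 0.2, r = 1, seed {a}:
  # b adopts iff theta_b <= 1/2; c then adopts surely => E[sigma] = 2.
  g <- path_graph(3)
  b1 <- behavior_set(0.2)
  seeds <- seeds_k1(1, 3)
  est <- estimate_metrics(g, b1, function(graph, r) seeds, mode = "sticky",
                          runs = 100000, regime = "threshold_avg",
                          rng_seed = 99, r = rep(1, 3))
  expect_lt(abs(est$mean[["participation"]] - 2.0),
            3 * est$se[["participation"]] + 1e-9)
})

test_that("sticky adoption is monotone and terminates", {
  g <- gen_small_world(60, 2, 0.2, rng_seed = 8)
  e <- sample_endowments(g, 3, rng_seed = 9)
  s <- select_random(g, e$r, seed_budget_vector(c(3, 3, 3)), b3,
                     rng_seed = 10)
  prev <- rep(list(integer(0)), 60)
  for (cap in 1:6) {
    out <- run_diffusion(g, e, b3, s, mode = "sticky", max_epochs = cap)
    now <- out$state$adopted
    expect_true(all(vapply(seq_len(60), function(v) {
      all(prev[[v]] %in% now[[v]])
    }, logical(1))))
    prev <- now
  }
  full <- run_diffusion(g, e, b3, s, mode = "sticky")
  expect_true(full$result$converged)
  expect_lte(full$result$epochs_run, 60 * 3)
})

test_that("spent resource never exceeds the (post-top-up) endowment", {
  for (seed in 1:5) {
    g <- gen_preferential_attachment(80, rng_seed = seed)
    e <- sample_endowments(g, 3, rng_seed = seed + 50)
    s <- select_naive_degree(g, e$r, b3, seed_budget_vector(c(3, 3, 3)),
                             "random_t", rng_seed = seed)
    for (mode in c("sticky", "reevaluate")) {
      out <- run_diffusion(g, e, b3, s, mode = mode)
      expect_true(all(out$state$s <= out$state$r + 1e-9))
      expect_equal(out$state$s,
                   vapply(out$state$adopted,
                          function(a) sum(b3$cost[a]), numeric(1)))
      # pinned behaviors are retained
      for (i in 1:3) {
        expect_true(all(vapply(s$sets[[i]], function(v) {
          i %in% out$state$adopted[[v]]
        }, logical(1))))
      }
    }
  }
})

test_that("payoff is monotone in signal and utility", {
  ls <- seq(0, 1, 0.1)
  p <- vapply(ls, function(l) payoff(b3, 2, l, w = 0.4), numeric(1))
  expect_true(all(diff(p) >= 0))
  us <- seq(0, 1, 0.1)
  p2 <- vapply(us, function(u) {
    payoff(behavior_set(c(0.2, 0.5), c(0.1, u)), 2, 0.3, w = 0.4)
  }, numeric(1))
  expect_true(all(diff(p2) >= 0))
})

test_that("with one unit-cost behavior the model reduces to linear threshold", {
  b1 <- behavior_set(1, 1)
  set.seed(123)
  for (rep in 1:20) {
    g <- gen_small_world(8, 2, 0.5)
    n <- 8
    seeds <- sample.int(n, 2)
    for (draw in 1:3) {
      theta <- runif(n)
      e <- endowment(rep(1, n), matrix(theta, n, 1))
      out <- run_diffusion(g, e, b1, seeds_k1(seeds, n), mode = "sticky")
      got <- lengths(out$state$adopted) > 0
      expect_identical(got, lt_oracle(g, theta, seeds))
    }
  }
})

test_that("re-evaluation mode reports truncation instead of failing", {
  g <- gen_preferential_attachment(120, rng_seed = 2)
  e <- sample_endowments(g, 3, rng_seed = 3)
  out <- run_diffusion(g, e, b3, NULL, mode = "reevaluate", max_epochs = 1000)
  expect_true(is.logical(out$result$converged))
  # a one-epoch cap cannot certify convergence on a seeded instance
  s <- select_random(g, e$r, seed_budget_vector(c(4, 4, 4)), b3,
                     rng_seed = 4)
  out1 <- run_diffusion(g, e, b3, s, mode = "reevaluate", max_epochs = 1)
  expect_true(out1$result$epochs_run <= 1)
})
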