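b3 <- behavior_set(c(0.2, 0.5, 0.7))

test_that("behavior distribution strategies apportion the budget", {
  expect_equal(as.integer(distribute_behaviors("uniform", 51, b3)),
               c(17L, 17L, 17L))
  expect_equal(as.integer(distribute_behaviors("highest_only", 51, b3)),
               c(0L, 0L, 51L))
  expect_equal(as.integer(distribute_behaviors("lowest_only", 51, b3)),
               c(51L, 0L, 0L))
  # quotas 7.29 / 18.21 / 25.5; the spare goes to the largest remainder
  expect_equal(as.integer(distribute_behaviors("proportional_cost", 51, b3)),
               c(7L, 18L, 26L))
  inv <- distribute_behaviors("inverse_cost", 51, b3)
  expect_equal(sum(inv), 51L)
  expect_true(inv[1] > inv[2] && inv[2] > inv[3])
})

test_that("random selection is uniform-without-replacement and reproducible", {
  g <- path_graph(3)
  r <- c(0.9, 0.9, 0.9)
  s <- select_random(g, r, seed_budget_vector(c(1, 1, 1)), b3,
                     rng_seed = 1)
  expect_setequal(unlist(s$sets), 1:3)
  s2 <- select_random(g, r, seed_budget_vector(c(1, 1, 1)), b3,
                      rng_seed = 1)
  expect_identical(s, s2)
  s0 <- select_random(g, r, seed_budget_vector(c(0, 0, 0)), b3)
  expect_equal(sum(lengths(s0$sets)), 0)
  expect_error(select_random(g, r, seed_budget_vector(c(2, 1, 1)), b3),
               "exceeds")
})

test_that("naive degree selection follows the scan rules", {
  st <- star_graph(6)
  r <- rep(1, 7)
  s <- select_naive_degree(st, r, b3, seed_budget_vector(c(1, 0, 0)),
                           "random_nt", rng_seed = 2)
  expect_identical(s$sets[[1]], 1L)  # the hub wins

  # a resource-poor node is consumed from the ranking without assignment
  g <- path_graph(4)  # degrees 1 2 2 1
  rp <- c(0.1, 0.1, 1, 1)
  s2 <- select_naive_degree(g, rp, b3, seed_budget_vector(c(1, 0, 0)),
                            "random_nt", rng_seed = 3)
  expect_identical(s2$sets[[1]], 3L)  # node 2 was scanned first but skipped
  expect_true(all(s2$topped_up == 0))

  # with top-up the poor node is taken and topped to the exact cost
  s3 <- select_naive_degree(g, rp, b3, seed_budget_vector(c(0, 1, 0)),
                            "random_t", rng_seed = 3)
  v <- s3$sets[[2]]
  expect_true(v %in% 2:3)
  if (rp[v] < 0.5) expect_equal(s3$topped_up[v], 0.5 - rp[v])

  # knapsack tie-breaking pins the utility-maximizing affordable set
  s4 <- select_naive_degree(st, c(1, rep(0, 6)), b3,
                            seed_budget_vector(c(1, 0, 1)), "knapsack",
                            rng_seed = 4)
  expect_identical(s4$sets[[1]], 1L)  # hub takes {1, 3}: u = 0.9 beats others
  expect_identical(s4$sets[[3]], 1L)
  expect_error(select_naive_degree(st, rep(0, 7), b3,
                                   seed_budget_vector(c(8, 0, 0)),
                                   "random_t"),
               "exhausted")
})

test_that("degree+resource scores count resource-sufficient neighbors", {
  st <- star_graph(5)
  r_rich <- c(0.1, rep(1, 5))
  s <- select_degree_resource(st, r_rich, b3, seed_budget_vector(c(1, 0, 0)),
                              rng_seed = 5)
  expect_identical(s$sets[[1]], 1L)  # d_1(hub) = 5 dominates

  # all neighbors resource-poor: every score is zero, selection still fills
  r_poor <- rep(0.1, 6)
  s2 <- select_degree_resource(st, r_poor, b3,
                               seed_budget_vector(c(2, 0, 0)),
                               rng_seed = 6)
  expect_equal(length(s2$sets[[1]]), 2)
  expect_true(all(s2$topped_up[s2$sets[[1]]] > 0))
})

test_that("collisions assign one behavior and refill from the next rank", {
  # hub claims every behavior; after the collision each shorted behavior
  # must refill, so all budget slots are filled with distinct nodes
  st <- star_graph(6)
  r <- rep(1, 7)
  s <- select_degree_resource(st, r, b3, seed_budget_vector(c(2, 2, 2)),
                              rng_seed = 7)
  picked <- unlist(s$sets)
  expect_equal(length(picked), 6)
  expect_equal(anyDuplicated(picked), 0)
  expect_true(1L %in% picked)  # the hub went somewhere
})

test_that("CIW scores follow the influence-weight formula", {
  st <- star_graph(5)
  r <- rep(1, 6)
  e1 <- ciw(st, r, b3, 1)
  expect_equal(e1[[1]], 6)        # hub: 1 + 5 * (1/1)
  expect_equal(e1[[2]], 1.2)      # leaf: 1 + 1/5
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "1"
  expect_equal(ciw(iso, 1, b3, 1)[[1]], 1)
  # resource-poor neighbors do not contribute
  e_poor <- ciw(st, c(1, rep(0.1, 5)), b3, 2)
  expect_equal(e_poor[[1]], 1)
  # excluded nodes are discounted
  e_ex <- ciw(st, r, b3, 1, excluded = c(2L, 3L))
  expect_equal(e_ex[[1]], 4)
})

test_that("CIW heuristics pick the hub and stay reproducible", {
  st <- star_graph(5)
  r <- rep(1, 6)
  s <- select_ciw_ranked(st, r, b3, seed_budget_vector(c(1, 0, 0)),
                         rng_seed = 8)
  expect_identical(s$sets[[1]], 1L)
  s2 <- select_ciw_ranked(st, r, b3, seed_budget_vector(c(1, 0, 0)),
                          rng_seed = 8)
  expect_identical(s, s2)

  # single-seed budgets: max-margin's first pick coincides with the ranking
  g <- gen_preferential_attachment(60, rng_seed = 9)
  rr <- rep(1, 60)  # equal resources: scores identical across methods
  m1 <- select_ciw_max_margin(g, rr, b3, seed_budget_vector(c(1, 0, 0)),
                              rng_seed = 10)
  m2 <- select_ciw_ranked(g, rr, b3, seed_budget_vector(c(1, 0, 0)),
                          rng_seed = 10)
  expect_identical(m1$sets[[1]], m2$sets[[1]])
})

test_that("max-margin discounts neighbors of already-selected seeds", {
  # two adjacent hubs: after hub A is taken, B's score drops by 1/|N(A)|
  g <- igraph::make_empty_graph(8, directed = FALSE)
  g <- igraph::add_edges(g, rbind(
    c(1, 1, 1, 2, 2, 2, 1),
    c(3, 4, 5, 6, 7, 8, 2)))
  igraph::V(g)$name <- as.character(1:8)
  r <- rep(1, 8)
  e_full <- ciw(g, r, b3, 1)
  expect_equal(e_full[[1]], 1 + 3 + 1 / 4)  # 3 leaves + hub B
  s <- select_ciw_max_margin(g, r, b3, seed_budget_vector(c(2, 0, 0)),
                             rng_seed = 11)
  expect_setequal(s$sets[[1]], c(1L, 2L))
})

test_that("expected immediate adoption matches closed forms and Monte Carlo", {
  # a degree-1 node whose only neighbor is a seed adopts surely (k = 1)
  g <- star_graph(3)
  b1 <- behavior_set(0.2)
  seeds <- seeds_k1(1L, 4)
  expect_equal(compute_ia(g, rep(1, 4), b1, seeds, 1), 3)

  # no node adjacent to a seed of behavior 2
  expect_equal(compute_ia(g, rep(1, 4), behavior_set(c(0.2, 0.5)),
                          seed_assignment(list(1L, integer(0)), 4), 2), 0)

  # degree-2 node with one seeded neighbor: probability 1/2
  gp <- path_graph(3)
  expect_equal(compute_ia(gp, rep(1, 3), b1, seeds_k1(1L, 3), 1), 0.5)

  # multi-behavior case against a one-step Monte-Carlo oracle
  set.seed(12)
  g6 <- gen_small_world(6, 2, 0.4)
  r <- runif(6, 0.3, 1)
  seeds3 <- seed_assignment(list(1L, 4L, integer(0)), 6, "S-NT")
  ia <- vapply(1:3, function(i) compute_ia(g6, r, b3, seeds3, i, w = 0.5),
               numeric(1))
  runs <- 10000
  counts <- matrix(0, runs, 3)
  for (it in seq_len(runs)) {
    e <- endowment(r, matrix(runif(18), 6, 3))
    out <- run_diffusion(g6, e, b3, seeds3, w = 0.5, mode = "sticky",
                         max_epochs = 1)
    counts[it, ] <- vapply(1:3, function(i) {
      sum(vapply(seq_len(6), function(v) {
        !(v %in% c(1L, 4L)) && i %in% out$state$adopted[[v]]
      }, logical(1)))
    }, numeric(1))
  }
  for (i in 1:3) {
    se <- sd(counts[, i]) / sqrt(runs)
    expect_lt(abs(mean(counts[, i]) - ia[i]), 3 * se + 1e-6)
  }
})

test_that("incremental EIA selection is exhaustive-optimal for one seed", {
  set.seed(13)
  g <- gen_preferential_attachment(20)
  r <- runif(20, 0.2, 1)
  b1 <- behavior_set(0.4)
  s <- select_eia(g, r, b1, seed_budget_vector(1L), rng_seed = 14)
  ia_all <- vapply(1:20, function(v) {
    compute_ia(g, r, b1, seeds_k1(v, 20), 1)
  }, numeric(1))
  expect_equal(ia_all[s$sets[[1]]], max(ia_all), tolerance = 1e-9)

  # empty budget, and no node is ever selected twice
  s0 <- select_eia(g, r, b1, seed_budget_vector(0L))
  expect_length(s0$sets[[1]], 0)
  s6 <- select_eia(g, r, behavior_set(c(0.2, 0.5)),
                   seed_budget_vector(c(3L, 3L)), rng_seed = 15)
  expect_equal(anyDuplicated(unlist(s6$sets)), 0)
})

test_that("greedy selection maximizes exact spread and meets the 1-1/e bound", {
  g <- cycle_graph(8)
  b1 <- behavior_set(0.3)
  set.seed(16)
  r <- runif(8, 0.3, 1)  # everyone affordable: no top-up distortion
  exact_spread <- function(seeds) {
    exact_sigma_k1(g, unlist(seeds$sets), eligible = r >= 0.3)
  }
  s1 <- select_greedy_kkt(g, r, b1, seed_budget_vector(1L),
                          rng_seed = 17, spread_fn = exact_spread)
  brute <- vapply(1:8, function(v) {
    exact_sigma_k1(g, v, eligible = r >= 0.3)
  }, numeric(1))
  expect_equal(brute[s1$sets[[1]]], max(brute), tolerance = 1e-9)

  s2 <- select_greedy_kkt(g, r, b1, seed_budget_vector(2L),
                          rng_seed = 18, spread_fn = exact_spread)
  achieved <- exact_sigma_k1(g, s2$sets[[1]], eligible = r >= 0.3)
  pairs <- utils::combn(8, 2)
  opt <- max(vapply(seq_len(ncol(pairs)), function(j) {
    exact_sigma_k1(g, pairs[, j], eligible = r >= 0.3)
  }, numeric(1)))
  expect_gte(achieved, (1 - 1 / exp(1)) * opt)

  # Monte-Carlo scoring is deterministic under a fixed seed
  m1 <- select_greedy_kkt(g, r, b1, seed_budget_vector(2L),
                          spread_runs = 50, rng_seed = 19)
  m2 <- select_greedy_kkt(g, r, b1, seed_budget_vector(2L),
                          spread_runs = 50, rng_seed = 19)
  expect_identical(m1, m2)
})

test_that("every heuristic honors the budget and the variant contract", {
  set.seed(20)
  g <- gen_spatially_clustered(60, 6)
  r <- runif(60)
  budget <- distribute_behaviors("uniform", 9, b3)
  seeders <- list(
    random = function(v) select_random(g, r, budget, b3, v),
    degree_resource = function(v) select_degree_resource(g, r, b3, budget, v),
    ciw_rank = function(v) select_ciw_ranked(g, r, b3, budget, v),
    ciw_margin = function(v) select_ciw_max_margin(g, r, b3, budget, v),
    eia = function(v) select_eia(g, r, b3, budget, variant = v)
  )
  for (nm in names(seeders)) {
    for (v in c("S-T", "S-NT")) {
      s <- seeders[[nm]](v)
      expect_equal(lengths(s$sets), as.integer(budget),
                   info = paste(nm, v))
      r_eff <- r + s$topped_up
      for (i in 1:3) {
        expect_true(all(r_eff[s$sets[[i]]] >= b3$cost[i] - 1e-9),
                    info = paste(nm, v))
      }
      if (v == "S-NT") {
        expect_true(all(s$topped_up == 0), info = nm)
        for (i in 1:3) {
          expect_true(all(r[s$sets[[i]]] >= b3$cost[i] - 1e-9), info = nm)
        }
      }
    }
  }
})

test_that("multi-behavior variants can stack behaviors on one seed", {
  st <- star_graph(4)
  r <- c(1, rep(0.05, 4))
  s <- select_naive_degree(st, r, b3, seed_budget_vector(c(1, 1, 0)),
                           "knapsack", rng_seed = 21)
  # the hub affords {1, 2} together (0.7 <= 1)
  expect_identical(s$sets[[1]], 1L)
  expect_identical(s$sets[[2]], 1L)
  expect_identical(s$variant, "M-NT")
})
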