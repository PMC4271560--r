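test_that("manhattan distance matches its definition", {
  expect_identical(manhattan_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(manhattan_distance(c(0, 0), c(1, 2)), 3)
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(manhattan_distance(a, b), sum(abs(a - b)))
  }
  expect_error(manhattan_distance(1:3, 1:4), "equal dimensions")
})

test_that("shared fitness obeys the sharing-kernel identities", {
  prm <- sharing_params(epsilon = 1, alpha = 50)
  # identical individuals: every kernel term is 1, so f_S = f_R * pop size
  pop <- matrix(0.5, nrow = 6, ncol = 3)
  expect_equal(shared_fitness(rep(3, 6), pop, prm), rep(3 * 6, 6))
  # isolated individuals keep their raw fitness
  iso <- rbind(c(0, 0), c(10, 10), c(-10, 5))
  expect_equal(shared_fitness(c(1, 2, 3), iso, prm), c(1, 2, 3))
  # two individuals at distance eps/2 with alpha = 1: m = 1.5
  prm1 <- sharing_params(epsilon = 1, alpha = 1)
  two <- rbind(c(0, 0), c(0.25, 0.25))
  expect_equal(shared_fitness(c(1, 1), two, prm1), c(1.5, 1.5))
  expect_error(shared_fitness(c(1, 2), pop, prm), "same length")
})

test_that("sharing preserves raw ranking of mutually isolated individuals", {
  prm <- sharing_params(epsilon = 0.5, alpha = 50)
  set.seed(33)
  pos <- matrix(10 * seq_len(8), ncol = 1) + rnorm(8, 0, 0.1)
  raw <- runif(8)
  expect_identical(order(shared_fitness(raw, pos, prm)), order(raw))
  expect_equal(shared_fitness(raw, pos, prm), raw)
})

test_that("DE trials honour degenerate limits, bounds and determinism", {
  set.seed(4)
  pop <- matrix(runif(20), nrow = 5, ncol = 4)
  st <- de_state_init(5, 0, 1)
  st$best <- 1L
  # F = 0 with crossover keeping parent coordinates: best-guided collapses
  # to the parent
  tr <- de_generate_trial(pop, 3L, st, F = 0, cr = 0, strategy = 2L)
  expect_equal(tr$x, pop[3, ])
  # bounds are respected under an extreme scale factor
  tr2 <- de_generate_trial(pop, 2L, st, F = 2, cr = 1)
  expect_true(all(tr2$x >= 0 & tr2$x <= 1))
  expect_error(de_generate_trial(pop[1:3, ], 1L, st), "at least 4")
  # same seed, same trial (crossover rates fixed so no state mutates)
  st$cr <- rep(0.5, 5)
  a <- cqs:::with_seed(10, de_generate_trial(pop, 1L, st))
  b <- cqs:::with_seed(10, de_generate_trial(pop, 1L, st))
  expect_identical(a, b)
})

test_that("the fraction of rand-base trials tracks the strategy probability", {
  set.seed(6)
  pop <- matrix(runif(40), nrow = 10, ncol = 4)
  st <- de_state_init(10, 0, 1)
  st$best <- 1L
  for (p in c(0.25, 0.7)) {
    st$p <- p
    frac <- mean(vapply(seq_len(10000), function(i)
      de_generate_trial(pop, 1L, st)$strategy == 1L, logical(1)))
    expect_lt(abs(frac - p), 0.05)
  }
})

test_that("the local search descends a sphere and never worsens", {
  res <- dscg_local_search(c(3, 4), function(x) sum(x^2), 200)
  expect_lt(sqrt(sum(as.numeric(res)^2)), 1e-3)
  expect_lte(attr(res, "evals"), 200L)
  # budget 1: no line search fits, x0 comes back unevaluated
  res1 <- dscg_local_search(c(3, 4), function(x) sum(x^2), 1)
  expect_equal(as.numeric(res1), c(3, 4))
  expect_identical(attr(res1, "evals"), 0L)
  # monotone on assorted starts and objectives, within budget
  objs <- list(function(x) sum(abs(x)), function(x) sum((x - 2)^2),
               function(x) sum(x^2) + 5 * sin(sum(x))^2 + 10)
  set.seed(40)
  for (f in objs) for (i in 1:5) {
    x0 <- rnorm(3, 0, 3)
    r <- dscg_local_search(x0, f, 60)
    expect_lte(attr(r, "value"), f(x0))
    expect_lte(attr(r, "evals"), 60L)
  }
  # a start at the optimum stays there
  r0 <- dscg_local_search(c(0, 0), function(x) sum(x^2), 50)
  expect_equal(attr(r0, "value"), 0)
})

test_that("run_ma converges on a convex toy, deterministically, within budget", {
  target <- c(0.3, 0.7)
  calls <- 0L
  obj <- function(x) { calls <<- calls + 1L; sum((x - target)^2) }
  cfg <- ma_config(pop_size = 10, dim = 2, lower = 0, upper = 1,
                   max_evals = 5000, seed = 7)
  res <- run_ma(obj, cfg, sharing_params(epsilon = 0.2))
  expect_lt(max(abs(res$population[1, ] - target)), 0.05)
  expect_lte(calls, 5000L + 10L) # budget + initialization
  expect_identical(res$evals, 5000L)
  res2 <- run_ma(function(x) sum((x - target)^2), cfg,
                 sharing_params(epsilon = 0.2))
  expect_identical(res$population, res2$population)
  expect_identical(res$raw, res2$raw)
  # trace records both raw and shared bests per generation
  expect_true(all(c("generation", "best_raw", "best_shared") %in%
                    names(res$trace)))
  expect_identical(nrow(res$trace), res$generations)
})

test_that("fitness sharing disperses the population on an equal-peak toy", {
  f5 <- function(x) 1 - sin(5 * pi * x[1])^6
  mean_pairdist <- function(eps, seed) {
    cfg <- ma_config(pop_size = 10, dim = 1, lower = 0, upper = 1,
                     max_evals = 3000, ls_evals = 10, seed = seed)
    r <- run_ma(f5, cfg, sharing_params(epsilon = eps, alpha = 50))
    mean(dist(r$population, method = "manhattan"))
  }
  # epsilon ~ 0 disables the kernel (all pairs isolated): no niching force.
  # Averaged over seeds since single runs are noisy.
  with_sharing <- vapply(1:5, function(s) mean_pairdist(0.05, s), numeric(1))
  without <- vapply(1:5, function(s) mean_pairdist(1e-9, s), numeric(1))
  expect_gt(mean(with_sharing), mean(without))
})
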