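# Multimodal memetic optimizer: self-adaptive differential evolution with
# neighborhood search for the global stage, fitness sharing for niching, and
# a Davies-Swann-Campey-style derivative-free line search (with Gram-Schmidt
# re-orthogonalization of the direction set) for local refinement.

#' Fitness-sharing parameters
#'
#' @param epsilon niching radius (Manhattan distance); individuals closer
#'   than `epsilon` degrade each other's shared fitness.
#' @param alpha shape of the sharing kernel `(1 - d/epsilon)^alpha`.
#' @return An object of class `sharing_params`.
#' @export
sharing_params <- function(epsilon, alpha = 50) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  structure(list(epsilon = epsilon, alpha = alpha), class = "sharing_params")
}

#' Memetic-algorithm configuration
#'
#' @param pop_size number of individuals (>= 2; the DE stage needs >= 4).
#' @param dim dimensionality of the search space.
#' @param lower,upper box bounds; coordinates are kept strictly inside
#'   `(lower, upper)` by a `1e-9` margin.
#' @param max_evals budget of raw-objective evaluations (initialization of
#'   the population is not counted against it).
#' @param ls_evals per-individual, per-generation budget of the local
#'   search; defaults to `2 * dim`.
#' @param ls_step initial step size of the local search; defaults to a
#'   tenth of the box width.
#' @param seed RNG seed making the whole run reproducible.
#' @return An object of class `ma_config`.
#' @export
ma_config <- function(pop_size, dim, lower = 0, upper = 1,
                      max_evals = 1e4, ls_evals = 2L * dim,
                      ls_step = 0.1 * (upper - lower), seed = 1L) {
  stopifnot(pop_size >= 2, dim >= 1, max_evals > 0, upper > lower,
            ls_step > 0)
  structure(
    list(pop_size = as.integer(pop_size), dim = as.integer(dim),
         lower = lower, upper = upper,
         max_evals = as.integer(max_evals),
         ls_evals = as.integer(ls_evals), ls_step = ls_step,
         seed = as.integer(seed)),
    class = "ma_config"
  )
}

#' Manhattan distance between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return `sum(abs(a - b))`.
#' @export
manhattan_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal dimensions")
  sum(abs(a - b))
}

# Niche count of a point against a set of other positions (matrix rows).
niche_count <- function(x, others, params) {
  if (nrow(others) == 0L) return(1)
  d <- colSums(abs(t(others) - x))
  inside <- d <= params$epsilon
  1 + sum((1 - d[inside] / params$epsilon)^params$alpha)
}

#' Shared fitness of a population under fitness sharing
#'
#' Crowded individuals get inflated (worse, under minimization) fitness:
#' `f_S(x_i) = f_R(x_i) * m_i` with niche count
#' `m_i = 1 + sum_{j != i, d_ij <= eps} (1 - d_ij/eps)^alpha`, where `d_ij`
#' is the Manhattan distance. Isolated individuals keep `f_S == f_R`.
#'
#' @param raw nonnegative raw fitness values, one per individual.
#' @param positions matrix of positions (one row per individual) or a list
#'   of numeric vectors.
#' @param params a [sharing_params()].
#' @return Numeric vector of shared fitness values.
#' @export
shared_fitness <- function(raw, positions, params) {
  if (is.list(positions)) positions <- do.call(rbind, positions)
  positions <- as.matrix(positions)
  if (length(raw) != nrow(positions))
    stop("raw fitness and positions must have the same length")
  D <- as.matrix(stats::dist(positions, method = "manhattan"))
  sh <- (1 - D / params$epsilon)^params$alpha
  sh[D > params$epsilon] <- 0
  diag(sh) <- 0
  unname(raw * (1 + rowSums(sh)))
}

#' Initialize the self-adaptation state of the differential-evolution stage
#'
#' Holds the mutation-strategy probability `p`, the Gaussian-vs-Cauchy
#' step-size mixing probability `fp` and the crossover-rate mean `crm`,
#' all re-estimated by [run_ma()] from recorded successes and failures
#' (windows: `p` and `fp` every 50 generations, `crm` every 25; per-individual
#' crossover rates resampled every 5).
#'
#' @param pop_size population size.
#' @param lower,upper box bounds used to clamp trials.
#' @return An environment of class `de_state`.
#' @export
de_state_init <- function(pop_size, lower, upper) {
  e <- new.env(parent = emptyenv())
  e$p <- 0.5
  e$fp <- 0.5
  e$crm <- 0.5
  e$cr <- rep(NA_real_, pop_size)
  e$best <- 1L
  e$ns <- c(0L, 0L); e$nf <- c(0L, 0L)      # strategy successes/failures
  e$fns <- c(0L, 0L); e$fnf <- c(0L, 0L)    # F-distribution successes/failures
  e$cr_rec <- numeric(0)                     # successful CRs
  e$cr_w <- numeric(0)                       # their fitness improvements
  e$lower <- lower
  e$upper <- upper
  class(e) <- "de_state"
  e
}

de_refresh_cr <- function(state) {
  state$cr <- pmin(pmax(rnorm(length(state$cr), state$crm, 0.1), 0), 1)
}

de_adapt <- function(state, gen) {
  if (gen %% 25L == 0L && length(state$cr_rec) > 0) {
    state$crm <- sum(state$cr_rec * state$cr_w) / sum(state$cr_w)
    state$cr_rec <- numeric(0)
    state$cr_w <- numeric(0)
  }
  if (gen %% 50L == 0L) {
    ns <- state$ns; nf <- state$nf
    if (sum(ns) > 0L) {
      denom <- ns[2] * (ns[1] + nf[1]) + ns[1] * (ns[2] + nf[2])
      if (denom > 0)
        state$p <- min(max(ns[1] * (ns[2] + nf[2]) / denom, 0.05), 0.95)
    }
    state$ns <- c(0L, 0L); state$nf <- c(0L, 0L)
    fns <- state$fns; fnf <- state$fnf
    if (sum(fns) > 0L) {
      denom <- fns[2] * (fns[1] + fnf[1]) + fns[1] * (fns[2] + fnf[2])
      if (denom > 0)
        state$fp <- min(max(fns[1] * (fns[2] + fnf[2]) / denom, 0.05), 0.95)
    }
    state$fns <- c(0L, 0L); state$fnf <- c(0L, 0L)
  }
  invisible(state)
}

#' Generate one differential-evolution trial vector
#'
#' One of two mutation strategies is chosen with the self-adapted
#' probability held in `state`: rand-base `x_r1 + F*(x_r2 - x_r3)` or
#' best-guided `x_i + F*(x_best - x_i) + F*(x_r1 - x_r2)`. The scale factor
#' `F` is drawn from `|N(0.5, 0.3)|` or `|Cauchy(0, 1)|` with the adapted
#' mixing probability; binomial crossover uses the individual's adapted
#' crossover rate. The trial is clamped strictly inside the bounds.
#'
#' @param pop population matrix, one row per individual (needs >= 4 rows).
#' @param i index of the parent.
#' @param state a `de_state` as maintained by [run_ma()].
#' @param F,cr,strategy optional overrides of the sampled scale factor,
#'   crossover rate and mutation strategy (used in tests of degenerate
#'   limits).
#' @return A list with `x` (the trial), `strategy` (1 = rand-base,
#'   2 = best-guided), `F`, `cr` and `f_gauss` (whether `F` was Gaussian).
#' @export
de_generate_trial <- function(pop, i, state, F = NULL, cr = NULL,
                              strategy = NULL) {
  n <- nrow(pop)
  if (n < 4L) stop("differential evolution needs a population of at least 4")
  d <- ncol(pop)
  strategy <- strategy %||% if (runif(1) < state$p) 1L else 2L
  f_gauss <- runif(1) < state$fp
  if (is.null(F)) {
    F <- if (f_gauss) abs(rnorm(1, 0.5, 0.3)) else abs(rcauchy(1))
    F <- min(F, 2)
  }
  if (is.null(cr)) {
    if (is.na(state$cr[i])) de_refresh_cr(state)
    cr <- state$cr[i]
  }
  r <- sample(setdiff(seq_len(n), i), 3L)
  mutant <- if (strategy == 1L) {
    pop[r[1], ] + F * (pop[r[2], ] - pop[r[3], ])
  } else {
    pop[i, ] + F * (pop[state$best, ] - pop[i, ]) + F * (pop[r[1], ] - pop[r[2], ])
  }
  jrand <- sample.int(d, 1L)
  take <- runif(d) < cr
  take[jrand] <- TRUE
  x <- pop[i, ]
  x[take] <- mutant[take]
  x <- pmin(pmax(x, state$lower + 1e-9), state$upper - 1e-9)
  list(x = x, strategy = strategy, F = F, cr = cr, f_gauss = f_gauss)
}

#' Derivative-free local search (Davies-Swann-Campey style)
#'
#' Successive line searches along an orthogonal direction set: each line
#' search doubles a step while it improves, then refines the bracket by
#' quadratic interpolation. After every sweep the direction set is rebuilt
#' by Gram-Schmidt with the sweep's net progress direction first. The step
#' is halved when a sweep makes no progress. The result never has a worse
#' objective value than `x0`, and at most `eval_budget` objective calls are
#' made (a budget of 1 returns `x0` unevaluated: no line search fits).
#'
#' @param x0 starting point.
#' @param objective function mapping a numeric vector to a scalar.
#' @param eval_budget maximum number of objective evaluations (>= 1).
#' @param step initial step size.
#' @param lower,upper optional box bounds for candidate points.
#' @return The improved point, with attributes `value` (its objective) and
#'   `evals` (objective calls used).
#' @export
dscg_local_search <- function(x0, objective, eval_budget, step = 0.5,
                              lower = -Inf, upper = Inf) {
  if (eval_budget < 1) stop("eval_budget must be >= 1")
  n <- length(x0)
  used <- 0L
  evalf <- function(x) {
    used <<- used + 1L
    objective(x)
  }
  clamp <- function(x) pmin(pmax(x, lower), upper)
  if (eval_budget < 2L) {
    out <- x0
    attr(out, "value") <- NA_real_
    attr(out, "evals") <- 0L
    return(out)
  }
  best_x <- clamp(x0)
  best_f <- evalf(best_x)
  V <- diag(n)
  s <- step
  repeat {
    sweep_start <- best_x
    improved_sweep <- FALSE
    for (k in seq_len(n)) {
      if (used >= eval_budget) break
      dirv <- V[, k]
      # bracket: try +s, then -s
      for (sgn in c(1, -1)) {
        if (used >= eval_budget) break
        t1 <- sgn * s
        x1 <- clamp(best_x + t1 * dirv)
        f1 <- evalf(x1)
        if (f1 < best_f) {
          # expand while improving
          t0 <- 0; f0 <- best_f
          while (used < eval_budget) {
            t2 <- 2 * t1
            x2 <- clamp(best_x + t2 * dirv)
            f2 <- evalf(x2)
            if (f2 < f1) {
              t0 <- t1; f0 <- f1
              t1 <- t2; f1 <- f2
            } else {
              # quadratic interpolation on (t0, t1, t2)
              denom <- (f0 - 2 * f1 + f2)
              if (used < eval_budget && is.finite(denom) && denom > 0) {
                tq <- t1 + (t2 - t1) / 2 * (f0 - f2) / (2 * denom)
                xq <- clamp(best_x + tq * dirv)
                fq <- evalf(xq)
                if (fq < f1) {
                  t1 <- tq; f1 <- fq
                }
              }
              break
            }
          }
          best_x <- clamp(best_x + t1 * dirv)
          best_f <- f1
          improved_sweep <- TRUE
          break # direction done; don't also try the other sign
        }
      }
    }
    if (used >= eval_budget) break
    progress <- best_x - sweep_start
    if (!improved_sweep || sqrt(sum(progress^2)) < 1e-12) {
      s <- s / 2
      if (s < 1e-9) break
    } else {
      V <- gram_schmidt_directions(progress, n)
    }
  }
  out <- best_x
  attr(out, "value") <- best_f
  attr(out, "evals") <- used
  out
}

# Orthonormal direction set with z (normalized) first, completed from the
# standard basis by Gram-Schmidt.
gram_schmidt_directions <- function(z, n) {
  V <- matrix(0, n, n)
  V[, 1] <- z / sqrt(sum(z^2))
  k <- 1L
  for (j in seq_len(n)) {
    if (k == n) break
    e <- numeric(n)
    e[j] <- 1
    w <- e - V[, seq_len(k), drop = FALSE] %*%
      crossprod(V[, seq_len(k), drop = FALSE], e)
    nw <- sqrt(sum(w^2))
    if (nw > 1e-8) {
      k <- k + 1L
      V[, k] <- w / nw
    }
  }
  V
}

#' Run the memetic algorithm
#'
#' Alternates one generation of differential evolution -- selection by
#' shared fitness, computed against the current population -- with a
#' per-individual local-search refinement, until the raw-objective
#' evaluation budget is exhausted. Shared fitness is recomputed once per
#' generation; a trial replaces its parent iff its shared fitness (niche
#' count taken against the other current individuals) is lower. Local
#' search accepts only raw improvements, so it cannot worsen any
#' individual. Fully reproducible from `config$seed`.
#'
#' @param objective function from a numeric vector of length `config$dim`
#'   to a nonnegative scalar (smaller is better).
#' @param config an [ma_config()].
#' @param sharing a [sharing_params()].
#' @return An object of class `ma_result`: `population` (matrix sorted by
#'   raw fitness), `raw` (sorted raw fitness), `trace` (per-generation
#'   data.frame with best raw and best shared fitness), `evals`,
#'   `generations`.
#' @export
run_ma <- function(objective, config, sharing) {
  stopifnot(inherits(config, "ma_config"), inherits(sharing, "sharing_params"))
  with_seed(config$seed, {
    np <- config$pop_size
    d <- config$dim
    lo <- config$lower + 1e-9
    hi <- config$upper - 1e-9
    evals <- 0L
    limit <- config$max_evals
    evalf <- function(x) {
      evals <<- evals + 1L
      objective(x)
    }
    pop <- matrix(runif(np * d, lo, hi), nrow = np, ncol = d)
    raw <- apply(pop, 1L, objective) # initialization, outside the budget
    state <- de_state_init(np, config$lower, config$upper)
    gen <- 0L
    trace <- vector("list", 0L)
    while (evals < limit) {
      gen <- gen + 1L
      if (gen %% 5L == 1L) de_refresh_cr(state)
      state$best <- which.min(raw)
      sh <- shared_fitness(raw, pop, sharing)
      if (np >= 4L) {
        for (i in seq_len(np)) {
          if (evals >= limit) break
          tr <- de_generate_trial(pop, i, state)
          f_t <- evalf(tr$x)
          m_t <- niche_count(tr$x, pop[-i, , drop = FALSE], sharing)
          if (f_t * m_t < sh[i]) {
            improvement <- max(raw[i] - f_t, 0)
            pop[i, ] <- tr$x
            raw[i] <- f_t
            state$ns[tr$strategy] <- state$ns[tr$strategy] + 1L
            fi <- if (tr$f_gauss) 1L else 2L
            state$fns[fi] <- state$fns[fi] + 1L
            state$cr_rec <- c(state$cr_rec, tr$cr)
            state$cr_w <- c(state$cr_w, improvement + 1e-12)
          } else {
            state$nf[tr$strategy] <- state$nf[tr$strategy] + 1L
            fi <- if (tr$f_gauss) 1L else 2L
            state$fnf[fi] <- state$fnf[fi] + 1L
          }
        }
      }
      for (i in seq_len(np)) {
        budget <- min(config$ls_evals, limit - evals)
        if (budget < 2L) break
        res <- dscg_local_search(pop[i, ], evalf, budget,
                                 step = config$ls_step,
                                 lower = lo, upper = hi)
        if (!is.na(attr(res, "value")) && attr(res, "value") <= raw[i]) {
          raw[i] <- attr(res, "value")
          pop[i, ] <- as.numeric(res)
        }
      }
      de_adapt(state, gen)
      trace[[gen]] <- data.frame(
        generation = gen, evals = evals,
        best_raw = min(raw),
        best_shared = min(shared_fitness(raw, pop, sharing)))
    }
    ord <- order(raw)
    structure(
      list(population = pop[ord, , drop = FALSE],
           raw = raw[ord],
           trace = if (length(trace)) do.call(rbind, trace) else
             data.frame(generation = integer(0), evals = integer(0),
                        best_raw = numeric(0), best_shared = numeric(0)),
           evals = evals, generations = gen,
           config = config, sharing = sharing),
      class = "ma_result"
    )
  })
}

#' @export
print.ma_result <- function(x, ...) {
  cat(sprintf(
    "ma_result: %d individuals, %d generations, %d evaluations\n  best raw fitness: %.6g\n",
    nrow(x$population), x$generations, x$evals, x$raw[1]))
  invisible(x)
}
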