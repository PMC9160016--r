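test_that("a target with no infection events yields an all-zero fit", {
  set.seed(1)
  S <- cbind(rep(0L, 30), matrix(rbinom(60, 1, 0.5), ncol = 2))
  fit <- em_full(S, 0, pair_candidates = c(1L, 2L),
                 triple_candidates = rbind(c(1L, 2L)))
  expect_true(all(fit$p_pair == 0))
  expect_true(all(fit$p_triple$p == 0))
  expect_equal(fit$epsilon, 0)
})

test_that("log-likelihood is non-decreasing within every EM segment", {
  sc <- toy_complex()
  S <- simulate_contagion(sc, 600, alpha = 0.9, omega = 2, mu = 1,
                          rho0 = 0.3, reseed = TRUE, seed = 7)
  for (i in c(0, 2, 4)) {
    fit <- em_full(S, i,
                   pair_candidates = setdiff(0:5, i),
                   triple_candidates = unrank_pairs_for_test(6))
    tr <- fit$loglik_trace
    bounds <- cumsum(fit$trace_segments)
    start <- 1L
    for (b in bounds) {
      seg <- tr[start:b]
      if (length(seg) > 1L) {
        expect_true(all(diff(seg) >= -1e-8 * abs(seg[-length(seg)])))
      }
      start <- b + 1L
    }
  }
})

test_that("responsibilities recomputed from the fit sum to one at every event", {
  sc <- toy_complex()
  S <- simulate_contagion(sc, 500, alpha = 0.9, omega = 2, mu = 1,
                          rho0 = 0.3, reseed = TRUE, seed = 8)
  i <- 0L
  cand <- setdiff(0:5, i)
  tc <- unrank_pairs_for_test(6)
  tc <- tc[tc[, 1L] != i & tc[, 2L] != i, ]
  fit <- em_full(S, i, cand, tc, prune = FALSE)
  ec <- empirical_conditionals(S, i, candidate_pairs = tc)
  m <- unclass(S)
  sus <- which(m[-nrow(m), i + 1L] == 0L)
  events <- sus[m[sus + 1L, i + 1L] == 1L]
  pcp <- ec$pair$p; pcp[is.na(pcp)] <- 0
  pct <- ec$triple$p; pct[is.na(pct)] <- 0
  for (t in events) {
    act_p <- m[t, ec$pair$j + 1L]
    act_t <- m[t, ec$triple$j + 1L] * m[t, ec$triple$k + 1L]
    num_p <- fit$p_pair[as.character(ec$pair$j)] * pcp * act_p
    num_t <- fit$p_triple$p * pct * act_t
    denom <- sum(num_p) + sum(num_t) + fit$epsilon
    rho <- c(num_p, num_t, fit$epsilon) / denom
    expect_equal(sum(rho), 1, tolerance = 1e-10)
  }
})

test_that("EM attains the grid-search maximum on a small instance", {
  sc <- simplicial_complex(4, edges = rbind(c(0, 1), c(2, 3)))
  S <- simulate_contagion(sc, 40, beta1 = 0.6, beta2 = 0, mu = 1,
                          rho0 = 0.5, reseed = TRUE, seed = 13)
  i <- 0L
  cand <- c(1L, 2L)
  fit <- em_full(S, i, cand, NULL, prune = FALSE)
  ll_em <- pairwise_loglik(unclass(S), i, cand,
                           p = unname(fit$p_pair), eps = max(fit$epsilon, 1e-12))
  grid <- seq(0.01, 1, by = 0.015)
  eps_grid <- seq(0.01, 0.5, by = 0.01)
  best <- -Inf
  for (p1 in grid) for (p2 in grid) {
    lls <- vapply(eps_grid, function(e) {
      pairwise_loglik(unclass(S), i, cand, c(p1, p2), e)
    }, numeric(1))
    best <- max(best, max(lls))
  }
  expect_gte(ll_em, best - 1e-6)             # EM at least as good as any grid point
  expect_lt(ll_em - best, 0.05)              # and the grid gets within resolution
})

test_that("em_full with no triple candidates reproduces em_first_step", {
  sc <- toy_complex()
  S <- simulate_contagion(sc, 400, alpha = 0.9, omega = 2, mu = 1,
                          rho0 = 0.3, reseed = TRUE, seed = 9)
  a <- em_first_step(S, 2)
  b <- em_full(S, 2, pair_candidates = setdiff(0:5, 2),
               triple_candidates = NULL, prune = FALSE)
  expect_equal(a$p_pair, b$p_pair)
  expect_equal(a$epsilon, b$epsilon)
  expect_equal(a$loglik_trace, b$loglik_trace)
})

test_that("first-step probabilities rank true neighbours above the rest", {
  # star centred at 0 with leaves 1-4 plus a separate path 5-6-7
  sc <- simplicial_complex(
    8, edges = rbind(c(0, 1), c(0, 2), c(0, 3), c(0, 4), c(5, 6), c(6, 7)))
  S <- simulate_contagion(sc, 6000, beta1 = 0.4, beta2 = 0, mu = 1,
                          rho0 = 0.4, reseed = TRUE, seed = 17)
  fit <- em_first_step(S, 0)
  leaves <- fit$p_pair[c("1", "2", "3", "4")]
  others <- fit$p_pair[c("5", "6", "7")]
  expect_gt(min(leaves), max(others))
})

test_that("stationarity conditions hold at convergence for surviving channels", {
  sc <- toy_complex()
  S <- simulate_contagion(sc, 800, alpha = 0.9, omega = 2, mu = 1,
                          rho0 = 0.3, reseed = TRUE, seed = 19)
  i <- 1L
  cand <- setdiff(0:5, i)
  fit <- em_full(S, i, cand, NULL)
  ec <- empirical_conditionals(S, i)
  m <- unclass(S)
  sus <- which(m[-nrow(m), i + 1L] == 0L)
  y <- m[sus + 1L, i + 1L]
  pc <- ec$pair$p; pc[is.na(pc)] <- 0
  act <- m[sus, ec$pair$j + 1L, drop = FALSE]
  w <- fit$p_pair[as.character(ec$pair$j)] * pc
  d <- as.vector(act %*% w) + max(fit$epsilon, 1e-12)
  for (jx in seq_along(w)) {
    pj <- fit$p_pair[[jx]]
    if (pj > 0) {
      lhs <- sum(y * (w[jx] * act[, jx] / d))   # sum of responsibilities
      rhs <- pc[jx] * sum(act[, jx]) * pj       # stationarity balance
      expect_equal(lhs, rhs, tolerance = 1e-3)
    }
  }
})

test_that("random restarts reproduce the all-ones objective (concavity)", {
  sc <- toy_complex()
  S <- simulate_contagion(sc, 500, alpha = 0.9, omega = 2, mu = 1,
                          rho0 = 0.3, reseed = TRUE, seed = 23)
  one <- em_full(S, 3, setdiff(0:5, 3), NULL, n_restarts = 1)
  multi <- em_full(S, 3, setdiff(0:5, 3), NULL, n_restarts = 3, seed = 5)
  expect_equal(one$loglik_trace[length(one$loglik_trace)],
               multi$loglik_trace[length(multi$loglik_trace)],
               tolerance = 1e-6)
  expect_equal(unname(one$p_pair), unname(multi$p_pair), tolerance = 1e-3)
})
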