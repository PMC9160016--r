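test_that("state_matrix enforces its alphabet", {
  expect_s3_class(state_matrix(matrix(0:1, 2, 2), "binary"), "state_matrix")
  expect_error(state_matrix(matrix(c(0, 2), 1, 2), "binary"), "lie in")
  expect_error(state_matrix(matrix(c(0, 1), 1, 2), "spin"), "lie in")
})

test_that("no transmission and certain recovery empties the system after row 1", {
  sc <- toy_complex()
  S <- simulate_contagion(sc, 20, alpha = 0, omega = 0, mu = 1, rho0 = 0.5,
                          seed = 1)
  expect_true(all(unclass(S)[-1L, ] == 0L))
  expect_gt(sum(unclass(S)[1L, ]), 0)
})

test_that("certain transmission with no recovery absorbs into all-infected", {
  sc <- simplicial_complex(5, edges = rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 4)))
  S <- simulate_contagion(sc, 10, beta1 = 1, beta2 = 0, mu = 0, rho0 = 0.2,
                          seed = 3)
  m <- unclass(S)
  for (t in seq_len(nrow(m) - 1L)) {
    expect_true(all(m[t + 1L, m[t, ] == 1L] == 1L))  # monotone infected set
  }
  expect_true(all(m[nrow(m), ] == 1L))
})

test_that("single-edge one-step infection frequency matches beta1", {
  # 20000 disjoint edges, one endpoint infected, mu = 0: the fraction of
  # partners infected at the next step estimates beta1
  n_edge <- 20000
  edges <- cbind(seq(0, 2 * n_edge - 2, by = 2), seq(1, 2 * n_edge - 1, by = 2))
  sc <- simplicial_complex(2 * n_edge, edges = edges)
  init <- rep(c(1L, 0L), n_edge)
  beta1 <- 0.3
  S <- simulate_contagion(sc, 2, beta1 = beta1, beta2 = 0, mu = 0,
                          init = init, seed = 11)
  phat <- mean(unclass(S)[2L, init == 0L])
  se <- sqrt(beta1 * (1 - beta1) / n_edge)
  expect_lt(abs(phat - beta1), 3 * se)
})

test_that("every recorded infection has an active channel (mu = 1 traces)", {
  sc <- generate_ersc(40, 6, 2, seed = 2)
  S <- simulate_contagion(sc, 400, alpha = 0.8, omega = 2.4, mu = 1,
                          rho0 = 0.2, reseed = TRUE, seed = 4)
  expect_true(all_infections_explained(S, sc, attr(S, "reseed_events")))
})

test_that("reseeding records events and keeps the series alive", {
  sc <- generate_ersc(40, 6, 2, seed = 2)
  S <- simulate_contagion(sc, 500, alpha = 0.8, omega = 2.4, mu = 1,
                          rho0 = 0.2, reseed = TRUE, seed = 4)
  ev <- attr(S, "reseed_events")
  expect_gt(length(ev), 0)
  m <- unclass(S)
  # the row before a reseed is extinct; the reseed row carries the seeds
  expect_true(all(rowSums(m[ev - 1L, , drop = FALSE]) == 0))
  expect_true(all(rowSums(m[ev, , drop = FALSE]) == floor(0.2 * 40)))
  # without reseeding the same dynamics go extinct and stay extinct
  S0 <- simulate_contagion(sc, 500, alpha = 0.8, omega = 2.4, mu = 1,
                           rho0 = 0.2, reseed = FALSE, seed = 4)
  m0 <- unclass(S0)
  dead <- which(rowSums(m0) == 0)
  if (length(dead)) expect_true(all(rowSums(m0[dead[1L]:500, , drop = FALSE]) == 0))
})

test_that("contagion and Ising runs are reproducible under a fixed seed", {
  sc <- toy_complex()
  expect_identical(
    simulate_contagion(sc, 50, alpha = 0.5, omega = 1, mu = 0.5, seed = 9),
    simulate_contagion(sc, 50, alpha = 0.5, omega = 1, mu = 0.5, seed = 9))
  expect_identical(simulate_ising(sc, 50, delta = 1, seed = 9),
                   simulate_ising(sc, 50, delta = 1, seed = 9))
})

test_that("infinite-temperature and free spins flip at rate 1/2", {
  sc <- toy_complex()
  for (args in list(list(delta = 0, J1 = 2, J2 = 3),
                    list(delta = 2, J1 = 0, J2 = 0))) {
    S <- do.call(simulate_ising,
                 c(list(sc = sc, steps = 2000, seed = 5), args))
    m <- unclass(S)
    flips <- colMeans(m[-1L, ] != m[-nrow(m), ])
    se <- sqrt(0.25 / (nrow(m) - 1))
    expect_true(all(abs(flips - 0.5) < 4 * se))
  }
})

test_that("two-spin chain matches its exact stationary distribution", {
  sc <- simplicial_complex(2, edges = rbind(c(0, 1)))
  J1 <- 1; delta <- 0.8
  S <- simulate_ising(sc, 40000, J1 = J1, J2 = 0, delta = delta, seed = 21)
  m <- unclass(S)
  aligned_hat <- mean(m[, 1L] == m[, 2L])
  pi <- two_spin_stationary(J1, delta)
  aligned_exact <- pi[1L] + pi[4L]       # (-1,-1) and (+1,+1)
  expect_lt(abs(aligned_hat - aligned_exact), 0.02)
})

test_that("strong coupling orders a connected system relative to delta = 0", {
  sc <- simplicial_complex(8, edges = unrank_pairs_for_test(8))
  mag <- function(delta, seed) {
    S <- simulate_ising(sc, 2000, J1 = 1, J2 = 0, delta = delta, seed = seed)
    m <- unclass(S)
    mean(abs(rowMeans(m[1501:2000, ])))
  }
  expect_gt(mag(2, 31), mag(0, 31))
})

test_that("asynchronous Glauber updates run and keep the alphabet", {
  sc <- toy_complex()
  S <- simulate_ising(sc, 30, delta = 1, method = "glauber", seed = 2)
  expect_true(all(unclass(S) %in% c(-1L, 1L)))
  expect_equal(dim(S), c(30L, 6L))
})
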