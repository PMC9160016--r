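test_that("constructor canonicalises input and validates closure", {
  sc <- simplicial_complex(4, edges = rbind(c(1, 0), c(2, 0), c(2, 1), c(3, 2), c(0, 1)),
                           triangles = rbind(c(2, 1, 0)))
  expect_equal(sc$edges, rbind(c(0L, 1L), c(0L, 2L), c(1L, 2L), c(2L, 3L)))
  expect_equal(sc$triangles, rbind(c(0L, 1L, 2L)))
  expect_equal(unname(average_degrees(sc)), c(2 * 4 / 4, 3 * 1 / 4))

  expect_error(simplicial_complex(4, edges = rbind(c(0, 4))), "labels")
  expect_error(simplicial_complex(4, edges = rbind(c(1, 1))), "self-loop")
  expect_error(
    simplicial_complex(4, edges = rbind(c(0, 1), c(0, 2)),
                       triangles = rbind(c(0, 1, 2))),
    "closure.*\\(0, 1, 2\\)")
})

test_that("ERSC rejects infeasible degree targets with the defining constraint", {
  expect_error(generate_ersc(200, k1_target = 4, k2_target = 2),
               "k1_target > 2\\*k2_target")
  expect_error(generate_ersc(5, k1_target = 10, k2_target = 2),
               "n_nodes - 1\\) > 2\\*k2_target")
})

test_that("ERSC with k2 = 0 is a plain random graph", {
  sc <- generate_ersc(200, k1_target = 6, k2_target = 0, seed = 42)
  expect_equal(nrow(sc$triangles), 0L)
  # p1 = 6/199; |E| ~ Binomial(C(200,2), p1)
  expect_gt(nrow(sc$edges), 400)
  expect_lt(nrow(sc$edges), 800)
})

test_that("ERSC realized degrees are unbiased for the targets", {
  k1s <- k2s <- numeric(50)
  for (s in 1:50) {
    sc <- generate_ersc(200, 12, 4, seed = s)
    k <- average_degrees(sc)
    k1s[s] <- k[["k1"]]; k2s[s] <- k[["k2"]]
  }
  se1 <- sd(k1s) / sqrt(50)
  se2 <- sd(k2s) / sqrt(50)
  expect_lt(abs(mean(k1s) - 12), 3 * se1)
  expect_lt(abs(mean(k2s) - 4), 3 * se2)
})

test_that("generators are reproducible and closure-valid", {
  gens <- list(
    function(s) generate_ersc(60, 6, 2, seed = s),
    function(s) generate_sfsc(60, 3, 2, seed = s),
    function(s) generate_swsc(60, 3, 0.2, 2, seed = s)
  )
  for (g in gens) {
    a <- g(7); b <- g(7); c <- g(8)
    expect_identical(a, b)
    expect_false(identical(a, c))
    expect_silent(validate_complex(a))
  }
})

test_that("SFSC backbone has the expected size and heavy degree tail", {
  n <- 200; m <- 3
  sc <- generate_sfsc(n, m, k2_target = 0, seed = 1)
  expect_equal(nrow(sc$triangles), 0L)
  expect_equal(nrow(sc$edges), choose(m, 2) + m * (n - m))

  ratio <- vapply(1:20, function(s) {
    d <- tabulate(c(generate_sfsc(n, m, 0, seed = s)$edges) + 1L, n)
    max(d) / median(d)
  }, numeric(1))
  expect_true(all(ratio >= 3))
})

test_that("SFSC realized k1 tracks 2m + 2 k2 (1 - 2m/N)", {
  k1s <- vapply(1:20, function(s) {
    average_degrees(generate_sfsc(200, 3, 4, seed = s))[["k1"]]
  }, numeric(1))
  pred <- 2 * 3 + 2 * 4 * (1 - 6 / 200)   # = 13.76
  expect_lt(abs(mean(k1s) - pred), 3 * sd(k1s) / sqrt(20) + 0.1)
})

test_that("SWSC degree structure matches the rewiring regime", {
  sc0 <- generate_swsc(100, 3, rewire_p = 0, k2_target = 0, seed = 1)
  deg0 <- tabulate(c(sc0$edges) + 1L, 100)
  expect_true(all(deg0 == 6L))

  deg_mean <- deg_var <- numeric(10)
  for (s in 1:10) {
    sc1 <- generate_swsc(100, 3, rewire_p = 1, k2_target = 0, seed = s)
    d <- tabulate(c(sc1$edges) + 1L, 100)
    deg_mean[s] <- mean(d); deg_var[s] <- var(d)
  }
  expect_equal(deg_mean, rep(6, 10))     # rewiring conserves edge count
  expect_true(all(deg_var > 0))

  expect_error(generate_swsc(6, 3, 0.1), "2m < n_nodes")
  expect_error(generate_swsc(100, 3, 1.5), "rewire_p")
})
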