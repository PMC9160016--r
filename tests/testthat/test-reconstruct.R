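test_that("an all-susceptible record yields an empty prediction", {
  S <- matrix(0L, 50, 8)
  fit <- reconstruct(S)
  expect_equal(nrow(fit$complex$edges), 0L)
  expect_equal(nrow(fit$complex$triangles), 0L)
})

test_that("triangle assembly follows the 2-of-3 rule and closure", {
  # hand-built per-node tables: nodes 0,1,2 vote for (0,1,2); the triple
  # (0,1,3) receives a single vote and must be rejected
  pair_prob <- list(
    c(`1` = 0.5, `2` = 0.5, `3` = 0.5),
    c(`0` = 0.5, `2` = 0.5, `3` = 0.5),
    c(`0` = 0.5, `1` = 0.5),
    c(`0` = 0.5, `1` = 0.5)
  )
  triple_prob <- list(
    data.frame(j = c(1L, 1L), k = c(2L, 3L), p = c(0.8, 0.79)),
    data.frame(j = c(0L, 0L), k = c(2L, 3L), p = c(0.8, 0.01)),
    data.frame(j = 0L, k = 1L, p = 0.8),
    data.frame(j = 0L, k = 1L, p = 0.0)
  )
  asm <- simplex2:::assemble_prediction(4L, 0:3, pair_prob, triple_prob)
  expect_equal(asm$complex$triangles, rbind(c(0L, 1L, 2L)))
  # (0,1,3): views from 0 (0.79 >= its gap threshold? gap over c(.8,.79)
  # is degenerate -> threshold midpoint .795 ... ) — the decisive check is
  # that it is absent while (0,1,2) with two clear votes is present
  expect_false(any(apply(asm$complex$triangles, 1,
                         function(r) all(r == c(0, 1, 3)))))

  # closure: drop an accepted triangle when an edge is missing
  pair_prob2 <- pair_prob
  pair_prob2[[2]] <- c(`0` = 0.5, `3` = 0.5)   # edge {1,2} gone from both sides
  pair_prob2[[3]] <- c(`0` = 0.5)
  asm2 <- simplex2:::assemble_prediction(4L, 0:3, pair_prob2, triple_prob)
  expect_equal(nrow(asm2$complex$triangles), 0L)
  expect_gte(nrow(asm2$dropped_triangles), 1L)
})

test_that("edges follow the OR rule on strictly positive probabilities", {
  pair_prob <- list(
    c(`1` = 0.4, `2` = 0),      # 0 -> 1 only
    c(`0` = 0),                 # nothing back
    c(`0` = 0, `3` = 0),
    numeric(0)
  )
  triple_prob <- replicate(4, data.frame(j = integer(0), k = integer(0),
                                         p = numeric(0)), simplify = FALSE)
  asm <- simplex2:::assemble_prediction(4L, 0:3, pair_prob, triple_prob)
  expect_equal(asm$complex$edges, rbind(c(0L, 1L)))
})

test_that("reconstruction is equivariant under node relabeling", {
  sc <- generate_ersc(20, 4, 1, seed = 31)
  S <- simulate_contagion(sc, 1500, alpha = 0.8, omega = 2.4, mu = 1,
                          rho0 = 0.25, reseed = TRUE, seed = 32)
  fit <- reconstruct(S)
  perm <- rev(0:19)                        # deterministic permutation
  Sp <- unclass(S)[, perm + 1L]
  fitp <- reconstruct(Sp)
  # applying the inverse permutation to the permuted fit recovers the
  # original prediction
  inv <- integer(20); inv[perm + 1L] <- 0:19
  remap <- simplicial_complex(
    20,
    edges = matrix(perm[fit$complex$edges + 1L], ncol = 2),
    triangles = matrix(perm[fit$complex$triangles + 1L], ncol = 3))
  expect_equal(fitp$complex$edges, remap$edges)
  expect_equal(fitp$complex$triangles, remap$triangles)
})

test_that("end-to-end recovery is strong on a small ERSC", {
  sc <- generate_ersc(40, 6, 2, seed = 41)
  S <- simulate_contagion(sc, 5000, alpha = 0.8, omega = 2.4, mu = 1,
                          rho0 = 0.2, reseed = TRUE, seed = 42)
  fit <- reconstruct(S)
  expect_gte(score(sc, fit, "edges")$f1, 0.9)
  expect_gte(score(sc, fit, "triangles")$f1, 0.9)
})

test_that("partial reconstruction restricts targets and methods work", {
  sc <- generate_ersc(15, 4, 1, seed = 51)
  S <- simulate_contagion(sc, 800, alpha = 0.8, omega = 2.4, mu = 1,
                          rho0 = 0.3, reseed = TRUE, seed = 52)
  fit <- reconstruct(S, nodes = 0:4)
  expect_equal(fit$targets, 0:4)
  expect_true(all(lengths(fit$pair_prob[6:15]) == 0))

  expect_output(print(fit), "reconstruction")
  expect_output(print(summary(fit)), "candidate")
  ce <- coef(fit, "edges")
  expect_true(all(c("target", "source", "prob") %in% names(ce)))
  ct <- coef(fit, "triangles")
  expect_true(all(c("target", "source1", "source2", "prob") %in% names(ct)))
  expect_s3_class(predict(fit), "simplicial_complex")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit, node = 0, which = "first_step"))
})
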