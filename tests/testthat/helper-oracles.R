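# Shared fixtures and independent oracles used across the suite.

# Brute-force maximum-gap split over a descending positive list.
brute_gap <- function(values) {
  pos <- sort(values[values > 0], decreasing = TRUE)
  if (length(pos) < 2L) return(list(split = length(pos), threshold = 0))
  scores <- vapply(seq_len(length(pos) - 1L), function(l) {
    (pos[l] / pos[l + 1L]) * (pos[l] - pos[l + 1L])
  }, numeric(1))
  l <- which(scores == max(scores))[1L]
  list(split = l, threshold = (pos[l] + pos[l + 1L]) / 2)
}

# Poisson log-likelihood of a pairs-only model, straight from its
# definition (used as the grid-search oracle target).
pairwise_loglik <- function(S, i, cand, p, eps) {
  n <- ncol(S)
  sus <- which(S[-nrow(S), i + 1L] == 0L)
  y <- S[sus + 1L, i + 1L]
  A <- S[sus, cand + 1L, drop = FALSE]
  pc <- colSums(A * y) / colSums(A)
  pc[is.na(pc)] <- 0
  ll <- 0
  for (m in seq_along(sus)) {
    e <- sum(p * pc * A[m, ]) + eps
    ll <- ll + y[m] * log(e) - e
  }
  ll
}

# Exact stationary distribution of the synchronous two-spin Ising chain.
two_spin_stationary <- function(J1, delta) {
  states <- list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  flip_p <- function(s) {
    de <- 2 * J1 * s * rev(s)        # dE_i = 2 J1 S_i S_j for each spin
    1 / (1 + exp(delta * de))
  }
  P <- matrix(0, 4, 4)
  for (a in 1:4) {
    fp <- flip_p(states[[a]])
    for (b in 1:4) {
      flips <- states[[a]] != states[[b]]
      P[a, b] <- prod(ifelse(flips, fp, 1 - fp))
    }
  }
  ev <- eigen(t(P))
  v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  v / sum(v)
}

# Does every consecutive infected state have an active transmission
# channel at the previous step (given the true complex)?
all_infections_explained <- function(S, sc, reseed_rows = integer(0)) {
  m <- unclass(S)
  adj <- matrix(0L, sc$n_nodes, sc$n_nodes)
  if (nrow(sc$edges)) {
    adj[sc$edges + 1L] <- 1L
    adj[sc$edges[, 2:1, drop = FALSE] + 1L] <- 1L
  }
  tri <- sc$triangles
  for (t in seq_len(nrow(m) - 1L)) {
    if ((t + 1L) %in% reseed_rows) next
    new_inf <- which(m[t, ] == 0L & m[t + 1L, ] == 1L)
    for (i in new_inf) {
      a <- sum(adj[i, ] * m[t, ])
      b <- 0L
      if (nrow(tri)) {
        for (r in seq_len(nrow(tri))) {
          v <- tri[r, ] + 1L
          if (i %in% v) {
            o <- setdiff(v, i)
            if (all(m[t, o] == 1L)) b <- b + 1L
          }
        }
      }
      if (a + b == 0L) return(FALSE)
    }
  }
  TRUE
}

# All C(n,2) edges of a complete graph, 0-based.
unrank_pairs_for_test <- function(n) {
  t(utils::combn(0:(n - 1L), 2L))
}

# A deterministic small complex with both edge-only and triangle structure.
toy_complex <- function() {
  simplicial_complex(
    6,
    edges = rbind(c(0, 1), c(0, 2), c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
    triangles = rbind(c(0, 1, 2))
  )
}
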