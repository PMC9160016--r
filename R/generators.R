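# Synthetic 2-simplicial complex generators.
#
# All three generators share the same triangle layer: 2-simplexes are added
# between node triples independently with probability
#   p2 = 2 k2 / ((N - 1)(N - 2)),
# which makes the expected three-body average degree 3 E[|T|] / N equal k2.
# Triangle faces are always unioned into the edge set so that closure holds
# by construction and triangle edges count towards the two-body degree.

# Unrank lexicographic pair indices r in 1..choose(n,2) to 0-based (u, v).
unrank_pairs <- function(r, n) {
  counts <- (n - 1L):1L
  cum <- cumsum(counts)
  u <- findInterval(r - 1L, cum)
  before <- c(0L, cum)[u + 1L]
  v <- u + 1L + (r - 1L - before)
  cbind(u, v)
}

# Unrank lexicographic triple indices r in 1..choose(n,3) to 0-based (u,v,w).
unrank_triples <- function(r, n) {
  counts <- choose((n - 1L):2L, 2L)
  cum <- cumsum(counts)
  u <- findInterval(r - 1L, cum)
  before <- c(0L, cum)[u + 1L]
  rem <- r - before              # pair rank within labels u+1 .. n-1
  out <- matrix(0L, nrow = length(r), ncol = 3L)
  out[, 1L] <- u
  for (uv in unique(u)) {        # sub-unranking size depends on u
    sel <- u == uv
    sub <- unrank_pairs(rem[sel], n - 1L - uv)
    out[sel, 2L] <- sub[, 1L] + uv + 1L
    out[sel, 3L] <- sub[, 2L] + uv + 1L
  }
  out
}

# Bernoulli(p) sample over all choose(n, k) unordered k-sets, drawn by
# thinning: sample the Binomial count, then that many distinct index ranks
# uniformly. Distributionally identical to independent per-set coin flips.
sample_ksets <- function(n, k, p) {
  total <- choose(n, k)
  if (p <= 0 || total < 1) return(matrix(integer(0), ncol = k))
  cnt <- stats::rbinom(1L, size = total, prob = min(p, 1))
  if (cnt == 0L) return(matrix(integer(0), ncol = k))
  idx <- sort.int(sample.int(total, cnt))
  if (k == 2L) unrank_pairs(idx, n) else unrank_triples(idx, n)
}

triangle_faces <- function(tri) {
  rbind(tri[, c(1L, 2L), drop = FALSE],
        tri[, c(1L, 3L), drop = FALSE],
        tri[, c(2L, 3L), drop = FALSE])
}

# Triangle-layer probability p2 from the target three-body degree k2.
p2_from_k2 <- function(n_nodes, k2_target) {
  if (k2_target < 0) stop("`k2_target` must be non-negative")
  2 * k2_target / ((n_nodes - 1) * (n_nodes - 2))
}

assemble_complex <- function(n_nodes, base_edges, triangles) {
  edges <- rbind(base_edges, triangle_faces(triangles))
  simplicial_complex(n_nodes, edges = edges, triangles = triangles)
}

#' Generate a random (Erdos-Renyi style) 2-simplicial complex
#'
#' Edges are placed between every node pair independently with probability
#' `p1 = (k1 - 2 k2) / ((N - 1) - 2 k2)` and 2-simplexes between every node
#' triple independently with probability `p2 = 2 k2 / ((N - 1)(N - 2))`;
#' each sampled triangle's three faces are added to the edge set. With
#' these choices the realized average degrees are unbiased for the targets:
#' a triangle contributes 2 to each member's two-body degree, which the p1
#' formula discounts.
#'
#' @param n_nodes Number of nodes N.
#' @param k1_target Target average two-body degree k1.
#' @param k2_target Target average three-body degree k2 (0 gives a plain
#'   random graph).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A [simplicial_complex()].
#' @examples
#' sc <- generate_ersc(200, k1_target = 6, k2_target = 2, seed = 1)
#' average_degrees(sc)
#' @export
generate_ersc <- function(n_nodes, k1_target, k2_target = 0, seed = NULL) {
  if (k1_target <= 2 * k2_target) {
    stop("ERSC requires k1_target > 2*k2_target so that the edge ",
         "probability p1 = (k1 - 2 k2)/((N-1) - 2 k2) is positive")
  }
  if ((n_nodes - 1) <= 2 * k2_target) {
    stop("ERSC requires (n_nodes - 1) > 2*k2_target so that the ",
         "denominator of p1 = (k1 - 2 k2)/((N-1) - 2 k2) is positive")
  }
  p1 <- (k1_target - 2 * k2_target) / ((n_nodes - 1) - 2 * k2_target)
  if (p1 > 1) stop("targets give edge probability p1 > 1")
  p2 <- p2_from_k2(n_nodes, k2_target)
  with_seed(seed, {
    base <- sample_ksets(n_nodes, 2L, p1)
    tri <- sample_ksets(n_nodes, 3L, p2)
    assemble_complex(n_nodes, base, tri)
  })
}

#' Generate a scale-free 2-simplicial complex
#'
#' Grows a preferential-attachment backbone: starting from a complete graph
#' on `m` nodes, each arriving node attaches `m` edges to distinct existing
#' nodes chosen with probability proportional to their current degree.
#' 2-simplexes are then added between all triples with probability `p2`
#' derived from `k2_target`, and their faces unioned into the edge set.
#' The resulting two-body average degree is approximately
#' `2 m + 2 k2 (1 - 2 m / N)`.
#'
#' @param n_nodes Number of nodes.
#' @param m Edges attached by each arriving node (`1 <= m < n_nodes`).
#' @inheritParams generate_ersc
#' @return A [simplicial_complex()].
#' @export
generate_sfsc <- function(n_nodes, m, k2_target = 0, seed = NULL) {
  m <- as.integer(m)
  if (m < 1L || n_nodes <= m) stop("need 1 <= m < n_nodes")
  p2 <- p2_from_k2(n_nodes, k2_target)
  with_seed(seed, {
    deg <- integer(n_nodes)
    n_seed_edges <- choose(m, 2L)
    edges <- matrix(0L, nrow = n_seed_edges + m * (n_nodes - m), ncol = 2L)
    if (m > 1L) {
      edges[seq_len(n_seed_edges), ] <- unrank_pairs(seq_len(n_seed_edges), m)
      deg[seq_len(m)] <- m - 1L
    }
    pos <- n_seed_edges
    for (new in m:(n_nodes - 1L)) {          # 0-based label of the arrival
      w <- deg[seq_len(new)]
      if (all(w == 0)) w <- rep(1, new)      # first arrival on an edgeless seed
      targets <- sample.int(new, m, prob = w) - 1L
      edges[pos + seq_len(m), ] <- cbind(targets, new)
      pos <- pos + m
      deg[targets + 1L] <- deg[targets + 1L] + 1L
      deg[new + 1L] <- m
    }
    tri <- sample_ksets(n_nodes, 3L, p2)
    assemble_complex(n_nodes, edges, tri)
  })
}

#' Generate a small-world 2-simplicial complex
#'
#' Builds a Watts-Strogatz ring: every node is joined to its `m` nearest
#' neighbours on each side (degree exactly `2 m`), then each lattice edge
#' is rewired with probability `rewire_p` to a uniformly chosen new
#' endpoint (avoiding self-loops and duplicate edges; the rewiring keeps
#' the total edge count, so the mean degree stays `2 m`). 2-simplexes are
#' added as in [generate_ersc()].
#'
#' @param n_nodes Number of nodes; must exceed `2 m`.
#' @param m Lattice half-degree.
#' @param rewire_p Rewiring probability in `[0, 1]`.
#' @inheritParams generate_ersc
#' @return A [simplicial_complex()].
#' @export
generate_swsc <- function(n_nodes, m, rewire_p = 0.1, k2_target = 0,
                          seed = NULL) {
  m <- as.integer(m)
  if (m < 1L || 2L * m >= n_nodes) stop("need 1 <= m and 2m < n_nodes")
  if (rewire_p < 0 || rewire_p > 1) stop("`rewire_p` must be in [0, 1]")
  p2 <- p2_from_k2(n_nodes, k2_target)
  with_seed(seed, {
    u <- rep(0:(n_nodes - 1L), each = m)
    v <- (u + rep(seq_len(m), n_nodes)) %% n_nodes
    edges <- cbind(u, v)
    have <- new.env(hash = TRUE, parent = emptyenv())
    for (r in seq_len(nrow(edges))) {
      assign(pair_key(edges[r, 1L], edges[r, 2L]), TRUE, envir = have)
    }
    rewire <- stats::runif(nrow(edges)) < rewire_p
    for (r in which(rewire)) {
      uu <- edges[r, 1L]
      cand <- setdiff(sample.int(n_nodes, n_nodes) - 1L, uu)
      for (w in cand) {
        k <- pair_key(uu, w)
        if (!exists(k, envir = have, inherits = FALSE)) {
          rm(list = pair_key(edges[r, 1L], edges[r, 2L]), envir = have)
          assign(k, TRUE, envir = have)
          edges[r, 2L] <- w
          break
        }
      }
    }
    tri <- sample_ksets(n_nodes, 3L, p2)
    assemble_complex(n_nodes, edges, tri)
  })
}
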