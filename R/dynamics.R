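# Forward simulators producing binary state matrices on a 2-simplicial
# complex: SIS-type simplicial contagion and simplicial Ising dynamics.

#' Construct a state matrix
#'
#' A state matrix records one row per time step and one column per node.
#' The alphabet is `{0, 1}` (susceptible/infected) for contagion data and
#' `{-1, +1}` for spin data.
#'
#' @param values A T x N matrix of states.
#' @param alphabet `"binary"` for 0/1 data, `"spin"` for -1/+1 data.
#' @return An integer matrix of class `state_matrix` with attribute
#'   `alphabet`.
#' @export
state_matrix <- function(values, alphabet = c("binary", "spin")) {
  alphabet <- match.arg(alphabet)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  allowed <- if (alphabet == "binary") c(0L, 1L) else c(-1L, 1L)
  if (anyNA(values) || !all(values %in% allowed)) {
    stop("state values must all lie in {", paste(allowed, collapse = ", "), "}")
  }
  structure(values, alphabet = alphabet, class = c("state_matrix", "matrix"))
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("state matrix: %d time steps x %d nodes (%s alphabet)\n",
              nrow(x), ncol(x), attr(x, "alphabet")))
  if (attr(x, "alphabet") == "binary") {
    cat(sprintf("  mean active fraction: %.4f\n", mean(x)))
  } else {
    cat(sprintf("  mean magnetization: %.4f\n", mean(x)))
  }
  ev <- attr(x, "reseed_events")
  if (length(ev)) cat(sprintf("  reseeded after extinction at %d row(s)\n",
                              length(ev)))
  invisible(x)
}

# Precomputed per-node triangle partner index table: for each triangle
# (u,v,w) and each member, the indices (1-based) of the two other members.
triangle_index <- function(sc) {
  tr <- sc$triangles
  if (!nrow(tr)) {
    return(list(node = integer(0), p1 = integer(0), p2 = integer(0)))
  }
  list(node = c(tr[, 1L], tr[, 2L], tr[, 3L]) + 1L,
       p1 = c(tr[, 2L], tr[, 1L], tr[, 1L]) + 1L,
       p2 = c(tr[, 3L], tr[, 3L], tr[, 2L]) + 1L)
}

# Sum `w` into a length-n vector by 1-based index `idx`.
index_sum <- function(w, idx, n) {
  out <- numeric(n)
  if (length(idx)) {
    agg <- rowsum(w, idx)
    out[as.integer(rownames(agg))] <- agg
  }
  out
}

# Directed incidence index: each undirected edge contributes both ways,
# so the infected-neighbour count is index_sum(s[partner], node, n).
edge_index <- function(sc) {
  e <- sc$edges
  list(node = c(e[, 1L], e[, 2L]) + 1L,
       partner = c(e[, 2L], e[, 1L]) + 1L)
}

#' Simulate simplicial SIS contagion
#'
#' Susceptible-infected-susceptible spreading on a 2-simplicial complex
#' with synergistic reinforcement. At each synchronous step a susceptible
#' node i is exposed through every edge whose other endpoint is infected
#' (per-channel probability `beta1`) and through every 2-simplex containing
#' i whose two other members are both infected (probability `beta2`);
#' channels act independently, so the infection probability is
#' `1 - (1 - beta1)^a * (1 - beta2)^b` for a active edges and b active
#' triangles. Each infected node recovers with probability `mu`, evaluated
#' on the time-t snapshot, so a newly infected node cannot recover in the
#' same step.
#'
#' The transmission rates are tied to the realized average degrees of the
#' supplied complex: `beta1 = alpha / k1`, `beta2 = omega / k2`. Pass
#' `beta1` / `beta2` directly to bypass that scaling.
#'
#' @param sc A [simplicial_complex()].
#' @param steps Number of recorded time steps T (the initial configuration
#'   is row 1).
#' @param alpha,omega Rate constants; `beta1 = alpha/k1`, `beta2 = omega/k2`.
#' @param mu Recovery probability in `[0, 1]`.
#' @param rho0 Initially infected fraction; `floor(rho0 * N)` nodes are
#'   drawn uniformly.
#' @param beta1,beta2 Direct per-channel infection probabilities; override
#'   `alpha`/`omega` when supplied.
#' @param init Optional explicit 0/1 initial state vector of length N.
#' @param reseed If `TRUE`, re-initialize `floor(rho0 * N)` infected nodes
#'   whenever the epidemic goes extinct before T rows are collected; the
#'   affected row indices are stored in attribute `reseed_events`. Default
#'   `FALSE`: extinction leaves all remaining rows zero.
#' @param seed Optional integer seed.
#' @return A `binary` [state_matrix()] with `steps` rows.
#' @examples
#' sc <- generate_ersc(50, 6, 2, seed = 1)
#' S <- simulate_contagion(sc, steps = 200, alpha = 0.8, omega = 2.4,
#'                         mu = 1, rho0 = 0.2, seed = 2)
#' @export
simulate_contagion <- function(sc, steps, alpha = 0.8, omega = 2.4, mu = 1,
                               rho0 = 0.2, beta1 = NULL, beta2 = NULL,
                               init = NULL, reseed = FALSE, seed = NULL) {
  stopifnot(inherits(sc, "simplicial_complex"), steps >= 1)
  n <- sc$n_nodes
  k <- average_degrees(sc)
  if (is.null(beta1)) {
    if (alpha < 0) stop("`alpha` must be non-negative")
    # rate-to-probability conversion; a per-channel probability cannot
    # exceed 1 (omega/k2 > 1 means a fully infected triangle always
    # transmits)
    beta1 <- if (k[["k1"]] > 0) min(1, alpha / k[["k1"]]) else 0
  }
  if (is.null(beta2)) {
    if (omega < 0) stop("`omega` must be non-negative")
    beta2 <- if (k[["k2"]] > 0) min(1, omega / k[["k2"]]) else 0
  }
  if (beta1 < 0 || beta1 > 1 || beta2 < 0 || beta2 > 1) {
    stop(sprintf(
      "infection probabilities must lie in [0, 1]; got beta1 = %.4g, beta2 = %.4g",
      beta1, beta2))
  }
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  eix <- edge_index(sc)
  tix <- triangle_index(sc)
  n0 <- max(1L, floor(rho0 * n))
  with_seed(seed, {
    s <- integer(n)
    if (!is.null(init)) {
      stopifnot(length(init) == n, all(init %in% c(0L, 1L)))
      s <- as.integer(init)
    } else {
      s[sample.int(n, n0)] <- 1L
    }
    out <- matrix(0L, nrow = steps, ncol = n)
    reseed_events <- integer(0)
    out[1L, ] <- s
    if (steps > 1L) {
      for (t in 2:steps) {
        if (reseed && sum(s) == 0L) {
          # extinction: the all-zero row stays on record; this row gets a
          # fresh uniform seeding, so the reseed transition has no active
          # channel and is attributable only to noise
          s[sample.int(n, n0)] <- 1L
          reseed_events <- c(reseed_events, t)
          out[t, ] <- s
          next
        }
        a <- index_sum(s[eix$partner], eix$node, n)
        b <- index_sum(s[tix$p1] * s[tix$p2], tix$node, n)
        p_inf <- 1 - (1 - beta1)^a * (1 - beta2)^b
        u <- stats::runif(n)
        s <- ifelse(s == 0L,
                    as.integer(u < p_inf),
                    as.integer(u >= mu))
        out[t, ] <- s
      }
    }
    sm <- state_matrix(out, "binary")
    attr(sm, "reseed_events") <- reseed_events
    attr(sm, "beta") <- c(beta1 = beta1, beta2 = beta2)
    sm
  })
}

#' Simulate simplicial Ising dynamics
#'
#' Spin dynamics on a 2-simplicial complex under the Hamiltonian
#' `H = -J1 * sum_(i,j) S_i S_j - J2 * sum_(i,j,k) S_i S_j S_k`,
#' where the sums run over edges and triangles. The energy change of
#' flipping spin i is
#' `dE_i = 2 J1 * sum_(i,j) S_i S_j + 2 J2 * sum_(i,j,k) S_i S_j S_k`
#' (sums over the simplexes containing i), and i flips with probability
#' `1 / (1 + exp(delta * dE_i))` at inverse temperature `delta`.
#'
#' By default the update is synchronous: every node draws an independent
#' flip decision from the time-t configuration. `method = "glauber"`
#' instead performs N random single-spin updates per recorded row.
#'
#' @param sc A [simplicial_complex()].
#' @param steps Number of recorded rows T.
#' @param J1,J2 Two-body and three-body coupling strengths.
#' @param delta Inverse temperature (>= 0); `delta = 0` flips every spin
#'   with probability 1/2.
#' @param method `"synchronous"` (default) or `"glauber"`.
#' @param init Optional explicit -1/+1 initial spin vector; by default
#'   spins are assigned +1 or -1 with equal probability.
#' @param seed Optional integer seed.
#' @return A `spin` [state_matrix()] with `steps` rows.
#' @export
simulate_ising <- function(sc, steps, J1 = 1, J2 = 1, delta = 1,
                           method = c("synchronous", "glauber"),
                           init = NULL, seed = NULL) {
  stopifnot(inherits(sc, "simplicial_complex"), steps >= 1)
  method <- match.arg(method)
  if (delta < 0 || !is.finite(J1) || !is.finite(J2)) {
    stop("need finite couplings and delta >= 0")
  }
  n <- sc$n_nodes
  eix <- edge_index(sc)
  tix <- triangle_index(sc)
  delta_e <- function(s) {
    2 * J1 * s * index_sum(s[eix$partner], eix$node, n) +
      2 * J2 * s * index_sum(s[tix$p1] * s[tix$p2], tix$node, n)
  }
  with_seed(seed, {
    s <- if (!is.null(init)) {
      stopifnot(length(init) == n, all(init %in% c(-1L, 1L)))
      as.integer(init)
    } else {
      sample(c(-1L, 1L), n, replace = TRUE)
    }
    out <- matrix(0L, nrow = steps, ncol = n)
    out[1L, ] <- s
    if (steps > 1L) {
      for (t in 2:steps) {
        if (method == "synchronous") {
          p_flip <- 1 / (1 + exp(delta * delta_e(s)))
          flip <- stats::runif(n) < p_flip
          s[flip] <- -s[flip]
        } else {
          for (rep in seq_len(n)) {
            i <- sample.int(n, 1L)
            de <- delta_e(s)[i]
            if (stats::runif(1) < 1 / (1 + exp(delta * de))) s[i] <- -s[i]
          }
        }
        out[t, ] <- s
      }
    }
    state_matrix(out, "spin")
  })
}
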