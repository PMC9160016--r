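# Empirical transition conditionals estimated by counting from the state
# matrix. For a target node i, consecutive row pairs (t, t+1) with node i
# susceptible at t are the observation windows:
#   P_j^i  = #{t : S_i^t = 0, S_j^t = 1,           S_i^{t+1} = 1} /
#            #{t : S_i^t = 0, S_j^t = 1}
#   P_jk^i = the analogue conditioning on S_j^t * S_k^t = 1.
# Entries whose conditioning event never occurs are undefined (NA).

# Internal workhorse: the per-target design used by both the conditional
# estimator and the EM. Returns the susceptible-row indicator matrix A
# (one column per pairwise candidate), the next-step infection indicator y,
# and (optionally) product columns for triple candidates.
node_design <- function(S, i, pair_cand, triple_cand = NULL) {
  n <- ncol(S)
  col <- i + 1L
  t_idx <- which(S[-nrow(S), col] == 0L)      # rows t with i susceptible
  y <- S[t_idx + 1L, col]
  A <- matrix(as.double(S[t_idx, pair_cand + 1L, drop = FALSE]),
              nrow = length(t_idx))
  out <- list(y = as.double(y), A = A, pair_cand = pair_cand)
  if (!is.null(triple_cand) && nrow(triple_cand)) {
    jpos <- match(triple_cand[, 1L], pair_cand)
    kpos <- match(triple_cand[, 2L], pair_cand)
    if (anyNA(jpos) || anyNA(kpos)) {
      # triple members outside the pairwise candidate set: pull their
      # columns straight from S
      Bj <- matrix(as.double(S[t_idx, triple_cand[, 1L] + 1L, drop = FALSE]),
                   nrow = length(t_idx))
      Bk <- matrix(as.double(S[t_idx, triple_cand[, 2L] + 1L, drop = FALSE]),
                   nrow = length(t_idx))
      out$B <- Bj * Bk
    } else {
      out$B <- A[, jpos, drop = FALSE] * A[, kpos, drop = FALSE]
    }
    out$triple_cand <- triple_cand
  }
  out
}

#' Empirical conditional infection probabilities
#'
#' Estimates, for a target node `i`, the conditional probabilities of
#' infection at the next step given that a candidate source node (or an
#' already-infected candidate pair) is infected while `i` is susceptible.
#' These empirical conditionals are the sufficient statistics consumed by
#' the EM estimator.
#'
#' @param S A binary [state_matrix()] (or 0/1 matrix).
#' @param i Target node, 0-based.
#' @param candidate_pairs Optional two-column matrix of 0-based node pairs
#'   restricting the triple conditionals; by default all pairs of other
#'   nodes are evaluated, which is quadratic in N.
#' @return An object of class `empirical_conditionals`: list with `target`
#'   and data frames `pair` (`j`, `p`, `n_obs`) and `triple` (`j`, `k`,
#'   `p`, `n_obs`). `p` is `NA` (undefined) when the conditioning event
#'   never occurs (`n_obs = 0`).
#' @examples
#' S <- rbind(c(0, 1), c(1, 1), c(0, 0), c(0, 1), c(0, 1))
#' empirical_conditionals(S, 0)$pair
#' @export
empirical_conditionals <- function(S, i, candidate_pairs = NULL) {
  S <- check_binary_states(S)
  n <- ncol(S)
  if (i < 0 || i >= n) stop("target node out of range")
  others <- setdiff(0:(n - 1L), i)
  if (is.null(candidate_pairs)) {
    if (length(others) >= 2L) {
      cmb <- utils::combn(others, 2L)
      candidate_pairs <- cbind(cmb[1L, ], cmb[2L, ])
    } else {
      candidate_pairs <- matrix(integer(0), ncol = 2L)
    }
  } else {
    candidate_pairs <- canonical_rows(candidate_pairs, 2L)
  }
  d <- node_design(S, i, others, candidate_pairs)
  n_pair <- colSums(d$A)
  s_pair <- as.vector(crossprod(d$A, d$y))
  pair <- data.frame(j = others,
                     p = ifelse(n_pair > 0, s_pair / n_pair, NA_real_),
                     n_obs = as.integer(n_pair))
  if (!is.null(d$B)) {
    n_tri <- colSums(d$B)
    s_tri <- as.vector(crossprod(d$B, d$y))
    triple <- data.frame(j = candidate_pairs[, 1L], k = candidate_pairs[, 2L],
                         p = ifelse(n_tri > 0, s_tri / n_tri, NA_real_),
                         n_obs = as.integer(n_tri))
  } else {
    triple <- data.frame(j = integer(0), k = integer(0),
                         p = numeric(0), n_obs = integer(0))
  }
  structure(list(target = i, pair = pair, triple = triple),
            class = "empirical_conditionals")
}

#' @export
print.empirical_conditionals <- function(x, ...) {
  cat(sprintf("empirical conditionals for node %d: %d pairwise, %d triple\n",
              x$target, nrow(x$pair), nrow(x$triple)))
  cat(sprintf("  defined: %d pairwise, %d triple\n",
              sum(!is.na(x$pair$p)), sum(!is.na(x$triple$p))))
  invisible(x)
}

check_binary_states <- function(S) {
  if (inherits(S, "state_matrix") && attr(S, "alphabet") != "binary") {
    stop("reconstruction requires a binary (0/1) state matrix; spin data ",
         "are not supported")
  }
  S <- unclass(as.matrix(S))
  if (!all(S %in% c(0L, 1L))) stop("state matrix entries must be 0 or 1")
  if (nrow(S) < 2L) stop("need at least 2 time steps")
  storage.mode(S) <- "integer"
  S
}
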