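# Poisson-likelihood EM for per-target interaction probabilities.
#
# For a target node i, the expected number of infections of i at t+1 is
# modelled as
#   E_i = sum_j P_{j->i} P_j^i Psi_j + sum_{jk} P_{jk->i} P_jk^i Psi_jk + eps_i
# over the observation windows in which i is susceptible, with Psi the 0/1
# activity indicators of the candidate channels and eps_i a noise rate.
# The number of infection events is treated as Poisson with mean E_i, and
# the log-likelihood
#   L = sum_m (Psi_i^{m+1} log E_i^{m+1} - E_i^{m+1})
# is maximised by EM: the E-step attributes each infection event to the
# candidate channels (responsibilities rho, sharing the denominator E),
# and the M-step rescales each channel by its attributed share. L is
# concave in the parameters (a sum of logs of affine functions minus a
# linear function), so EM converges monotonically to the global maximum.

# Core EM on a prepared design.
#   X:     M x P matrix of 0/1 channel activity (pair and triple columns)
#   y:     length-M 0/1 next-step infection indicator
#   pcond: length-P empirical conditionals (NA / 0 channels are frozen)
# Returns parameters over all P columns (frozen ones at 0), the noise rate
# and the log-likelihood trace of the best run.
em_core <- function(X, y, pcond, tol = 1e-6, max_iter = 500L,
                    n_restarts = 1L, eps_floor = 1e-12, prune = TRUE,
                    prune_mask = NULL, seed = NULL) {
  M <- nrow(X); P <- ncol(X)
  p_out <- numeric(P)
  if (M == 0L || sum(y) == 0) {
    # no observation windows or no infection events: every M-step
    # numerator vanishes, so all parameters (and the noise rate) are zero
    return(list(p = p_out, epsilon = 0, loglik = numeric(0),
                iterations = 0L, converged = TRUE, n_restarts_used = 0L))
  }
  active <- which(!is.na(pcond) & pcond > 0)
  if (length(active) == 0L) {
    # no usable channel: the model is pure noise with rate mean(y)
    eps <- sum(y) / M
    ll <- sum(y * log(eps)) - M * eps
    return(list(p = p_out, epsilon = eps, loglik = ll,
                iterations = 1L, converged = TRUE, n_restarts_used = 1L))
  }
  if (is.null(prune_mask)) prune_mask <- rep(TRUE, P)
  y1 <- y == 1
  # One run alternates (a) blocks of EM iterations and (b) an active-set
  # refinement. A channel whose maximum-likelihood value sits on the
  # boundary 0 only decays geometrically under EM (its M-step multiplier
  # stays below 1), so plain iteration leaves small positive remnants.
  # Once the interior parameters have settled, such channels are detected
  # by the first-order condition at zero: with the channel's own
  # contribution removed from the event denominators, a multiplier
  #   r0_j = sum_{events with Psi_j = 1} 1 / (E - p_j P_j^i) / sum_m Psi_j
  # below 1 means the gradient at p_j = 0 is negative, i.e. zero is
  # optimal given the other parameters; the channel is then fixed at
  # exactly 0 and the remainder re-converged. The objective is concave,
  # so this terminates at the global maximum with exact zeros on the
  # inactive channels.
  # Only the event rows (y = 1) enter the per-iteration linear algebra:
  # the non-event rows contribute to the objective and the M-step solely
  # through the column totals cs0 = sum_m Psi_j, since
  # sum_m E^{t_m+1} = sum_j w_j cs0_j + M eps.
  A1_all <- X[y1, , drop = FALSE]
  cs0_all <- colSums(X)
  block <- 100L
  run_once <- function(act, p0, e0) {
    A1 <- A1_all[, act, drop = FALSE]
    cs0 <- cs0_all[act]
    pc <- pcond[act]
    p <- p0; eps <- e0
    ll <- numeric(0)
    segments <- integer(0)
    it_total <- 0L
    converged <- FALSE
    hard_cap <- 4L * max_iter
    repeat {
      it <- 0L
      converged <- FALSE
      ratio <- rep(1, length(act))
      r1 <- NULL
      repeat {
        it <- it + 1L
        w <- p * pc
        d1 <- as.vector(A1 %*% w) + eps   # event-row denominators E
        r1 <- 1 / d1
        ll[it_total + it] <- sum(log(d1)) - sum(w * cs0) - M * eps
        # M-step as a per-channel multiplier:
        #   p_new = p * [pc * sum_events(Psi/E)] / [pc * sum_m Psi]
        ratio <- as.vector(crossprod(A1, r1)) / cs0
        p_new <- p * ratio
        eps_new <- max(eps * sum(r1) / M, eps_floor)
        diff <- max(abs(c(p_new - p, eps_new - eps)))
        scale <- max(abs(c(p, eps)), 1e-12)
        p <- p_new; eps <- eps_new
        if (diff / scale < tol) { converged <- TRUE; break }
        if (it >= block) break
      }
      it_total <- it_total + it
      segments <- c(segments, it)
      # first-order boundary test for channels still decaying
      drop_j <- logical(length(act))
      if (prune && length(act) && (converged || it_total >= 2L * block)) {
        suspect <- which(ratio < 1 - 1e-6 & prune_mask[act])
        if (length(suspect)) {
          w <- p * pc
          d1 <- 1 / r1                  # current event denominators E
          for (s in suspect) {
            mask <- A1[, s] == 1
            r0 <- sum(1 / (d1[mask] - w[s])) / cs0[s]
            drop_j[s] <- r0 < 1 - 1e-6
          }
        }
      }
      if (any(drop_j)) {
        act <- act[!drop_j]
        A1 <- A1[, !drop_j, drop = FALSE]
        cs0 <- cs0[!drop_j]
        pc <- pc[!drop_j]
        p <- p[!drop_j]
      } else if (converged || it_total >= (if (prune) hard_cap else max_iter)) {
        break
      }
    }
    list(act = act, p = p, eps = eps, ll = ll, segments = segments,
         converged = converged)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(max(1L, n_restarts))) {
      init_p <- if (r == 1L) rep(1, length(active)) else
        stats::runif(length(active))
      init_e <- if (r == 1L) 1 else stats::runif(1)
      run <- run_once(active, init_p, init_e)
      if (is.null(best) || run$ll[length(run$ll)] > best$ll[length(best$ll)]) {
        best <- run
      }
    }
  })
  p_out[best$act] <- best$p
  list(p = p_out, epsilon = best$eps, loglik = best$ll,
       trace_segments = best$segments,
       iterations = sum(best$segments), converged = best$converged,
       n_restarts_used = max(1L, n_restarts))
}

em_options <- function(tol = 1e-6, max_iter = 500L, n_restarts = 1L,
                       eps_floor = 1e-12, clip = 1e-9, prune = TRUE,
                       seed = NULL) {
  list(tol = tol, max_iter = as.integer(max_iter),
       n_restarts = as.integer(n_restarts), eps_floor = eps_floor,
       clip = clip, prune = isTRUE(prune), seed = seed)
}

# Shared front end for em_full / em_first_step.
em_node <- function(S, i, pair_candidates, triple_candidates, opts) {
  S <- check_binary_states(S)
  n <- ncol(S)
  if (i < 0 || i >= n) stop("target node out of range")
  pair_candidates <- sort(unique(as.integer(pair_candidates)))
  if (any(pair_candidates == i)) stop("target cannot be its own candidate")
  triple_candidates <- canonical_rows(triple_candidates, 2L)
  d <- node_design(S, i, pair_candidates, triple_candidates)
  X <- cbind(d$A, d$B)
  nX <- colSums(X)
  sX <- as.vector(crossprod(X, d$y))
  pcond <- ifelse(nX > 0, sX / nX, NA_real_)
  # only pair channels are ever pruned to exact zero: the edge rule needs
  # sharp positivity, while triangle assembly thresholds its values at a
  # maximum gap, which relies on the small remnants of non-interacting
  # triple channels forming a separable tail
  mask <- c(rep(TRUE, ncol(d$A)),
            rep(FALSE, if (is.null(d$B)) 0L else ncol(d$B)))
  fit <- em_core(X, d$y, pcond, tol = opts$tol, max_iter = opts$max_iter,
                 n_restarts = opts$n_restarts, eps_floor = opts$eps_floor,
                 prune = opts$prune, prune_mask = mask, seed = opts$seed)
  npair <- length(pair_candidates)
  p_pair <- fit$p[seq_len(npair)]
  names(p_pair) <- pair_candidates
  if (nrow(triple_candidates)) {
    p_triple <- data.frame(j = triple_candidates[, 1L],
                           k = triple_candidates[, 2L],
                           p = fit$p[npair + seq_len(nrow(triple_candidates))])
  } else {
    p_triple <- data.frame(j = integer(0), k = integer(0), p = numeric(0))
  }
  structure(list(target = i, p_pair = p_pair, p_triple = p_triple,
                 epsilon = fit$epsilon, loglik_trace = fit$loglik,
                 trace_segments = fit$trace_segments %||%
                   length(fit$loglik),
                 iterations = fit$iterations, converged = fit$converged,
                 n_restarts_used = fit$n_restarts_used),
            class = "sc_em")
}

#' Full EM estimate of pairwise and triple interaction probabilities
#'
#' Maximises the Poisson likelihood of the target node's infection events
#' over the pairwise probabilities `P_{j->i}`, the triple probabilities
#' `P_{jk->i}` and the noise rate `eps_i`, by expectation-maximization.
#' The E-step computes, for every observation window that ends in an
#' infection, the responsibility of each active channel (all channels share
#' one normalising denominator, so responsibilities sum to 1 at every
#' infection event); the M-step divides each channel's total responsibility
#' by its total activity weighted by the empirical conditional. Channels
#' whose conditioning event never occurs, or never precedes an infection,
#' are frozen at 0 and excluded from the sums.
#'
#' The objective is concave, so the default single run from the all-ones
#' initialization attains the global maximum; `n_restarts > 1` adds random
#' re-initializations and keeps the run with the highest final
#' log-likelihood.
#'
#' @param S Binary [state_matrix()] (or 0/1 matrix).
#' @param i Target node, 0-based.
#' @param pair_candidates Integer vector of candidate source nodes
#'   (0-based, excluding `i`).
#' @param triple_candidates Two-column matrix of candidate source pairs.
#' @param tol Convergence tolerance: relative L-infinity change of the
#'   parameter vector between iterations.
#' @param max_iter Maximum EM iterations per run.
#' @param n_restarts Number of EM runs (first from all-ones, the rest from
#'   uniform random initializations).
#' @param prune Apply the first-order boundary refinement that fixes
#'   channels whose maximum sits at zero to exactly 0 (see Details).
#'   Without it, such channels retain small positive remnants of their
#'   geometric decay.
#' @param seed Optional seed for the random restarts.
#' @return An object of class `sc_em`: list with `p_pair` (named vector),
#'   `p_triple` (data frame `j`, `k`, `p`), `epsilon`, `loglik_trace`,
#'   `iterations`, `converged`, `n_restarts_used`.
#' @seealso [em_first_step()], [reconstruct()]
#' @export
em_full <- function(S, i, pair_candidates, triple_candidates,
                    tol = 1e-6, max_iter = 500L, n_restarts = 1L,
                    prune = TRUE, seed = NULL) {
  em_node(S, i, pair_candidates, triple_candidates,
          em_options(tol = tol, max_iter = max_iter,
                     n_restarts = n_restarts, prune = prune, seed = seed))
}

#' First-step EM: pairwise channels only
#'
#' The first step of the two-step reconstruction strategy: the same EM
#' machinery as [em_full()] with the three-body channels omitted, fitted
#' against every other node as a pairwise candidate. Its output ranks
#' "approximate" neighbours of the target; see [approximate_neighbors()].
#'
#' Boundary pruning is off by default here: the first step feeds a
#' maximum-gap truncation whose job is to keep every true neighbour, and
#' pairs-only fits deliberately mis-attribute three-body effects, so
#' channels must not be forced to exact zero at this stage.
#'
#' @inheritParams em_full
#' @return An `sc_em` object whose `p_triple` table is empty.
#' @export
em_first_step <- function(S, i, tol = 1e-6, max_iter = 500L,
                          n_restarts = 1L, prune = FALSE, seed = NULL) {
  S <- check_binary_states(S)
  others <- setdiff(0:(ncol(S) - 1L), i)
  em_node(S, i, others, NULL,
          em_options(tol = tol, max_iter = max_iter,
                     n_restarts = n_restarts, prune = prune, seed = seed))
}

#' @export
print.sc_em <- function(x, ...) {
  cat(sprintf("EM fit for node %d: %d pairwise, %d triple channel(s)\n",
              x$target, length(x$p_pair), nrow(x$p_triple)))
  cat(sprintf("  nonzero: %d pairwise, %d triple; epsilon = %.3g\n",
              sum(x$p_pair > 0), sum(x$p_triple$p > 0), x$epsilon))
  cat(sprintf("  %d iteration(s), %sconverged, final loglik %.6g\n",
              x$iterations, if (x$converged) "" else "NOT ",
              if (length(x$loglik_trace)) x$loglik_trace[length(x$loglik_trace)]
              else NA_real_))
  invisible(x)
}
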