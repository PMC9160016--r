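# Two-step reconstruction of a 2-simplicial complex from a state matrix.

#' Reconstruct a 2-simplicial complex from binary time-series data
#'
#' The main fitting function of the package. For every node i it runs the
#' two-step strategy:
#'
#' 1. *First step* — [em_first_step()] fits pairwise channels against all
#'    other nodes, and [approximate_neighbors()] truncates the resulting
#'    probability list at a conservative maximum-gap threshold, yielding
#'    the candidate neighbourhood of i.
#' 2. *Second step* — [em_full()] refits on the columns of the candidate
#'    neighbours only, with every unordered pair of candidates as a
#'    three-body channel (closure implies both members of a 2-simplex at i
#'    are neighbours of i, so no other pair needs to be scored).
#'
#' Assembly: an edge \{i, j\} is predicted when `P_{j->i} > 0` or
#' `P_{i->j} > 0` (values below `clip` are treated as exact zeros). For
#' triangles, each node's triple probabilities are truncated at their own
#' maximum-gap threshold and a triple \{i, j, k\} is accepted when at
#' least two of the three directed conditions pass (the 2-of-3 conflict
#' rule). Accepted triples whose three edges are not all predicted are
#' dropped to enforce closure; they are reported in `dropped_triangles`.
#'
#' @param S Binary [state_matrix()] (or 0/1 matrix), T time steps x N
#'   nodes.
#' @param tol,max_iter,n_restarts EM controls, see [em_full()].
#' @param clip Probabilities below this value are set to exactly 0 before
#'   assembly, absorbing floating-point dust in the M-step numerators.
#' @param seed Optional seed (only consumed by random EM restarts when
#'   `n_restarts > 1`).
#' @param nodes Optional subset of target nodes (0-based) for partial
#'   reconstruction; assembly then only sees their fits.
#' @param verbose Print per-node progress.
#' @return An object of class `sc_reconstruction`: list with
#'   \describe{
#'     \item{complex}{the predicted [simplicial_complex()]}
#'     \item{pair_prob}{list (by node) of named vectors `P_{j->i}` over the
#'       node's candidate neighbours, clipped}
#'     \item{triple_prob}{list (by node) of data frames `j`, `k`, `p`}
#'     \item{first_step}{list (by node) of named first-step vectors
#'       `P^0_{j->i}`}
#'     \item{neighbors}{list of candidate neighbour sets from step 1}
#'     \item{epsilon}{per-node noise rates}
#'     \item{iterations}{per-node EM iteration counts (step1 + step2)}
#'     \item{triangle_thresholds}{per-node maximum-gap thresholds on the
#'       triple probabilities}
#'     \item{dropped_triangles}{matrix of 2-of-3 accepted triples removed
#'       by closure enforcement}
#'   }
#' @examples
#' sc <- generate_ersc(30, 6, 2, seed = 1)
#' S <- simulate_contagion(sc, 3000, alpha = 0.8, omega = 2.4, mu = 1,
#'                         rho0 = 0.2, seed = 2)
#' fit <- reconstruct(S)
#' score(sc, fit, "edges")
#' @seealso [score()], [coef.sc_reconstruction()], [predict.sc_reconstruction()]
#' @export
reconstruct <- function(S, tol = 1e-6, max_iter = 500L, n_restarts = 1L,
                        clip = 1e-9, seed = NULL, nodes = NULL,
                        verbose = FALSE) {
  S <- check_binary_states(S)
  n <- ncol(S)
  # step 1 keeps decaying channels (inclusive candidate ranking); step 2
  # prunes boundary channels to exact zero so the P > 0 edge rule is sharp
  opts1 <- em_options(tol = tol, max_iter = max_iter, n_restarts = n_restarts,
                      clip = clip, prune = FALSE, seed = seed)
  opts <- em_options(tol = tol, max_iter = max_iter, n_restarts = n_restarts,
                     clip = clip, prune = TRUE, seed = seed)
  targets <- if (is.null(nodes)) 0:(n - 1L) else sort(unique(as.integer(nodes)))
  pair_prob <- vector("list", n)
  triple_prob <- vector("list", n)
  first_step <- vector("list", n)
  neighbors <- vector("list", n)
  epsilon <- rep(NA_real_, n)
  iterations <- matrix(0L, nrow = n, ncol = 2L,
                       dimnames = list(NULL, c("step1", "step2")))
  others_all <- 0:(n - 1L)
  for (i in targets) {
    fs <- tryCatch(
      em_node(S, i, setdiff(others_all, i), NULL, opts1),
      error = function(e) NULL)
    if (is.null(fs)) {
      first_step[[i + 1L]] <- numeric(0)
      neighbors[[i + 1L]] <- integer(0)
      pair_prob[[i + 1L]] <- numeric(0)
      triple_prob[[i + 1L]] <- data.frame(j = integer(0), k = integer(0),
                                          p = numeric(0))
      next
    }
    p0 <- fs$p_pair
    p0[p0 < clip] <- 0
    first_step[[i + 1L]] <- p0
    nb <- approximate_neighbors(p0)
    neighbors[[i + 1L]] <- nb
    iterations[i + 1L, 1L] <- fs$iterations
    if (length(nb) == 0L) {
      pair_prob[[i + 1L]] <- numeric(0)
      triple_prob[[i + 1L]] <- data.frame(j = integer(0), k = integer(0),
                                          p = numeric(0))
      epsilon[i + 1L] <- fs$epsilon
      next
    }
    tc <- if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      cbind(cmb[1L, ], cmb[2L, ])
    } else NULL
    ss <- em_node(S, i, nb, tc, opts)
    pp <- ss$p_pair
    pp[pp < clip] <- 0
    pair_prob[[i + 1L]] <- pp
    pt <- ss$p_triple
    pt$p[pt$p < clip] <- 0
    triple_prob[[i + 1L]] <- pt
    epsilon[i + 1L] <- ss$epsilon
    iterations[i + 1L, 2L] <- ss$iterations
    if (verbose) {
      message(sprintf("node %d: %d candidate(s), %d+%d EM iterations",
                      i, length(nb), fs$iterations, ss$iterations))
    }
  }
  asm <- assemble_prediction(n, targets, pair_prob, triple_prob)
  structure(c(asm,
              list(pair_prob = pair_prob, triple_prob = triple_prob,
                   first_step = first_step, neighbors = neighbors,
                   epsilon = epsilon, iterations = iterations,
                   n_nodes = n, n_steps = nrow(S), targets = targets,
                   options = opts, call = match.call())),
            class = "sc_reconstruction")
}

# Edge OR-rule and triangle 2-of-3 rule + closure enforcement.
assemble_prediction <- function(n, targets, pair_prob, triple_prob) {
  edge_keys <- new.env(hash = TRUE, parent = emptyenv())
  for (i in targets) {
    pp <- pair_prob[[i + 1L]]
    for (j in as.integer(names(pp)[pp > 0])) {
      assign(pair_key(i, j), TRUE, envir = edge_keys)
    }
  }
  ek <- ls(edge_keys)
  edges <- if (length(ek)) {
    do.call(rbind, lapply(strsplit(ek, "-", fixed = TRUE),
                          function(x) as.integer(x)))
  } else matrix(integer(0), ncol = 2L)
  # per-node triangle thresholds and votes
  thresholds <- rep(NA_real_, n)
  votes <- new.env(hash = TRUE, parent = emptyenv())
  for (i in targets) {
    pt <- triple_prob[[i + 1L]]
    if (!nrow(pt)) next
    g <- gap_threshold(pt$p)
    thresholds[i + 1L] <- g$threshold
    pass <- pt$p > 0 & pt$p >= g$threshold
    if (!any(pass)) next
    keys <- triple_key(rep(i, sum(pass)), pt$j[pass], pt$k[pass])
    for (k in keys) {
      assign(k, (if (exists(k, envir = votes, inherits = FALSE))
        get(k, envir = votes) else 0L) + 1L, envir = votes)
    }
  }
  tk <- ls(votes)
  accepted <- tk[vapply(tk, function(k) get(k, envir = votes) >= 2L,
                        logical(1))]
  tri <- if (length(accepted)) {
    do.call(rbind, lapply(strsplit(accepted, "-", fixed = TRUE), as.integer))
  } else matrix(integer(0), ncol = 3L)
  dropped <- matrix(integer(0), ncol = 3L)
  if (nrow(tri)) {
    ekeys <- if (nrow(edges)) pair_key(edges[, 1L], edges[, 2L]) else character(0)
    closed <- pair_key(tri[, 1L], tri[, 2L]) %in% ekeys &
      pair_key(tri[, 1L], tri[, 3L]) %in% ekeys &
      pair_key(tri[, 2L], tri[, 3L]) %in% ekeys
    dropped <- tri[!closed, , drop = FALSE]
    tri <- tri[closed, , drop = FALSE]
  }
  list(complex = simplicial_complex(n, edges = edges, triangles = tri),
       triangle_thresholds = thresholds,
       dropped_triangles = dropped)
}

#' @export
print.sc_reconstruction <- function(x, ...) {
  cat(sprintf("2-simplicial complex reconstruction (%d nodes, %d time steps)\n",
              x$n_nodes, x$n_steps))
  cat(sprintf("  predicted: %d edge(s), %d triangle(s)\n",
              nrow(x$complex$edges), nrow(x$complex$triangles)))
  if (nrow(x$dropped_triangles)) {
    cat(sprintf("  %d triangle(s) dropped by closure enforcement\n",
                nrow(x$dropped_triangles)))
  }
  cat(sprintf("  mean candidate neighbourhood: %.1f node(s)\n",
              mean(lengths(x$neighbors[x$targets + 1L]))))
  invisible(x)
}

#' @export
summary.sc_reconstruction <- function(object, ...) {
  out <- list(
    n_nodes = object$n_nodes,
    n_steps = object$n_steps,
    n_edges = nrow(object$complex$edges),
    n_triangles = nrow(object$complex$triangles),
    n_dropped = nrow(object$dropped_triangles),
    neighbor_sizes = summary(lengths(object$neighbors[object$targets + 1L])),
    iterations = summary(rowSums(object$iterations[object$targets + 1L, ,
                                                   drop = FALSE])),
    epsilon = summary(object$epsilon[object$targets + 1L])
  )
  class(out) <- "summary.sc_reconstruction"
  out
}

#' @export
print.summary.sc_reconstruction <- function(x, ...) {
  cat(sprintf("reconstruction of %d nodes from %d time steps\n",
              x$n_nodes, x$n_steps))
  cat(sprintf("  %d edge(s), %d triangle(s), %d dropped by closure\n",
              x$n_edges, x$n_triangles, x$n_dropped))
  cat("  candidate neighbourhood sizes:\n"); print(x$neighbor_sizes)
  cat("  EM iterations per node (both steps):\n"); print(x$iterations)
  cat("  noise rate epsilon:\n"); print(x$epsilon)
  invisible(x)
}

#' Interaction probability tables from a reconstruction
#'
#' @param object An `sc_reconstruction` fit.
#' @param type `"edges"` for the pairwise probabilities `P_{j->i}` (second
#'   step), `"triangles"` for `P_{jk->i}`, `"first_step"` for the
#'   first-step `P^0_{j->i}`.
#' @param ... Unused.
#' @return A data frame with columns `target`, `source` (or `source1`,
#'   `source2`) and `prob`, one row per fitted channel.
#' @export
coef.sc_reconstruction <- function(object, type = c("edges", "triangles",
                                                    "first_step"), ...) {
  type <- match.arg(type)
  if (type == "triangles") {
    rows <- lapply(object$targets, function(i) {
      pt <- object$triple_prob[[i + 1L]]
      if (!nrow(pt)) return(NULL)
      data.frame(target = i, source1 = pt$j, source2 = pt$k, prob = pt$p)
    })
  } else {
    field <- if (type == "edges") object$pair_prob else object$first_step
    rows <- lapply(object$targets, function(i) {
      pp <- field[[i + 1L]]
      if (!length(pp)) return(NULL)
      data.frame(target = i, source = as.integer(names(pp)),
                 prob = unname(pp))
    })
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- if (type == "triangles") {
      data.frame(target = integer(0), source1 = integer(0),
                 source2 = integer(0), prob = numeric(0))
    } else {
      data.frame(target = integer(0), source = integer(0), prob = numeric(0))
    }
  }
  rownames(out) <- NULL
  out
}

#' Predicted complex from a reconstruction
#'
#' @param object An `sc_reconstruction` fit.
#' @param ... Unused.
#' @return The predicted [simplicial_complex()].
#' @export
predict.sc_reconstruction <- function(object, ...) object$complex

#' Plot the inferred probability profile of one target node
#'
#' Shows the descending second-step probabilities for the chosen node with
#' the relevant truncation threshold, mirroring how the assembly rules
#' read them: pairwise values are kept when positive, triple values when
#' above the node's maximum-gap threshold.
#'
#' @param x An `sc_reconstruction` fit.
#' @param node Target node (0-based).
#' @param which `"pairs"`, `"triples"` or `"first_step"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted values.
#' @export
plot.sc_reconstruction <- function(x, node = 0L,
                                   which = c("pairs", "triples",
                                             "first_step"), ...) {
  which <- match.arg(which)
  vals <- switch(which,
                 pairs = x$pair_prob[[node + 1L]],
                 triples = x$triple_prob[[node + 1L]]$p,
                 first_step = x$first_step[[node + 1L]])
  vals <- sort(as.numeric(vals), decreasing = TRUE)
  if (!length(vals)) stop("no fitted values for this node")
  graphics::plot(seq_along(vals), vals, type = "h", lwd = 2,
                 xlab = "rank", ylab = "probability",
                 main = sprintf("node %d: %s", node, which), ...)
  graphics::points(seq_along(vals), vals, pch = 16)
  thr <- if (which == "triples") x$triangle_thresholds[node + 1L] else NULL
  if (!is.null(thr) && is.finite(thr)) {
    graphics::abline(h = thr, lty = 2, col = "red")
  }
  invisible(vals)
}
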