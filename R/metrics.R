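# Scoring reconstructions and the random state-flipping perturbation.

#' Score a reconstruction against the ground truth
#'
#' Treats every unordered node pair (edges mode) or node triple (triangles
#' mode) as a binary classification instance, with connections present in
#' the truth as the positive class, and reports the confusion counts,
#' precision `P = TP/(TP+FP)`, recall `R = TP/(TP+FN)` and their harmonic
#' mean `F1 = 2PR/(P+R)`. An empty prediction against a non-empty truth
#' scores `P = F1 = 0`; when truth and prediction are both empty the
#' reconstruction is exact and all three are 1.
#'
#' @param truth A [simplicial_complex()] ground truth.
#' @param predicted A [simplicial_complex()] or an `sc_reconstruction` fit
#'   (its predicted complex is used); must have the same `n_nodes`.
#' @param class_mode `"edges"` or `"triangles"`.
#' @return An object of class `sc_metrics`: list with `tp`, `fp`, `tn`,
#'   `fn`, `precision`, `recall`, `f1`, `class_mode`.
#' @examples
#' truth <- simplicial_complex(4, edges = rbind(c(0, 1), c(2, 3)))
#' pred  <- simplicial_complex(4, edges = rbind(c(0, 1), c(1, 2)))
#' score(truth, pred, "edges")   # TP 1, FP 1, FN 1 -> F1 = 0.5
#' @export
score <- function(truth, predicted, class_mode = c("edges", "triangles")) {
  class_mode <- match.arg(class_mode)
  if (inherits(predicted, "sc_reconstruction")) predicted <- predicted$complex
  stopifnot(inherits(truth, "simplicial_complex"),
            inherits(predicted, "simplicial_complex"))
  if (truth$n_nodes != predicted$n_nodes) {
    stop("truth and prediction disagree on n_nodes")
  }
  n <- truth$n_nodes
  if (class_mode == "edges") {
    tk <- pair_key(truth$edges[, 1L], truth$edges[, 2L])
    pk <- pair_key(predicted$edges[, 1L], predicted$edges[, 2L])
    total <- choose(n, 2)
  } else {
    tk <- triple_key(truth$triangles[, 1L], truth$triangles[, 2L],
                     truth$triangles[, 3L])
    pk <- triple_key(predicted$triangles[, 1L], predicted$triangles[, 2L],
                     predicted$triangles[, 3L])
    total <- choose(n, 3)
  }
  tp <- length(intersect(tk, pk))
  fp <- length(pk) - tp
  fn <- length(tk) - tp
  tn <- total - tp - fp - fn
  if (length(tk) == 0L && length(pk) == 0L) {
    prec <- rec <- f1 <- 1
  } else {
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = prec, recall = rec, f1 = f1,
                 class_mode = class_mode),
            class = "sc_metrics")
}

#' @export
print.sc_metrics <- function(x, ...) {
  cat(sprintf("%s: TP %d, FP %d, FN %d, TN %d\n", x$class_mode,
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  precision %.4f, recall %.4f, F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Randomly flip infected and susceptible states
#'
#' Robustness perturbation: uniformly selects `floor(f * #ones)` infected
#' (1) entries of the state matrix and sets them to 0, and the same number
#' of susceptible (0) entries and sets them to 1. The total number of
#' infected entries is therefore conserved exactly, and the Hamming
#' distance to the input is `2 * floor(f * #ones)`.
#'
#' @param S Binary [state_matrix()] (or 0/1 matrix).
#' @param f Fraction of infected entries to flip, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The perturbed matrix, same class and attributes as `S`.
#' @export
flip_states <- function(S, f, seed = NULL) {
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]")
  vals <- as.integer(S)
  if (!all(vals %in% c(0L, 1L))) stop("flip_states requires 0/1 states")
  ones <- which(vals == 1L)
  zeros <- which(vals == 0L)
  n_flip <- floor(f * length(ones))
  if (n_flip == 0L) return(S)
  if (length(zeros) < n_flip) {
    stop(sprintf("not enough susceptible entries to flip: need %d, have %d",
                 n_flip, length(zeros)))
  }
  with_seed(seed, {
    out <- S
    out[ones[sample.int(length(ones), n_flip)]] <- 0L
    out[zeros[sample.int(length(zeros), n_flip)]] <- 1L
    out
  })
}
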