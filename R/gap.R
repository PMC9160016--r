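# Maximum-gap truncation of a descending probability list.

#' Maximum-gap threshold
#'
#' Sorts the values in descending order and places a threshold in the
#' "maximum gap": the split index `l*` maximises the ratio-weighted gap
#' `(P'_l / P'_{l+1}) * (P'_l - P'_{l+1})` over all positions whose lower
#' value is strictly positive (so trailing zeros never participate). Ties
#' are broken towards the smallest `l`. The returned threshold is the
#' midpoint of the winning gap, which makes downstream strict and
#' non-strict comparisons equivalent for the listed values.
#'
#' @param values Numeric vector of non-negative values (any order).
#' @return An object of class `gap_threshold`: list with `sorted_values`
#'   (descending), `split_index` (`l*`, counted within the positive
#'   values), `threshold`, and `degenerate` (`TRUE` when fewer than two
#'   positive values exist, giving threshold 0 so all positives are kept,
#'   or when every candidate gap score is zero).
#' @examples
#' gap_threshold(c(0.9, 0.8, 0.1, 0.05))   # threshold 0.45 after index 2
#' @export
gap_threshold <- function(values) {
  if (any(values < 0)) stop("values must be non-negative")
  sorted <- sort(values, decreasing = TRUE)
  pos <- sorted[sorted > 0]
  if (length(pos) < 2L) {
    return(structure(list(sorted_values = sorted, split_index = length(pos),
                          threshold = 0, degenerate = TRUE),
                     class = "gap_threshold"))
  }
  hi <- pos[-length(pos)]
  lo <- pos[-1L]
  score <- (hi / lo) * (hi - lo)
  l_star <- which.max(score)            # first maximum: smallest l on ties
  structure(list(sorted_values = sorted,
                 split_index = l_star,
                 threshold = (pos[l_star] + pos[l_star + 1L]) / 2,
                 degenerate = score[l_star] == 0),
            class = "gap_threshold")
}

#' @export
print.gap_threshold <- function(x, ...) {
  cat(sprintf("maximum-gap threshold: %.6g (split after rank %d of %d%s)\n",
              x$threshold, x$split_index, length(x$sorted_values),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Approximate neighbourhood from a first-step fit
#'
#' Applies the maximum-gap truncation twice to the first-step pairwise
#' probabilities: the first gap threshold separates the dominant values;
#' a second gap search on the values strictly below it yields a smaller,
#' conservative threshold. Every node whose probability exceeds the second
#' threshold is kept, which is designed to retain all true neighbours at
#' the cost of some false candidates (they are weeded out in the second
#' EM pass).
#'
#' @param first_step An `sc_em` object from [em_first_step()], or a named
#'   numeric vector of first-step probabilities (names = 0-based nodes).
#' @return Integer vector of candidate neighbour labels (0-based).
#' @export
approximate_neighbors <- function(first_step) {
  p0 <- if (inherits(first_step, "sc_em")) first_step$p_pair else first_step
  if (is.null(names(p0))) stop("need a named probability vector")
  if (all(p0 <= 0)) return(integer(0))
  g1 <- gap_threshold(p0)
  below <- p0[p0 < g1$threshold]
  bar <- if (length(below)) gap_threshold(below)$threshold else 0
  sort(as.integer(names(p0)[p0 > bar]))
}
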