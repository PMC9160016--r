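# Experiment harness: generate -> simulate -> (flip) -> reconstruct -> score
# sweeps over the time-series length T or the flipping fraction f.

#' Run a reconstruction experiment sweep
#'
#' For each seed, generates a synthetic 2-simplicial complex, simulates
#' simplicial contagion, optionally perturbs the state matrix, runs the
#' two-step reconstruction and scores edges and triangles against the
#' ground truth. Exactly one of `t_grid` (accuracy versus time-series
#' length) or `f_grid` (robustness versus flipping fraction) drives the
#' sweep; with neither, a single cell at `t_steps` is run.
#'
#' For a `t_grid` sweep the contagion is simulated once per seed at
#' `max(t_grid)` steps and truncated to each grid value, so the curves for
#' one seed are nested prefixes of the same trajectory. For an `f_grid`
#' sweep the simulation runs at `t_steps` and each fraction is applied to
#' a fresh copy.
#'
#' @param generator `"ersc"`, `"sfsc"` or `"swsc"`.
#' @param n_nodes,k1,k2,m,rewire_p Generator parameters; `k1` is used by
#'   the ERSC, `m` by the other two.
#' @param alpha,omega,mu,rho0 Contagion parameters (see
#'   [simulate_contagion()]).
#' @param t_grid Integer vector of time-series lengths.
#' @param f_grid Numeric vector of flipping fractions.
#' @param t_steps Time-series length when `t_grid` is not given.
#' @param seeds Integer vector; one full realization (new complex, new
#'   trajectory) per entry.
#' @param reseed Re-seed the contagion on extinction (recommended for
#'   near-threshold dynamics, where long informative series are needed).
#' @param em List of control arguments forwarded to [reconstruct()].
#' @param verbose Print one line per completed cell.
#' @return A long-format data frame of class `sc_experiment` with columns
#'   `grid`, `value`, `seed`, `mode`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`, `f1`; failed cells carry `NA` scores. Use
#'   [summary.sc_experiment()] for the mean/SD table.
#' @export
run_experiment <- function(generator = c("ersc", "sfsc", "swsc"),
                           n_nodes = 200, k1 = 6, k2 = 2, m = 3,
                           rewire_p = 0.1,
                           alpha = 0.8, omega = 2.4, mu = 1, rho0 = 0.2,
                           t_grid = NULL, f_grid = NULL, t_steps = 10000,
                           seeds = 1:5, reseed = TRUE, em = list(),
                           verbose = FALSE) {
  generator <- match.arg(generator)
  if (!is.null(t_grid) && !is.null(f_grid)) {
    stop("give only one of `t_grid` and `f_grid`")
  }
  gen <- function(s) switch(generator,
    ersc = generate_ersc(n_nodes, k1, k2, seed = s),
    sfsc = generate_sfsc(n_nodes, m, k2, seed = s),
    swsc = generate_swsc(n_nodes, m, rewire_p, k2, seed = s))
  grid_name <- if (!is.null(t_grid)) "T" else if (!is.null(f_grid)) "f"
    else "T"
  grid_vals <- t_grid %||% f_grid %||% t_steps
  rows <- list()
  for (s in seeds) {
    sc <- gen(s)
    sim_steps <- if (!is.null(t_grid)) max(t_grid) else t_steps
    S <- simulate_contagion(sc, sim_steps, alpha = alpha, omega = omega,
                            mu = mu, rho0 = rho0, reseed = reseed,
                            seed = s + 10000L)
    for (v in grid_vals) {
      cell <- tryCatch({
        Sv <- if (grid_name == "T") {
          state_matrix(unclass(S)[seq_len(v), , drop = FALSE], "binary")
        } else if (v > 0) {
          flip_states(S, v, seed = s + 20000L)
        } else S
        fit <- do.call(reconstruct, c(list(S = Sv), em))
        lapply(c("edges", "triangles"), function(mode) {
          sm <- score(sc, fit, mode)
          data.frame(grid = grid_name, value = v, seed = s, mode = mode,
                     tp = sm$tp, fp = sm$fp, fn = sm$fn, tn = sm$tn,
                     precision = sm$precision, recall = sm$recall,
                     f1 = sm$f1)
        })
      }, error = function(e) {
        warning(sprintf("cell %s=%g seed=%d failed: %s", grid_name, v, s,
                        conditionMessage(e)), call. = FALSE)
        list(data.frame(grid = grid_name, value = v, seed = s, mode = "edges",
                        tp = NA, fp = NA, fn = NA, tn = NA, precision = NA,
                        recall = NA, f1 = NA),
             data.frame(grid = grid_name, value = v, seed = s,
                        mode = "triangles", tp = NA, fp = NA, fn = NA,
                        tn = NA, precision = NA, recall = NA, f1 = NA))
      })
      rows <- c(rows, cell)
      if (verbose) {
        message(sprintf("%s=%g seed=%d done", grid_name, v, s))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sc_experiment", "data.frame")
  out
}

#' Summarise an experiment sweep
#'
#' @param object An `sc_experiment` data frame from [run_experiment()].
#' @param ... Unused.
#' @return Data frame with the mean and SD of F1 per grid value and class.
#' @export
summary.sc_experiment <- function(object, ...) {
  agg <- stats::aggregate(f1 ~ grid + value + mode, data = object,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)),
                          na.action = stats::na.omit)
  out <- data.frame(grid = agg$grid, value = agg$value, mode = agg$mode,
                    f1_mean = agg$f1[, "mean"], f1_sd = agg$f1[, "sd"])
  out[order(out$mode, out$value), ]
}

#' Plot an experiment sweep
#'
#' F1 against the swept quantity, one line per class mode.
#'
#' @param x An `sc_experiment` data frame.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the summary table that was plotted.
#' @export
plot.sc_experiment <- function(x, ...) {
  sm <- summary(x)
  vals <- sort(unique(sm$value))
  em <- sm$f1_mean[sm$mode == "edges"][order(sm$value[sm$mode == "edges"])]
  tm <- sm$f1_mean[sm$mode == "triangles"][order(sm$value[sm$mode == "triangles"])]
  graphics::matplot(vals, cbind(em, tm), type = "b", pch = c(15, 17),
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = unique(sm$grid), ylab = "F1", ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("edges", "triangles"),
                   col = c("steelblue", "firebrick"), pch = c(15, 17),
                   lty = 1, bty = "n")
  invisible(sm)
}
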