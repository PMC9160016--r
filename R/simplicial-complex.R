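#' Construct a 2-simplicial complex
#'
#' A 2-simplicial complex is a collection of nodes, edges (1-simplexes) and
#' filled triangles (2-simplexes) satisfying the closure requirement: every
#' face of an included simplex is itself included, so the three edges of
#' every triangle must belong to the edge set.
#'
#' Node labels are 0-based integers in `[0, n_nodes)`, matching the on-disk
#' edge/triangle list format used throughout the package.
#'
#' @param n_nodes Number of nodes (positive integer).
#' @param edges Two-column matrix (or vector coercible to one) of node
#'   pairs; order within a row and duplicate rows are ignored.
#' @param triangles Three-column matrix of node triples; order within a row
#'   and duplicates are ignored.
#' @param check If `TRUE` (default) validate labels, self-loops and closure;
#'   a closure violation is an error.
#' @return An object of class `simplicial_complex`: a list with elements
#'   `n_nodes`, `edges` (m x 2 integer matrix, each row sorted, u < v) and
#'   `triangles` (q x 3 integer matrix, u < v < w).
#' @examples
#' sc <- simplicial_complex(4, edges = rbind(c(0, 1), c(0, 2), c(1, 2), c(2, 3)),
#'                          triangles = rbind(c(0, 1, 2)))
#' average_degrees(sc)
#' @seealso [generate_ersc()], [generate_sfsc()], [generate_swsc()],
#'   [validate_complex()], [average_degrees()]
#' @export
simplicial_complex <- function(n_nodes, edges = NULL, triangles = NULL,
                               check = TRUE) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1L) {
    stop("`n_nodes` must be a single positive integer")
  }
  sc <- structure(
    list(
      n_nodes = n_nodes,
      edges = canonical_rows(edges, 2L),
      triangles = canonical_rows(triangles, 3L)
    ),
    class = "simplicial_complex"
  )
  if (check) validate_complex(sc)
  sc
}

#' Validate a 2-simplicial complex
#'
#' Checks node-label range, absence of self-loops/degenerate triples, and
#' the closure requirement (all three edges of every triangle are present).
#'
#' @param sc A [simplicial_complex()] object.
#' @return `sc`, invisibly; errors describe the first violation found.
#' @export
validate_complex <- function(sc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  e <- sc$edges; tr <- sc$triangles
  labs <- c(e, tr)
  if (length(labs) && (min(labs) < 0L || max(labs) >= sc$n_nodes)) {
    stop("node labels must lie in [0, n_nodes)")
  }
  if (nrow(e) && any(e[, 1L] == e[, 2L])) stop("self-loop in edge set")
  if (nrow(tr) && any(tr[, 1L] == tr[, 2L] | tr[, 2L] == tr[, 3L])) {
    stop("degenerate triple in triangle set")
  }
  if (nrow(tr)) {
    ek <- pair_key(e[, 1L], e[, 2L])
    ok <- pair_key(tr[, 1L], tr[, 2L]) %in% ek &
      pair_key(tr[, 1L], tr[, 3L]) %in% ek &
      pair_key(tr[, 2L], tr[, 3L]) %in% ek
    if (any(!ok)) {
      bad <- tr[which(!ok)[1L], ]
      stop(sprintf(
        "closure violated: triangle (%d, %d, %d) references an edge missing from the edge set",
        bad[1L], bad[2L], bad[3L]))
    }
  }
  invisible(sc)
}

#' Average two-body and three-body degrees
#'
#' The average degree of pairwise connections is `k1 = 2 |E| / N` and of
#' three-body connections `k2 = 3 |T| / N`, where `|E|` and `|T|` are the
#' numbers of edges and triangles.
#'
#' @param sc A [simplicial_complex()] object.
#' @return Named numeric vector `c(k1 = ..., k2 = ...)`.
#' @export
average_degrees <- function(sc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  c(k1 = 2 * nrow(sc$edges) / sc$n_nodes,
    k2 = 3 * nrow(sc$triangles) / sc$n_nodes)
}

#' @export
print.simplicial_complex <- function(x, ...) {
  k <- average_degrees(x)
  cat("2-simplicial complex\n")
  cat(sprintf("  nodes:     %d\n", x$n_nodes))
  cat(sprintf("  edges:     %d (k1 = %.3f)\n", nrow(x$edges), k[["k1"]]))
  cat(sprintf("  triangles: %d (k2 = %.3f)\n", nrow(x$triangles), k[["k2"]]))
  invisible(x)
}

#' @export
summary.simplicial_complex <- function(object, ...) {
  deg <- tabulate(c(object$edges) + 1L, nbins = object$n_nodes)
  tdeg <- tabulate(c(object$triangles) + 1L, nbins = object$n_nodes)
  out <- list(n_nodes = object$n_nodes,
              n_edges = nrow(object$edges),
              n_triangles = nrow(object$triangles),
              k = average_degrees(object),
              degree_summary = summary(deg),
              triangle_degree_summary = summary(tdeg))
  class(out) <- "summary.simplicial_complex"
  out
}

#' @export
print.summary.simplicial_complex <- function(x, ...) {
  cat(sprintf("2-simplicial complex: %d nodes, %d edges, %d triangles\n",
              x$n_nodes, x$n_edges, x$n_triangles))
  cat(sprintf("  k1 = %.3f, k2 = %.3f\n", x$k[["k1"]], x$k[["k2"]]))
  cat("  node degree (edges):\n")
  print(x$degree_summary)
  cat("  node degree (triangles):\n")
  print(x$triangle_degree_summary)
  invisible(x)
}

#' Plot a 2-simplicial complex
#'
#' Draws the underlying graph with 2-simplexes shaded.
#'
#' @param x A [simplicial_complex()] object.
#' @param layout Optional n x 2 coordinate matrix; defaults to a
#'   Fruchterman-Reingold layout of the edge graph.
#' @param triangle_col Fill colour for the 2-simplexes.
#' @param vertex_cex Node symbol expansion.
#' @param ... Unused.
#' @return The layout matrix, invisibly.
#' @export
plot.simplicial_complex <- function(x, layout = NULL,
                                    triangle_col = grDevices::adjustcolor("orange", 0.4),
                                    vertex_cex = 0.8, ...) {
  g <- as_igraph(x)
  if (is.null(layout)) layout <- igraph::layout_with_fr(g)
  graphics::plot.new()
  graphics::plot.window(range(layout[, 1L]), range(layout[, 2L]), asp = 1)
  if (nrow(x$triangles)) {
    for (r in seq_len(nrow(x$triangles))) {
      idx <- x$triangles[r, ] + 1L
      graphics::polygon(layout[idx, 1L], layout[idx, 2L],
                        col = triangle_col, border = NA)
    }
  }
  if (nrow(x$edges)) {
    graphics::segments(layout[x$edges[, 1L] + 1L, 1L],
                       layout[x$edges[, 1L] + 1L, 2L],
                       layout[x$edges[, 2L] + 1L, 1L],
                       layout[x$edges[, 2L] + 1L, 2L],
                       col = "grey30")
    }
  graphics::points(layout, pch = 21, bg = "steelblue", cex = vertex_cex)
  invisible(layout)
}

#' Convert a 2-simplicial complex to an igraph graph
#'
#' Only the 1-skeleton (nodes and edges) is represented; triangle
#' membership is not carried over.
#'
#' @param sc A [simplicial_complex()] object.
#' @return An undirected [igraph::graph] with `n_nodes` vertices.
#' @export
as_igraph <- function(sc) {
  stopifnot(inherits(sc, "simplicial_complex"))
  g <- igraph::make_empty_graph(n = sc$n_nodes, directed = FALSE)
  if (nrow(sc$edges)) g <- igraph::add_edges(g, t(sc$edges + 1L))
  g
}

# Edge set membership helper: logical lookup table keyed by pair_key.
edge_set <- function(sc) {
  if (!nrow(sc$edges)) return(character(0))
  pair_key(sc$edges[, 1L], sc$edges[, 2L])
}
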