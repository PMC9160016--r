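# Plain-text file formats and the real-world contact-stream builder.
#
# A complex on disk is three files sharing one prefix:
#   <prefix>.nodes      one line: n_nodes
#   <prefix>.edges      two tab-separated 0-based columns, u < v
#   <prefix>.triangles  three tab-separated 0-based columns, u < v < w
# State matrices are headerless CSV (rows = time steps); an RDS container
# carrying the alphabet is available for large runs.

#' Write a 2-simplicial complex to edge/triangle list files
#'
#' @param sc A [simplicial_complex()].
#' @param prefix Path prefix; `<prefix>.nodes`, `<prefix>.edges` and
#'   `<prefix>.triangles` are (over)written.
#' @return `prefix`, invisibly.
#' @export
write_complex <- function(sc, prefix) {
  stopifnot(inherits(sc, "simplicial_complex"))
  writeLines(as.character(sc$n_nodes), paste0(prefix, ".nodes"))
  utils::write.table(sc$edges, paste0(prefix, ".edges"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sc$triangles, paste0(prefix, ".triangles"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

read_simplex_file <- function(path, ncol) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(matrix(integer(0), ncol = ncol))
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(lengths(parts) != ncol)
  if (length(bad)) {
    stop(sprintf("%s line %d: expected %d fields, found %d",
                 path, bad[1L], ncol, length(parts[[bad[1L]]])))
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))),
              ncol = ncol, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop(sprintf("%s line %d: non-integer field", path, bad))
  }
  m
}

#' Read a 2-simplicial complex from edge/triangle list files
#'
#' @param prefix Path prefix written by [write_complex()].
#' @param on_closure_violation `"error"` (default) to reject a triangle
#'   list referencing a missing edge, `"drop"` to discard the offending
#'   triangles with a warning.
#' @return A [simplicial_complex()].
#' @export
read_complex <- function(prefix,
                         on_closure_violation = c("error", "drop")) {
  on_closure_violation <- match.arg(on_closure_violation)
  n_nodes <- as.integer(readLines(paste0(prefix, ".nodes"))[1L])
  if (is.na(n_nodes)) stop("invalid node-count header in ", prefix, ".nodes")
  edges <- read_simplex_file(paste0(prefix, ".edges"), 2L)
  tri <- read_simplex_file(paste0(prefix, ".triangles"), 3L)
  if (length(c(edges, tri)) &&
      (min(c(edges, tri)) < 0L || max(c(edges, tri)) >= n_nodes)) {
    stop("node label out of range [0, ", n_nodes, ") in ", prefix)
  }
  if (on_closure_violation == "drop" && nrow(tri)) {
    ek <- pair_key(edges[, 1L], edges[, 2L])
    ok <- pair_key(tri[, 1L], tri[, 2L]) %in% ek &
      pair_key(tri[, 1L], tri[, 3L]) %in% ek &
      pair_key(tri[, 2L], tri[, 3L]) %in% ek
    if (any(!ok)) {
      warning(sprintf("dropped %d triangle(s) violating closure", sum(!ok)))
      tri <- tri[ok, , drop = FALSE]
    }
  }
  simplicial_complex(n_nodes, edges = edges, triangles = tri)
}

#' Write a state matrix
#'
#' @param S A [state_matrix()].
#' @param path Output file.
#' @param format `"csv"` for headerless integer CSV (rows = time steps) or
#'   `"rds"` for a serialized container that also records the alphabet.
#' @return `path`, invisibly.
#' @export
write_state_matrix <- function(S, path, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.table(unclass(S), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    saveRDS(list(values = unclass(S), alphabet = attr(S, "alphabet")), path)
  }
  invisible(path)
}

#' Read a state matrix
#'
#' CSV input is headerless integer CSV; the alphabet is inferred from the
#' values (any negative entry means spin data). RDS input restores the
#' stored alphabet.
#'
#' @param path File written by [write_state_matrix()].
#' @param format `"csv"` or `"rds"`; default guesses from the extension.
#' @return A [state_matrix()].
#' @export
read_state_matrix <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.rds$", path, ignore.case = TRUE))
    "rds" else "csv")
  if (format == "rds") {
    obj <- readRDS(path)
    return(state_matrix(obj$values, obj$alphabet))
  }
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   colClasses = "integer"))
  dimnames(m) <- NULL
  state_matrix(m, if (any(m < 0)) "spin" else "binary")
}

#' Write reconstruction probability tables
#'
#' Emits the per-target probability tables of a fit as tab-separated
#' files: `<prefix>.pairs.tsv` (`target`, `source`, `prob`),
#' `<prefix>.triples.tsv` (`target`, `source1`, `source2`, `prob`) and
#' `<prefix>.first_step.tsv`.
#'
#' @param fit An `sc_reconstruction` object.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_prob_tables <- function(fit, prefix) {
  stopifnot(inherits(fit, "sc_reconstruction"))
  utils::write.table(coef(fit, "edges"), paste0(prefix, ".pairs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(coef(fit, "triangles"), paste0(prefix, ".triples.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(coef(fit, "first_step"),
                     paste0(prefix, ".first_step.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a probability table written by [write_prob_tables()]
#'
#' @param path A `.tsv` file with a header line.
#' @return A data frame.
#' @export
read_prob_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Read a face-to-face contact-event stream
#'
#' Three tab-separated columns without header: timestamp in seconds,
#' node u, node v (SocioPatterns column order). Records are sorted by
#' timestamp on load.
#'
#' @param path Input TSV file.
#' @return A data frame with columns `time`, `u`, `v` of class
#'   `contact_stream`.
#' @export
read_contact_stream <- function(path) {
  m <- read_simplex_file(path, 3L)
  contact_stream(m[, 1L], m[, 2L], m[, 3L])
}

#' Construct a contact-event stream object
#'
#' @param time Integer timestamps (seconds).
#' @param u,v 0-based node labels, `u != v`.
#' @return Data frame of class `contact_stream`, sorted by time.
#' @export
contact_stream <- function(time, u, v) {
  if (any(u == v)) stop("self-contact records are not allowed")
  if (any(u < 0 | v < 0)) stop("node labels must be non-negative")
  df <- data.frame(time = as.numeric(time), u = as.integer(pmin(u, v)),
                   v = as.integer(pmax(u, v)))
  df <- df[order(df$time), ]
  rownames(df) <- NULL
  class(df) <- c("contact_stream", "data.frame")
  df
}

#' Build a 2-simplicial complex from a contact-event stream
#'
#' Mirrors the construction used for empirical face-to-face data:
#' 1. aggregate contacts into pair weights over the whole stream;
#' 2. remove pairs with weight below `zeta` and binarize the rest — these
#'    are the edges;
#' 3. cut the raw clock into consecutive windows of `window_s` seconds
#'    (`floor(time / window_s)`); within a window, every node triple whose
#'    three pairwise contacts all occur is one occurrence of a candidate
#'    2-simplex;
#' 4. rank candidates by their total occurrence count across windows and
#'    keep the top `keep_frac` fraction (`floor(keep_frac * n)`,
#'    candidates tied with the cutoff count are all kept);
#' 5. drop kept triangles whose three edges did not all survive the
#'    weight threshold (closure), with a warning.
#'
#' @param stream A [contact_stream()] (or data frame with `time`, `u`,
#'   `v`).
#' @param zeta Minimum raw contact count for a pair to become an edge.
#' @param window_s Window length in seconds (default 300, i.e. 5 minutes).
#' @param keep_frac Fraction of candidate 2-simplexes retained (default
#'   0.5).
#' @param n_nodes Optional node count; default `max(label) + 1`.
#' @return A [simplicial_complex()].
#' @examples
#' # a small synthetic stream with two planted triads ships with the package
#' st <- read_contact_stream(system.file("extdata", "synthetic_contacts.tsv",
#'                                       package = "simplex2"))
#' build_complex_from_contacts(st, zeta = 5)
#' @export
build_complex_from_contacts <- function(stream, zeta, window_s = 300,
                                        keep_frac = 0.5, n_nodes = NULL) {
  if (!nrow(stream)) stop("empty contact stream")
  if (zeta < 0 || window_s <= 0 || keep_frac < 0 || keep_frac > 1) {
    stop("invalid threshold, window or retention fraction")
  }
  n_nodes <- n_nodes %||% (max(stream$u, stream$v) + 1L)
  key <- pair_key(stream$u, stream$v)
  w <- table(key)
  kept_pairs <- names(w)[as.vector(w) >= zeta]
  if (!length(kept_pairs)) {
    warning("weight threshold zeta removed every edge; returning an ",
            "empty complex")
    return(simplicial_complex(n_nodes))
  }
  edges <- do.call(rbind, lapply(strsplit(kept_pairs, "-", fixed = TRUE),
                                 as.integer))
  # candidate 2-simplexes: triangles of the per-window contact graphs
  win <- floor(stream$time / window_s)
  counts <- new.env(hash = TRUE, parent = emptyenv())
  for (wv in unique(win)) {
    sel <- win == wv
    pk <- unique(key[sel])
    ends <- do.call(rbind, lapply(strsplit(pk, "-", fixed = TRUE),
                                  as.integer))
    labs <- sort(unique(c(ends)))
    g <- igraph::make_empty_graph(length(labs), directed = FALSE)
    g <- igraph::add_edges(g, t(matrix(match(ends, labs), ncol = 2L)))
    tr <- matrix(as.integer(igraph::triangles(g)), nrow = 3L)
    if (!ncol(tr)) next
    keys <- triple_key(labs[tr[1L, ]], labs[tr[2L, ]], labs[tr[3L, ]])
    for (k in keys) {
      assign(k, (if (exists(k, envir = counts, inherits = FALSE))
        get(k, envir = counts) else 0L) + 1L, envir = counts)
    }
  }
  cand <- ls(counts)
  tri <- matrix(integer(0), ncol = 3L)
  if (length(cand)) {
    freq <- vapply(cand, function(k) get(k, envir = counts), integer(1))
    n_keep <- floor(keep_frac * length(cand))
    if (n_keep > 0L) {
      cutoff <- sort(freq, decreasing = TRUE)[n_keep]
      kept <- cand[freq >= cutoff]      # ties with the cutoff all kept
      tri <- do.call(rbind, lapply(strsplit(kept, "-", fixed = TRUE),
                                   as.integer))
      ek <- pair_key(edges[, 1L], edges[, 2L])
      closed <- pair_key(tri[, 1L], tri[, 2L]) %in% ek &
        pair_key(tri[, 1L], tri[, 3L]) %in% ek &
        pair_key(tri[, 2L], tri[, 3L]) %in% ek
      if (any(!closed)) {
        warning(sprintf(
          "dropped %d candidate 2-simplex(es) lacking a surviving edge",
          sum(!closed)))
        tri <- tri[closed, , drop = FALSE]
      }
    }
  }
  simplicial_complex(n_nodes, edges = edges, triangles = tri)
}
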