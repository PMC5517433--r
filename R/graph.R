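#' Simple undirected graphs
#'
#' `simple_net` is a light container for an undirected simple graph (no
#' self-loops, no parallel edges): a dense 0-based external labelling, an
#' adjacency list, and cached degrees. It is the observed network that
#' patches are sampled from.
#'
#' @param edges A two-column matrix (or data frame) of vertex labels, one
#'   undirected edge per row. Duplicate and reversed-duplicate rows collapse
#'   to a single edge; self-loops are an error.
#' @param n Number of vertices. Defaults to `max(label) + 1` for 0-based
#'   integer labels; isolated vertices beyond the largest endpoint must be
#'   declared explicitly.
#'
#' @return An object of class `simple_net` with fields `n`, `adj` (list of
#'   integer neighbour vectors, internal 1-based indices), `deg`, `edges`
#'   (canonical two-column 0-based matrix with `u < v`), and `labels`
#'   (external label of each internal vertex).
#' @examples
#' g <- simple_net(rbind(c(0, 1), c(1, 2)))
#' net_degrees(g) # 1 2 1
#' @export
simple_net <- function(edges, n = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  if (any(edges != floor(edges)) || any(edges < 0)) {
    stop("vertex labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(edges) <- "integer"
  if (any(edges[, 1] == edges[, 2])) {
    stop("self-loops are not allowed in a simple_net", call. = FALSE)
  }
  if (is.null(n)) n <- if (nrow(edges)) max(edges) + 1L else 0L
  n <- as.integer(n)
  if (nrow(edges) && max(edges) >= n) stop("edge endpoint exceeds declared n", call. = FALSE)
  u <- pmin(edges[, 1], edges[, 2])
  v <- pmax(edges[, 1], edges[, 2])
  o <- order(u, v)
  u <- u[o]; v <- v[o]
  keep <- !duplicated(u * as.double(n) + v)
  u <- u[keep]; v <- v[keep]
  ends <- c(u, v) + 1L # internal 1-based
  adj <- split(c(v, u) + 1L, factor(ends, levels = seq_len(n)))
  adj <- lapply(adj, as.integer)
  names(adj) <- NULL
  structure(
    list(
      n = n,
      adj = adj,
      deg = lengths(adj),
      edges = cbind(u = u, v = v),
      labels = 0:(n - 1L)
    ),
    class = "simple_net"
  )
}

#' @export
print.simple_net <- function(x, ...) {
  cat(sprintf(
    "<simple_net> %d vertices, %d edges, mean degree %.3f\n",
    x$n, nrow(x$edges), if (x$n) mean(x$deg) else NA_real_
  ))
  invisible(x)
}

#' Vertex degrees of a graph
#'
#' @param graph A [simple_net()].
#' @param vertices Optional internal vertex indices (1-based); default all.
#' @return Integer vector of degrees.
#' @export
net_degrees <- function(graph, vertices = NULL) {
  stopifnot(inherits(graph, "simple_net"))
  if (is.null(vertices)) graph$deg else graph$deg[vertices]
}

#' Observed degree-frequency table of a graph
#'
#' @param graph A [simple_net()].
#' @return A tibble with columns `k`, `count`, `freq` (`N_k / n`).
#' @export
net_degree_table <- function(graph) {
  stopifnot(inherits(graph, "simple_net"))
  tab <- table(factor(graph$deg, levels = 0:max(c(graph$deg, 0L))))
  tibble::tibble(
    k = as.integer(names(tab)),
    count = as.integer(tab),
    freq = as.integer(tab) / graph$n
  )
}

#' @export
as_tibble.simple_net <- function(x, ...) {
  tibble::tibble(u = x$edges[, 1], v = x$edges[, 2])
}

#' Convert to an igraph object
#'
#' @param graph A [simple_net()].
#' @return An [igraph::graph] with the same vertices (names = external labels)
#'   and edges.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "simple_net"))
  igraph::graph_from_edgelist(graph$edges + 1L, directed = FALSE) |>
    igraph::add_vertices(max(0L, graph$n - max(c(graph$edges + 1L, 0L))))
}

#' Read and write plain-text edge lists
#'
#' One undirected edge per line as two whitespace-separated non-negative
#' integer labels. Blank lines and lines starting with `#` are ignored.
#' Duplicate lines (in either orientation) collapse to one edge; self-loop
#' lines are rejected. [write_edgelist()] emits the canonical form — one
#' `"u v"` line per edge with `u < v`, sorted — so that write-after-read is a
#' byte-identical normal form.
#'
#' @param path File path.
#' @param n Optional vertex count override (for trailing isolates).
#' @param relabel Map arbitrary (possibly sparse) integer labels to dense
#'   0-based internal indices; the original label of each internal vertex is
#'   kept in the `labels` field and used again on writing.
#' @return [read_edgelist()] returns a [simple_net()];
#'   [write_edgelist()] returns `path` invisibly.
#' @export
read_edgelist <- function(path, n = NULL, relabel = FALSE) {
  lines <- readLines(path)
  raw <- trimws(lines)
  keep <- nzchar(raw) & !startsWith(raw, "#")
  idx <- which(keep)
  if (!length(idx)) return(simple_net(matrix(integer(), ncol = 2), n = n))
  parts <- strsplit(raw[idx], "[[:space:]]+")
  bad <- which(vapply(parts, function(p) {
    length(p) != 2L || anyNA(suppressWarnings(as.integer(p)))
  }, logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed edge on line %d: '%s'", idx[bad[1]], raw[idx[bad[1]]]), call. = FALSE)
  }
  m <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  loop <- which(m[, 1] == m[, 2])
  if (length(loop)) {
    stop(sprintf("self-loop on line %d: '%s'", idx[loop[1]], raw[idx[loop[1]]]), call. = FALSE)
  }
  if (relabel) {
    labs <- sort(unique(as.vector(m)))
    g <- simple_net(matrix(match(m, labs) - 1L, ncol = 2L), n = length(labs))
    g$labels <- labs
    return(g)
  }
  simple_net(m, n = n)
}

#' @rdname read_edgelist
#' @param graph A [simple_net()].
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "simple_net"))
  u <- graph$labels[graph$edges[, 1] + 1L]
  v <- graph$labels[graph$edges[, 2] + 1L]
  writeLines(sprintf("%d %d", pmin(u, v), pmax(u, v)), path)
  invisible(path)
}
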