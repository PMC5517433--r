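#' Erdos--Gallai graphicality check
#'
#' @param degree_seq Integer vector of prescribed degrees.
#' @return `TRUE` if some simple graph realises the sequence.
#' @export
is_graphical <- function(degree_seq) {
  d <- sort(as.integer(degree_seq), decreasing = TRUE)
  if (any(d < 0) || sum(d) %% 2 == 1) return(FALSE)
  if (!length(d) || d[1] == 0) return(TRUE)
  n <- length(d)
  if (d[1] > n - 1) return(FALSE)
  lhs <- cumsum(d)
  for (k in seq_len(n)) {
    tail <- if (k < n) sum(pmin(d[(k + 1):n], k)) else 0
    if (lhs[k] > k * (k - 1) + tail) return(FALSE)
  }
  TRUE
}

#' Pair stubs into a configuration-model multigraph
#'
#' Each vertex `v` contributes `degree_seq[v]` stubs; stubs are matched
#' uniformly at random. The result may contain self-loops and parallel edges
#' (to be removed by [rewire_to_simple()]).
#'
#' @param degree_seq Integer degrees, even total.
#' @return Two-column integer matrix of edge endpoints (internal 1-based
#'   indices), possibly with loops and repeats.
#' @export
pair_stubs <- function(degree_seq) {
  d <- as.integer(degree_seq)
  if (any(d < 0)) stop("degrees must be non-negative", call. = FALSE)
  if (sum(d) %% 2 == 1) stop("degree sum must be even to pair stubs", call. = FALSE)
  stubs <- rep.int(seq_along(d), d)
  if (!length(stubs)) return(matrix(integer(), ncol = 2L))
  stubs <- stubs[sample.int(length(stubs))]
  matrix(stubs, ncol = 2L)
}

# Undirected edge codes for O(1)-ish duplicate detection: min*K + max with
# K = n + 1 stays exact in doubles for any graph order this package targets.
edge_codes <- function(edges, n) {
  pmin(edges[, 1], edges[, 2]) * as.double(n + 1) + pmax(edges[, 1], edges[, 2])
}

#' Rewire a configuration-model multigraph to a simple graph
#'
#' Applies degree-preserving double-edge swaps until no self-loops or parallel
#' edges remain. Each sweep visits every currently defective edge, pairs it
#' with a uniformly chosen partner edge, and accepts a swap orientation that
#' introduces no new defect. The output graph has exactly `degree_seq` as its
#' degree sequence.
#'
#' @param edges Two-column matrix from [pair_stubs()] (1-based indices).
#' @param degree_seq The prescribed degrees (checked for graphicality first).
#' @param max_sweeps Proposal budget in units of sweeps over defective edges.
#' @return A [simple_net()] on `length(degree_seq)` vertices.
#' @export
rewire_to_simple <- function(edges, degree_seq, max_sweeps = 100L) {
  d <- as.integer(degree_seq)
  n <- length(d)
  if (!is_graphical(d)) stop("degree sequence is not graphical", call. = FALSE)
  if (nrow(edges)) {
    got <- tabulate(edges, nbins = n)
    if (!identical(got, d)) stop("edges do not realise degree_seq", call. = FALSE)
  }
  m <- nrow(edges)
  codes <- edge_codes(edges, n)
  budget <- max_sweeps * max(m, 1L)
  used <- 0L
  repeat {
    defect <- which(edges[, 1] == edges[, 2] | duplicated(codes))
    if (!length(defect)) break
    if (used >= budget) {
      stop(sprintf(
        "rewiring budget exhausted with %d defective edges remaining", length(defect)
      ), call. = FALSE)
    }
    for (i in defect) {
      used <- used + 1L
      j <- sample.int(m, 1L)
      if (j == i) next
      a <- edges[i, 1]; b <- edges[i, 2]
      c_ <- edges[j, 1]; d_ <- edges[j, 2]
      # two swap orientations; try them in random order
      for (flip in sample(c(TRUE, FALSE))) {
        p <- if (flip) c(a, c_, b, d_) else c(a, d_, b, c_)
        if (p[1] == p[2] || p[3] == p[4]) next
        new1 <- min(p[1], p[2]) * as.double(n + 1) + max(p[1], p[2])
        new2 <- min(p[3], p[4]) * as.double(n + 1) + max(p[3], p[4])
        if (new1 == new2) next
        other <- codes[-c(i, j)]
        if (new1 %in% other || new2 %in% other) next
        edges[i, ] <- p[1:2]
        edges[j, ] <- p[3:4]
        codes[i] <- new1
        codes[j] <- new2
        break
      }
    }
  }
  simple_net(edges - 1L, n = n)
}

#' Generate a simple graph from a degree law
#'
#' Convenience pipeline: sample a degree sequence from `model`, pair stubs
#' (configuration model), rewire to a simple graph.
#'
#' @param model A [degree_model()].
#' @param n Graph order.
#' @param max_sweeps Passed to [rewire_to_simple()].
#' @return A [simple_net()] of order `n` whose degree sequence is an i.i.d.
#'   draw from `model` (parity-repaired).
#' @export
sample_network <- function(model, n, max_sweeps = 100L) {
  repeat {
    d <- sample_degrees(model, n)
    if (is_graphical(d)) break
  }
  rewire_to_simple(pair_stubs(d), d, max_sweeps = max_sweeps)
}
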