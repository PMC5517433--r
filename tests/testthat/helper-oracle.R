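# Independent brute-force patch enumerator used to cross-check lsmi().
#
# Works directly on the edge matrix with an explicit per-edge loop: at each
# wave every untraced edge with at least one endpoint in the frontier is
# traced, and its endpoints that have never been recorded are recorded once
# per such edge (multiplicity). Structurally unrelated to the incidence-list
# BFS inside the package.
oracle_patch <- function(graph, seed, d) {
  edges <- graph$edges + 1L
  visited <- logical(graph$n)
  visited[seed] <- TRUE
  traced <- logical(nrow(edges))
  frontier <- seed
  waves <- vector("list", d)
  for (w in seq_len(d)) {
    new_rec <- integer()
    for (e in which(!traced)) {
      a <- edges[e, 1]; b <- edges[e, 2]
      if (a %in% frontier || b %in% frontier) {
        traced[e] <- TRUE
        if (!visited[a]) new_rec <- c(new_rec, a)
        if (!visited[b]) new_rec <- c(new_rec, b)
      }
    }
    waves[[w]] <- new_rec
    visited[new_rec] <- TRUE
    frontier <- unique(new_rec)
  }
  list(seed_degree = graph$deg[seed], waves = waves)
}

# all labeled graphs on n vertices as edge-subset bitmasks; connected only
all_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  ne <- nrow(pairs)
  out <- list()
  for (mask in 0:(2^ne - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(ne - 1))) > 0)
    if (length(sel) < n - 1) next
    g <- simple_net(pairs[sel, , drop = FALSE] - 1L, n = n)
    ig <- igraph::graph_from_edgelist(g$edges + 1L, directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    if (igraph::is_connected(ig)) out[[length(out) + 1L]] <- g
  }
  out
}

random_connected_graph <- function(n, p = 0.45) {
  repeat {
    pairs <- t(utils::combn(n, 2))
    sel <- stats::runif(nrow(pairs)) < p
    if (sum(sel) < n - 1) next
    g <- simple_net(pairs[sel, , drop = FALSE] - 1L, n = n)
    ig <- igraph::graph_from_edgelist(g$edges + 1L, directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    if (igraph::is_connected(ig)) return(g)
  }
}

# Exhaustive comparison of lsmi() against the enumerator: every labeled
# connected graph on 2..5 vertices, every seed, waves up to 3 (shallower
# depths are prefixes), plus a seeded sample of 6-vertex graphs. Also audits
# the edge-trace ledger: a patch can hold at most one inclusion record per
# graph edge. Cached — shared between the unit and acceptance suites.
oracle_check <- function() {
  cached("oracle_check", {
    graphs <- list()
    for (n in 2:5) graphs <- c(graphs, all_connected_graphs(n))
    set.seed(606)
    graphs <- c(graphs, replicate(60, random_connected_graph(6), simplify = FALSE))
    mismatches <- 0L
    ledger_violations <- 0L
    for (g in graphs) {
      ps <- lsmi(g, seeds = seq_len(g$n), d = 3)
      for (s in seq_len(g$n)) {
        impl <- ps$patches[[s]]
        orac <- oracle_patch(g, s, 3)
        if (!identical(patch_signature(impl), oracle_signature(g, orac))) {
          mismatches <- mismatches + 1L
        }
        n_records <- sum(lengths(lapply(impl$waves, `[[`, "degree")))
        if (n_records > nrow(g$edges)) ledger_violations <- ledger_violations + 1L
      }
    }
    list(
      graphs = length(graphs),
      mismatches = mismatches,
      ledger_violations = ledger_violations
    )
  })
}

# sorted per-wave degree multisets of an lsmi patch, for comparison
patch_signature <- function(patch) {
  lapply(patch$waves, function(w) sort(w$degree))
}
oracle_signature <- function(graph, oracle) {
  lapply(oracle$waves, function(w) sort(graph$deg[w]))
}
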