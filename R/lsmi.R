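# Labeled Snowball with Multiple Inclusions.
#
# A patch is the ego network grown around one seed for d waves. Within a
# patch no edge is ever traced twice; a vertex first reached at wave j along
# r distinct previously-untraced edges is recorded r times at that wave
# (the "multiple inclusions"). Patches are grown independently, so they may
# overlap and a seed of one patch can be recorded as a non-seed of another.

# package-local counter so tests can audit how many snowballs a procedure grows
the <- new.env(parent = emptyenv())
the$lsmi_calls <- 0L

#' Sample seed vertices
#'
#' Uniform sampling without replacement. The order of the returned seeds is
#' meaningful: nested seed counts `m_1 < ... < m_l` use prefixes of one
#' ordered draw, so patches for smaller seed counts are subsets of the
#' maximal patch set.
#'
#' @param graph A [simple_net()].
#' @param m Number of seeds, `1 <= m <= n`.
#' @return Integer vector of internal vertex indices (1-based).
#' @export
sample_seeds <- function(graph, m) {
  stopifnot(inherits(graph, "simple_net"))
  if (m < 1 || m > graph$n) stop("m must be between 1 and the graph order", call. = FALSE)
  sample.int(graph$n, m)
}

# incidence lists: per vertex, ids and far endpoints of incident edges
incidence_lists <- function(graph) {
  ne <- nrow(graph$edges)
  u <- graph$edges[, 1] + 1L
  v <- graph$edges[, 2] + 1L
  ends <- c(u, v)
  eid <- rep.int(seq_len(ne), 2L)
  nbr <- c(v, u)
  f <- factor(ends, levels = seq_len(graph$n))
  list(
    eid = split(eid, f),
    nbr = split(nbr, f)
  )
}

#' Grow LSMI patches around seeds
#'
#' Breadth-first growth for `d` waves around each seed. Within a patch each
#' undirected edge is traversed at most once; a new vertex reached at wave
#' `j` via `r` distinct untraced edges is recorded `r` times at wave `j`. An
#' untraced edge between two already-recorded vertices is marked traced but
#' contributes no record. Every recorded vertex stores its full degree in
#' `graph`. Patches are grown independently and may overlap.
#'
#' @param graph A [simple_net()].
#' @param seeds Ordered distinct internal vertex indices (from
#'   [sample_seeds()]).
#' @param d Wave depth, `d >= 0` (`d = 0` records seed degrees only).
#' @return A `patch_set`: list with `patches` (per seed: `seed`,
#'   `seed_degree`, `waves` — per wave, a list with integer `vertex` and
#'   `degree` vectors carrying multiplicities), `d_max`, and `seeds`.
#' @examples
#' g <- simple_net(rbind(c(0, 1), c(1, 2), c(2, 3)))
#' ps <- lsmi(g, seeds = 2L, d = 1)
#' ps$patches[[1]]$waves[[1]]$degree # degrees of vertices 0 and 2: 1, 2
#' @export
lsmi <- function(graph, seeds, d) {
  stopifnot(inherits(graph, "simple_net"), d >= 0)
  seeds <- as.integer(seeds)
  if (anyDuplicated(seeds)) stop("seeds must be distinct", call. = FALSE)
  if (any(seeds < 1 | seeds > graph$n)) stop("seed not in graph", call. = FALSE)
  the$lsmi_calls <- the$lsmi_calls + 1L
  inc <- incidence_lists(graph)
  ne <- nrow(graph$edges)
  patches <- lapply(seeds, function(s) {
    waves <- vector("list", d)
    visited <- logical(graph$n)
    visited[s] <- TRUE
    traced <- logical(ne)
    frontier <- s
    for (w in seq_len(d)) {
      if (!length(frontier)) {
        waves[[w]] <- list(vertex = integer(), degree = integer())
        next
      }
      eids <- unlist(inc$eid[frontier], use.names = FALSE)
      nbrs <- unlist(inc$nbr[frontier], use.names = FALSE)
      keep <- !traced[eids] & !duplicated(eids)
      eids <- eids[keep]
      nbrs <- nbrs[keep]
      traced[eids] <- TRUE
      new_rec <- nbrs[!visited[nbrs]]
      waves[[w]] <- list(vertex = new_rec, degree = graph$deg[new_rec])
      visited[new_rec] <- TRUE
      frontier <- unique(new_rec)
    }
    list(seed = s, seed_degree = graph$deg[s], waves = waves)
  })
  structure(
    list(patches = patches, d_max = as.integer(d), seeds = seeds),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  nrec <- sum(vapply(x$patches, function(p) {
    sum(vapply(p$waves, function(w) length(w$degree), integer(1)))
  }, numeric(1)))
  cat(sprintf(
    "<patch_set> %d seeds, %d waves, %d non-seed inclusion records\n",
    length(x$patches), x$d_max, nrec
  ))
  invisible(x)
}

#' Restrict a patch set to fewer seeds and shallower waves
#'
#' A pure view: takes the first `m` patches and truncates each to `w` waves,
#' without touching the graph. Because seed order is retained and patches are
#' grown independently, every seed-wave combination of a grid can be served
#' by one maximal [lsmi()] call.
#'
#' @param patchset A `patch_set`.
#' @param m Seed count, `m <= length(patchset$patches)`.
#' @param w Wave depth, `0 <= w <= patchset$d_max`.
#' @return A `patch_set`.
#' @export
subpatch <- function(patchset, m, w) {
  stopifnot(inherits(patchset, "patch_set"))
  if (m < 1 || m > length(patchset$patches)) stop("m out of range", call. = FALSE)
  if (w < 0 || w > patchset$d_max) stop("w out of range", call. = FALSE)
  patches <- lapply(patchset$patches[seq_len(m)], function(p) {
    p$waves <- p$waves[seq_len(w)]
    p
  })
  structure(
    list(patches = patches, d_max = as.integer(w), seeds = patchset$seeds[seq_len(m)]),
    class = "patch_set"
  )
}

# flat degree pools used by the bootstrap: seed degrees and all non-seed
# inclusion records (with multiplicity) up to the patch set's wave depth
patch_pools <- function(patchset) {
  seed_deg <- vapply(patchset$patches, function(p) p$seed_degree, integer(1))
  ns <- unlist(lapply(patchset$patches, function(p) {
    unlist(lapply(p$waves, function(w) w$degree), use.names = FALSE)
  }), use.names = FALSE)
  list(seed = as.integer(seed_deg), nonseed = as.integer(if (is.null(ns)) integer() else ns))
}

#' @export
as_tibble.patch_set <- function(x, ...) {
  rows <- purrr::imap(x$patches, function(p, i) {
    seed_row <- tibble::tibble(
      patch = i, seed = p$seed, wave = 0L, vertex = p$seed, degree = p$seed_degree
    )
    wave_rows <- purrr::imap(p$waves, function(wv, w) {
      tibble::tibble(
        patch = i, seed = p$seed, wave = as.integer(w),
        vertex = as.integer(wv$vertex), degree = as.integer(wv$degree)
      )
    })
    dplyr::bind_rows(seed_row, wave_rows)
  })
  dplyr::bind_rows(rows)
}

#' Serialise a patch set to JSON (and back)
#'
#' Audit/replay format: one object per patch with the seed, its degree, and
#' per-wave arrays of `[vertex, degree]` pairs.
#'
#' @param patchset A `patch_set`.
#' @param path File path.
#' @return `write_patches()` returns `path` invisibly; `read_patches()`
#'   returns a `patch_set`.
#' @export
write_patches <- function(patchset, path) {
  stopifnot(inherits(patchset, "patch_set"))
  obj <- list(
    d_max = patchset$d_max,
    patches = lapply(patchset$patches, function(p) {
      list(
        seed = p$seed,
        seed_degree = p$seed_degree,
        waves = lapply(p$waves, function(w) {
          if (length(w$vertex)) cbind(w$vertex, w$degree) else matrix(integer(), ncol = 2)
        })
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  patches <- lapply(seq_along(obj$patches$seed), function(i) {
    waves <- obj$patches$waves[[i]]
    if (is.null(waves)) waves <- list()
    list(
      seed = as.integer(obj$patches$seed[i]),
      seed_degree = as.integer(obj$patches$seed_degree[i]),
      waves = lapply(waves, function(w) {
        w <- matrix(as.integer(w), ncol = 2)
        list(vertex = w[, 1], degree = w[, 2])
      })
    )
  })
  structure(
    list(
      patches = patches,
      d_max = as.integer(obj$d_max),
      seeds = vapply(patches, function(p) p$seed, integer(1))
    ),
    class = "patch_set"
  )
}
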