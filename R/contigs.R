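# BFS shortest path from vertex a to vertex b over positive-weight edges,
# at most max_depth edges long; returns vector of vertex indices (a..b) or NULL
bfs_path <- function(g, oa, a, b, max_depth = Inf) {
  nv <- n_vertices(g)
  parent <- integer(nv)
  depth <- integer(nv)
  seen <- logical(nv)
  queue <- a; seen[a] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    if (depth[v] >= max_depth) next
    for (e in oa[[v]]) {
      if (g$weight[e] <= 0) next
      t <- g$to[e]
      if (!seen[t]) {
        seen[t] <- TRUE; parent[t] <- v; depth[t] <- depth[v] + 1L
        if (t == b) {
          path <- b
          while (path[1] != a) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, t)
      }
    }
  }
  NULL
}

#' Does a simple return path exist for an edge?
#'
#' For an edge (u, v), a simple return path is a directed path of
#' positive-weight edges from v back to u such that the resulting cycle
#' (path plus edge) contains at least one vertex with more than one in-edge
#' and at least one vertex with more than one out-edge. Edges with a return
#' path are the loop-back edges of tandem repeats; this is what lets the
#' traversal re-enter a repeat instead of declaring the junction ambiguous.
#'
#' The search is depth-bounded (`max_return_depth` edges, default 1000):
#' tandem-repeat loops have at most motif-length edges, while on a circular
#' genome *every* edge closes the genome-scale cycle, which must not count
#' as a repeat loop (otherwise every repeat junction of a circular genome
#' would be ambiguous).
#'
#' @param g a `dbg` graph.
#' @param edge either an edge index or a length-2 character vector
#'   `c(from_label, to_label)`.
#' @param max_return_depth maximum return-path length in edges.
#' @return `TRUE` or `FALSE`.
#' @export
simple_return_path <- function(g, edge, max_return_depth = 1000L) {
  if (is.character(edge)) {
    ei <- edge_index(g, edge[1], edge[2])
    if (ei == 0) stop("edge not in graph: ", edge[1], "->", edge[2])
  } else ei <- as.integer(edge)
  return_path_static(g, ei, out_adj(g), out_deg(g), in_deg(g),
                     max_return_depth)
}

return_path_static <- function(g, ei, oa, od, id, max_depth = 1000L) {
  u <- g$from[ei]; v <- g$to[ei]
  path <- bfs_path(g, oa, v, u, max_depth)
  if (is.null(path)) return(FALSE)
  cyc <- unique(path)
  any(id[cyc] > 1) && any(od[cyc] > 1)
}

#' Is a vertex ambiguous for traversal?
#'
#' A vertex is unambiguous when each side (in and out) has at most one edge,
#' or exactly two edges of which exactly one has a simple return path. Any
#' side with three or more edges, or with two edges of which zero or both
#' have return paths, makes the vertex ambiguous; contigs end (and restart)
#' at ambiguous vertices.
#'
#' @param g a `dbg` graph.
#' @param v vertex label or index.
#' @param max_return_depth see [simple_return_path()].
#' @return `TRUE` if ambiguous.
#' @export
is_ambiguous <- function(g, v, max_return_depth = 1000L) {
  if (is.character(v)) {
    vi <- match(v, g$labels)
    if (is.na(vi)) stop("unknown vertex: ", v)
  } else vi <- as.integer(v)
  oa <- out_adj(g); ia <- in_adj(g)
  od <- out_deg(g); id <- in_deg(g)
  side_ambiguous <- function(edges) {
    m <- length(edges)
    if (m <= 1) return(FALSE)
    if (m >= 3) return(TRUE)
    nrp <- sum(vapply(edges, function(e) {
      return_path_static(g, e, oa, od, id, max_return_depth)
    }, FALSE))
    nrp != 1
  }
  side_ambiguous(oa[[vi]]) || side_ambiguous(ia[[vi]])
}

#' Start vertices for contig generation
#'
#' All vertices with in-degree 0 and out-degree at least 1, in lexicographic
#' order. Weakly connected components with no such vertex (perfect cycles,
#' e.g. circular genomes) contribute their lexicographically smallest vertex
#' with an out-edge instead.
#'
#' @param g a `dbg` graph.
#' @return character vector of vertex labels.
#' @export
find_start_vertices <- function(g) {
  if (n_edges(g) == 0) return(character())
  od <- out_deg(g); id <- in_deg(g)
  comp <- weak_components(g)
  starts <- integer(0)
  for (cc in split(seq_len(n_vertices(g)), comp)) {
    s <- cc[id[cc] == 0 & od[cc] >= 1]
    if (length(s) == 0) s <- cc[od[cc] >= 1][1]  # cycle fallback (labels sorted)
    starts <- c(starts, s)
  }
  g$labels[sort(starts)]
}

weak_components <- function(g) {
  nv <- n_vertices(g)
  comp <- integer(nv)
  nbr <- vector("list", nv)
  for (i in seq_along(g$from)) {
    nbr[[g$from[i]]] <- c(nbr[[g$from[i]]], g$to[i])
    nbr[[g$to[i]]] <- c(nbr[[g$to[i]]], g$from[i])
  }
  cid <- 0L
  for (v in seq_len(nv)) {
    if (comp[v] != 0L) next
    cid <- cid + 1L
    stack <- v
    while (length(stack) > 0) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[x] != 0L) next
      comp[x] <- cid
      stack <- c(stack, nbr[[x]][comp[nbr[[x]]] == 0L])
    }
  }
  comp
}

#' Assembly result container
#'
#' @param contigs ordered character vector of contig sequences.
#' @return list of class `assembly_result` with `contigs`, `n_contigs`,
#'   `n50` and `longest`.
#' @export
assembly_result <- function(contigs) {
  lens <- nchar(contigs)
  n50 <- 0L
  if (length(lens) > 0) {
    sl <- sort(lens, decreasing = TRUE)
    n50 <- sl[which(cumsum(sl) >= sum(sl) / 2)[1]]
  }
  structure(list(contigs = contigs, n_contigs = length(contigs),
                 n50 = as.integer(n50),
                 longest = if (length(lens)) max(lens) else 0L),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly: %d contig(s), N50 = %d bp, longest = %d bp\n",
              x$n_contigs, x$n50, x$longest))
  invisible(x)
}

#' Generate contigs by weight-consuming traversal
#'
#' Starting from each start vertex, the walk appends one base per edge and
#' decrements that edge's weight (removing it at zero). At an unambiguous
#' vertex with two out-edges the edge with a simple return path is preferred
#' while it has weight left (this is what spools a tandem motif out the
#' correct number of times), the other edge afterwards. Arriving at an
#' ambiguous vertex ends the contig; new contigs start from that vertex.
#' Ambiguity and return paths are classified once on the input graph, before
#' any weight is consumed. All tie-breaks are lexicographic, so identical
#' graphs give identical ordered contig sets.
#'
#' @param g a balanced `dbg` graph.
#' @param max_return_depth bound on return-path length, see
#'   [simple_return_path()].
#' @return an [assembly_result()]. Attribute `leftover` reports any
#'   positive-weight edges remaining after the sweep limit.
#' @export
generate_contigs <- function(g, max_return_depth = 1000L) {
  if (n_edges(g) == 0) return(assembly_result(character()))
  nv <- n_vertices(g)
  od <- out_deg(g); id <- in_deg(g)
  oa <- out_adj(g); ia <- in_adj(g)
  # static classification on the full graph
  rp <- rep(NA, n_edges(g))
  need_rp <- unique(c(unlist(oa[which(od == 2)], use.names = FALSE),
                      unlist(ia[which(id == 2)], use.names = FALSE)))
  for (e in need_rp) rp[e] <- return_path_static(g, e, oa, od, id, max_return_depth)
  amb <- logical(nv)
  for (v in seq_len(nv)) {
    a_out <- if (od[v] >= 3) TRUE else if (od[v] == 2) sum(rp[oa[[v]]]) != 1 else FALSE
    a_in <- if (id[v] >= 3) TRUE else if (id[v] == 2) sum(rp[ia[[v]]]) != 1 else FALSE
    amb[v] <- a_out || a_in
  }
  pref <- rep(NA_integer_, nv)  # preferred (return-path) out-edge
  for (v in which(od == 2 & !amb)) {
    es <- oa[[v]]
    pref[v] <- es[which(rp[es])[1]]
  }

  w <- g$weight
  last_char <- substr(g$labels, g$k - 1L, g$k - 1L)
  contigs <- character()
  queue <- integer(0)
  queued <- logical(nv)
  budget <- sum(w) + n_vertices(g) + 10L

  pos_out <- function(v) {
    es <- oa[[v]]
    es[w[es] > 0]
  }
  walk_from <- function(v0) {
    head_chars <- strsplit(g$labels[v0], "")[[1]]
    buf <- character(length(head_chars) + sum(w))  # preallocated upper bound
    buf[seq_along(head_chars)] <- head_chars
    pos <- length(head_chars)
    v <- v0
    repeat {
      es <- pos_out(v)
      if (length(es) == 0) break
      if (v != v0 && amb[v]) {
        if (!queued[v]) { queue <<- c(queue, v); queued[v] <<- TRUE }
        break
      }
      if (length(es) == 1) {
        e <- es
      } else if (!amb[v] && !is.na(pref[v])) {
        e <- if (w[pref[v]] > 0) pref[v] else es[es != pref[v]][1]
      } else {
        e <- es[1]  # lexicographically smallest target
      }
      w[e] <<- w[e] - 1
      pos <- pos + 1L
      buf[pos] <- last_char[g$to[e]]
      v <- g$to[e]
      budget <<- budget - 1L
      if (budget <= 0) break
    }
    paste(buf[seq_len(pos)], collapse = "")
  }

  seed_queue <- function() {
    # residual starts: in-degree-0 sources first, then ambiguous junctions,
    # then the cycle fallback
    rod <- vapply(seq_len(nv), function(v) length(pos_out(v)), 1L)
    rid <- tabulate(g$to[w > 0], nv)
    cand <- which(rid == 0 & rod > 0)
    if (length(cand) == 0) cand <- which(amb & rod > 0)
    if (length(cand) == 0) cand <- which(rod > 0)[1]
    cand
  }

  queue <- match(find_start_vertices(g), g$labels)
  queue <- queue[vapply(queue, function(v) length(pos_out(v)) > 0, TRUE)]
  queued[queue] <- TRUE
  repeat {
    if (length(queue) == 0) {
      if (!any(w > 0) || budget <= 0) break
      queue <- seed_queue()
      if (length(queue) == 0) break
      queued[queue] <- TRUE
    }
    v0 <- queue[1]; queue <- queue[-1]; queued[v0] <- FALSE
    while (length(pos_out(v0)) > 0 && budget > 0) {
      contigs <- c(contigs, walk_from(v0))
    }
  }
  res <- assembly_result(contigs)
  if (any(w > 0)) {
    attr(res, "leftover") <- graph_edges(g)[w > 0, , drop = FALSE]
    warning(sum(w > 0), " positive-weight edge(s) left after traversal sweep limit")
  }
  res
}
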