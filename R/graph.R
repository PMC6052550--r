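#' De Bruijn graph constructor
#'
#' Vertices are (k-1)-mers, edges are k-mers carrying an integer weight.
#' Vertices are kept sorted so vertex index order equals lexicographic order;
#' edges are sorted by (from, to), which makes every downstream tie-break
#' deterministic.
#'
#' @param k graph dimension.
#' @param from,to character vectors of (k-1)-mer labels.
#' @param weight numeric vector of edge weights.
#' @return object of class `dbg`.
#' @keywords internal
dbg_create <- function(k, from, to, weight) {
  stopifnot(length(from) == length(to), length(from) == length(weight))
  labels <- sort(unique(c(from, to)))
  fi <- match(from, labels)
  ti <- match(to, labels)
  o <- order(fi, ti)
  structure(list(k = as.integer(k), labels = labels,
                 from = fi[o], to = ti[o], weight = as.numeric(weight[o])),
            class = "dbg")
}

#' Build the weighted de Bruijn graph from a k-mer table
#'
#' One edge per distinct k-mer, with weight equal to its count; the vertex
#' set is all length-(k-1) prefixes and suffixes.
#'
#' @param table a `kmer_table` from [count_kmers()].
#' @return a `dbg` graph.
#' @export
build_graph <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  if (length(table$counts) == 0) stop("empty k-mer table")
  km <- names(table$counts)
  k <- table$k
  dbg_create(k, substr(km, 1L, k - 1L), substr(km, 2L, k),
             as.numeric(table$counts))
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k = %d, %d vertices, %d edges, total weight %g\n",
              x$k, length(x$labels), length(x$from), sum(x$weight)))
  invisible(x)
}

n_vertices <- function(g) length(g$labels)
n_edges <- function(g) length(g$from)
total_weight <- function(g) sum(g$weight)

out_deg <- function(g) tabulate(g$from, n_vertices(g))
in_deg <- function(g) tabulate(g$to, n_vertices(g))

# adjacency: list per vertex of edge indices (edges are (from,to)-sorted, so
# out lists are in lexicographic target order already)
out_adj <- function(g) split(seq_along(g$from), factor(g$from, seq_len(n_vertices(g))))
in_adj <- function(g) split(seq_along(g$to), factor(g$to, seq_len(n_vertices(g))))

# drop edges by index and prune isolated vertices
dbg_drop_edges <- function(g, idx) {
  if (length(idx) == 0) return(g)
  keep <- setdiff(seq_along(g$from), idx)
  dbg_create(g$k, g$labels[g$from[keep]], g$labels[g$to[keep]], g$weight[keep])
}

# replace weights (same edge set)
dbg_set_weights <- function(g, w) {
  stopifnot(length(w) == n_edges(g))
  g$weight <- as.numeric(w)
  g
}

#' Edge list of a graph as a data.frame
#'
#' @param g a `dbg` graph.
#' @return `data.frame` with columns `from`, `to`, `weight`.
#' @export
graph_edges <- function(g) {
  data.frame(from = g$labels[g$from], to = g$labels[g$to], weight = g$weight,
             stringsAsFactors = FALSE)
}

# find the edge index for an ordered label pair, 0 if absent
edge_index <- function(g, u, v) {
  ui <- match(u, g$labels); vi <- match(v, g$labels)
  if (is.na(ui) || is.na(vi)) return(0L)
  w <- which(g$from == ui & g$to == vi)
  if (length(w) == 0) 0L else w[1]
}

#' Remove edges below a weight cutoff
#'
#' Edges with weight strictly below `cutoff` are deleted and isolated
#' vertices pruned; `cutoff = 0` is the identity.
#'
#' @param g a `dbg` graph.
#' @param cutoff non-negative integer.
#' @return cleaned graph.
#' @export
remove_low_weight_edges <- function(g, cutoff) {
  if (cutoff < 0) stop("cutoff must be >= 0")
  dbg_drop_edges(g, which(g$weight < cutoff))
}

#' Remove tips (short dead-end paths)
#'
#' A tip is a maximal unbranched path of at most `max_tip_length` edges that
#' dead-ends (no outgoing edge at its last vertex, or no incoming at its
#' first) and hangs off a branch vertex. It is removed when its minimum edge
#' weight is below `weight_ratio` times the strongest competing edge at the
#' branch point. Iterates to a fixpoint.
#'
#' @param g a `dbg` graph.
#' @param max_tip_length maximum tip length in edges (default `2 * k`).
#' @param weight_ratio relative weight threshold (default 0.2).
#' @return cleaned graph.
#' @export
remove_tips <- function(g, max_tip_length = NULL, weight_ratio = 0.2) {
  if (is.null(max_tip_length)) max_tip_length <- 2L * g$k
  if (max_tip_length < 1) stop("max_tip_length must be >= 1")
  for (sweep in 1:100) {
    if (n_edges(g) == 0) break
    od <- out_deg(g); id <- in_deg(g)
    oa <- out_adj(g); ia <- in_adj(g)
    del <- integer(0)
    # dead-end tips: walk back from sinks to a branch vertex (out-degree > 1)
    for (t in which(od == 0 & id == 1)) {
      path <- integer(0); cur <- t
      repeat {
        e <- ia[[cur]]
        if (length(e) != 1) break
        path <- c(e, path)
        prev <- g$from[e]
        if (od[prev] > 1) {
          competing <- max(g$weight[setdiff(oa[[prev]], path[1])])
          if (length(path) <= max_tip_length &&
              min(g$weight[path]) < weight_ratio * competing) {
            del <- c(del, path)
          }
          break
        }
        if (id[prev] != 1 || od[prev] != 1) break
        cur <- prev
        if (length(path) > max_tip_length) break
      }
    }
    # dead-start tips: walk forward from sources to a merge vertex (in > 1)
    for (t in which(id == 0 & od == 1)) {
      path <- integer(0); cur <- t
      repeat {
        e <- oa[[cur]]
        if (length(e) != 1) break
        path <- c(path, e)
        nxt <- g$to[e]
        if (id[nxt] > 1) {
          competing <- max(g$weight[setdiff(ia[[nxt]], path[length(path)])])
          if (length(path) <= max_tip_length &&
              min(g$weight[path]) < weight_ratio * competing) {
            del <- c(del, path)
          }
          break
        }
        if (id[nxt] != 1 || od[nxt] != 1) break
        cur <- nxt
        if (length(path) > max_tip_length) break
      }
    }
    del <- unique(del)
    if (length(del) == 0) break
    g <- dbg_drop_edges(g, del)
  }
  g
}

# follow an unbranched chain starting with edge e; returns edge indices,
# interior vertex indices and the endpoint vertex
follow_chain <- function(g, e, id, od, oa, max_len) {
  edges <- e
  interior <- integer(0)
  cur <- g$to[e]
  while (id[cur] == 1 && od[cur] == 1 && length(edges) < max_len) {
    interior <- c(interior, cur)
    e2 <- oa[[cur]]
    edges <- c(edges, e2)
    cur <- g$to[e2]
  }
  list(edges = edges, interior = interior, end = cur)
}

#' Remove simple bubbles
#'
#' When two vertex-disjoint unbranched paths of at most `max_bubble_length`
#' edges connect the same ordered vertex pair, the path with the lower total
#' weight is deleted and its minimum edge weight added to every edge of the
#' survivor. Ties go to the lexicographically smaller path spelling. Nested
#' bubbles resolve through fixpoint iteration.
#'
#' @param g a `dbg` graph.
#' @param max_bubble_length maximum path length in edges (default `2 * k`).
#' @return cleaned graph.
#' @export
remove_bubbles <- function(g, max_bubble_length = NULL) {
  if (is.null(max_bubble_length)) max_bubble_length <- 2L * g$k
  if (max_bubble_length < 1) stop("max_bubble_length must be >= 1")
  for (sweep in 1:100) {
    if (n_edges(g) == 0) break
    od <- out_deg(g); id <- in_deg(g)
    oa <- out_adj(g)
    changed <- FALSE
    for (v in which(od >= 2)) {
      paths <- lapply(oa[[v]], follow_chain, g = g, id = id, od = od, oa = oa,
                      max_len = max_bubble_length)
      ends <- vapply(paths, function(p) p$end, 1L)
      for (ev in unique(ends[duplicated(ends)])) {
        if (ev == v) next  # loop back to source: not a bubble
        grp <- paths[ends == ev]
        if (length(grp) < 2) next
        # pairwise check the first two vertex-disjoint candidates
        for (a in 1:(length(grp) - 1)) for (b in (a + 1):length(grp)) {
          pa <- grp[[a]]; pb <- grp[[b]]
          if (length(intersect(pa$interior, pb$interior)) > 0) next
          wa <- sum(g$weight[pa$edges]); wb <- sum(g$weight[pb$edges])
          spell <- function(p) paste(g$labels[c(v, p$interior, ev)], collapse = ">")
          keep_a <- if (wa != wb) wa > wb else spell(pa) < spell(pb)
          survivor <- if (keep_a) pa else pb
          loser <- if (keep_a) pb else pa
          g$weight[survivor$edges] <- g$weight[survivor$edges] +
            min(g$weight[loser$edges])
          g <- dbg_drop_edges(g, loser$edges)
          changed <- TRUE
          break
        }
        if (changed) break
      }
      if (changed) break
    }
    if (!changed) break
  }
  g
}

#' Dump graph as a tab-separated edge list
#'
#' Lines are `<from>\t<to>\t<weight>`.
#'
#' @param g a `dbg` graph.
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  e <- graph_edges(g)
  writeLines(sprintf("%s\t%s\t%g", e$from, e$to, e$weight), path)
  invisible(NULL)
}

#' Dump graph as GFA v1
#'
#' Segments are vertices ((k-1)-mers); links carry the edge weight in an
#' `RC` tag for visualization.
#'
#' @param g a `dbg` graph.
#' @param path output path.
#' @export
write_gfa <- function(g, path) {
  segs <- sprintf("S\t%s\t%s", g$labels, g$labels)
  links <- sprintf("L\t%s\t+\t%s\t+\t%dM\tRC:i:%d",
                   g$labels[g$from], g$labels[g$to], g$k - 2L,
                   as.integer(round(g$weight)))
  writeLines(c("H\tVN:Z:1.0", segs, links), path)
  invisible(NULL)
}
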