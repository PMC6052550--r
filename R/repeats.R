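#' Vertex degree (weighted, signed)
#'
#' In this model the degree of a vertex is the sum of its in-edge weights
#' minus the sum of its out-edge weights; all interior vertices of a
#' correctly balanced repeat loop have degree zero.
#'
#' @param g a `dbg` graph.
#' @param v vertex label (character) or index.
#' @return signed numeric degree.
#' @export
vertex_degree <- function(g, v) {
  if (is.character(v)) {
    vi <- match(v, g$labels)
    if (is.na(vi)) stop("unknown vertex: ", v)
  } else {
    vi <- as.integer(v)
    if (vi < 1 || vi > n_vertices(g)) stop("unknown vertex index: ", v)
  }
  sum(g$weight[g$to == vi]) - sum(g$weight[g$from == vi])
}

#' Detect tandem-repeat loops
#'
#' A tandem repeat appears as a cycle attached to the rest of the graph by a
#' single external in-edge and a single external out-edge: exactly one cycle
#' vertex (the entry) has two in-edges and one out-edge, exactly one (the
#' exit) has one in-edge and two out-edges, and every other cycle vertex has
#' one in-edge and one out-edge. Cycles violating this pattern (e.g. two
#' external entries) are not reported.
#'
#' Branch walks are bounded at `max_branch_edges` (default 1000), so the
#' genome-scale cycle of a circular genome is never mistaken for a repeat
#' loop branch.
#'
#' @param g a cleaned, normalized `dbg` graph.
#' @param max_branch_edges bound on branch length in edges.
#' @return list of `loop_structure` objects, each with `entry`/`exit` vertex
#'   labels, `body_edges`/`back_edges` (edge indices of the entry-to-exit and
#'   exit-to-entry branches), interior vertex indices, and the external
#'   in/out edge indices.
#' @export
detect_tandem_loops <- function(g, max_branch_edges = 1000L) {
  if (n_edges(g) == 0) return(list())
  od <- out_deg(g); id <- in_deg(g)
  oa <- out_adj(g)
  guard <- min(n_edges(g) + 2L, max_branch_edges)
  loops <- list()
  for (entry in which(id == 2 & od == 1)) {
    # body: follow the unique out-edge through 1-in/1-out vertices
    e <- oa[[entry]]
    body_edges <- e; body_int <- integer(0)
    cur <- g$to[e]; steps <- 0L; ok_exit <- FALSE
    while (steps < guard) {
      steps <- steps + 1L
      if (cur == entry) break                    # cycle with no exit vertex
      if (id[cur] == 1 && od[cur] == 2) { ok_exit <- TRUE; break }
      if (id[cur] != 1 || od[cur] != 1) break
      body_int <- c(body_int, cur)
      e <- oa[[cur]]
      body_edges <- c(body_edges, e)
      cur <- g$to[e]
    }
    if (!ok_exit) next
    exit <- cur
    # back branch: one of exit's two out-edges must chain back to the entry
    found <- FALSE
    for (e2 in oa[[exit]]) {
      back_edges <- e2; back_int <- integer(0)
      cur2 <- g$to[e2]; steps <- 0L
      while (steps < guard) {
        steps <- steps + 1L
        if (cur2 == entry) { found <- TRUE; break }
        if (id[cur2] != 1 || od[cur2] != 1 || cur2 == exit) break
        back_int <- c(back_int, cur2)
        e3 <- oa[[cur2]]
        back_edges <- c(back_edges, e3)
        cur2 <- g$to[e3]
      }
      if (found) break
    }
    if (!found) next
    if (length(intersect(body_int, back_int)) > 0) next
    ext_in <- setdiff(which(g$to == entry), back_edges[length(back_edges)])
    ext_out <- setdiff(oa[[exit]], back_edges[1])
    if (length(ext_in) != 1 || length(ext_out) != 1) next
    loops[[length(loops) + 1L]] <- structure(
      list(entry = g$labels[entry], exit = g$labels[exit],
           entry_idx = entry, exit_idx = exit,
           body_edges = body_edges, back_edges = back_edges,
           body_interior = body_int, back_interior = back_int,
           ext_in = ext_in, ext_out = ext_out),
      class = "loop_structure")
  }
  loops
}

#' @export
print.loop_structure <- function(x, ...) {
  cat(sprintf("tandem loop: entry %s, exit %s; body %d edge(s), back %d edge(s)\n",
              x$entry, x$exit, length(x$body_edges), length(x$back_edges)))
  invisible(x)
}

#' Equalize edge weights along a branch
#'
#' Every edge of the (unbranched) path is set to the rounded (half-up)
#' median of the branch's weights, making the branch weight-uniform while
#' staying robust to a single deviant edge.
#'
#' @param g a `dbg` graph.
#' @param branch integer vector of edge indices forming an unbranched path.
#' @return graph with updated weights.
#' @export
equalize_branch_weights <- function(g, branch) {
  if (length(branch) == 0) return(g)
  g$weight[branch] <- round_half_up(median(g$weight[branch]))
  g
}

#' Balance a tandem loop so that every loop vertex has degree zero
#'
#' The branch with more edges keeps its (uniform) weight; the other branch
#' receives the unique uniform weight that zeroes the degree of the entry and
#' exit vertices given the external in/out edge weights. When no consistent
#' non-negative solution exists (external weights differ, or the solution is
#' negative) the loop is left unchanged and a diagnostic is attached.
#'
#' @param g a `dbg` graph with weight-uniform loop branches.
#' @param loop a `loop_structure` from [detect_tandem_loops()].
#' @return graph (attribute `diagnostic` carries a message on failure).
#' @export
balance_loop <- function(g, loop) {
  w_body <- median(g$weight[loop$body_edges])
  w_back <- median(g$weight[loop$back_edges])
  w_in <- g$weight[loop$ext_in]
  w_out <- g$weight[loop$ext_out]
  fail <- function(msg) {
    attr(g, "diagnostic") <- sprintf("loop %s->%s not balanced: %s",
                                     loop$entry, loop$exit, msg)
    g
  }
  if (w_in != w_out) {
    return(fail(sprintf("external in/out weights differ (%g vs %g)", w_in, w_out)))
  }
  # entry balance: w_in + w_back = w_body; ties adjust the back branch, which
  # carries the m-1 return traversals
  if (length(loop$body_edges) >= length(loop$back_edges)) {
    new_back <- w_body - w_in
    if (new_back < 0) return(fail("negative back-branch weight"))
    g$weight[loop$back_edges] <- new_back
  } else {
    g$weight[loop$body_edges] <- w_back + w_in
  }
  attr(g, "diagnostic") <- NULL
  g
}

#' Detect and balance all tandem loops
#'
#' Applies branch equalization followed by balancing to every detected loop
#' and iterates until no loop changes (at most 100 sweeps). Edges driven to
#' weight zero are removed between sweeps. Non-loop edges are never touched.
#'
#' @param g a normalized `dbg` graph.
#' @return graph with balanced loops; attribute `loop_report` holds a
#'   per-loop diagnostic table (entry, exit, branch lengths, pre/post
#'   weights).
#' @export
resolve_all <- function(g) {
  report <- list()
  for (sweep in 1:100) {
    loops <- detect_tandem_loops(g)
    if (length(loops) == 0) break
    changed <- FALSE
    for (loop in loops) {
      pre_body <- median(g$weight[loop$body_edges])
      pre_back <- median(g$weight[loop$back_edges])
      w0 <- g$weight
      g <- equalize_branch_weights(g, loop$body_edges)
      g <- equalize_branch_weights(g, loop$back_edges)
      g <- balance_loop(g, loop)
      diag <- attr(g, "diagnostic")
      report[[length(report) + 1L]] <- data.frame(
        entry = loop$entry, exit = loop$exit,
        body_len = length(loop$body_edges), back_len = length(loop$back_edges),
        body_pre = pre_body, back_pre = pre_back,
        body_post = median(g$weight[loop$body_edges]),
        back_post = median(g$weight[loop$back_edges]),
        note = if (is.null(diag)) "" else diag,
        stringsAsFactors = FALSE)
      if (!identical(w0, g$weight)) changed <- TRUE
    }
    zero <- which(g$weight == 0)
    if (length(zero) > 0) g <- dbg_drop_edges(g, zero)
    if (!changed) break
    if (sweep == 100) warning("loop balancing did not converge in 100 sweeps")
  }
  attr(g, "loop_report") <- if (length(report)) do.call(rbind, report) else NULL
  g
}
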