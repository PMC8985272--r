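# Minimum cycle basis of an undirected simple graph, Horton-style:
# candidate cycles are built from per-vertex BFS shortest-path trees
# (cycle(v, e) = path(v,x) + path(v,y) + edge(x,y)), sorted by length with a
# lexicographic tie-break, and greedily selected for linear independence
# over GF(2) on edge-incidence vectors. Candidates longer than `max_len`
# are skipped; short basis cycles are unaffected by the cap because greedy
# selection fills the basis shortest-first, so only basis elements longer
# than the cap (which the caller would not report anyway) can be missed.
# Self-loops and multi-edges must be removed by the caller.
min_cycle_basis <- function(g, max_len = 100L) {
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (m == 0 || n == 0) return(list())
  comp <- igraph::components(g)
  dim_space <- m - n + comp$no
  if (dim_space <= 0) return(list())
  el <- igraph::as_edgelist(g, names = FALSE)
  # hop-count metric: the edge weight attribute (genome support) must not
  # influence path lengths
  D <- igraph::distances(g, weights = NA)
  cand_len <- integer(0); cand_key <- character(0); cand_nodes <- list()
  cand_edges <- list(); seen <- new.env(hash = TRUE)
  vnames <- igraph::V(g)$name
  for (v in seq_len(n)) {
    len_v <- D[v, el[, 1]] + D[v, el[, 2]] + 1
    ok <- which(is.finite(len_v) & len_v >= 3 & len_v <= max_len)
    if (!length(ok)) next
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = v, output = "vpath", weights = NA)$vpath)
    for (ei in ok) {
      x <- el[ei, 1]; y <- el[ei, 2]
      px <- as.integer(sp[[x]]); py <- as.integer(sp[[y]])
      if (length(px) != D[v, x] + 1 || length(py) != D[v, y] + 1) next
      # paths must share only v, else the walk is not a simple cycle
      if (length(intersect(px[-1], py[-1]))) next
      nodes <- c(px, rev(py[-1]))
      key <- paste(sort(nodes), collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      eidx <- cycle_edge_ids(g, nodes)
      if (is.null(eidx)) next
      cand_len <- c(cand_len, length(nodes))
      cand_key <- c(cand_key, key)
      cand_nodes[[length(cand_nodes) + 1L]] <- nodes
      cand_edges[[length(cand_edges) + 1L]] <- eidx
    }
  }
  if (!length(cand_len)) return(list())
  ord <- order(cand_len, cand_key)
  basis <- list(); reduced <- list(); pivots <- integer(0)
  for (i in ord) {
    vec <- logical(m); vec[cand_edges[[i]]] <- TRUE
    # reduce against selected rows (GF(2) elimination)
    for (r in seq_along(reduced)) {
      if (vec[pivots[r]]) vec <- xor(vec, reduced[[r]])
    }
    if (any(vec)) {
      basis[[length(basis) + 1L]] <- canonical_cycle(vnames[cand_nodes[[i]]])
      reduced[[length(reduced) + 1L]] <- vec
      pivots <- c(pivots, which(vec)[1])
      if (length(basis) == dim_space) break
    }
  }
  basis
}

# Edge ids of the closed walk through `nodes` (integer vertex ids);
# NULL if any consecutive pair is not an edge.
cycle_edge_ids <- function(g, nodes) {
  pairs <- rbind(cbind(nodes[-length(nodes)], nodes[-1]),
                 c(nodes[length(nodes)], nodes[1]))
  ids <- igraph::get_edge_ids(g, t(pairs), error = FALSE)
  if (any(ids == 0)) return(NULL)
  ids
}

# Canonical rotation of a cycle's node names: start at the lexicographically
# smallest node and traverse toward its smaller neighbour.
canonical_cycle <- function(nodes) {
  k <- length(nodes)
  s <- which.min(rank(nodes, ties.method = "first"))
  rot <- c(nodes[s:k], nodes[seq_len(s - 1)])
  if (k >= 3 && rot[2] > rot[k]) rot <- c(rot[1], rev(rot[-1]))
  rot
}
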