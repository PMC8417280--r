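# Candidate transcript enumeration: all source-to-sink paths of a
# splicing graph, with iterative pruning of the weakest edge until the
# path count is bounded.

#' Enumerate candidate transcripts from a splicing graph
#'
#' All source-to-sink paths (sources: in-degree 0; sinks: out-degree 0)
#' are enumerated. While the path count exceeds `max_candidates`, the
#' edge with the minimum support count is removed (ties broken
#' lexicographically by `(from, to)`) and paths are re-enumerated; an
#' edge is skipped by the pruner when its removal would leave a node with
#' no remaining in- or out-edge where it previously had one (orphaning).
#'
#' @param graph A `splicing_graph`.
#' @param max_candidates Upper bound on the candidate count (default 100).
#' @param frag_mu Mean fragment length used for effective lengths
#'   (default 250).
#' @return A list of class `candidate_set`: `candidates` (list with
#'   `path`, `sequence`, `effective_length` per candidate), `pruned`
#'   (data frame log of removed edges), `graph_id`.
#' @export
enumerate_candidates <- function(graph, max_candidates = 100L,
                                 frag_mu = 250) {
  stopifnot(max_candidates >= 1L)
  nodes <- names(graph$nodes)
  edges <- graph$edges[, c("from", "to", "support")]
  cyc <- find_cycle(nodes, edges)
  if (!is.null(cyc)) {
    stop("splicing graph ", graph$graph_id, " contains a directed cycle ",
         "through nodes: ", paste(cyc, collapse = " -> "),
         "; paths are undefined on cyclic graphs")
  }
  sources <- lex_sort(setdiff(nodes, edges$to))  # fixed at the input graph
  pruned <- edges[0, , drop = FALSE]
  repeat {
    np <- count_paths(nodes, edges, sources)
    if (np <= max_candidates) break
    cand <- edges[lex_order(edges$support, edges$from, edges$to), ,
                  drop = FALSE]
    removed <- FALSE
    for (i in seq_len(nrow(cand))) {
      e <- cand[i, ]
      rest <- edges[!(edges$from == e$from & edges$to == e$to), ,
                    drop = FALSE]
      if (orphans_node(rest, e)) next
      pruned <- rbind(pruned, e)
      edges <- rest
      removed <- TRUE
      break
    }
    if (!removed) break  # every remaining edge is load-bearing
  }
  paths <- enumerate_paths(nodes, edges, sources)
  cands <- lapply(paths, function(p) {
    seq <- spell_path(graph, p)
    list(path = p, sequence = seq,
         effective_length = max(nchar(seq) - frag_mu + 1, 1))
  })
  structure(list(candidates = cands, pruned = pruned,
                 graph_id = graph$graph_id, k = graph$k),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", length(x$candidates), "candidates for graph",
      x$graph_id, "|", nrow(x$pruned), "edges pruned\n")
  invisible(x)
}

# Removal of edge e is disallowed when the tail node would lose its last
# out-edge: paths reaching it would then end prematurely, truncating a
# candidate. Losing the last in-edge is allowed — the head (and anything
# reachable only through it) simply becomes unreachable from the fixed
# sources and drops out of the enumeration, which is how pruning reduces
# the path count.
orphans_node <- function(rest, e) {
  sum(rest$from == e$from) == 0L
}

# Spell the sequence of a node path: concatenation minus the k-1 overlap
# at each junction.
spell_path <- function(graph, path) {
  k <- graph$k
  seqs <- graph$nodes[path]
  if (length(seqs) == 1L) return(unname(seqs))
  paste0(seqs[1], paste(substring(seqs[-1], k), collapse = ""))
}

adjacency <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
  }
  lapply(adj, function(v) if (is.null(v)) character(0) else lex_sort(v))
}

find_cycle <- function(nodes, edges) {
  adj <- adjacency(nodes, edges)
  colour <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  stack <- character(0)
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return()
    colour[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (colour[w] == 1L) {
        cyc <<- c(stack[which(stack == w)[1]:length(stack)], w)
        return()
      }
      if (colour[w] == 0L) visit(w)
      if (!is.null(cyc)) return()
    }
    colour[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in nodes) if (colour[v] == 0L) visit(v)
  cyc
}

# Number of paths from the given sources to current sinks, by dynamic
# programming in topological order (graph must be acyclic). Capped to
# avoid overflow.
count_paths <- function(nodes, edges, sources = NULL, cap = 1e9) {
  if (length(nodes) == 0L) return(0)
  if (is.null(sources)) sources <- lex_sort(setdiff(nodes, edges$to))
  adj <- adjacency(nodes, edges)
  indeg <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  order_ <- character(0)
  queue <- lex_sort(names(indeg)[indeg == 0L])
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    order_ <- c(order_, v)
    for (w in adj[[v]]) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- c(queue, w)
    }
  }
  npaths <- stats::setNames(rep(0, length(nodes)), nodes)
  for (v in rev(order_)) {
    if (length(adj[[v]]) == 0L) {
      npaths[v] <- 1
    } else {
      npaths[v] <- min(sum(npaths[adj[[v]]]), cap)
    }
  }
  sum(npaths[sources])
}

# Depth-first enumeration of all paths from the given sources to current
# sinks, lexicographically ordered.
enumerate_paths <- function(nodes, edges, sources = NULL) {
  if (length(nodes) == 0L) return(list())
  if (is.null(sources)) sources <- lex_sort(setdiff(nodes, edges$to))
  adj <- adjacency(nodes, edges)
  paths <- list()
  walk <- function(v, acc) {
    nxt <- adj[[v]]
    if (length(nxt) == 0L) {
      paths[[length(paths) + 1L]] <<- c(acc, v)
      return()
    }
    for (w in nxt) walk(w, c(acc, v))
  }
  for (s in sources) walk(s, character(0))
  paths
}
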