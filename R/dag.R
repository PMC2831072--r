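#' Directed acyclic graph over genes
#'
#' A `bn_dag` stores a node set and a logical adjacency matrix where
#' `adj[i, j]` is `TRUE` when gene `i` is a parent of gene `j`.  The
#' constructor validates acyclicity, rejects self-loops and duplicate nodes.
#'
#' @param nodes character vector of unique gene identifiers.
#' @param edges optional two-column matrix or data frame of directed edges
#'   (from, to); may be `NULL` for an empty graph.
#' @return an object of class `bn_dag`.
#' @examples
#' d <- bn_dag(c("sodA", "katG"), data.frame(from = "sodA", to = "katG"))
#' dag_edges(d)
#' @export
bn_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) bnx_stop("a DAG needs at least one node")
  if (anyDuplicated(nodes)) {
    bnx_stop("duplicate node id: ", nodes[duplicated(nodes)][1L])
  }
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges[, 1:2, drop = FALSE])
    storage.mode(edges) <- "character"
    unknown <- setdiff(c(edges), nodes)
    if (length(unknown)) bnx_stop("edge references unknown node: ", unknown[1L])
    if (any(edges[, 1L] == edges[, 2L])) {
      bnx_stop("self-loop on node: ", edges[edges[, 1L] == edges[, 2L], 1L][1L])
    }
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    if (anyDuplicated(key)) bnx_stop("duplicate edge in edge list")
    adj[cbind(edges[, 1L], edges[, 2L])] <- TRUE
  }
  if (!is_acyclic_adj(adj)) bnx_stop("edge list contains a cycle")
  structure(list(nodes = nodes, adj = adj), class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<bn_dag> %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  if (nrow(e)) {
    cat(paste0("  ", utils::head(paste(e$from, "->", e$to), 20L),
               collapse = "\n"), "\n")
    if (nrow(e) > 20L) cat(sprintf("  ... %d more\n", nrow(e) - 20L))
  }
  invisible(x)
}

## Kahn topological check on a logical adjacency matrix.
is_acyclic_adj <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  alive <- rep(TRUE, n)
  repeat {
    src <- which(alive & indeg == 0)
    if (!length(src)) break
    alive[src] <- FALSE
    if (length(src) == 1L) {
      indeg <- indeg - adj[src, ]
    } else {
      indeg <- indeg - colSums(adj[src, , drop = FALSE])
    }
  }
  !any(alive)
}

## Topological order of node indices.
topo_order_adj <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  alive <- rep(TRUE, n)
  ord <- integer(0)
  while (any(alive)) {
    src <- which(alive & indeg == 0)
    if (!length(src)) bnx_stop("graph contains a cycle")
    u <- src[1L]
    ord <- c(ord, u)
    alive[u] <- FALSE
    indeg <- indeg - adj[u, ]
    indeg[!alive] <- 0
  }
  ord
}

## TRUE when a path from -> to exists (length >= 1).
reaches_adj <- function(adj, from, to) {
  seen <- rep(FALSE, nrow(adj))
  stack <- which(adj[from, ])
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u == to) return(TRUE)
    if (!seen[u]) {
      seen[u] <- TRUE
      stack <- c(stack, which(adj[u, ] & !seen))
    }
  }
  FALSE
}

#' Edges of a DAG
#' @param dag a [bn_dag()].
#' @return data frame with columns `from`, `to` (alphabetical order).
#' @export
dag_edges <- function(dag) {
  idx <- which(dag$adj, arr.ind = TRUE)
  out <- data.frame(from = dag$nodes[idx[, 1L]], to = dag$nodes[idx[, 2L]],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' @rdname dag_edges
#' @param node a node id.
#' @export
dag_parents <- function(dag, node) {
  stopifnot(node %in% dag$nodes)
  dag$nodes[dag$adj[, node]]
}

#' @rdname dag_edges
#' @export
dag_children <- function(dag, node) {
  stopifnot(node %in% dag$nodes)
  dag$nodes[dag$adj[node, ]]
}

## Canonical identity string (node set is fixed by context).
dag_key <- function(dag) {
  e <- dag_edges(dag)
  paste(paste(e$from, e$to, sep = ">"), collapse = ";")
}

#' Enumerate the legal single-edge moves from a DAG
#'
#' Moves are edge additions, deletions, and reversals that keep the graph
#' acyclic and respect the in-degree cap.
#'
#' @param dag a [bn_dag()].
#' @param max_parents in-degree cap.
#' @return data frame with columns `type` (`"add"`, `"delete"`, `"reverse"`),
#'   `from`, `to`.
#' @export
enumerate_moves <- function(dag, max_parents = 5L) {
  adj <- dag$adj
  nodes <- dag$nodes
  n <- length(nodes)
  npar <- colSums(adj)
  type <- character(0); from <- integer(0); to <- integer(0)
  for (j in seq_len(n)) {
    if (npar[j] < max_parents) {
      for (i in seq_len(n)) {
        if (i != j && !adj[i, j] && !adj[j, i] &&
            !reaches_adj(adj, j, i)) {
          type <- c(type, "add"); from <- c(from, i); to <- c(to, j)
        }
      }
    }
  }
  e <- which(adj, arr.ind = TRUE)
  if (nrow(e)) {
    type <- c(type, rep("delete", nrow(e)))
    from <- c(from, e[, 1L]); to <- c(to, e[, 2L])
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1L]; j <- e[r, 2L]
      if (npar[i] < max_parents) {
        adj2 <- adj; adj2[i, j] <- FALSE
        if (!reaches_adj(adj2, i, j)) {
          type <- c(type, "reverse"); from <- c(from, i); to <- c(to, j)
        }
      }
    }
  }
  data.frame(type = type, from = nodes[from], to = nodes[to],
             stringsAsFactors = FALSE)
}

#' Propose a random neighbor of a DAG
#'
#' Picks uniformly among the currently legal add/delete/reverse moves; when
#' no legal move exists the DAG is returned unchanged.
#'
#' @inheritParams enumerate_moves
#' @return a [bn_dag()] differing from `dag` by at most one move.
#' @export
propose_move <- function(dag, max_parents = 5L) {
  mv <- enumerate_moves(dag, max_parents)
  if (!nrow(mv)) return(dag)
  pick <- mv[sample.int(nrow(mv), 1L), ]
  apply_move(dag, pick$type, pick$from, pick$to)
}

apply_move <- function(dag, type, from, to) {
  adj <- dag$adj
  switch(type,
    add = { adj[from, to] <- TRUE },
    delete = { adj[from, to] <- FALSE },
    reverse = { adj[from, to] <- FALSE; adj[to, from] <- TRUE },
    bnx_stop("unknown move type: ", type))
  structure(list(nodes = dag$nodes, adj = adj), class = "bn_dag")
}

#' Random DAG via a random topological order
#'
#' Draws a uniform node permutation and includes each forward edge
#' independently with probability `edge_prob`, truncating parent sets that
#' exceed `max_parents` by uniform subsampling.  Acyclic by construction.
#'
#' @param nodes node ids.
#' @param edge_prob probability of each forward edge.
#' @param max_parents in-degree cap (`Inf` for none).
#' @return a [bn_dag()].
#' @export
random_dag <- function(nodes, edge_prob = 0.25, max_parents = 5L) {
  stopifnot(edge_prob >= 0, edge_prob <= 1)
  n <- length(nodes)
  ord <- sample.int(n)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (n > 1L && edge_prob > 0) {
    for (pos in 2:n) {
      j <- ord[pos]
      cand <- ord[seq_len(pos - 1L)]
      pick <- cand[runif(length(cand)) < edge_prob]
      if (length(pick) > max_parents) {
        pick <- pick[sample.int(length(pick), max_parents)]
      }
      adj[pick, j] <- TRUE
    }
  }
  structure(list(nodes = as.character(nodes), adj = adj), class = "bn_dag")
}
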