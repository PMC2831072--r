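#' Networks sharing the top score
#'
#' @param pool a `network_pool` from [multi_restart_search()].
#' @return list of [scored_network()]s whose log score is within
#'   `pool$score_tolerance` of the pool maximum.
#' @export
top_group <- function(pool) {
  stopifnot(inherits(pool, "network_pool"))
  if (!length(pool$networks)) bnx_stop("pool is empty")
  sc <- pool_scores(pool)
  pool$networks[sc >= max(sc) - pool$score_tolerance]
}

#' Consensus of equally top-scoring networks
#'
#' An edge `a -> b` is directed in the consensus iff it appears with that
#' orientation in every network of the group.  A skeleton `a -- b` is
#' undirected iff every network contains the edge in one orientation or
#' the other and both orientations occur somewhere across the group (a
#' single DAG cannot hold both at once).  Skeletons missing from any group
#' network are excluded.  Support counts by orientation are reported for
#' every skeleton present in at least one network.
#'
#' @param group nonempty list of [scored_network()]s on a common node set.
#' @return object of class `consensus_network`: fields `nodes`, `directed`
#'   (data frame from/to), `undirected` (data frame a/b), `support` (data
#'   frame a, b, n_forward, n_backward, n_total).
#' @export
build_consensus <- function(group) {
  if (!length(group)) bnx_stop("consensus group is empty")
  nodes <- group[[1L]]$dag$nodes
  for (sn in group) {
    if (!setequal(sn$dag$nodes, nodes)) {
      bnx_stop("networks in the group have mixed node sets")
    }
  }
  k <- length(group)
  fwd <- list()
  for (sn in group) {
    e <- dag_edges(sn$dag)
    if (!nrow(e)) next
    a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
    sk <- paste(a, b, sep = "\r")
    isfwd <- e$from == a
    for (r in seq_len(nrow(e))) {
      cur <- fwd[[sk[r]]] %||% c(0L, 0L)
      cur[if (isfwd[r]) 1L else 2L] <- cur[if (isfwd[r]) 1L else 2L] + 1L
      fwd[[sk[r]]] <- cur
    }
  }
  sk_keys <- names(fwd)
  ab <- if (length(sk_keys)) do.call(rbind, strsplit(sk_keys, "\r", fixed = TRUE))
        else matrix(character(0), 0, 2)
  n_f <- vapply(fwd, `[`, integer(1), 1L)
  n_b <- vapply(fwd, `[`, integer(1), 2L)
  n_t <- n_f + n_b
  support <- data.frame(a = ab[, 1L], b = ab[, 2L],
                        n_forward = as.integer(n_f),
                        n_backward = as.integer(n_b),
                        n_total = as.integer(n_t),
                        stringsAsFactors = FALSE, row.names = NULL)
  unanimous <- n_t == k
  dir_f <- unanimous & n_f == k
  dir_b <- unanimous & n_b == k
  undir <- unanimous & n_f > 0L & n_b > 0L
  directed <- data.frame(
    from = c(ab[dir_f, 1L], ab[dir_b, 2L]),
    to = c(ab[dir_f, 2L], ab[dir_b, 1L]),
    stringsAsFactors = FALSE)
  directed <- directed[order(directed$from, directed$to), , drop = FALSE]
  undirected <- data.frame(a = ab[undir, 1L], b = ab[undir, 2L],
                           stringsAsFactors = FALSE)
  structure(list(nodes = nodes, directed = directed,
                 undirected = undirected, support = support,
                 group_size = k),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d nodes, %d directed + %d undirected edges (group of %d)\n",
              length(x$nodes), nrow(x$directed), nrow(x$undirected),
              x$group_size))
  invisible(x)
}

#' Convert a consensus network to an edge list
#' @param consensus a `consensus_network`.
#' @return a [network_edge_list()].
#' @export
consensus_edge_list <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_network"))
  d <- consensus$directed
  u <- consensus$undirected
  network_edge_list(rbind(
    if (nrow(d)) data.frame(d$from, d$to, "directed",
                            stringsAsFactors = FALSE) else NULL,
    if (nrow(u)) data.frame(u$a, u$b, "undirected",
                            stringsAsFactors = FALSE) else NULL))
}

#' Overlap between a consensus network and a reference edge list
#'
#' Reports the fraction of consensus edges whose skeleton (unordered pair)
#' appears in the reference, and separately the fraction whose orientation
#' is compatible: a directed consensus edge needs the same direction (or
#' an undirected reference edge on that skeleton); an undirected consensus
#' edge matches a reference edge in either orientation.
#'
#' @param consensus a `consensus_network`.
#' @param reference a [network_edge_list()] of curated edges.
#' @return list with `n_edges`, `skeleton_fraction`, `orientation_fraction`
#'   and a per-edge data frame `detail`.
#' @export
compare_to_reference <- function(consensus, reference) {
  stopifnot(inherits(consensus, "consensus_network"),
            inherits(reference, "network_edge_list"))
  re <- reference$edges
  ref_skel <- unique(paste(pmin(re$source, re$target),
                           pmax(re$source, re$target), sep = "\r"))
  ref_dir <- unique(c(paste(re$source, re$target, sep = "\r")[re$orientation == "directed"]))
  ref_undir <- unique(paste(pmin(re$source, re$target),
                            pmax(re$source, re$target),
                            sep = "\r")[re$orientation == "undirected"])
  d <- consensus$directed
  u <- consensus$undirected
  detail <- rbind(
    if (nrow(d)) data.frame(edge = paste(d$from, "->", d$to),
                            skel = paste(pmin(d$from, d$to),
                                         pmax(d$from, d$to), sep = "\r"),
                            dirkey = paste(d$from, d$to, sep = "\r"),
                            type = "directed", stringsAsFactors = FALSE)
    else NULL,
    if (nrow(u)) data.frame(edge = paste(u$a, "--", u$b),
                            skel = paste(pmin(u$a, u$b), pmax(u$a, u$b),
                                         sep = "\r"),
                            dirkey = NA_character_,
                            type = "undirected", stringsAsFactors = FALSE)
    else NULL)
  if (is.null(detail) || !nrow(detail)) {
    return(list(n_edges = 0L, skeleton_fraction = NA_real_,
                orientation_fraction = NA_real_,
                detail = data.frame()))
  }
  detail$skeleton_match <- detail$skel %in% ref_skel
  detail$orientation_match <- ifelse(
    detail$type == "directed",
    detail$dirkey %in% ref_dir | detail$skel %in% ref_undir,
    detail$skel %in% ref_skel)
  list(n_edges = nrow(detail),
       skeleton_fraction = mean(detail$skeleton_match),
       orientation_fraction = mean(detail$orientation_match),
       detail = detail[, c("edge", "type", "skeleton_match",
                           "orientation_match")])
}
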