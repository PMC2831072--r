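#' Expansion (single-added-gene) configuration
#'
#' Extends [search_config()] with the expansion-specific budgets: the
#' screen budget per candidate gene, and the top-n deeper rerank with
#' replicate searches.  The compendium-scale analysis screened each of
#' 4,178 candidates with 1e7-proposal searches and reran the top 200 with
#' 150 replicates of 2.5e7 proposals; desk-scale defaults keep the same
#' algorithm at tractable budgets.
#'
#' @param screen_networks_per_gene proposals per candidate in the screen.
#' @param rerank_top_n candidates re-examined in the rerank phase.
#' @param rerank_networks proposals per rerank replicate.
#' @param rerank_replicates independent replicate searches per reranked
#'   candidate (their maximum score is kept).
#' @param ... passed to [search_config()].
#' @return an `expansion_config` (also a `search_config`).
#' @export
expansion_config <- function(screen_networks_per_gene = 100000L,
                             rerank_top_n = 200L,
                             rerank_networks = screen_networks_per_gene,
                             rerank_replicates = 150L, ...) {
  cfg <- search_config(...)
  check_count(screen_networks_per_gene, "screen_networks_per_gene",
              zero_ok = TRUE)
  check_count(rerank_top_n, "rerank_top_n")
  check_count(rerank_networks, "rerank_networks", zero_ok = TRUE)
  check_count(rerank_replicates, "rerank_replicates")
  cfg$screen_networks_per_gene <- as.integer(screen_networks_per_gene)
  cfg$rerank_top_n <- as.integer(rerank_top_n)
  cfg$rerank_networks <- as.integer(rerank_networks)
  cfg$rerank_replicates <- as.integer(rerank_replicates)
  class(cfg) <- c("expansion_config", "search_config")
  cfg
}

#' Seed a core network with one disconnected candidate
#'
#' @param core a [bn_dag()].
#' @param candidate gene id not already in the core.
#' @return a [bn_dag()] over the core nodes plus the candidate, with the
#'   core topology unchanged and the candidate isolated.
#' @export
seed_expanded_dag <- function(core, candidate) {
  stopifnot(inherits(core, "bn_dag"))
  if (candidate %in% core$nodes) {
    bnx_stop("candidate '", candidate, "' is already in the core network")
  }
  nodes <- c(core$nodes, candidate)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  adj[core$nodes, core$nodes] <- core$adj
  structure(list(nodes = nodes, adj = adj), class = "bn_dag")
}

#' Score one candidate gene added to the core
#'
#' Runs an annealing search on the data slice holding the core genes plus
#' the one candidate, starting from the core topology with the candidate
#' disconnected.  The core edges are a starting point only ("unfixed
#' structural prior"): every edge is mutable during the search.
#'
#' @param data a [discrete_matrix()] containing core genes and candidate.
#' @param core a [bn_dag()] of core genes.
#' @param candidate candidate gene id.
#' @param config an [expansion_config()].
#' @param seed integer seed for this evaluation (the screen derives it
#'   from the run seed and the candidate id).
#' @return the best [scored_network()] found.
#' @export
expand_one <- function(data, core, candidate, config = expansion_config(),
                       seed = NULL) {
  stopifnot(inherits(config, "expansion_config"))
  unknown <- setdiff(c(core$nodes, candidate), data$gene_ids)
  if (length(unknown)) bnx_stop("unknown gene id: ", unknown[1L])
  start <- seed_expanded_dag(core, candidate)
  cfg <- config
  cfg$networks_per_run <- config$screen_networks_per_gene
  cfg$keep_top <- 1L
  cfg$rng_seed <- seed
  anneal_run(data, start, cfg)[[1L]]
}

#' Rank candidate genes by single-gene network expansion
#'
#' Every candidate is evaluated independently with [expand_one()] on its
#' own RNG substream keyed by (seed, candidate id, replicate 1), so the
#' ranking does not depend on evaluation order.  Candidates are sorted by
#' best expanded log score (descending), ties broken lexicographically by
#' gene id.
#'
#' @param data a [discrete_matrix()].
#' @param core a [bn_dag()] of core genes.
#' @param candidates character vector of candidate gene ids, disjoint from
#'   the core.
#' @param config an [expansion_config()].
#' @return an `expansion_result`: `ranking` (data frame rank, gene,
#'   log_score), `networks` (named list of best [scored_network()]s) and
#'   `induced` (named list of the candidate's parent/child sets).
#' @export
bn_plus_one <- function(data, core, candidates,
                        config = expansion_config()) {
  stopifnot(inherits(config, "expansion_config"))
  candidates <- as.character(candidates)
  if (length(intersect(candidates, core$nodes))) {
    bnx_stop("candidates must be disjoint from the core genes")
  }
  if (anyDuplicated(candidates)) bnx_stop("duplicate candidate gene")
  base_seed <- config$rng_seed %||% sample.int(.Machine$integer.max, 1L)
  networks <- lapply(candidates, function(g) {
    expand_one(data, core, g, config,
               seed = derive_seed(base_seed, "bn+1", g, 1L))
  })
  names(networks) <- candidates
  finish_expansion(networks, core)
}

finish_expansion <- function(networks, core) {
  candidates <- names(networks)
  scores <- vapply(networks, `[[`, numeric(1), "log_score")
  ord <- order(-scores, candidates)
  ranking <- data.frame(rank = seq_along(ord), gene = candidates[ord],
                        log_score = scores[ord], row.names = NULL,
                        stringsAsFactors = FALSE)
  induced <- lapply(networks, function(sn) {
    g <- setdiff(sn$dag$nodes, core$nodes)
    induced_edges(sn, g)
  })
  structure(list(ranking = ranking, networks = networks[ranking$gene],
                 induced = induced[ranking$gene]),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf("<expansion_result> %d candidates\n", nrow(x$ranking)))
  print(utils::head(x$ranking, 10L))
  invisible(x)
}

#' Rerank the leading candidates with replicate searches
#'
#' For each of the `rerank_top_n` best candidates of a prior screen, runs
#' `rerank_replicates` independent searches (budget `rerank_networks`
#' each) and keeps the maximum score found across replicates (replicate 1
#' reuses the screen's RNG substream, so with one replicate at the screen
#' budget the screen is reproduced exactly).  Candidates outside the
#' rerank window keep their screen results; the full list is re-sorted.
#'
#' @param data a [discrete_matrix()].
#' @param core the core [bn_dag()].
#' @param prior_result an `expansion_result` from [bn_plus_one()].
#' @param config an [expansion_config()]; `rng_seed` must match the screen
#'   to reuse its substreams.
#' @return an `expansion_result`.
#' @export
rerank_top <- function(data, core, prior_result,
                       config = expansion_config()) {
  stopifnot(inherits(prior_result, "expansion_result"),
            inherits(config, "expansion_config"))
  if (!nrow(prior_result$ranking)) bnx_stop("prior result is empty")
  base_seed <- config$rng_seed %||% sample.int(.Machine$integer.max, 1L)
  top_n <- min(config$rerank_top_n, nrow(prior_result$ranking))
  leaders <- prior_result$ranking$gene[seq_len(top_n)]
  cfg <- config
  cfg$screen_networks_per_gene <- config$rerank_networks
  networks <- prior_result$networks
  for (g in leaders) {
    best <- NULL
    for (rep in seq_len(config$rerank_replicates)) {
      sn <- expand_one(data, core, g, cfg,
                       seed = derive_seed(base_seed, "bn+1", g, rep))
      if (is.null(best) || sn$log_score > best$log_score) best <- sn
    }
    networks[[g]] <- best
  }
  finish_expansion(networks, core)
}

#' Edges induced on the added candidate
#'
#' @param network a [scored_network()] (or [bn_dag()]).
#' @param candidate node id of the added gene.
#' @return list with `parents` and `children`: the candidate's parent and
#'   child node sets in the network.
#' @export
induced_edges <- function(network, candidate) {
  dag <- if (inherits(network, "scored_network")) network$dag else network
  stopifnot(inherits(dag, "bn_dag"))
  if (!candidate %in% dag$nodes) {
    bnx_stop("candidate '", candidate, "' is not a node of the network")
  }
  list(parents = dag_parents(dag, candidate),
       children = dag_children(dag, candidate))
}
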