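#' Search configuration
#'
#' Bundles every tunable of the annealing search.  `networks_per_run`
#' counts move proposals (visited candidate structures) per restart; the
#' compendium analysis this reimplements used 2.5e7 proposals per restart
#' over 4000 restarts, keeping the five best distinct networks per run —
#' desk-scale defaults are far smaller but the algorithm is identical.
#'
#' @param networks_per_run move proposals per restart.
#' @param restarts number of independent annealing runs.
#' @param keep_top best distinct networks retained per run.
#' @param max_parents in-degree cap.
#' @param initial_temperature annealing start temperature (log-score units).
#' @param cooling_factor geometric cooling multiplier per proposal, in (0,1).
#' @param reheat_after reset to `initial_temperature` after this many
#'   consecutive rejections.
#' @param start_density probability of each forward edge in random restart
#'   starts (0 = empty starts).
#' @param score_tolerance absolute log-score tolerance for "identical
#'   score" grouping.
#' @param rng_seed integer seed (`NULL` to use the current RNG state).
#' @param prior,ess structure score prior, see [log_family_score()].
#' @return a `search_config` list.
#' @export
search_config <- function(networks_per_run = 10000L, restarts = 1L,
                          keep_top = 5L, max_parents = 5L,
                          initial_temperature = 100, cooling_factor = 0.9999,
                          reheat_after = 500L, start_density = 0,
                          score_tolerance = 1e-6, rng_seed = NULL,
                          prior = c("ch", "bdeu"), ess = 1) {
  check_count(networks_per_run, "networks_per_run", zero_ok = TRUE)
  check_count(restarts, "restarts")
  check_count(keep_top, "keep_top")
  check_count(max_parents, "max_parents")
  check_count(reheat_after, "reheat_after", zero_ok = TRUE)
  if (!is.numeric(initial_temperature) || initial_temperature <= 0) {
    bnx_stop("'initial_temperature' must be positive")
  }
  if (!is.numeric(cooling_factor) || cooling_factor <= 0 ||
      cooling_factor >= 1) {
    bnx_stop("'cooling_factor' must be in (0, 1)")
  }
  if (start_density < 0 || start_density > 1) {
    bnx_stop("'start_density' must be in [0, 1]")
  }
  structure(list(networks_per_run = as.integer(networks_per_run),
                 restarts = as.integer(restarts),
                 keep_top = as.integer(keep_top),
                 max_parents = as.integer(max_parents),
                 initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 reheat_after = as.integer(reheat_after),
                 start_density = start_density,
                 score_tolerance = score_tolerance,
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
                 prior = match.arg(prior), ess = ess),
            class = "search_config")
}

new_network_pool <- function(networks, score_tolerance = 1e-6) {
  keys <- vapply(networks, function(sn) dag_key(sn$dag), character(1))
  networks <- networks[!duplicated(keys)]
  scores <- vapply(networks, `[[`, numeric(1), "log_score")
  networks <- networks[order(-scores)]
  structure(list(networks = networks, score_tolerance = score_tolerance),
            class = "network_pool")
}

#' @export
print.network_pool <- function(x, ...) {
  sc <- vapply(x$networks, `[[`, numeric(1), "log_score")
  cat(sprintf("<network_pool> %d distinct networks, best log score %.6f\n",
              length(x$networks), if (length(sc)) max(sc) else NA_real_))
  invisible(x)
}

#' Pool scores
#' @param pool a `network_pool`.
#' @return numeric vector of log scores, best first.
#' @export
pool_scores <- function(pool) {
  vapply(pool$networks, `[[`, numeric(1), "log_score")
}

#' One simulated-annealing run
#'
#' Executes `networks_per_run` add/delete/reverse proposals from `start`.
#' Improvements are always accepted; a worsening of `delta` is accepted
#' with probability `exp(delta / T)`; `T` cools geometrically each proposal
#' and is reheated after `reheat_after` consecutive rejections.  The
#' `keep_top` best distinct structures ever visited (proposed or held) are
#' returned, best first.  Deterministic given `config$rng_seed`.
#'
#' @param data a [discrete_matrix()].
#' @param start a [bn_dag()] whose nodes are genes of `data`; the data are
#'   sliced to the start's node set.
#' @param config a [search_config()].
#' @return list of [scored_network()]s (attribute `trajectory`: best-score
#'   checkpoints).
#' @export
anneal_run <- function(data, start, config = search_config()) {
  stopifnot(inherits(data, "discrete_matrix"), inherits(start, "bn_dag"),
            inherits(config, "search_config"))
  unknown <- setdiff(start$nodes, data$gene_ids)
  if (length(unknown)) bnx_stop("unknown gene id: ", unknown[1L])
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  sub <- data$states[start$nodes, , drop = FALSE]
  res <- cpp_anneal(sub, rep(data$arity, length(start$nodes)), start$adj,
                    config$networks_per_run, config$keep_top,
                    config$max_parents, config$initial_temperature,
                    config$cooling_factor, config$reheat_after,
                    config$ess, config$prior == "bdeu")
  nets <- lapply(res$networks, function(nt) {
    adj <- nt$adj
    dimnames(adj) <- list(start$nodes, start$nodes)
    dag <- structure(list(nodes = start$nodes, adj = adj), class = "bn_dag")
    scored_network(dag, nt$log_score,
                   setNames(nt$per_family, start$nodes))
  })
  attr(nets, "trajectory") <- res$trajectory
  nets
}

#' Multi-restart structure search
#'
#' Runs `config$restarts` independent annealing runs, each from a fresh
#' random start DAG (empty by default; `start_density` controls edge
#' density), pools the retained networks, deduplicates by structure and
#' returns them sorted by score.  Restart RNG substreams are derived from
#' `rng_seed` and the restart index.
#'
#' @param data a [discrete_matrix()].
#' @param genes gene subset to model (defaults to all genes of `data`).
#' @param config a [search_config()].
#' @return a `network_pool`.
#' @export
multi_restart_search <- function(data, genes = NULL,
                                 config = search_config()) {
  stopifnot(inherits(data, "discrete_matrix"),
            inherits(config, "search_config"))
  genes <- as.character(genes %||% data$gene_ids)
  unknown <- setdiff(genes, data$gene_ids)
  if (length(unknown)) bnx_stop("unknown gene id: ", unknown[1L])
  base_seed <- config$rng_seed %||% sample.int(.Machine$integer.max, 1L)
  all_nets <- list()
  trajectories <- vector("list", config$restarts)
  for (s in seq_len(config$restarts)) {
    set.seed(derive_seed(base_seed, "restart", s))
    start <- if (config$start_density > 0) {
      random_dag(genes, config$start_density, config$max_parents)
    } else {
      bn_dag(genes)
    }
    run_cfg <- config
    run_cfg$rng_seed <- NULL  # RNG state already positioned for this restart
    nets <- anneal_run(data, start, run_cfg)
    trajectories[[s]] <- attr(nets, "trajectory")
    all_nets <- c(all_nets, nets)
  }
  pool <- new_network_pool(all_nets, config$score_tolerance)
  attr(pool, "trajectories") <- trajectories
  pool
}
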