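# Independent oracles used across the suite.
#
# The scoring oracle never touches lgamma or the package's counting code:
# log-factorials are explicit sums of log(1..N) and parent configurations
# are enumerated with expand.grid, with samples matched by direct
# comparison.  For the spec'd worked examples, small-integer ratios
# (1/540 etc.) are exact in double precision.

lfact <- function(n) if (n < 2L) 0 else sum(log(seq_len(n)))

# Exact-formula family score: (r-1)!/(N_ij+r-1)! * prod_k N_ijk! per config.
oracle_family_score <- function(states, child, parents, arity) {
  cs <- states[child, ]
  parents <- sort(parents)
  configs <- if (length(parents)) {
    as.matrix(expand.grid(rep(list(0:(arity - 1L)), length(parents))))
  } else {
    matrix(0L, 1L, 0L)
  }
  tot <- 0
  for (ci in seq_len(nrow(configs))) {
    keep <- rep(TRUE, length(cs))
    for (pi in seq_along(parents)) {
      keep <- keep & states[parents[pi], ] == configs[ci, pi]
    }
    nij <- sum(keep)
    nijk <- vapply(0:(arity - 1L), function(k) sum(cs[keep] == k), integer(1))
    tot <- tot + lfact(arity - 1L) - lfact(nij + arity - 1L) +
      sum(vapply(nijk, lfact, numeric(1)))
  }
  tot
}

oracle_network_score <- function(adj, states, arity) {
  nodes <- rownames(adj)
  sum(vapply(nodes, function(nd)
    oracle_family_score(states, nd, nodes[adj[, nd]], arity), numeric(1)))
}

# All DAG adjacency matrices over a node set (543 at n = 4, 25 at n = 3).
all_dags <- function(nodes) {
  n <- length(nodes)
  cells <- which(diag(n) == 0)
  out <- list()
  for (code in 0:(2^length(cells) - 1L)) {
    bits <- bitwAnd(code %/% 2^(seq_along(cells) - 1L), 1L) == 1L
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    adj[cells[bits]] <- TRUE
    if (bnexpand:::is_acyclic_adj(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

# Best score over an explicit DAG list, via a per-(child, parent-set) score
# table so the 543-DAG sweep is cheap.  Scorer may be the package's (the
# independence for search tests is the exhaustive enumeration itself).
exhaustive_best_score <- function(dags, data) {
  nodes <- rownames(dags[[1L]])
  n <- length(nodes)
  fam <- matrix(NA_real_, n, 2^n, dimnames = list(nodes, NULL))
  score_one <- function(adj) {
    sum(vapply(seq_len(n), function(j) {
      mask <- sum(2^(which(adj[, j]) - 1L)) + 1L
      if (is.na(fam[j, mask])) {
        fam[j, mask] <<- log_family_score(
          family_counts(data, nodes[j], nodes[adj[, j]]))
      }
      fam[j, mask]
    }, numeric(1)))
  }
  max(vapply(dags, score_one, numeric(1)))
}

# Exact hypergeometric enumeration for a 2x2 table (a, b, c, d), using
# lfact only.  Returns one-sided (enrichment) and two-sided
# (minimum-likelihood, relative tolerance 1e-7) p-values.
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b; tot <- m + nn
  lo <- max(0L, k - nn); hi <- min(k, m)
  logp <- vapply(lo:hi, function(x) {
    lfact(m) + lfact(nn) + lfact(k) + lfact(tot - k) - lfact(tot) -
      lfact(x) - lfact(m - x) - lfact(k - x) - lfact(nn - k + x)
  }, numeric(1))
  probs <- exp(logp)
  p_obs <- probs[(lo:hi) == a]
  list(p_one_sided = min(1, sum(probs[(lo:hi) >= a])),
       p_two_sided = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)])),
       total = sum(probs))
}

# Random discrete matrix fixture.
rand_discrete <- function(n, m, arity = 3L, genes = sprintf("g%02d", seq_len(n))) {
  st <- matrix(sample.int(arity, n * m, replace = TRUE) - 1L, n, m,
               dimnames = list(genes, sprintf("s%03d", seq_len(m))))
  discrete_matrix(st, arity = arity)
}

# The planted-regulator world used by the expansion tests: 8 core genes
# (sparse random DAG), one hidden parent of two core genes at strength 0.9,
# 20 independent noise candidates.
make_planted_world <- function(seed, m = 300L, n_core = 8L, n_noise = 20L,
                               strength = 0.9) {
  set.seed(seed)
  dag <- sample_dag(n_core, edge_prob = 0.25)
  model <- ground_truth_model(dag, 3L, sample_cpts(dag, 3L, strength),
                              bnexpand:::default_emissions(dag$nodes, 3L))
  pl <- plant_regulator(model, n_targets = 2L, n_noise_candidates = n_noise,
                        strength = strength)
  sim <- simulate_expression(pl$model, m)
  list(world = pl, sim = sim)
}

skeleton_f1 <- function(dag_est, dag_true) {
  skel <- function(d) {
    e <- dag_edges(d)
    unique(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  est <- skel(dag_est); tru <- skel(dag_true)
  tp <- length(intersect(est, tru))
  if (!length(est) || !length(tru) || !tp) return(0)
  prec <- tp / length(est); rec <- tp / length(tru)
  2 * prec * rec / (prec + rec)
}
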