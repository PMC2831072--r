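## Synthetic ground truth: sparse discrete DAG models with per-state
## Gaussian emissions, planted hidden regulators, independent noise genes,
## and annotated metadata with a term planted in chosen bins.  Everything
## the other modules consume can be generated here, deterministically under
## a fixed seed, at a scale where the whole suite runs in minutes.

#' Ground-truth generative model
#'
#' @param dag a [bn_dag()].
#' @param arity number of discrete states per node.
#' @param cpts named list (per node) of `q x arity` row-stochastic
#'   matrices; rows follow the mixed-radix order of the node's parents
#'   sorted by id (first parent most significant).
#' @param emission named list (per node) of `mean` (strictly increasing
#'   with state) and `sd` (positive) vectors of length `arity`.
#' @return object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(dag, arity, cpts, emission) {
  stopifnot(inherits(dag, "bn_dag"))
  arity <- check_count(arity, "arity")
  for (nd in dag$nodes) {
    cpt <- cpts[[nd]]
    q <- arity ^ length(dag_parents(dag, nd))
    stopifnot(is.matrix(cpt), nrow(cpt) == q, ncol(cpt) == arity)
    if (any(abs(rowSums(cpt) - 1) > 1e-12)) {
      bnx_stop("CPT rows of node '", nd, "' do not sum to 1")
    }
    em <- emission[[nd]]
    stopifnot(length(em$mean) == arity, length(em$sd) == arity)
    if (any(diff(em$mean) <= 0)) {
      bnx_stop("emission means of node '", nd, "' must be strictly increasing")
    }
    if (any(em$sd <= 0)) bnx_stop("emission sd of node '", nd, "' must be positive")
  }
  structure(list(dag = dag, arity = arity, cpts = cpts, emission = emission),
            class = "ground_truth_model")
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat(sprintf("<ground_truth_model> %d nodes, arity %d, %d edges\n",
              length(x$dag$nodes), x$arity, nrow(dag_edges(x$dag))))
  invisible(x)
}

#' Random sparse DAG
#'
#' Draws a uniform topological order and includes each forward edge with
#' probability `edge_prob`, truncating to `max_parents`.
#'
#' @param n_nodes number of nodes (ids `g01`, `g02`, ...).
#' @param max_parents in-degree cap.
#' @param edge_prob forward-edge probability in `[0, 1]`.
#' @return a [bn_dag()].
#' @export
sample_dag <- function(n_nodes, max_parents = 5L, edge_prob = 0.25) {
  check_count(n_nodes, "n_nodes")
  random_dag(sprintf("g%02d", seq_len(n_nodes)), edge_prob, max_parents)
}

#' Random sharpened CPTs
#'
#' Each CPT row is a flat Dirichlet draw blended with a random one-hot
#' vector so that one state carries probability at least `strength`
#' (`strength = 1` gives deterministic relations).
#'
#' @param dag a [bn_dag()].
#' @param arity states per node.
#' @param strength sharpening weight in `(0, 1]`.
#' @return named list of CPT matrices (see [ground_truth_model()]).
#' @export
sample_cpts <- function(dag, arity = 3L, strength = 0.9) {
  stopifnot(strength > 0, strength <= 1)
  arity <- check_count(arity, "arity")
  cpts <- lapply(dag$nodes, function(nd) {
    q <- arity ^ length(dag_parents(dag, nd))
    t(vapply(seq_len(q), function(j) {
      dir <- rgamma(arity, 1)
      dir <- dir / sum(dir)
      hot <- sample.int(arity, 1L)
      row <- (1 - strength) * dir
      row[hot] <- row[hot] + strength
      row
    }, numeric(arity)))
  })
  names(cpts) <- dag$nodes
  cpts
}

default_emissions <- function(nodes, arity, sep = 2, sd = 0.5) {
  em <- lapply(nodes, function(nd)
    list(mean = sep * (seq_len(arity) - 1L), sd = rep(sd, arity)))
  names(em) <- nodes
  em
}

## Draw one categorical state per column given a CPT row index per column.
draw_states <- function(cpt, j_idx) {
  p <- cpt[j_idx + 1L, , drop = FALSE]
  u <- runif(length(j_idx))
  cum <- t(apply(p, 1L, cumsum))
  as.integer(rowSums(u > cum))
}

#' Simulate samples from a ground-truth model
#'
#' Ancestral sampling in topological order; each node's continuous readout
#' is drawn from the Gaussian emission of its sampled state.  The returned
#' discrete matrix is the ground truth against which discretization of the
#' continuous matrix can be compared.
#'
#' @param model a [ground_truth_model()].
#' @param m_samples number of samples (columns).
#' @return list with `states` (a [discrete_matrix()]) and `values` (numeric
#'   expression matrix of identical shape).
#' @export
simulate_expression <- function(model, m_samples) {
  stopifnot(inherits(model, "ground_truth_model"))
  check_count(m_samples, "m_samples")
  dag <- model$dag
  r <- model$arity
  nodes <- dag$nodes
  sample_ids <- sprintf("s%04d", seq_len(m_samples))
  st <- matrix(0L, length(nodes), m_samples,
               dimnames = list(nodes, sample_ids))
  vals <- matrix(0, length(nodes), m_samples,
                 dimnames = list(nodes, sample_ids))
  for (u in topo_order_adj(dag$adj)) {
    nd <- nodes[u]
    pa <- sort(dag_parents(dag, nd))
    j <- if (length(pa)) {
      mixed_radix_index(st[pa, , drop = FALSE], rep(r, length(pa)))
    } else {
      rep.int(0L, m_samples)
    }
    s <- draw_states(model$cpts[[nd]], j)
    st[u, ] <- s
    em <- model$emission[[nd]]
    vals[u, ] <- rnorm(m_samples, em$mean[s + 1L], em$sd[s + 1L])
  }
  list(states = discrete_matrix(st, arity = r), values = vals)
}

#' Plant a hidden regulator and noise candidates
#'
#' Adds one hidden gene (`hreg`) as a parent of `n_targets` core nodes:
#' each target's conditional distribution becomes a `strength`-weighted
#' blend of a copy of the regulator state with its original CPT, so the
#' targets are strongly coupled to the regulator.  Also adds
#' `n_noise_candidates` root genes independent of everything.  The
#' original core DAG is returned for use as the expansion core.
#'
#' @param model a [ground_truth_model()] of the core genes.
#' @param n_targets number of core nodes to couple to the regulator.
#' @param n_noise_candidates independent noise genes to add.
#' @param strength coupling weight in `(0, 1]`.
#' @return list with `model` (augmented [ground_truth_model()]), `core_dag`
#'   (the original DAG), `hidden` (`"hreg"`), and `candidates`
#'   (`hidden` plus the noise gene ids).
#' @export
plant_regulator <- function(model, n_targets = 2L, n_noise_candidates = 20L,
                            strength = 0.9) {
  stopifnot(inherits(model, "ground_truth_model"),
            strength > 0, strength <= 1)
  check_count(n_targets, "n_targets")
  check_count(n_noise_candidates, "n_noise_candidates", zero_ok = TRUE)
  core <- model$dag
  r <- model$arity
  if (n_targets > length(core$nodes)) bnx_stop("more targets than core nodes")
  npar <- colSums(core$adj)
  targets <- core$nodes[order(npar, core$nodes)][seq_len(n_targets)]
  hidden <- "hreg"
  noise <- if (n_noise_candidates > 0) {
    sprintf("noise%02d", seq_len(n_noise_candidates))
  } else character(0)
  nodes <- c(core$nodes, hidden, noise)
  edges <- dag_edges(core)
  edges <- rbind(edges, data.frame(from = hidden, to = targets,
                                   stringsAsFactors = FALSE))
  dag <- bn_dag(nodes, edges)
  cpts <- model$cpts
  emission <- model$emission
  # regulator: uniform root so its discretized bins are balanced
  cpts[[hidden]] <- matrix(1 / r, 1L, r)
  emission[[hidden]] <- default_emissions(hidden, r)[[1L]]
  for (tg in targets) {
    old_pa <- sort(dag_parents(core, tg))
    new_pa <- sort(c(old_pa, hidden))
    q_new <- r ^ length(new_pa)
    hid_pos <- match(hidden, new_pa)
    radix_new <- rev(cumprod(rev(c(rep(r, length(new_pa) - 1L), 1))))
    cpt <- matrix(0, q_new, r)
    for (j in seq_len(q_new) - 1L) {
      digits <- (j %/% radix_new) %% r
      h <- digits[hid_pos]
      old_digits <- digits[-hid_pos]
      j_old <- if (length(old_digits)) {
        sum(old_digits * rev(cumprod(rev(c(rep(r, length(old_digits) - 1L), 1)))))
      } else 0L
      row <- (1 - strength) * model$cpts[[tg]][j_old + 1L, ]
      row[h + 1L] <- row[h + 1L] + strength
      cpt[j + 1L, ] <- row
    }
    cpts[[tg]] <- cpt
  }
  for (nz in noise) {
    dirch <- rgamma(r, 1); dirch <- dirch / sum(dirch)
    cpts[[nz]] <- matrix(dirch, 1L, r)
    emission[[nz]] <- default_emissions(nz, r)[[1L]]
  }
  aug <- ground_truth_model(dag, r, cpts, emission)
  list(model = aug, core_dag = core, hidden = hidden,
       candidates = c(hidden, noise))
}

#' Synthetic annotated metadata with a planted term
#'
#' Samples falling in `target_bin` (a joint state pair of the two genes)
#' receive `term` in their description with probability `hit_rate`, all
#' other samples with probability `background_rate`; the remaining text is
#' filled from a fixed innocuous vocabulary so every sample has nonempty
#' metadata.
#'
#' @param states a [discrete_matrix()].
#' @param gene_a,gene_b gene ids defining the joint bins.
#' @param term the planted word.
#' @param target_bin integer pair `(s_a, s_b)`.
#' @param hit_rate,background_rate term probabilities in `[0, 1]`.
#' @return metadata data frame (sample_id, title, description).
#' @export
make_metadata <- function(states, gene_a, gene_b, term = "biofilm",
                          target_bin = c(2L, 2L), hit_rate = 1,
                          background_rate = 0.05) {
  stopifnot(hit_rate >= 0, hit_rate <= 1,
            background_rate >= 0, background_rate <= 1)
  if (length(target_bin) != 2L || any(target_bin < 0) ||
      any(target_bin >= states$arity)) {
    bnx_stop("target_bin must be two states in [0, arity)")
  }
  bins <- assign_bins(states, gene_a, gene_b)
  filler <- c("culture", "growth", "aerobic", "medium", "exponential",
              "minimal", "glucose", "batch", "wildtype", "timepoint")
  in_target <- bins$state_a == target_bin[1L] & bins$state_b == target_bin[2L]
  rate <- ifelse(in_target, hit_rate, background_rate)
  with_term <- runif(nrow(bins)) < rate
  desc <- vapply(seq_len(nrow(bins)), function(i) {
    words <- sample(filler, 3L)
    if (with_term[i]) {
      words <- append(words, term, after = sample.int(3L, 1L))
    }
    paste(words, collapse = " ")
  }, character(1))
  data.frame(sample_id = bins$sample_id,
             title = paste("chip", seq_len(nrow(bins))),
             description = desc, row.names = NULL, stringsAsFactors = FALSE)
}
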