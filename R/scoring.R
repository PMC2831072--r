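## BDe scoring (Cooper-Herskovits uniform all-ones Dirichlet prior, with an
## optional likelihood-equivalent BDeu variant).  The score of a DAG
## decomposes over families: for child i with r_i states and q_i parent
## configurations,
##   log P(D_i | Pa_i) = sum_j [ lgamma(r_i) - lgamma(N_ij + r_i)
##                               + sum_k lgamma(N_ijk + 1) ]
## which is the log of (r_i - 1)! / (N_ij + r_i - 1)! * prod_k N_ijk!.

#' Sufficient statistics for one family
#'
#' Tallies `N_ijk`, the number of samples with the child in state `k` under
#' parent configuration `j`.  Configurations are enumerated in mixed-radix
#' order over the parents sorted by gene id (first parent most
#' significant).
#'
#' @param data a [discrete_matrix()].
#' @param child child gene id.
#' @param parents character vector of parent gene ids (may be empty).
#' @return an object of class `family_counts`: fields `child`, `parents`
#'   (sorted), `r_i`, `q_i`, `n_ijk` (`q_i` x `r_i` matrix), `n_ij`.
#' @export
family_counts <- function(data, child, parents = character(0)) {
  stopifnot(inherits(data, "discrete_matrix"))
  parents <- as.character(parents)
  unknown <- setdiff(c(child, parents), data$gene_ids)
  if (length(unknown)) bnx_stop("unknown gene id: ", unknown[1L])
  if (child %in% parents) bnx_stop("child cannot be its own parent")
  parents <- sort(parents)
  r <- data$arity
  q <- as.integer(r ^ length(parents))
  if (q * r > 5e7) bnx_stop("parent configuration table too large")
  cs <- data$states[child, ]
  if (length(parents)) {
    ps <- data$states[parents, , drop = FALSE]
    j <- mixed_radix_index(ps, rep(r, length(parents)))
  } else {
    j <- rep.int(0L, length(cs))
  }
  idx <- j * r + cs + 1L
  counts <- tabulate(idx, nbins = q * r)
  n_ijk <- matrix(counts, nrow = q, ncol = r, byrow = TRUE)
  structure(list(child = child, parents = parents, r_i = r, q_i = q,
                 n_ijk = n_ijk, n_ij = as.integer(rowSums(n_ijk))),
            class = "family_counts")
}

#' Log BDe family score
#'
#' @param counts a [family_counts()] table.
#' @param prior `"ch"` for the all-ones Cooper-Herskovits prior (default)
#'   or `"bdeu"` for the likelihood-equivalent prior with equivalent sample
#'   size `ess`.
#' @param ess equivalent sample size for `prior = "bdeu"`.
#' @return the log marginal likelihood contribution of the family
#'   (finite, `<= 0`).
#' @export
log_family_score <- function(counts, prior = c("ch", "bdeu"), ess = 1) {
  stopifnot(inherits(counts, "family_counts"))
  prior <- match.arg(prior)
  n_ijk <- counts$n_ijk
  n_ij <- counts$n_ij
  r <- counts$r_i
  if (prior == "ch") {
    sum(lgamma(r) - lgamma(n_ij + r)) + sum(lgamma(n_ijk + 1))
  } else {
    a_ij <- ess / counts$q_i
    a_ijk <- a_ij / r
    sum(lgamma(a_ij) - lgamma(n_ij + a_ij)) +
      sum(lgamma(n_ijk + a_ijk) - lgamma(a_ijk))
  }
}

#' Scored network
#'
#' A DAG with its total log BDe score and the per-family decomposition
#' (the total equals the sum of the family terms).
#'
#' @param dag a [bn_dag()].
#' @param log_score total log score.
#' @param per_family named numeric vector of family scores.
#' @return object of class `scored_network`.
#' @export
scored_network <- function(dag, log_score, per_family) {
  stopifnot(inherits(dag, "bn_dag"))
  per_family <- per_family[dag$nodes]
  if (abs(sum(per_family) - log_score) > 1e-6) {
    bnx_stop("log_score does not match the sum of family scores")
  }
  structure(list(dag = dag, log_score = log_score, per_family = per_family),
            class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("<scored_network> %d nodes, %d edges, log score %.6f\n",
              length(x$dag$nodes), nrow(dag_edges(x$dag)), x$log_score))
  invisible(x)
}

#' Log BDe score of a DAG
#'
#' Sums [log_family_score()] over every node's family.  Family scores are
#' cached by (child, parent set) in the optional `cache` environment so
#' repeated families across candidate structures are computed once.
#'
#' @param dag a [bn_dag()] whose nodes are genes of `data`.
#' @param data a [discrete_matrix()].
#' @param cache optional environment used as a memo table.
#' @inheritParams log_family_score
#' @return a [scored_network()].
#' @export
log_network_score <- function(dag, data, cache = NULL,
                              prior = c("ch", "bdeu"), ess = 1) {
  stopifnot(inherits(dag, "bn_dag"), inherits(data, "discrete_matrix"))
  prior <- match.arg(prior)
  unknown <- setdiff(dag$nodes, data$gene_ids)
  if (length(unknown)) bnx_stop("unknown gene id: ", unknown[1L])
  fam <- vapply(dag$nodes, function(nd) {
    pa <- dag_parents(dag, nd)
    key <- paste(nd, paste(sort(pa), collapse = ","), sep = "|")
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    s <- log_family_score(family_counts(data, nd, pa), prior = prior, ess = ess)
    if (!is.null(cache)) cache[[key]] <- s
    s
  }, numeric(1))
  scored_network(dag, sum(fam), fam)
}
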