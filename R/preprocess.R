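#' Discretized expression matrix
#'
#' Container for a genes x samples matrix of integer states in
#' `[0, arity)`, with the per-gene cut values that produced them.  Arity is
#' fixed by the quantization level (default 3 for q3), not by the number of
#' states a gene actually occupies, so the state space is constant across
#' genes when scoring.
#'
#' @param states integer matrix, genes x samples, with dimnames.
#' @param arity number of quantization levels.
#' @param bin_edges optional genes x (arity - 1) numeric matrix of cut
#'   values; a value `v` maps to state `sum(v > edges)`.
#' @return an object of class `discrete_matrix` with fields `states`,
#'   `arity`, `bin_edges`, `gene_ids`, `sample_ids`.
#' @export
discrete_matrix <- function(states, arity = 3L, bin_edges = NULL) {
  arity <- check_count(arity, "arity")
  if (arity < 2L) bnx_stop("'arity' must be at least 2")
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if ((nrow(states) > 0L && is.null(rownames(states))) ||
      (ncol(states) > 0L && is.null(colnames(states)))) {
    bnx_stop("'states' must carry gene and sample ids as dimnames")
  }
  if (is.null(rownames(states))) rownames(states) <- character(0)
  if (is.null(colnames(states))) colnames(states) <- character(0)
  if (anyDuplicated(rownames(states))) bnx_stop("duplicate gene ids")
  if (anyDuplicated(colnames(states))) bnx_stop("duplicate sample ids")
  if (length(states) && (anyNA(states) || any(states < 0L) ||
                         any(states >= arity))) {
    bnx_stop("states must be integers in [0, arity)")
  }
  if (!is.null(bin_edges)) {
    bin_edges <- as.matrix(bin_edges)
    stopifnot(nrow(bin_edges) == nrow(states),
              ncol(bin_edges) == arity - 1L)
    if (any(apply(bin_edges, 1L, is.unsorted, na.rm = TRUE))) {
      bnx_stop("bin_edges must be non-decreasing per gene")
    }
  }
  structure(list(states = states, arity = arity, bin_edges = bin_edges,
                 gene_ids = rownames(states),
                 sample_ids = colnames(states)),
            class = "discrete_matrix")
}

#' @export
print.discrete_matrix <- function(x, ...) {
  cat(sprintf("<discrete_matrix> %d genes x %d samples, arity %d\n",
              nrow(x$states), ncol(x$states), x$arity))
  invisible(x)
}

#' Filter genes by coefficient of variation
#'
#' The coefficient of variation of a gene is its sample standard deviation
#' (n - 1 denominator) divided by the absolute value of its mean across
#' samples; genes with c.v. at or above the threshold are kept.  Genes with
#' mean exactly zero get infinite c.v. and survive any finite threshold.
#'
#' @param matrix numeric expression matrix, genes x samples, with dimnames.
#' @param threshold non-negative c.v. cutoff (the compendium analysis used
#'   1.0).
#' @return list with `kept` (gene ids in input order) and `table` (data
#'   frame: gene_id, mean, sd, cv, kept).
#' @export
cv_filter <- function(matrix, threshold = 1.0) {
  matrix <- validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L) bnx_stop("c.v. needs at least 2 samples")
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    bnx_stop("'threshold' must be a single non-negative number")
  }
  mu <- rowMeans(matrix)
  sdev <- apply(matrix, 1L, stats::sd)
  cv <- ifelse(mu == 0, Inf, sdev / abs(mu))
  keep <- cv >= threshold
  list(kept = rownames(matrix)[keep],
       table = data.frame(gene_id = rownames(matrix), mean = mu, sd = sdev,
                          cv = cv, kept = keep, row.names = NULL,
                          stringsAsFactors = FALSE))
}

## Admissible cut positions for a sorted vector: rank positions where the
## value strictly increases (plus 0 and m), so tied values can never
## straddle a bin boundary.
admissible_cuts <- function(vs) {
  m <- length(vs)
  c(0L, which(diff(vs) > 0), m)
}

## Choose levels-1 non-decreasing cut positions from B maximizing the
## entropy of bin occupancy (minimizing sum n_b log n_b), tie-broken by
## minimal max bin size, then by the lexicographically LARGEST cut tuple so
## ties of runs of equal values land in the lowest admissible state.
choose_cuts <- function(B, m, levels) {
  nlogn <- function(x) ifelse(x > 0, x * log(x), 0)
  if (levels == 2L) {
    cuts <- matrix(B, ncol = 1L)
  } else if (levels == 3L) {
    g <- expand.grid(c1 = B, c2 = B)
    g <- g[g$c1 <= g$c2, , drop = FALSE]
    cuts <- as.matrix(g)
  } else {
    # general case: recursive enumeration of non-decreasing tuples
    grow <- function(prefix, k) {
      if (k == 0L) return(matrix(prefix, nrow = 1L))
      lo <- if (length(prefix)) prefix[length(prefix)] else B[1L]
      do.call(rbind, lapply(B[B >= lo], function(b) grow(c(prefix, b), k - 1L)))
    }
    cuts <- grow(integer(0), levels - 1L)
  }
  sizes <- cbind(cuts[, 1L],
                 if (levels > 2L) cuts[, -1L, drop = FALSE] -
                   cuts[, -(levels - 1L), drop = FALSE],
                 m - cuts[, levels - 1L])
  obj <- rowSums(nlogn(sizes))
  best <- which(obj <= min(obj) + 1e-9)
  if (length(best) > 1L) {
    mx <- apply(sizes[best, , drop = FALSE], 1L, max)
    best <- best[mx == min(mx)]
  }
  if (length(best) > 1L) {
    ord <- do.call(order, c(lapply(seq_len(levels - 1L),
                                   function(k) -cuts[best, k])))
    best <- best[ord[1L]]
  }
  as.integer(cuts[best[1L], ])
}

#' Equal-frequency (maximum-entropy) discretization
#'
#' Per gene independently, samples are rank-ordered and split into `levels`
#' bins as equal in occupancy as the data allow (q3 quantization for the
#' default 3 levels).  Cut positions are restricted to boundaries between
#' distinct values, so tied values always share a state; among admissible
#' cuts the bin-occupancy entropy is maximized.  State 0 holds the lowest
#' values.
#'
#' @param matrix numeric expression matrix, genes x samples, with dimnames.
#' @param levels number of bins per gene (>= 2; default 3).
#' @return a [discrete_matrix()] with recorded `bin_edges`.
#' @export
q3_discretize <- function(matrix, levels = 3L) {
  matrix <- validate_expression_matrix(matrix)
  levels <- check_count(levels, "levels")
  if (levels < 2L) bnx_stop("'levels' must be at least 2")
  m <- ncol(matrix)
  if (m < levels) bnx_stop("need at least 'levels' samples per gene")
  states <- matrix(0L, nrow(matrix), m, dimnames = dimnames(matrix))
  edges <- matrix(NA_real_, nrow(matrix), levels - 1L,
                  dimnames = list(rownames(matrix), NULL))
  for (g in seq_len(nrow(matrix))) {
    v <- matrix[g, ]
    ord <- order(v)
    vs <- v[ord]
    cuts <- choose_cuts(admissible_cuts(vs), m, levels)
    st <- integer(m)
    pos <- seq_len(m)
    st[ord] <- rowSums(outer(pos, cuts, ">"))
    states[g, ] <- st
    edges[g, ] <- vapply(cuts, function(cc) {
      if (cc == 0L) -Inf else if (cc == m) Inf else (vs[cc] + vs[cc + 1L]) / 2
    }, numeric(1))
  }
  discrete_matrix(states, arity = levels, bin_edges = edges)
}
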