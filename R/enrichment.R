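## Term enrichment: words from sample titles/descriptions are tested for
## association with discretization bins of a selected gene pair using
## Fisher's exact test on the 2x2 table (in bin / out of bin) x (term /
## non-term).

#' Tokenize sample annotations
#'
#' A term is any individual word of a sample's title or description:
#' text is lowercased and split on non-alphanumeric characters; tokens
#' shorter than two characters or purely numeric are dropped; per-sample
#' token sets are deduplicated.
#'
#' @param metadata data frame with columns `sample_id`, `title`,
#'   `description`.
#' @param stop_words optional character vector of tokens to drop (none by
#'   default, so signal words like "biofilm" are never filtered).
#' @return a `term_index`: `per_sample` (named list of token sets) and
#'   `vocabulary` (data frame term / n_samples).
#' @export
tokenize_metadata <- function(metadata, stop_words = character(0)) {
  stopifnot(all(c("sample_id", "title", "description") %in% names(metadata)))
  if (anyDuplicated(metadata$sample_id)) bnx_stop("duplicate sample_id")
  per_sample <- lapply(seq_len(nrow(metadata)), function(i) {
    txt <- tolower(paste(metadata$title[i], metadata$description[i]))
    toks <- strsplit(txt, "[^a-z0-9]+")[[1L]]
    toks <- toks[nchar(toks) >= 2L & !grepl("^[0-9]+$", toks)]
    sort(unique(setdiff(toks, stop_words)))
  })
  names(per_sample) <- metadata$sample_id
  all_tok <- unlist(per_sample, use.names = FALSE)
  vocab <- if (length(all_tok)) {
    tab <- table(all_tok)
    data.frame(term = names(tab), n_samples = as.integer(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(term = character(0), n_samples = integer(0))
  }
  structure(list(per_sample = per_sample, vocabulary = vocab),
            class = "term_index")
}

#' Joint discretization bins for a gene pair
#'
#' @param states a [discrete_matrix()].
#' @param gene_a,gene_b gene ids present in `states`.
#' @return data frame with one row per sample: `sample_id`, `state_a`,
#'   `state_b`, `joint` (label `"a,b"`).
#' @export
assign_bins <- function(states, gene_a, gene_b) {
  stopifnot(inherits(states, "discrete_matrix"))
  unknown <- setdiff(c(gene_a, gene_b), states$gene_ids)
  if (length(unknown)) bnx_stop("unknown gene id: ", unknown[1L])
  sa <- states$states[gene_a, ]
  sb <- states$states[gene_b, ]
  data.frame(sample_id = states$sample_ids, state_a = as.integer(sa),
             state_b = as.integer(sb),
             joint = paste(sa, sb, sep = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher's exact test for a 2x2 table
#'
#' `a` = in-bin samples with the term, `b` = in-bin without, `c` =
#' out-of-bin with, `d` = out-of-bin without.  The one-sided (enrichment)
#' p-value is the upper hypergeometric tail; the two-sided p-value sums the
#' probabilities of all tables with the same margins whose probability is
#' at most that of the observed table (relative tolerance 1e-7 in the
#' comparison, the standard convention).
#'
#' @param a,b,c,d non-negative integer cell counts, not all zero.
#' @return list with `p_one_sided`, `p_two_sided`, `odds_ratio` (sample
#'   odds ratio, `NA` when undefined).
#' @export
fisher_pvalue <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    bnx_stop("cell counts must be non-negative integers")
  }
  if (sum(cnt) == 0) bnx_stop("at least one cell count must be positive")
  m <- a + c      # total with term
  nn <- b + d     # total without term
  k <- a + b      # bin size
  lo <- max(0L, k - nn)
  hi <- min(k, m)
  supp <- lo:hi
  probs <- stats::dhyper(supp, m, nn, k)
  p_obs <- probs[supp == a]
  p_one <- sum(probs[supp >= a])
  p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_one_sided = min(1, p_one), p_two_sided = min(1, p_two),
       odds_ratio = if (b * c > 0) (a * d) / (b * c) else NA_real_)
}

#' Term enrichment over the bins of a gene pair
#'
#' For every vocabulary term carried by at least `min_term_count` samples,
#' tests its association with each joint bin cell `(s_a, s_b)` and each
#' marginal bin of either gene.  Samples without metadata are excluded
#' with a warning.  P-values are Benjamini-Hochberg adjusted across all
#' (term, bin) pairs tested; records are sorted by adjusted then raw
#' p-value.
#'
#' @inheritParams assign_bins
#' @param metadata data frame with columns `sample_id`, `title`,
#'   `description`.
#' @param min_term_count minimum number of annotated samples carrying a
#'   term for it to be tested.
#' @param stop_words passed to [tokenize_metadata()].
#' @return data frame with columns term, bin, bin_type (`"joint"`,
#'   `"marginal_a"`, `"marginal_b"`), a, b, c, d, p_one_sided, p_two_sided,
#'   p_bh.
#' @export
enrich_gene_pair <- function(states, metadata, gene_a, gene_b,
                             min_term_count = 3L, stop_words = character(0)) {
  bins <- assign_bins(states, gene_a, gene_b)
  covered <- bins$sample_id %in% metadata$sample_id
  if (!all(covered)) {
    warning(sum(!covered), " samples lack metadata and are excluded")
    bins <- bins[covered, , drop = FALSE]
  }
  meta <- metadata[match(bins$sample_id, metadata$sample_id), , drop = FALSE]
  idx <- tokenize_metadata(meta, stop_words = stop_words)
  terms <- idx$vocabulary$term[idx$vocabulary$n_samples >= min_term_count]
  m_tot <- nrow(bins)
  arity <- states$arity
  bin_defs <- rbind(
    expand.grid(bin_type = "joint", sa = 0:(arity - 1L), sb = 0:(arity - 1L),
                stringsAsFactors = FALSE),
    data.frame(bin_type = "marginal_a", sa = 0:(arity - 1L), sb = NA),
    data.frame(bin_type = "marginal_b", sa = NA, sb = 0:(arity - 1L)))
  if (!length(terms) || !m_tot) {
    return(data.frame(term = character(0), bin = character(0),
                      bin_type = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      p_one_sided = numeric(0), p_two_sided = numeric(0),
                      p_bh = numeric(0)))
  }
  has_term <- lapply(terms, function(tm)
    vapply(idx$per_sample, function(s) tm %in% s, logical(1)))
  rows <- list()
  for (bi in seq_len(nrow(bin_defs))) {
    bt <- bin_defs$bin_type[bi]
    in_bin <- switch(bt,
      joint = bins$state_a == bin_defs$sa[bi] & bins$state_b == bin_defs$sb[bi],
      marginal_a = bins$state_a == bin_defs$sa[bi],
      marginal_b = bins$state_b == bin_defs$sb[bi])
    label <- switch(bt,
      joint = sprintf("(%d,%d)", bin_defs$sa[bi], bin_defs$sb[bi]),
      marginal_a = sprintf("%s=%d", gene_a, bin_defs$sa[bi]),
      marginal_b = sprintf("%s=%d", gene_b, bin_defs$sb[bi]))
    for (ti in seq_along(terms)) {
      ht <- has_term[[ti]]
      a <- sum(in_bin & ht); b <- sum(in_bin & !ht)
      cc <- sum(!in_bin & ht); d <- sum(!in_bin & !ht)
      p <- fisher_pvalue(a, b, cc, d)
      rows[[length(rows) + 1L]] <- data.frame(
        term = terms[ti], bin = label, bin_type = bt,
        a = a, b = b, c = cc, d = d,
        p_one_sided = p$p_one_sided, p_two_sided = p$p_two_sided,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_two_sided, method = "BH")
  out <- out[order(out$p_bh, out$p_two_sided, out$term, out$bin), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
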