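#' Derive a reproducible sub-seed from a base seed and labels
#'
#' Folds the labels into a 31-bit polynomial rolling hash combined with the
#' base seed.  Used to give every restart, candidate gene, and rerank
#' replicate its own RNG substream keyed by identity (not position), so
#' results are invariant to evaluation order.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(vapply(list(...), as.character, character(1)),
                 collapse = "\r")
  h <- 0
  for (b in utf8ToInt(parts)) h <- (h * 31 + b) %% 2147483647
  h <- (h + abs(as.numeric(seed))) %% 2147483647
  as.integer(h + 1)
}

bnx_stop <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a value is a single positive whole number
#' @noRd
check_count <- function(x, name, zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) ||
      x < if (zero_ok) 0 else 1) {
    bnx_stop(sprintf("'%s' must be a single %s integer", name,
                     if (zero_ok) "non-negative" else "positive"))
  }
  invisible(as.integer(x))
}

## Mixed-radix configuration index for a sample's parent states.
## Parents are taken in the order given; the FIRST parent is the most
## significant digit.  states: matrix |parents| x m (0-based).
mixed_radix_index <- function(states, arities) {
  if (length(arities) == 0L) return(rep.int(0L, ncol(states)))
  w <- rev(cumprod(rev(c(arities[-1], 1))))
  as.integer(round(colSums(states * w)))
}
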