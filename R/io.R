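## Readers and writers for the external formats: expression TSV
## (genes-as-rows, M3D convention), gene lists, sample metadata, SIF/TSV
## edge lists, discretized state matrices, and JSON network pools.

#' Validate an expression matrix
#'
#' Checks the container invariants: numeric matrix, unique gene and sample
#' ids as dimnames, all values finite.
#'
#' @param matrix candidate matrix.
#' @return the validated matrix (invisibly unchanged).
#' @export
validate_expression_matrix <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    bnx_stop("expression data must be a numeric matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    bnx_stop("expression matrix must carry gene and sample ids as dimnames")
  }
  if (anyDuplicated(rownames(matrix))) {
    bnx_stop("duplicate gene id: ", rownames(matrix)[duplicated(rownames(matrix))][1L])
  }
  if (anyDuplicated(colnames(matrix))) {
    bnx_stop("duplicate sample id: ", colnames(matrix)[duplicated(colnames(matrix))][1L])
  }
  if (length(matrix) && any(!is.finite(matrix))) {
    bnx_stop("expression matrix contains non-finite values")
  }
  matrix
}

#' Read a tab-delimited expression matrix
#'
#' Expects genes as rows and samples as columns (first row sample ids,
#' first column gene ids); `transpose = TRUE` flips a samples-as-rows file
#' on read.  Row and column order is preserved from the file.
#'
#' @param path file path.
#' @param transpose flip the matrix after reading.
#' @return numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2L) bnx_stop("expression file needs a header and data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  sample_ids <- header[-1L]  # first header cell is a row-id label
  body <- cells[-1L]
  gene_ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    bnx_stop("duplicate gene id in file: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    bnx_stop("duplicate sample id in file: ",
             sample_ids[duplicated(sample_ids)][1L])
  }
  vals <- matrix(NA_real_, length(gene_ids), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (r in seq_along(body)) {
    row <- body[[r]][-1L]
    if (length(row) != length(sample_ids)) {
      bnx_stop(sprintf("row '%s' has %d values, expected %d",
                       gene_ids[r], length(row), length(sample_ids)))
    }
    num <- suppressWarnings(as.numeric(row))
    bad <- which(!is.finite(num))
    if (length(bad)) {
      bnx_stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                       row[bad[1L]], gene_ids[r], sample_ids[bad[1L]]))
    }
    vals[r, ] <- num
  }
  if (transpose) {
    vals <- t(vals)
  }
  validate_expression_matrix(vals)
}

#' @rdname read_expression_matrix
#' @param matrix numeric matrix to write.
#' @export
write_expression_matrix <- function(matrix, path) {
  matrix <- validate_expression_matrix(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(matrix)), collapse = "\t"), con)
  body <- apply(matrix, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored;
#' duplicates are dropped (with a warning) keeping first occurrence order.
#' When an expression matrix is supplied, listed genes absent from it are
#' reported via a warning and the `"missing"` attribute.
#'
#' @param path file path.
#' @param matrix optional companion expression matrix (or
#'   [discrete_matrix()]) to check membership against.
#' @return character vector of gene ids (attribute `missing`: absentees).
#' @export
read_gene_list <- function(path, matrix = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines)) {
    warning("duplicate gene ids in list: ",
            paste(unique(lines[duplicated(lines)]), collapse = ", "))
    lines <- unique(lines)
  }
  if (!length(lines)) bnx_stop("gene list is empty")
  missing <- character(0)
  if (!is.null(matrix)) {
    have <- if (inherits(matrix, "discrete_matrix")) matrix$gene_ids
            else rownames(matrix)
    missing <- setdiff(lines, have)
    if (length(missing)) {
      warning("genes not present in the expression matrix: ",
              paste(missing, collapse = ", "))
    }
  }
  attr(lines, "missing") <- missing
  lines
}

#' Edge list with orientation flags
#'
#' @param edges data frame (or matrix) with columns source, target,
#'   orientation (`"directed"` or `"undirected"`).
#' @return an object of class `network_edge_list`.
#' @export
network_edge_list <- function(edges) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(source = character(0), target = character(0),
                        orientation = character(0), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = as.character(edges[[1L]]),
                        target = as.character(edges[[2L]]),
                        orientation = as.character(edges[[3L]]),
                        stringsAsFactors = FALSE)
  }
  if (!all(edges$orientation %in% c("directed", "undirected"))) {
    bnx_stop("orientation must be 'directed' or 'undirected'")
  }
  if (any(edges$source == edges$target)) bnx_stop("self-loop in edge list")
  key <- paste(edges$source, edges$target, edges$orientation, sep = "\r")
  if (anyDuplicated(key)) bnx_stop("duplicate edge in edge list")
  structure(list(edges = edges), class = "network_edge_list")
}

#' Write a network edge list as SIF or TSV
#'
#' SIF dialect: one `source<TAB>relation<TAB>target` line per edge with
#' relation `->` (directed) or `--` (undirected).  TSV dialect: header
#' `source  target  orientation`.
#'
#' @param network a [network_edge_list()] (a [bn_dag()] is accepted and
#'   treated as all-directed).
#' @param path output path.
#' @param format `"sif"` or `"tsv"`.
#' @export
write_network <- function(network, path, format = c("sif", "tsv")) {
  if (!is.character(format) || !all(format %in% c("sif", "tsv"))) {
    bnx_stop("unknown network format; supported formats: sif, tsv")
  }
  format <- match.arg(format)
  if (inherits(network, "bn_dag")) {
    e <- dag_edges(network)
    network <- network_edge_list(
      if (nrow(e)) data.frame(e$from, e$to, "directed") else NULL)
  }
  stopifnot(inherits(network, "network_edge_list"))
  ed <- network$edges
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "sif") {
    if (nrow(ed)) {
      rel <- ifelse(ed$orientation == "directed", "->", "--")
      writeLines(paste(ed$source, rel, ed$target, sep = "\t"), con)
    }
  } else {
    writeLines("source\ttarget\torientation", con)
    if (nrow(ed)) {
      writeLines(paste(ed$source, ed$target, ed$orientation, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "sif") {
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(network_edge_list(NULL))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad)) bnx_stop("malformed SIF line: ", lines[bad][1L])
    m <- do.call(rbind, parts)
    orient <- ifelse(m[, 2L] == "->", "directed",
                     ifelse(m[, 2L] == "--", "undirected", NA))
    if (anyNA(orient)) bnx_stop("unknown SIF relation: ", m[is.na(orient), 2L][1L])
    network_edge_list(data.frame(m[, 1L], m[, 3L], orient))
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    network_edge_list(tab)
  }
}

#' Read/write sample metadata (sample_id, title, description)
#' @param path file path.
#' @return data frame with character columns `sample_id`, `title`,
#'   `description` (empty strings for missing text).
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE)
  need <- c("sample_id", "title", "description")
  if (!all(need %in% names(tab))) {
    bnx_stop("metadata file must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  tab[is.na(tab)] <- ""
  if (anyDuplicated(tab$sample_id)) {
    bnx_stop("duplicate sample_id in metadata: ",
             tab$sample_id[duplicated(tab$sample_id)][1L])
  }
  tab
}

#' @rdname read_metadata
#' @param metadata data frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  stopifnot(all(c("sample_id", "title", "description") %in% names(metadata)))
  write.table(metadata[, c("sample_id", "title", "description")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a discretized state matrix
#'
#' Layout mirrors the expression TSV (genes as rows, integer states); the
#' bin edges travel in a sidecar TSV whose column count fixes the arity.
#'
#' @param path states TSV path.
#' @param edges_path optional sidecar with per-gene cut values.
#' @param arity arity when no sidecar is given.
#' @return a [discrete_matrix()].
#' @export
read_discrete_matrix <- function(path, edges_path = NULL, arity = 3L) {
  vals <- read_expression_matrix(path)
  edges <- NULL
  if (!is.null(edges_path)) {
    etab <- read.delim(edges_path, stringsAsFactors = FALSE, check.names = FALSE)
    edges <- as.matrix(etab[, -1L, drop = FALSE])
    rownames(edges) <- etab[[1L]]
    edges <- edges[rownames(vals), , drop = FALSE]
    arity <- ncol(edges) + 1L
  }
  storage.mode(vals) <- "integer"
  discrete_matrix(vals, arity = arity, bin_edges = edges)
}

#' @rdname read_discrete_matrix
#' @param data a [discrete_matrix()].
#' @export
write_discrete_matrix <- function(data, path, edges_path = NULL) {
  stopifnot(inherits(data, "discrete_matrix"))
  con <- file(path, "w")
  writeLines(c(paste(c("gene_id", data$sample_ids), collapse = "\t"),
               paste(data$gene_ids,
                     apply(data$states, 1L, paste, collapse = "\t"),
                     sep = "\t")), con)
  close(con)
  if (!is.null(edges_path)) {
    if (is.null(data$bin_edges)) bnx_stop("no bin edges recorded")
    tab <- data.frame(gene_id = data$gene_ids, data$bin_edges,
                      check.names = FALSE)
    names(tab)[-1L] <- paste0("edge", seq_len(ncol(data$bin_edges)))
    write.table(tab, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## ---- network pool JSON ----

#' Serialize a network pool to JSON
#'
#' Pools carry a `schema_version` field, the score tolerance used for
#' identical-score grouping, and every network's node set, edge list,
#' total log score, and per-family scores.
#'
#' @param pool a `network_pool` (see [multi_restart_search()]).
#' @param path output path.
#' @export
write_pool <- function(pool, path) {
  stopifnot(inherits(pool, "network_pool"))
  nets <- lapply(pool$networks, function(sn) {
    e <- dag_edges(sn$dag)
    list(nodes = sn$dag$nodes,
         edges = if (nrow(e)) e else data.frame(from = character(0),
                                                to = character(0)),
         log_score = sn$log_score,
         per_family = as.list(sn$per_family))
  })
  jsonlite::write_json(list(schema_version = 1L,
                            score_tolerance = pool$score_tolerance,
                            networks = nets),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  networks <- lapply(obj$networks, function(nt) {
    nodes <- unlist(nt$nodes)
    edges <- if (length(nt$edges)) {
      data.frame(from = vapply(nt$edges, function(e) e$from, character(1)),
                 to = vapply(nt$edges, function(e) e$to, character(1)),
                 stringsAsFactors = FALSE)
    } else NULL
    scored_network(bn_dag(nodes, edges), nt$log_score,
                   unlist(nt$per_family))
  })
  new_network_pool(networks, obj$score_tolerance)
}
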