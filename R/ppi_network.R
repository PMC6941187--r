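#' Load a STRING-style scored edge list
#'
#' Reads a protein-protein association edge list in the STRING
#' `protein.links` dialect: whitespace- or tab-delimited rows of
#' `node_a node_b combined_score`, score on a 0-1000 scale, with an
#' optional header line (auto-detected when the third field of the first
#' row is not a number). Only high-confidence edges are kept: the score
#' must be *strictly greater* than `threshold` (default 700, the
#' conventional high-confidence cut, so a score of exactly 700 is
#' excluded). Self-loops are dropped and duplicate unordered pairs (STRING
#' files list both directions) collapse to one undirected edge.
#'
#' @param path Path to the edge list file.
#' @param threshold Minimum (exclusive) combined score, default 700.
#' @return data.frame with columns `node_a`, `node_b`, `combined_score`,
#'   one row per retained undirected edge, with endpoint pairs ordered
#'   lexicographically. Attribute `"stats"` carries parse counts
#'   (`n_rows`, `n_self_loops`, `n_unique_pairs`, `n_retained`).
#' @export
read_string_edges <- function(path, threshold = 700) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^[[:space:]]*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) vw_input_error(sprintf("edge file '%s' is empty", path))

  fields <- strsplit(vw_trim(lines), "[\t ]+")
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad) > 0L) {
    vw_input_error(sprintf(
      "edge file '%s': line %d has %d column(s); 3 required",
      path, line_no[bad[1L]], nf[bad[1L]]))
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  s_raw <- vapply(fields, `[[`, "", 3L)
  s <- suppressWarnings(as.numeric(s_raw))

  # Header auto-detection: a non-numeric score on the first line only.
  if (is.na(s[1L]) && length(s) > 1L) {
    a <- a[-1L]; b <- b[-1L]; s <- s[-1L]; line_no <- line_no[-1L]
  }
  if (anyNA(s)) {
    i <- which(is.na(s))[1L]
    vw_input_error(sprintf(
      "edge file '%s': line %d has unparsable combined_score '%s'",
      path, line_no[i], s_raw[if (length(s_raw) > length(s)) i + 1L else i]))
  }
  if (any(s < 0 | s > 1000)) {
    i <- which(s < 0 | s > 1000)[1L]
    vw_input_error(sprintf(
      "edge file '%s': line %d has combined_score %g outside [0, 1000]",
      path, line_no[i], s[i]))
  }

  n_rows <- length(s)
  self <- a == b
  a <- a[!self]; b <- b[!self]; s <- s[!self]

  # Canonicalize unordered pairs, then collapse duplicates keeping the
  # maximum score (STRING lists identical scores in both directions).
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -s)
  first <- !duplicated(key[ord])
  lo <- lo[ord][first]; hi <- hi[ord][first]; s <- s[ord][first]
  n_unique <- length(s)

  retained <- s > threshold
  out <- data.frame(node_a = lo[retained], node_b = hi[retained],
                    combined_score = s[retained], stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stats") <- list(n_rows = n_rows, n_self_loops = sum(self),
                             n_unique_pairs = n_unique,
                             n_retained = nrow(out))
  out
}

#' Translate edge endpoints through an identifier alias table
#'
#' STRING edge lists name proteins by database identifiers while DEG lists
#' carry gene symbols; an alias table bridges the two. Edges with an
#' endpoint missing from the alias are dropped (and counted), since an
#' untranslatable endpoint can never match a DEG.
#'
#' @param edges Edge data.frame from [read_string_edges()].
#' @param alias Named character vector (`names` = identifiers, values =
#'   gene symbols), or a 2-column data.frame `(identifier, gene_symbol)`,
#'   or `NULL`/empty for the identity mapping.
#' @return Translated edge data.frame; attribute `"n_dropped_unmapped"`
#'   counts dropped edges.
#' @export
apply_alias <- function(edges, alias = NULL) {
  if (is.data.frame(alias)) {
    alias <- stats::setNames(as.character(alias[[2L]]), as.character(alias[[1L]]))
  }
  if (is.null(alias) || length(alias) == 0L) {
    attr(edges, "n_dropped_unmapped") <- 0L
    return(edges)
  }
  a <- unname(alias[edges$node_a])
  b <- unname(alias[edges$node_b])
  ok <- !is.na(a) & !is.na(b)
  out <- data.frame(node_a = pmin(a[ok], b[ok]), node_b = pmax(a[ok], b[ok]),
                    combined_score = edges$combined_score[ok],
                    stringsAsFactors = FALSE)
  out <- unique(out[out$node_a != out$node_b, , drop = FALSE])
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_unmapped") <- sum(!ok)
  attr(out, "stats") <- attr(edges, "stats")
  out
}

#' Read a 2-column alias table
#'
#' @param path Delimited text, column 1 identifier, column 2 gene symbol.
#' @param delim Field delimiter pattern (default any tab/space run).
#' @return Named character vector mapping identifier to symbol.
#' @export
read_alias_table <- function(path, delim = "[\t ]+") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^[[:space:]]*$", lines)]
  fields <- strsplit(vw_trim(lines), delim)
  if (any(lengths(fields) < 2L)) {
    vw_input_error(sprintf("alias file '%s': every row needs 2 columns", path))
  }
  stats::setNames(vapply(fields, `[[`, "", 2L), vapply(fields, `[[`, "", 1L))
}

#' Induce the unweighted PPI subgraph on the DEG union
#'
#' Nodes are *all* members of `deg_union` -- including genes untouched by
#' any retained edge, which remain as isolates so that every DEG appears in
#' the ranked output. The adjacency matrix is binary, symmetric, with zero
#' diagonal, over a deterministic lexicographic node ordering.
#'
#' @param edges Edge data.frame (after aliasing, if any).
#' @param deg_union Nonempty character vector of gene symbols.
#' @return An object of class `vw_ppigraph`: list with `nodes` (sorted
#'   symbols), `adjacency` (sparse symmetric 0/1 Matrix), `n_edges`.
#' @export
induce_ppi_graph <- function(edges, deg_union) {
  if (length(deg_union) == 0L) vw_usage_error("deg_union is empty")
  nodes <- sort(unique(deg_union))
  ia <- match(edges$node_a, nodes)
  ib <- match(edges$node_b, nodes)
  ok <- !is.na(ia) & !is.na(ib)
  ia <- ia[ok]; ib <- ib[ok]
  m <- length(nodes)
  A <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = 1, dims = c(m, m),
                            dimnames = list(nodes, nodes))
  A@x[] <- 1  # duplicate (i,j) entries from parallel input rows clamp to 1
  structure(list(nodes = nodes, adjacency = A, n_edges = length(ia)),
            class = "vw_ppigraph")
}

#' Column-normalized transition matrix
#'
#' Divides each adjacency column by its sum, yielding the column-stochastic
#' transition matrix of the walk. An isolated node's column would sum to
#' zero and leak probability mass under the propagation update; such
#' nodes first receive a self-loop (diagonal 1), which preserves total mass
#' without redirecting flow through the rest of the graph.
#'
#' @param graph A `vw_ppigraph`.
#' @return Sparse column-stochastic matrix (`dgCMatrix`) over the graph's
#'   node ordering.
#' @export
transition_matrix <- function(graph) {
  stopifnot(inherits(graph, "vw_ppigraph"))
  A <- graph$adjacency
  deg <- Matrix::colSums(A)
  isolated <- deg == 0
  if (any(isolated)) {
    A <- A + Matrix::Diagonal(n = nrow(A), x = as.numeric(isolated))
    deg[isolated] <- 1
  }
  Ap <- methods::as(A %*% Matrix::Diagonal(x = 1 / deg), "CsparseMatrix")
  dimnames(Ap) <- dimnames(graph$adjacency)
  Ap
}

#' Node degrees of a PPI graph
#' @param graph A `vw_ppigraph`.
#' @return Named integer vector of node degrees (self-loops excluded).
#' @export
node_degrees <- function(graph) {
  stopifnot(inherits(graph, "vw_ppigraph"))
  stats::setNames(as.integer(Matrix::colSums(graph$adjacency)), graph$nodes)
}

#' @export
print.vw_ppigraph <- function(x, ...) {
  cat(sprintf("<PPI graph: %d nodes, %d edges, %d isolates>\n",
              length(x$nodes), x$n_edges,
              sum(Matrix::colSums(x$adjacency) == 0)))
  invisible(x)
}
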