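#' Construct a weighted protein-protein interaction graph
#'
#' Builds an undirected, confidence-weighted gene network from an edge table.
#' Edge weights are interpreted as interaction confidence scores in
#' \eqn{[0, 1]} (the STRING convention after rescaling). Duplicate or
#' reciprocal edges are collapsed keeping the maximum weight; node order is
#' first-appearance order and is preserved through all downstream vectors and
#' matrices.
#'
#' @param edges data frame with columns \code{from}, \code{to}, \code{weight}
#'   (character, character, numeric in \eqn{[0,1]}).
#' @param nodes optional character vector fixing the node set and order;
#'   defaults to first-appearance order over the edge rows. May include
#'   isolated genes.
#' @return An object of class \code{ppi_graph}: a list with \code{nodes}
#'   (character) and \code{edges} (data frame \code{from}, \code{to},
#'   \code{weight}, one row per unordered pair).
#' @seealso [read_edge_list()], [transition_matrix()]
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "weight") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- as.numeric(edges$weight)
  if (anyNA(weight)) stop("edge weights contain NA")
  if (any(weight < 0 | weight > 1)) {
    bad <- which(weight < 0 | weight > 1)[1L]
    stop(sprintf("edge weight %.6g outside [0, 1] (edge %s -- %s)",
                 weight[bad], from[bad], to[bad]))
  }
  if (is.null(nodes)) {
    nodes <- unique(as.vector(rbind(from, to)))  # first-appearance order
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicated node identifiers")
    missing <- setdiff(unique(c(from, to)), nodes)
    if (length(missing) > 0)
      stop("edge endpoints not in node list: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  # canonical unordered pair, max-merge duplicates
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  if (any(!keep)) {
    wmax <- tapply(weight, key, max)
    weight <- as.numeric(wmax[key[keep]])
    a <- a[keep]; b <- b[keep]
  } else {
    weight <- weight
  }
  g <- list(nodes = nodes,
            edges = data.frame(from = a, to = b, weight = weight,
                               stringsAsFactors = FALSE))
  class(g) <- "ppi_graph"
  g
}

#' Read a STRING-style weighted edge list
#'
#' Parses a whitespace/tab-delimited file of \code{geneA geneB score} rows.
#' Lines starting with \code{#} are ignored; a header row is auto-detected by
#' a non-numeric third column. STRING distributes integer combined scores in
#' 0--1000, so the default \code{score_scale = "string_1000"} divides raw
#' scores by 1000; use \code{"unit"} for files already on \eqn{[0,1]}.
#'
#' @param path path to the edge-list file.
#' @param score_scale \code{"string_1000"} (default, divide by 1000) or
#'   \code{"unit"} (use scores as-is).
#' @param min_score optional minimum confidence (on the unit scale) below
#'   which edges are dropped.
#' @return a [ppi_graph()] object.
#' @export
read_edge_list <- function(path, score_scale = c("string_1000", "unit"),
                           min_score = 0) {
  score_scale <- match.arg(score_scale)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("no edge rows in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nfield <- lengths(fields)
  if (any(nfield != 3)) {
    bad <- which(nfield != 3)[1L]
    stop(sprintf("malformed edge row at line %d of %s: expected 3 columns, found %d",
                 lineno[bad], path, nfield[bad]))
  }
  m <- do.call(rbind, fields)
  score_chr <- m[, 3]
  # header: non-numeric third column in the first row, numeric in the next
  if (is.na(suppressWarnings(as.numeric(score_chr[1]))) &&
      length(score_chr) > 1 &&
      !is.na(suppressWarnings(as.numeric(score_chr[2])))) {
    m <- m[-1, , drop = FALSE]
    lineno <- lineno[-1]
    score_chr <- m[, 3]
  }
  score <- suppressWarnings(as.numeric(score_chr))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1L]
    stop(sprintf("non-numeric score at line %d of %s: '%s'",
                 lineno[bad], path, score_chr[bad]))
  }
  if (score_scale == "string_1000") score <- score / 1000
  if (any(score < 0 | score > 1)) {
    bad <- which(score < 0 | score > 1)[1L]
    stop(sprintf("score %.6g at line %d of %s outside [0, 1] after scaling",
                 score[bad], lineno[bad], path))
  }
  keep <- score >= min_score
  ppi_graph(data.frame(from = m[keep, 1], to = m[keep, 2],
                       weight = score[keep], stringsAsFactors = FALSE))
}

#' Write a graph as a canonical unit-scale edge list
#'
#' @param g a [ppi_graph()] object.
#' @param path output TSV path (columns gene1, gene2, weight; no header).
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "ppi_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Row-stochastic transition matrix of a weighted graph
#'
#' Computes \eqn{A = D^{-1} W} where \eqn{W} is the symmetric weight matrix
#' and \eqn{D} the diagonal degree matrix with \eqn{d_{ii} = \sum_j w_{ij}}.
#' Every retained row sums to one. Isolated nodes (degree zero) either
#' receive a unit self-loop (\code{"self_loop"}, default, so that every gene
#' keeps an entry in downstream probability vectors) or are dropped with a
#' record of the removal (\code{"drop"}).
#'
#' @param g a [ppi_graph()] object.
#' @param isolated_policy \code{"self_loop"} or \code{"drop"}.
#' @return An object of class \code{transition_matrix}: list with \code{A}
#'   (sparse \code{dgCMatrix}, rows summing to 1), \code{nodes} (node order),
#'   and \code{dropped} (character vector of removed isolated nodes).
#' @export
transition_matrix <- function(g, isolated_policy = c("self_loop", "drop")) {
  stopifnot(inherits(g, "ppi_graph"))
  isolated_policy <- match.arg(isolated_policy)
  nodes <- g$nodes
  n <- length(nodes)
  if (n == 0) stop("empty graph")
  i <- match(g$edges$from, nodes)
  j <- match(g$edges$to, nodes)
  w <- g$edges$weight
  loop <- i == j
  W <- Matrix::sparseMatrix(
    i = c(i[!loop], j[!loop], i[loop]),
    j = c(j[!loop], i[!loop], j[loop]),
    x = c(w[!loop], w[!loop], w[loop]),
    dims = c(n, n))
  deg <- Matrix::rowSums(W)
  isolated <- deg == 0
  dropped <- character(0)
  if (any(isolated)) {
    if (isolated_policy == "self_loop") {
      idx <- which(isolated)
      W <- W + Matrix::sparseMatrix(i = idx, j = idx, x = rep(1, length(idx)),
                                    dims = c(n, n))
      deg[idx] <- 1
    } else {
      dropped <- nodes[isolated]
      if (all(isolated)) stop("drop policy would remove every node")
      W <- W[!isolated, !isolated, drop = FALSE]
      nodes <- nodes[!isolated]
      deg <- deg[!isolated]
    }
  }
  A <- Matrix::Diagonal(x = 1 / deg) %*% W
  A <- methods::as(A, "CsparseMatrix")
  dimnames(A) <- list(nodes, nodes)
  structure(list(A = A, nodes = nodes, dropped = dropped),
            class = "transition_matrix")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("ppi_graph: %d nodes, %d edges, weights in [%.3g, %.3g]\n",
              length(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) min(x$edges$weight) else NA,
              if (nrow(x$edges)) max(x$edges$weight) else NA))
  invisible(x)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d x %d, row-stochastic (%d isolated node(s) dropped)\n",
              nrow(x$A), ncol(x$A), length(x$dropped)))
  invisible(x)
}
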