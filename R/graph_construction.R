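#' Build a PPI adjacency matrix from a scored interaction table
#'
#' Keeps interactions whose confidence score is strictly greater than
#' `score_threshold` (default 300, on the 0-1000 combined-score scale used by
#' STRING-style tables); everything else, including pairs absent from the
#' table, gets adjacency 0. Edges touching proteins outside `node_index` are
#' dropped with a message. The result is symmetric and binary with a zero
#' diagonal; call [add_self_loops()] before normalization.
#'
#' @param edges Data frame with columns `protein1`, `protein2`, `score`.
#' @param node_index Ordered character vector of protein ids.
#' @param score_threshold Strict lower bound on the confidence score.
#' @return N x N symmetric binary `Matrix::sparseMatrix` with dimnames.
#' @export
build_ppi_adjacency <- function(edges, node_index, score_threshold = 300) {
  check_edge_table(edges)
  keep <- edges$score > score_threshold
  build_binary_adjacency(edges[keep, , drop = FALSE], node_index)
}

#' Build a sequence-similarity adjacency matrix from alignment hits
#'
#' Keeps hits whose e-value is strictly smaller than `evalue_threshold`
#' (default 1e-4). Hits are symmetrized by union: an edge is present if either
#' direction passes. Self-hits never create an off-diagonal edge.
#'
#' @param hits Data frame with columns `protein1` (query), `protein2`
#'   (subject), `score` (e-value).
#' @inheritParams build_ppi_adjacency
#' @param evalue_threshold Strict upper bound on the e-value.
#' @return N x N symmetric binary sparse matrix with dimnames.
#' @export
build_ssn_adjacency <- function(hits, node_index, evalue_threshold = 1e-4) {
  check_edge_table(hits)
  if (any(hits$score < 0))
    stop("negative e-values in similarity hits")
  keep <- hits$score < evalue_threshold
  build_binary_adjacency(hits[keep, , drop = FALSE], node_index)
}

check_edge_table <- function(edges) {
  need <- c("protein1", "protein2", "score")
  if (!is.data.frame(edges) || !all(need %in% names(edges)))
    stop("edge table needs columns protein1, protein2, score")
  bad <- which(is.na(edges$protein1) | is.na(edges$protein2) |
                 !is.finite(edges$score))
  if (length(bad))
    stop("malformed edge rows at lines: ",
         paste(utils::head(bad, 5), collapse = ", "))
  invisible(edges)
}

build_binary_adjacency <- function(edges, node_index) {
  n <- length(node_index)
  i <- match(edges$protein1, node_index)
  j <- match(edges$protein2, node_index)
  outside <- is.na(i) | is.na(j)
  if (any(outside))
    message(sum(outside), " edge(s) dropped: proteins outside the node index")
  i <- i[!outside]; j <- j[!outside]
  self <- i == j
  i <- i[!self]; j <- j[!self]
  a <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                            dims = c(n, n), dimnames = list(node_index, node_index))
  # duplicate entries accumulate; clamp back to binary
  a@x[] <- 1
  Matrix::drop0(a)
}

#' Intersect node sets onto one shared ordered protein index
#'
#' Only proteins present in every source (both networks and the attribute
#' table) are kept; counts removed from each source are reported.
#'
#' @param ... Two or more character vectors of protein ids.
#' @return Sorted character vector, the shared index.
#' @export
align_node_sets <- function(...) {
  sets <- lapply(list(...), unique)
  stopifnot(length(sets) >= 2L)
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0L)
    stop("node sets have empty intersection")
  removed <- vapply(sets, function(s) length(setdiff(s, shared)), integer(1))
  if (any(removed > 0))
    message("align_node_sets: removed ",
            paste(removed, collapse = "/"), " ids from the input sets")
  sort(shared, method = "radix")
}

#' Add self-loops to an adjacency matrix
#'
#' Sets the diagonal to one (A + I clamped to binary); idempotent.
#'
#' @param a Symmetric binary adjacency matrix.
#' @return The matrix with unit diagonal.
#' @export
add_self_loops <- function(a) {
  Matrix::diag(a) <- 1
  a
}

#' Symmetrically normalized adjacency
#'
#' Computes `D^(-1/2) A D^(-1/2)` where `D` is the diagonal degree matrix of
#' `a`. Requires every node to have degree >= 1, which self-loops guarantee.
#' With `row_stochastic = TRUE` the row-normalized `D^-1 A` is returned
#' instead (not used by the default pipeline).
#'
#' @param a Symmetric adjacency with self-loops.
#' @param row_stochastic Use `D^-1 A` instead of the symmetric form.
#' @return Normalized matrix of the same dimension; attribute `degree` holds
#'   the degree vector.
#' @export
normalize_adjacency <- function(a, row_stochastic = FALSE) {
  deg <- Matrix::rowSums(a)
  if (any(deg <= 0))
    stop("zero-degree node found; add self-loops before normalizing")
  if (row_stochastic) {
    an <- Matrix::Diagonal(x = 1 / deg) %*% a
  } else {
    dhalf <- Matrix::Diagonal(x = 1 / sqrt(deg))
    an <- dhalf %*% a %*% dhalf
  }
  dimnames(an) <- dimnames(a)
  attr(an, "degree") <- deg
  an
}

#' Construct an attributed graph
#'
#' Bundles a binary adjacency (self-loops enforced), its symmetric
#' normalization, and a row-aligned node-attribute matrix over one protein
#' index.
#'
#' @param adjacency Symmetric binary adjacency over the protein index.
#' @param attributes Numeric attribute matrix with matching rownames (from
#'   [assemble_attributes()]).
#' @return An object of class `attributed_graph` with elements `node_index`,
#'   `adjacency` (with self-loops), `adj_norm`, `attributes`.
#' @export
attributed_graph <- function(adjacency, attributes) {
  stopifnot(nrow(adjacency) == ncol(adjacency),
            nrow(attributes) == nrow(adjacency))
  if (!is.null(rownames(adjacency)) && !is.null(rownames(attributes)) &&
      !identical(rownames(adjacency), rownames(attributes)))
    stop("adjacency and attribute row order differ")
  a <- add_self_loops(adjacency)
  structure(
    list(node_index = rownames(a),
         adjacency = a,
         adj_norm = normalize_adjacency(a),
         attributes = as.matrix(attributes)),
    class = "attributed_graph")
}

#' @export
#' @method print attributed_graph
print.attributed_graph <- function(x, ...) {
  nnz <- Matrix::nnzero(x$adjacency) - nrow(x$adjacency)  # off-diagonal
  cat("Attributed graph:", nrow(x$adjacency), "proteins,",
      nnz / 2, "edges,", ncol(x$attributes), "attributes\n")
  invisible(x)
}
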