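# GO DAG handling: a go_dag is a list(terms = data.frame(id, namespace, name),
# parents = named list id -> character vector of parent ids via is_a/part_of).

EXPERIMENTAL_EVIDENCE <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC")

#' Construct a GO DAG object
#'
#' @param terms Data frame with columns `id`, `namespace` (values among
#'   `"molecular_function"`, `"biological_process"`, `"cellular_component"`)
#'   and optionally `name`.
#' @param parents Named list mapping each term id to a character vector of
#'   parent ids (is_a and, conventionally, part_of relations).
#' @return Object of class `go_dag`.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("id", "namespace") %in% names(terms)))
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  dag <- structure(list(terms = terms, parents = parents), class = "go_dag")
  check_acyclic(dag)
  dag
}

#' @export
#' @method print go_dag
print.go_dag <- function(x, ...) {
  cat("GO DAG:", nrow(x$terms), "terms (",
    paste(names(table(x$terms$namespace)), table(x$terms$namespace),
          collapse = ", "), ")\n")
  invisible(x)
}

check_acyclic <- function(dag) {
  # Kahn-style peeling on the child -> parent relation
  ids <- dag$terms$id
  deg <- vapply(dag$parents, function(p) length(intersect(p, ids)), integer(1))
  active <- rep(TRUE, length(ids)); names(active) <- ids
  children <- split(
    rep(ids, lengths(dag$parents)),
    unlist(dag$parents, use.names = FALSE))
  queue <- ids[deg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) stop("cycle detected in the ontology DAG")
  invisible(TRUE)
}

#' All ancestors of each term in a GO DAG
#'
#' @param dag A [go_dag()].
#' @return Named list: term id -> character vector of all ancestor ids
#'   (excluding the term itself).
#' @export
term_ancestors <- function(dag) {
  memo <- new.env(parent = emptyenv())
  get_anc <- function(id) {
    if (exists(id, envir = memo, inherits = FALSE)) return(memo[[id]])
    ps <- intersect(dag$parents[[id]], dag$terms$id)
    anc <- unique(c(ps, unlist(lapply(ps, get_anc), use.names = FALSE)))
    memo[[id]] <- anc
    anc
  }
  out <- lapply(dag$terms$id, get_anc)
  names(out) <- dag$terms$id
  out
}

#' Filter annotations by evidence code
#'
#' Keeps only assignments backed by an experimental evidence code; the default
#' allowed set is EXP, IDA, IPI, IMP, IGI, IEP, TAS, IC. Matching is
#' case-sensitive. Applied before ancestor propagation: evidence attaches to
#' direct annotations only.
#'
#' @param annotations Data frame with columns `protein`, `term`, `evidence`.
#' @param allowed_codes Character vector of codes to keep.
#' @return The filtered data frame.
#' @export
filter_evidence <- function(annotations, allowed_codes = EXPERIMENTAL_EVIDENCE) {
  stopifnot(all(c("protein", "term", "evidence") %in% names(annotations)))
  annotations[annotations$evidence %in% allowed_codes, , drop = FALSE]
}

#' Propagate annotations to all ancestor terms (true-path rule)
#'
#' Replaces each protein's term set by its union with every ancestor of every
#' annotated term, so that annotation is upward-closed under the is_a/part_of
#' parent relation. Terms absent from the DAG are dropped with a warning.
#' Idempotent.
#'
#' @param annotations Data frame with columns `protein`, `term` (an
#'   `evidence` column, if present, is not propagated).
#' @param dag A [go_dag()].
#' @return Named list: protein -> sorted character vector of terms, with
#'   attribute `closed = TRUE`.
#' @export
propagate_ancestors <- function(annotations, dag) {
  stopifnot(all(c("protein", "term") %in% names(annotations)))
  unknown <- setdiff(unique(annotations$term), dag$terms$id)
  if (length(unknown)) {
    warning("dropping ", length(unknown), " annotation term(s) not in the DAG")
    annotations <- annotations[!(annotations$term %in% unknown), , drop = FALSE]
  }
  anc <- term_ancestors(dag)
  direct <- split(annotations$term, annotations$protein)
  closed <- lapply(direct, function(ts) {
    ts <- unique(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))), method = "radix")
  })
  attr(closed, "closed") <- TRUE
  closed
}

#' Select GO terms by namespace and annotation count
#'
#' Returns the terms of one namespace annotated (after closure) to between
#' `min_proteins` and `max_proteins` proteins inclusive, lexicographically
#' ordered. Namespace roots (terms with no parents) are excluded by default:
#' after closure they are positive for every annotated protein and carry no
#' signal.
#'
#' @param closed Closed annotation list from [propagate_ancestors()].
#' @param dag A [go_dag()].
#' @param namespace One of `"molecular_function"`, `"biological_process"`,
#'   `"cellular_component"`; `NULL` keeps all namespaces.
#' @param min_proteins,max_proteins Inclusive bounds on the per-term protein
#'   count. The default lower bound 11 matches the smallest term stratum
#'   commonly evaluated (11-30 proteins).
#' @param drop_roots Exclude parentless terms? Default `TRUE`.
#' @return Character vector of term ids.
#' @export
select_terms <- function(closed, dag, namespace = NULL,
                         min_proteins = 11L, max_proteins = Inf,
                         drop_roots = TRUE) {
  stopifnot(isTRUE(attr(closed, "closed")))
  counts <- table(unlist(closed, use.names = FALSE))
  ids <- dag$terms$id
  if (!is.null(namespace))
    ids <- ids[dag$terms$namespace == namespace]
  if (drop_roots)
    ids <- ids[lengths(dag$parents[ids]) > 0L]
  ids <- ids[ids %in% names(counts)]
  n <- as.integer(counts[ids])
  sort(ids[n >= min_proteins & n <= max_proteins], method = "radix")
}

#' Binary protein-by-term label matrix
#'
#' @param closed Closed annotation list from [propagate_ancestors()].
#' @param term_index Ordered character vector of GO term ids (columns).
#' @param protein_index Ordered character vector of protein ids (rows); every
#'   id must be known (unannotated proteins are allowed if listed in
#'   `closed` with an empty set, or absent -- absence means an all-zero row
#'   only when `allow_unannotated = TRUE`).
#' @param allow_unannotated Give proteins missing from `closed` all-zero rows
#'   instead of erroring. Default `FALSE`.
#' @return Binary integer matrix with dimnames.
#' @export
build_label_matrix <- function(closed, term_index, protein_index,
                               allow_unannotated = FALSE) {
  stopifnot(isTRUE(attr(closed, "closed")))
  missing <- setdiff(protein_index, names(closed))
  if (length(missing) && !allow_unannotated)
    stop("proteins without annotation entry: ",
         paste(utils::head(missing, 5), collapse = ", "))
  y <- matrix(0L, nrow = length(protein_index), ncol = length(term_index),
              dimnames = list(protein_index, term_index))
  for (p in intersect(protein_index, names(closed))) {
    hits <- intersect(closed[[p]], term_index)
    y[p, hits] <- 1L
  }
  y
}
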