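#' Conjoint-triad amino-acid class map
#'
#' The 20 standard amino acids grouped into 7 physicochemical classes (by
#' dipole and side-chain volume), as used by the conjoint-triad (CT) sequence
#' encoding. Returned as a named integer vector mapping one-letter codes to
#' class indices 1..7. Pass a modified copy to [ct_encode()] to use an
#' alternative partition.
#'
#' @return Named integer vector of length 20 (values in 1..7).
#' @export
#' @examples
#' ct_class_map()[c("A", "C", "R")]
ct_class_map <- function() {
  c(A = 1L, G = 1L, V = 1L,
    I = 2L, L = 2L, F = 2L, P = 2L,
    Y = 3L, M = 3L, T = 3L, S = 3L,
    H = 4L, N = 4L, Q = 4L, W = 4L,
    R = 5L, K = 5L,
    D = 6L, E = 6L,
    C = 7L)
}

# letters that make a sequence unusable for CT encoding
AMBIGUOUS_AA <- c("B", "O", "J", "U", "X", "Z")

#' Check a protein sequence for ambiguous amino-acid letters
#'
#' Proteins whose sequence contains any of the ambiguous or non-standard
#' letters B, O, J, U, X, Z cannot be conjoint-triad encoded and are dropped
#' from the dataset.
#'
#' @param sequence Character scalar, an amino-acid sequence (upper case).
#' @return `TRUE` if the sequence contains only the 20 standard letters.
#' @export
#' @examples
#' validate_sequence("MKT")  # TRUE
#' validate_sequence("MKX")  # FALSE
validate_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  !grepl(paste0("[", paste(AMBIGUOUS_AA, collapse = ""), "]"), sequence)
}

#' Conjoint-triad (CT) encoding of a protein sequence
#'
#' Maps the 20 amino acids onto 7 classes and counts every ordered triad of
#' consecutive residues, giving a fixed vector of length 7^3 = 343. Entry
#' `idx(c1, c2, c3) = (c1-1)*49 + (c2-1)*7 + c3` holds the occurrence count of
#' class triad (c1, c2, c3); the counts over a sequence of length L sum to
#' L - 2. Counts are raw occurrence numbers by default; set
#' `normalize = TRUE` to divide by the window count.
#'
#' @param sequence Amino-acid sequence (length >= 3, standard letters only).
#' @param class_map Named integer vector mapping residues to classes 1..7;
#'   defaults to [ct_class_map()].
#' @param normalize Divide counts by `L - 2`? Default `FALSE`.
#' @return Numeric vector of length 343 with names `"c1.c2.c3"`.
#' @export
#' @examples
#' sum(ct_encode("MKTAYIAK"))  # 6 windows
ct_encode <- function(sequence, class_map = ct_class_map(), normalize = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!validate_sequence(sequence))
    stop("sequence contains ambiguous amino acids (one of ",
         paste(AMBIGUOUS_AA, collapse = ", "), ")")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(aa) < 3L)
    stop("sequence must have length >= 3 for triad encoding")
  cls <- unname(class_map[aa])
  if (anyNA(cls))
    stop("sequence contains letters outside the class map: ",
         paste(unique(aa[is.na(cls)]), collapse = ", "))
  n <- length(cls)
  idx <- (cls[1:(n - 2)] - 1L) * 49L + (cls[2:(n - 1)] - 1L) * 7L + cls[3:n]
  counts <- tabulate(idx, nbins = 343L)
  if (normalize) counts <- counts / (n - 2L)
  names(counts) <- ct_feature_names()
  counts
}

ct_feature_names <- function() {
  g <- expand.grid(c3 = 1:7, c2 = 1:7, c1 = 1:7)
  paste(g$c1, g$c2, g$c3, sep = ".")
}

#' Build a term vocabulary from per-protein term sets
#'
#' Keeps terms carried by strictly more than `min_occurrences` proteins, in
#' lexicographic order. The default threshold 0 keeps everything (used for
#' subcellular locations); domain vocabularies use `min_occurrences = 5`, i.e.
#' a domain must appear more than 5 times in the dataset to be retained.
#'
#' @param term_sets List of character vectors, one per protein.
#' @param min_occurrences Strict lower bound on the number of proteins
#'   carrying a term.
#' @return Character vector of retained terms, sorted.
#' @export
build_vocabulary <- function(term_sets, min_occurrences = 0L) {
  stopifnot(is.list(term_sets), min_occurrences >= 0)
  if (length(term_sets) == 0L) return(character(0))
  counts <- table(unlist(lapply(term_sets, unique), use.names = FALSE))
  keep <- names(counts)[counts > min_occurrences]
  sort(keep, method = "radix")
}

#' Bag-of-words encoding over a fixed vocabulary
#'
#' @param terms Character vector of terms carried by one protein (duplicates
#'   and out-of-vocabulary terms are ignored).
#' @param vocabulary Ordered character vector fixed before encoding.
#' @return Binary integer vector of `length(vocabulary)`, named by term.
#' @export
bow_encode <- function(terms, vocabulary) {
  stopifnot(is.character(vocabulary))
  bits <- as.integer(vocabulary %in% terms)
  names(bits) <- vocabulary
  bits
}

#' Standardize attribute columns
#'
#' Centers and scales each attribute column to zero mean and unit variance
#' (constant columns become all-zero). Mixed attribute blocks put raw triad
#' counts (magnitudes up to sequence length) next to binary indicator bits;
#' standardizing puts the blocks on one scale before the graph encoder so no
#' block dominates the first-layer pre-activations.
#'
#' @param x Numeric attribute matrix.
#' @return Matrix of the same shape (dimnames and `column_blocks` kept).
#' @export
standardize_attributes <- function(x) {
  blocks <- attr(x, "column_blocks")
  s <- scale(x)
  s[, attr(s, "scaled:scale") == 0] <- 0
  out <- matrix(as.numeric(s), nrow(x), ncol(x), dimnames = dimnames(x))
  attr(out, "column_blocks") <- blocks
  out
}

#' Assemble the node-attribute matrix
#'
#' Concatenates per-protein feature blocks row-wise into the N x R attribute
#' matrix: conjoint-triad sequence counts (optional), subcellular-location
#' bag-of-words, and protein-domain bag-of-words. The sequence block is
#' omitted for the sequence-similarity network, whose edges already encode
#' sequence information.
#'
#' @param records List of protein records, each a list with elements `id`,
#'   `sequence`, `locations`, `domains`.
#' @param protein_index Ordered character vector of protein ids defining row
#'   order.
#' @param location_vocab,domain_vocab Vocabularies from [build_vocabulary()].
#' @param include_sequence Include the 343-column CT block? Default `TRUE`.
#' @param class_map CT class map, see [ct_encode()].
#' @return Numeric matrix with rownames `protein_index` and attribute
#'   `column_blocks`, a named list giving the column span of each block.
#' @export
assemble_attributes <- function(records, protein_index,
                                location_vocab = character(0),
                                domain_vocab = character(0),
                                include_sequence = TRUE,
                                class_map = ct_class_map()) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate protein ids in records")
  missing <- setdiff(protein_index, ids)
  if (length(missing))
    stop("records missing for proteins: ", paste(missing, collapse = ", "))
  records <- records[match(protein_index, ids)]

  # rbind keeps n x k orientation for every k, including 0 and 1
  row_block <- function(fun, width) {
    rows <- lapply(records, fun)
    if (length(rows) == 0L) return(matrix(0, 0L, width))
    do.call(rbind, rows)
  }
  blocks <- list()
  if (include_sequence) {
    blocks$sequence <- row_block(
      function(r) ct_encode(r$sequence, class_map = class_map), 343L)
  }
  blocks$location <- row_block(
    function(r) as.numeric(bow_encode(r$locations, location_vocab)),
    length(location_vocab))
  blocks$domain <- row_block(
    function(r) as.numeric(bow_encode(r$domains, domain_vocab)),
    length(domain_vocab))

  x <- do.call(cbind, blocks)
  rownames(x) <- protein_index
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  attr(x, "column_blocks") <- Map(function(s, e) c(start = s, end = e),
                                  starts, ends)
  x
}
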