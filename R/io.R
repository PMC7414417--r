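# Readers and writers for the standard input formats. All tabular readers
# are thin wrappers over read.delim with column checking; FASTA goes through
# Biostrings.

#' Read a STRING-style interaction table
#'
#' Expects tab-separated columns `protein1`, `protein2`, `combined_score`
#' (header required, extra columns ignored).
#'
#' @param path File path.
#' @return Data frame with columns `protein1`, `protein2`, `score`.
#' @export
read_interactions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(d)))
    stop("interaction table must have columns ", paste(need, collapse = ", "))
  data.frame(protein1 = as.character(d$protein1),
             protein2 = as.character(d$protein2),
             score = as.numeric(d$combined_score),
             stringsAsFactors = FALSE)
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Standard 12-column headerless tabular output; columns used are 1 (query),
#' 2 (subject), 3 (percent identity), 11 (e-value) and 12 (bit score).
#'
#' @param path File path.
#' @return Data frame with columns `protein1` (query), `protein2` (subject),
#'   `identity`, `score` (the e-value), `bitscore`.
#' @export
read_blast_hits <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12L)
    stop("BLAST tabular file must have 12 columns (outfmt 6)")
  data.frame(protein1 = as.character(d[[1]]),
             protein2 = as.character(d[[2]]),
             identity = as.numeric(d[[3]]),
             score = as.numeric(d[[11]]),
             bitscore = as.numeric(d[[12]]),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta_sequences <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path)
  invisible(path)
}

#' Read a two-column protein-to-term table
#'
#' Tab-separated with header `protein`, `term`; used for subcellular
#' locations and protein domains.
#'
#' @param path File path.
#' @return Named list: protein -> character vector of terms.
#' @export
read_term_map <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("protein", "term") %in% names(d)))
    stop("term table must have columns protein, term")
  if (nrow(d) == 0L) return(structure(list(), names = character(0)))
  split(d$term, d$protein)
}

#' Read GO annotations from a GAF-like table
#'
#' Tab-separated with header columns `protein`, `term`, `evidence`,
#' `namespace` (extra columns ignored; comment lines starting with `!`
#' skipped).
#'
#' @param path File path.
#' @return Data frame with those four columns.
#' @export
read_annotations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "!",
                         colClasses = "character")
  need <- c("protein", "term", "evidence", "namespace")
  if (!all(need %in% names(d)))
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  d[, need]
}

#' Read a GO DAG from an OBO file
#'
#' Minimal OBO 1.2 reader covering `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` and `relationship: part_of` tags; obsolete terms are
#' skipped. is_a and part_of parents are merged into one parent relation,
#' the standard traversal set for ancestor propagation.
#'
#' @param path OBO file path.
#' @param relations Relationship types (besides is_a) treated as parent
#'   links. Default `"part_of"`.
#' @return A [go_dag()].
#' @export
read_obo <- function(path, relations = "part_of") {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); ns <- character(0); nm <- character(0)
  parents <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    tagval <- function(tag) {
      v <- chunk[startsWith(chunk, paste0(tag, ": "))]
      sub("\\s*!.*$", "", substring(v, nchar(tag) + 3L))
    }
    if (length(tagval("is_obsolete")) && any(tagval("is_obsolete") == "true"))
      next
    id <- tagval("id")[1]
    if (is.na(id) || !length(id)) next
    p <- tagval("is_a")
    rel <- tagval("relationship")
    if (length(rel)) {
      relmat <- do.call(rbind, strsplit(rel, "\\s+"))
      p <- c(p, relmat[relmat[, 1] %in% relations, 2])
    }
    ids <- c(ids, id)
    ns <- c(ns, if (length(tagval("namespace"))) tagval("namespace")[1] else NA)
    nm <- c(nm, if (length(tagval("name"))) tagval("name")[1] else id)
    parents[[id]] <- unique(p)
  }
  go_dag(data.frame(id = ids, namespace = ns, name = nm,
                    stringsAsFactors = FALSE),
         parents)
}

#' Write a GO DAG to a minimal OBO file
#'
#' @param dag A [go_dag()].
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (k in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[k]
    writeLines(c("",
                 "[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[k]),
                 paste0("namespace: ", dag$terms$namespace[k]),
                 if (length(dag$parents[[id]]))
                   paste0("is_a: ", dag$parents[[id]])), con)
  }
  invisible(path)
}

#' Write an embedding matrix as TSV
#'
#' @param embedding Numeric matrix with protein rownames.
#' @param path Output path.
#' @export
write_embedding <- function(embedding, path) {
  d <- data.frame(protein = rownames(embedding), embedding,
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score matrix as long-format TSV
#'
#' One row per (protein, term) pair, sorted by descending probability within
#' each protein.
#'
#' @param scores Numeric matrix (proteins x terms) with dimnames.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  d <- data.frame(protein = rep(rownames(scores), each = ncol(scores)),
                  term = rep(colnames(scores), times = nrow(scores)),
                  probability = as.vector(t(scores)),
                  stringsAsFactors = FALSE)
  d <- d[order(d$protein, -d$probability), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
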