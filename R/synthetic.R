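# Seed-reproducible synthetic datasets with the structure the method assumes:
# two planted-partition networks over one protein set, attribute bits
# correlated with the planted communities, and hierarchy-closed multi-labels.
# Sequences are random; similarity e-values are sampled, not computed from
# the sequences -- the pipeline consumes a hit table, never an aligner.

#' Specification for a synthetic dataset
#'
#' @param n_proteins Number of proteins (default 200).
#' @param n_communities Number of planted communities (default 4, balanced).
#' @param ppi_p_in,ppi_p_out Within/between-community edge probabilities for
#'   the interaction network.
#' @param ssn_p_in,ssn_p_out Same for the sequence-similarity network.
#' @param attr_signal Probability an attribute bit follows its community
#'   prototype (default 0.9).
#' @param n_location_terms,n_domain_terms Sizes of the location and domain
#'   vocabular pools (defaults 12 and 30, plus a few rare domain terms that
#'   fall under the vocabulary threshold).
#' @param dag_branching Children per internal term in the three-level toy GO
#'   DAG built for each namespace (default 4: 1 root, 4 mid, 16 leaves).
#' @param label_signal Probability a leaf label follows the protein's
#'   community (default 0.9); off-community leaves are annotated with
#'   probability `1 - label_signal`.
#' @param seq_length_range Sequence length bounds (default 50-500).
#' @param seed Integer seed; the fixture is fully determined by it.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 200L, n_communities = 4L,
                         ppi_p_in = 0.5, ppi_p_out = 0.005,
                         ssn_p_in = 0.4, ssn_p_out = 0.005,
                         attr_signal = 0.9,
                         n_location_terms = 12L, n_domain_terms = 30L,
                         dag_branching = 4L, label_signal = 0.9,
                         seq_length_range = c(50L, 500L), seed = 1L) {
  spec <- as.list(environment())
  if (ppi_p_in <= ppi_p_out || ssn_p_in <= ssn_p_out)
    stop("infeasible spec: within-community edge probability must exceed ",
         "the between-community probability")
  stopifnot(attr_signal >= 0, attr_signal <= 1,
            label_signal >= 0, label_signal <= 1)
  structure(spec, class = "fixture_spec")
}

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GO_NAMESPACES <- c(MF = "molecular_function", BP = "biological_process",
                   CC = "cellular_component")

#' Generate a synthetic dataset
#'
#' Produces everything the pipeline ingests: a scored interaction table
#' (community edges scored above the 300 confidence threshold, plus
#' low-confidence noise rows below it), a similarity hit table (community
#' hits below the 1e-4 e-value threshold, plus non-significant noise hits),
#' protein records with random sequences and community-correlated
#' location/domain term sets, a three-level toy GO DAG per namespace, and
#' direct GO annotations (mostly experimental evidence codes, some
#' electronic ones for the filter to drop) whose leaf terms follow the
#' planted communities.
#'
#' @param spec A [fixture_spec()].
#' @return Object of class `go_fixture`: list with `spec`, `communities`
#'   (named integer vector), `records`, `ppi_edges`, `ssn_hits`, `dag`,
#'   `annotations`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  comm <- rep_len(seq_len(spec$n_communities), n)
  names(comm) <- ids

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- comm[pairs[, 1]] == comm[pairs[, 2]]

  sample_network <- function(p_in, p_out) {
    p <- ifelse(same, p_in, p_out)
    pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  }

  ppi_idx <- sample_network(spec$ppi_p_in, spec$ppi_p_out)
  ppi_edges <- data.frame(
    protein1 = ids[ppi_idx[, 1]], protein2 = ids[ppi_idx[, 2]],
    score = round(stats::runif(nrow(ppi_idx), 400, 999)),
    stringsAsFactors = FALSE)
  # sub-threshold noise interactions the builder must drop
  n_noise <- if (nrow(pairs)) max(1L, round(0.1 * nrow(ppi_idx))) else 0L
  noise_idx <- pairs[sample.int(nrow(pairs), n_noise), , drop = FALSE]
  ppi_edges <- rbind(ppi_edges, data.frame(
    protein1 = ids[noise_idx[, 1]], protein2 = ids[noise_idx[, 2]],
    score = round(stats::runif(n_noise, 50, 300)),
    stringsAsFactors = FALSE))

  ssn_idx <- sample_network(spec$ssn_p_in, spec$ssn_p_out)
  ssn_hits <- data.frame(
    protein1 = ids[ssn_idx[, 1]], protein2 = ids[ssn_idx[, 2]],
    identity = round(stats::runif(nrow(ssn_idx), 30, 90), 1),
    score = 10^(-stats::runif(nrow(ssn_idx), 5, 30)),
    bitscore = round(stats::runif(nrow(ssn_idx), 80, 500), 1),
    stringsAsFactors = FALSE)
  n_noise <- if (nrow(pairs)) max(1L, round(0.1 * nrow(ssn_idx))) else 0L
  noise_idx <- pairs[sample.int(nrow(pairs), n_noise), , drop = FALSE]
  ssn_hits <- rbind(ssn_hits, data.frame(
    protein1 = ids[noise_idx[, 1]], protein2 = ids[noise_idx[, 2]],
    identity = round(stats::runif(n_noise, 20, 40), 1),
    score = 10^(-stats::runif(n_noise, 0, 3.5)),
    bitscore = round(stats::runif(n_noise, 30, 80), 1),
    stringsAsFactors = FALSE))

  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(spec$seq_length_range[1]:spec$seq_length_range[2], 1)
    paste(sample(STANDARD_AA, len, replace = TRUE), collapse = "")
  }, character(1))

  draw_terms <- function(n_terms, prefix) {
    terms <- sprintf("%s%03d", prefix, seq_len(n_terms))
    proto <- matrix(stats::runif(spec$n_communities * n_terms) < 0.5,
                    spec$n_communities, n_terms)
    sets <- lapply(seq_len(n), function(i) {
      follow <- stats::runif(n_terms) < spec$attr_signal
      bits <- ifelse(follow, proto[comm[i], ], !proto[comm[i], ])
      terms[bits]
    })
    sets
  }
  locations <- draw_terms(spec$n_location_terms, "LOC")
  domains <- draw_terms(spec$n_domain_terms, "PF")
  # rare domain terms below the vocabulary threshold
  if (n >= 5L) {
    for (r in 1:3) {
      carriers <- sample(n, sample(1:5, 1))
      for (i in carriers)
        domains[[i]] <- c(domains[[i]], sprintf("PFRARE%d", r))
    }
  }

  records <- lapply(seq_len(n), function(i)
    list(id = ids[i], sequence = seqs[i],
         locations = locations[[i]], domains = domains[[i]]))

  dag <- toy_go_dag(spec$dag_branching)
  leaf_rows <- dag$terms[dag$terms$is_leaf, ]
  ann <- list()
  for (ns in GO_NAMESPACES) {
    leaves <- leaf_rows$id[leaf_rows$namespace == ns]
    leaf_comm <- rep_len(seq_len(spec$n_communities), length(leaves))
    for (i in seq_len(n)) {
      p_ann <- ifelse(leaf_comm == comm[i],
                      spec$label_signal, 1 - spec$label_signal)
      hit <- leaves[stats::runif(length(leaves)) < p_ann]
      if (length(hit))
        ann[[length(ann) + 1L]] <- data.frame(
          protein = ids[i], term = hit, namespace = ns,
          stringsAsFactors = FALSE)
    }
  }
  annotations <- do.call(rbind, ann)
  if (is.null(annotations))
    annotations <- data.frame(protein = character(0), term = character(0),
                              namespace = character(0),
                              stringsAsFactors = FALSE)
  codes <- sample(EXPERIMENTAL_EVIDENCE, nrow(annotations), replace = TRUE)
  iea <- stats::runif(nrow(annotations)) < 0.1
  codes[iea] <- "IEA"
  annotations$evidence <- codes
  annotations <- annotations[, c("protein", "term", "evidence", "namespace")]

  structure(
    list(spec = spec, communities = comm, records = records,
         ppi_edges = ppi_edges, ssn_hits = ssn_hits,
         dag = dag, annotations = annotations),
    class = "go_fixture")
}

# three-level DAG per namespace: root -> branching mid terms -> branching^2
# leaves; each mid/leaf has one is_a parent plus (for diamond structure) a
# second parent for every fourth leaf
toy_go_dag <- function(branching = 4L) {
  terms <- list(); parents <- list()
  for (k in seq_along(GO_NAMESPACES)) {
    ns <- GO_NAMESPACES[[k]]
    code <- names(GO_NAMESPACES)[k]
    root <- sprintf("GO:%s0000", code)
    mids <- sprintf("GO:%s1%03d", code, seq_len(branching))
    leaves <- sprintf("GO:%s2%03d", code, seq_len(branching^2))
    terms[[k]] <- data.frame(
      id = c(root, mids, leaves),
      namespace = ns,
      name = c(paste(ns, "root"), paste0("mid ", seq_along(mids)),
               paste0("leaf ", seq_along(leaves))),
      is_leaf = c(FALSE, rep(FALSE, length(mids)), rep(TRUE, length(leaves))),
      stringsAsFactors = FALSE)
    parents[[root]] <- character(0)
    for (m in seq_along(mids)) parents[[mids[m]]] <- root
    for (l in seq_along(leaves)) {
      p <- mids[((l - 1L) %/% branching) + 1L]
      extra <- if (l %% 4L == 0L) mids[(l %% branching) + 1L] else NULL
      parents[[leaves[l]]] <- unique(c(p, extra))
    }
  }
  all_terms <- do.call(rbind, terms)
  dag <- go_dag(all_terms[, c("id", "namespace", "name")], parents)
  dag$terms$is_leaf <- all_terms$is_leaf
  dag
}

#' Write a synthetic dataset to standard file formats
#'
#' Emits the files the package readers consume: `sequences.fasta`,
#' `ppi.tsv` (protein1/protein2/combined_score), `ssn_hits.tsv` (12-column
#' BLAST tabular, no header), `locations.tsv` and `domains.tsv`
#' (protein/term), `go.obo`, and `annotations.tsv`
#' (protein/term/evidence/namespace).
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "go_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(fixture$records, `[[`, character(1), "id")
  seqs <- vapply(fixture$records, `[[`, character(1), "sequence")
  names(seqs) <- ids
  write_fasta_sequences(seqs, file.path(dir, "sequences.fasta"))

  ppi <- fixture$ppi_edges
  utils::write.table(
    data.frame(protein1 = ppi$protein1, protein2 = ppi$protein2,
               combined_score = ppi$score),
    file.path(dir, "ppi.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  h <- fixture$ssn_hits
  filler <- rep(list(integer(nrow(h))), 7)
  if (nrow(h)) filler <- list(100L, 10L, 1L, 1L, 100L, 1L, 100L)
  blast <- data.frame(c(list(h$protein1, h$protein2, h$identity), filler,
                        list(sprintf("%.17g", h$score), h$bitscore)))
  utils::write.table(blast, file.path(dir, "ssn_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  term_df <- function(field) {
    rows <- lapply(fixture$records, function(r)
      if (length(r[[field]]))
        data.frame(protein = r$id, term = r[[field]],
                   stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(protein = character(0), term = character(0))
    out
  }
  utils::write.table(term_df("locations"), file.path(dir, "locations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(term_df("domains"), file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  write_obo(fixture$dag, file.path(dir, "go.obo"))
  utils::write.table(fixture$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
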