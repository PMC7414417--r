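# End-to-end orchestration: encode attributes, build and normalize both
# networks, train the two VGAEs, concatenate embeddings, train one classifier
# per GO namespace on an 80/20 split, evaluate, and report.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. The embedding stage is
#' transductive: both VGAEs are trained unsupervised on all proteins before
#' the supervised split, and only the classifier respects the train/test
#' partition.
#'
#' @param ppi_score_threshold Strict confidence-score cutoff for interaction
#'   edges (default 300).
#' @param ssn_evalue_threshold Strict e-value cutoff for similarity edges
#'   (default 1e-4).
#' @param domain_min_occurrences Vocabulary cutoff: a domain term must appear
#'   strictly more often than this (default 5).
#' @param location_min_occurrences Same for locations (default 0: keep all).
#' @param vgae List of arguments passed to [vgae()] for both networks
#'   (hidden, latent, epochs, learning_rate).
#' @param classifier List of arguments passed to [mlp_classifier()].
#' @param test_fraction Held-out fraction of proteins for the supervised
#'   split (default 0.2).
#' @param min_term_proteins Minimum (closed) annotation count for a term to
#'   become a classifier label (default 11).
#' @param standardize_attributes Standardize attribute columns before the
#'   graph encoder (default `TRUE`; see [standardize_attributes()]).
#' @param namespaces GO namespaces to model (default all three).
#' @param thresholds Threshold grid for [fmax()].
#' @param seed Global seed; per-stage seeds are derived from it by hashing
#'   the stage name, so each stage is independently reproducible.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ppi_score_threshold = 300,
                            ssn_evalue_threshold = 1e-4,
                            domain_min_occurrences = 5L,
                            location_min_occurrences = 0L,
                            vgae = list(hidden = 800L, latent = 400L,
                                        epochs = 200L, learning_rate = 0.001),
                            classifier = list(hidden = c(1024L, 512L, 256L),
                                              dropout = 0.3, epochs = 100L,
                                              learning_rate = 0.001),
                            test_fraction = 0.2,
                            min_term_proteins = 11L,
                            standardize_attributes = TRUE,
                            namespaces = unname(GO_NAMESPACES),
                            thresholds = seq(0, 1, by = 0.01),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 7919L +
     sum(utf8ToInt(stage)) * 131L) %% .Machine$integer.max
}

#' Read pipeline inputs from files
#'
#' @param dir Directory holding `sequences.fasta`, `ppi.tsv`, `ssn_hits.tsv`,
#'   `locations.tsv`, `domains.tsv`, `go.obo`, `annotations.tsv` (the layout
#'   written by [write_fixture()]).
#' @return List with `records`, `ppi_edges`, `ssn_hits`, `dag`,
#'   `annotations`, shaped like a [generate_fixture()] result.
#' @export
read_pipeline_inputs <- function(dir) {
  paths <- file.path(dir, c("sequences.fasta", "ppi.tsv", "ssn_hits.tsv",
                            "locations.tsv", "domains.tsv", "go.obo",
                            "annotations.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(basename(missing), collapse = ", "))
  seqs <- read_fasta_sequences(paths[1])
  locs <- read_term_map(paths[4])
  doms <- read_term_map(paths[5])
  records <- lapply(names(seqs), function(id)
    list(id = id, sequence = unname(seqs[[id]]),
         locations = if (is.null(locs[[id]])) character(0) else locs[[id]],
         domains = if (is.null(doms[[id]])) character(0) else doms[[id]]))
  list(records = records,
       ppi_edges = read_interactions(paths[2]),
       ssn_hits = read_blast_hits(paths[3]),
       dag = read_obo(paths[6]),
       annotations = read_annotations(paths[7]))
}

#' Run the full function-prediction pipeline
#'
#' Stages: validate sequences and drop proteins with ambiguous letters;
#' align the node sets; build vocabularies and attribute matrices (the
#' similarity network never receives the sequence block); threshold both
#' networks into binary adjacencies; train one VGAE per network on all
#' proteins; concatenate the latent means; split proteins 80/20; per GO
#' namespace, filter annotations to experimental evidence, propagate to
#' ancestors, select label terms, train the classifier on the training rows
#' and evaluate on the held-out rows.
#'
#' @param data A [generate_fixture()] result or the list returned by
#'   [read_pipeline_inputs()].
#' @param config A [pipeline_config()].
#' @param networks Which networks feed the embedding: `"combined"` (default),
#'   `"ppi"`, or `"ssn"`.
#' @param attributes Which attribute blocks to use: `"ALL"` (default) or a
#'   subset of `c("sequence", "location", "domain")`. The sequence block is
#'   always excluded from the similarity network.
#' @param shuffled_control Also evaluate a control classifier trained on
#'   row-shuffled embeddings (default `FALSE`).
#' @param out_dir Optional directory for embeddings, scores, metric reports
#'   and the run manifest.
#' @param verbose Print stage progress.
#' @return Object of class `pipeline_result`: list with `embedding`,
#'   `evaluations` (per namespace [evaluate_predictions()] summaries),
#'   `scores`, `labels`, `split`, `vgae_fits`, `control_evaluations` (when
#'   requested), and `manifest`.
#' @export
run_pipeline <- function(data, config = pipeline_config(),
                         networks = c("combined", "ppi", "ssn"),
                         attributes = "ALL",
                         shuffled_control = FALSE,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  networks <- match.arg(networks)
  if (identical(attributes, "ALL"))
    attributes <- c("sequence", "location", "domain")
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%T"),
                                            "] ", ...)

  emb <- embed_networks(data, config, networks, attributes, verbose = verbose)
  say("embedding: ", nrow(emb$embedding), " proteins x ",
      ncol(emb$embedding), " dims")

  res <- classify_and_evaluate(emb$embedding, data, config,
                               shuffled_control = shuffled_control,
                               verbose = verbose)

  manifest <- list(config = unclass(config), networks = networks,
                   attributes = attributes,
                   n_proteins = nrow(emb$embedding),
                   stage_seeds = emb$stage_seeds)
  out <- structure(c(list(embedding = emb$embedding,
                          vgae_fits = emb$fits, manifest = manifest),
                     res),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# build both attributed graphs and train the VGAE(s); returns the
# concatenated embedding
embed_networks <- function(data, config, networks, attributes,
                           verbose = FALSE) {
  records <- Filter(function(r) validate_sequence(r$sequence), data$records)
  if (length(records) < length(data$records))
    message(length(data$records) - length(records),
            " protein(s) dropped: ambiguous amino acids")
  rec_ids <- vapply(records, `[[`, character(1), "id")
  net_ids <- unique(c(data$ppi_edges$protein1, data$ppi_edges$protein2))
  index <- align_node_sets(rec_ids, net_ids)
  records <- records[match(index, rec_ids)]

  loc_vocab <- build_vocabulary(lapply(records, `[[`, "locations"),
                                config$location_min_occurrences)
  dom_vocab <- build_vocabulary(lapply(records, `[[`, "domains"),
                                config$domain_min_occurrences)
  block_args <- list(
    location_vocab = if ("location" %in% attributes) loc_vocab else character(0),
    domain_vocab = if ("domain" %in% attributes) dom_vocab else character(0))

  fits <- list()
  stage_seeds <- list()
  parts <- list()
  if (networks %in% c("combined", "ppi")) {
    x_ppi <- do.call(assemble_attributes, c(
      list(records = records, protein_index = index,
           include_sequence = "sequence" %in% attributes), block_args))
    if (ncol(x_ppi) == 0L) stop("empty attribute set for the PPI network")
    if (isTRUE(config$standardize_attributes))
      x_ppi <- standardize_attributes(x_ppi)
    a_ppi <- build_ppi_adjacency(data$ppi_edges, index,
                                 config$ppi_score_threshold)
    g_ppi <- attributed_graph(a_ppi, x_ppi)
    s <- stage_seed(config$seed, "vgae_ppi")
    stage_seeds$vgae_ppi <- s
    fits$ppi <- do.call(vgae, c(list(graph = g_ppi, seed = s,
                                     verbose = verbose), config$vgae))
    parts$ppi <- fits$ppi$mu
  }
  if (networks %in% c("combined", "ssn")) {
    # sequence is never a node attribute on the similarity network: its
    # edges already carry the sequence information
    x_ssn <- do.call(assemble_attributes, c(
      list(records = records, protein_index = index,
           include_sequence = FALSE), block_args))
    if (ncol(x_ssn) == 0L)
      stop("empty attribute set for the similarity network ",
           "(sequence-only attributes are not usable on the SSN)")
    if (isTRUE(config$standardize_attributes))
      x_ssn <- standardize_attributes(x_ssn)
    a_ssn <- build_ssn_adjacency(data$ssn_hits, index,
                                 config$ssn_evalue_threshold)
    g_ssn <- attributed_graph(a_ssn, x_ssn)
    s <- stage_seed(config$seed, "vgae_ssn")
    stage_seeds$vgae_ssn <- s
    fits$ssn <- do.call(vgae, c(list(graph = g_ssn, seed = s,
                                     verbose = verbose), config$vgae))
    parts$ssn <- fits$ssn$mu
  }
  embedding <- if (length(parts) == 2L)
    concat_embeddings(parts$ppi, parts$ssn)
  else parts[[1]]
  list(embedding = embedding, fits = fits, stage_seeds = stage_seeds)
}

# supervised stage: split, per-namespace classifier training and evaluation
classify_and_evaluate <- function(embedding, data, config,
                                  shuffled_control = FALSE,
                                  verbose = FALSE) {
  index <- rownames(embedding)
  ann <- filter_evidence(data$annotations)
  closed <- propagate_ancestors(ann, data$dag)

  set.seed(stage_seed(config$seed, "split"))
  n_test <- max(1L, round(config$test_fraction * length(index)))
  test_ids <- sort(sample(index, n_test))
  train_ids <- setdiff(index, test_ids)
  split <- list(train = train_ids, test = test_ids)

  evals <- list(); scores <- list(); labels <- list(); models <- list()
  ctrl_evals <- list()
  for (ns in config$namespaces) {
    terms <- select_terms(closed, data$dag, namespace = ns,
                          min_proteins = config$min_term_proteins)
    if (length(terms) == 0L) {
      warning("no label terms selected for namespace ", ns)
      next
    }
    y <- build_label_matrix(closed, terms, index, allow_unannotated = TRUE)
    s <- stage_seed(config$seed, paste0("classifier_", ns))
    fit <- do.call(mlp_classifier, c(
      list(x = embedding[train_ids, , drop = FALSE],
           y = y[train_ids, , drop = FALSE], seed = s),
      config$classifier))
    sc <- predict(fit, embedding[test_ids, , drop = FALSE])
    evals[[ns]] <- evaluate_predictions(sc, y[test_ids, , drop = FALSE],
                                        config$thresholds)
    scores[[ns]] <- sc
    labels[[ns]] <- y
    models[[ns]] <- fit
    if (verbose) message(ns, ": F-max ", round(evals[[ns]]$f_max, 3))

    if (shuffled_control) {
      set.seed(stage_seed(config$seed, paste0("shuffle_", ns)))
      shuffled <- embedding[sample(nrow(embedding)), , drop = FALSE]
      rownames(shuffled) <- index
      cfit <- do.call(mlp_classifier, c(
        list(x = shuffled[train_ids, , drop = FALSE],
             y = y[train_ids, , drop = FALSE], seed = s),
        config$classifier))
      csc <- predict(cfit, shuffled[test_ids, , drop = FALSE])
      ctrl_evals[[ns]] <- evaluate_predictions(
        csc, y[test_ids, , drop = FALSE], config$thresholds)
    }
  }
  out <- list(evaluations = evals, scores = scores, labels = labels,
              classifiers = models, split = split)
  if (shuffled_control) out$control_evaluations <- ctrl_evals
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_embedding(result$embedding, file.path(out_dir, "embedding.tsv"))
  for (ns in names(result$scores)) {
    tag <- names(GO_NAMESPACES)[match(ns, GO_NAMESPACES)]
    write_scores(result$scores[[ns]],
                 file.path(out_dir, paste0("scores_", tag, ".tsv")))
    ev <- result$evaluations[[ns]]
    jsonlite::write_json(
      list(f_max = ev$f_max, M_aupr = ev$M_aupr, m_aupr = ev$m_aupr,
           n_terms_evaluated = ev$n_terms_evaluated),
      file.path(out_dir, paste0("eval_", tag, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
#' @method print pipeline_result
print.pipeline_result <- function(x, ...) {
  cat("Function-prediction pipeline result\n")
  cat("  proteins:", nrow(x$embedding),
      " embedding dims:", ncol(x$embedding), "\n")
  for (ns in names(x$evaluations)) {
    ev <- x$evaluations[[ns]]
    cat(sprintf("  %-20s F-max %.3f  M-AUPR %.3f  m-AUPR %.3f (%d terms)\n",
                ns, ev$f_max, ev$M_aupr, ev$m_aupr, ev$n_terms_evaluated))
  }
  invisible(x)
}

#' Compare network and attribute variants
#'
#' Runs the pipeline once per variant under shared derived seeds and collects
#' the evaluation metrics into one table, to compare single-network against
#' combined-network embeddings and attribute subsets. Variants requesting the
#' sequence attribute on the similarity network alone are skipped with a
#' warning.
#'
#' @param data As in [run_pipeline()].
#' @param config A [pipeline_config()].
#' @param variants List of lists with elements `network` (one of `"ppi"`,
#'   `"ssn"`, `"combined"`) and `attributes` (`"ALL"` or a character subset).
#' @return Data frame with columns `network`, `attributes`, `namespace`,
#'   `M_aupr`, `m_aupr`, `f_max`.
#' @export
run_ablation <- function(data, config = pipeline_config(),
                         variants = list(
                           list(network = "ppi", attributes = "ALL"),
                           list(network = "ssn", attributes = "ALL"),
                           list(network = "combined", attributes = "ALL"))) {
  rows <- list()
  for (v in variants) {
    atts <- if (identical(v$attributes, "ALL"))
      c("sequence", "location", "domain") else v$attributes
    if (v$network == "ssn" && identical(atts, "sequence")) {
      warning("skipping illegal variant: sequence attribute on the ",
              "similarity network")
      next
    }
    res <- run_pipeline(data, config, networks = v$network,
                        attributes = v$attributes)
    for (ns in names(res$evaluations)) {
      ev <- res$evaluations[[ns]]
      rows[[length(rows) + 1L]] <- data.frame(
        network = v$network,
        attributes = paste(atts, collapse = "+"),
        namespace = ns,
        M_aupr = ev$M_aupr, m_aupr = ev$m_aupr, f_max = ev$f_max,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(network = character(0), attributes = character(0),
                      namespace = character(0), M_aupr = numeric(0),
                      m_aupr = numeric(0), f_max = numeric(0)))
  do.call(rbind, rows)
}
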