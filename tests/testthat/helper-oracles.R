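# Independent brute-force oracles used to cross-check the package's metric,
# encoder and ontology implementations. These deliberately use different
# algorithms (cumulative-sum sweeps, per-node loops, BFS) from the package
# code paths they verify.

# step-sum AUPR via sort-and-accumulate over descending score groups
oracle_aupr <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  npos <- sum(y == 1)
  stopifnot(npos > 0)
  # group tied scores: cumulative TP / predictions at each group boundary
  boundary <- which(!duplicated(s, fromLast = TRUE))  # last index of each group
  ctp <- cumsum(y == 1)[boundary]
  cn <- boundary
  pr <- ctp / cn
  rc <- ctp / npos
  sum(diff(c(0, rc)) * pr)
}

# exhaustive F-max over every distinct score value, all counts recomputed
# from scratch with explicit loops
oracle_fmax <- function(scores, labels) {
  best <- 0
  for (t in sort(unique(as.vector(scores)))) {
    tp <- 0; npred <- 0; npos <- 0
    for (i in seq_len(nrow(scores))) {
      for (j in seq_len(ncol(scores))) {
        pred <- scores[i, j] >= t
        if (pred) npred <- npred + 1
        if (labels[i, j] == 1) npos <- npos + 1
        if (pred && labels[i, j] == 1) tp <- tp + 1
      }
    }
    if (npred == 0) next
    pr <- tp / npred; rc <- tp / npos
    if (pr + rc > 0) best <- max(best, 2 * pr * rc / (pr + rc))
  }
  best
}

# per-node message-passing form of the two-layer GCN encoder
oracle_gcn <- function(x, an, params) {
  an <- as.matrix(an)
  n <- nrow(x)
  h1 <- matrix(0, n, ncol(params$W0))
  for (i in seq_len(n)) {
    agg <- rep(0, ncol(x))
    for (j in seq_len(n)) agg <- agg + an[i, j] * x[j, ]
    h1[i, ] <- pmax(agg %*% params$W0, 0)
  }
  mu <- matrix(0, n, ncol(params$W_mu))
  ls <- matrix(0, n, ncol(params$W_sigma))
  for (i in seq_len(n)) {
    agg <- rep(0, ncol(h1))
    for (j in seq_len(n)) agg <- agg + an[i, j] * h1[j, ]
    mu[i, ] <- agg %*% params$W_mu
    ls[i, ] <- agg %*% params$W_sigma
  }
  list(mu = mu, log_sigma = ls)
}

# ancestor closure by explicit BFS over the parent relation
oracle_closure <- function(terms, parents) {
  out <- character(0)
  queue <- terms
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    if (t %in% out) next
    out <- c(out, t)
    queue <- c(queue, parents[[t]])
  }
  sort(out)
}

# random score/label instance for metric property tests
random_instance <- function(n_prot = 8, n_terms = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    labels <- matrix(rbinom(n_prot * n_terms, 1, 0.35), n_prot)
    if (sum(labels) > 0 && any(colSums(labels) > 0)) break
  }
  scores <- matrix(round(runif(n_prot * n_terms), 2), n_prot)
  colnames(labels) <- colnames(scores) <- paste0("t", seq_len(n_terms))
  list(scores = scores, labels = labels)
}

# small attributed random graph for encoder tests
random_attributed_graph <- function(n = 8, r = 5, p = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  rownames(a) <- colnames(a) <- sprintf("N%02d", seq_len(n))
  x <- matrix(rnorm(n * r), n, dimnames = list(rownames(a), NULL))
  attributed_graph(Matrix::Matrix(a, sparse = TRUE), x)
}

# tiny diamond-shaped DAG used across the ontology tests:
# leaf c -> {b1, b2} -> a (root), namespace molecular_function
diamond_dag <- function() {
  go_dag(
    data.frame(id = c("GO:a", "GO:b1", "GO:b2", "GO:c"),
               namespace = "molecular_function",
               stringsAsFactors = FALSE),
    list(`GO:a` = character(0), `GO:b1` = "GO:a", `GO:b2` = "GO:a",
         `GO:c` = c("GO:b1", "GO:b2")))
}

# random DAG + annotations for the true-path property tests
random_dag_annotations <- function(n_terms = 12, n_prot = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- paste0("GO:", sprintf("%04d", seq_len(n_terms)))
  parents <- list()
  parents[[ids[1]]] <- character(0)
  for (k in 2:n_terms)   # parents always earlier in the order: acyclic
    parents[[ids[k]]] <- sample(ids[seq_len(k - 1)], min(k - 1, sample(1:2, 1)))
  dag <- go_dag(data.frame(id = ids, namespace = "biological_process",
                           stringsAsFactors = FALSE), parents)
  ann <- data.frame(
    protein = sample(paste0("P", seq_len(n_prot)), 3 * n_prot, replace = TRUE),
    term = sample(ids, 3 * n_prot, replace = TRUE),
    evidence = "IDA", stringsAsFactors = FALSE)
  list(dag = dag, annotations = ann)
}
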