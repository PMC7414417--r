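# CAFA-style evaluation: pooled precision/recall over a threshold sweep,
# F-max, per-term AUPR via the step sum over distinct score thresholds,
# macro/micro AUPR, fixed-threshold precision/recall/F1, and the best-hit
# homology-transfer baseline.

#' Pooled precision and recall at one threshold
#'
#' A (protein, term) pair is predicted when its score is >= `t`. Precision is
#' pooled true positives over pooled predictions (NA when nothing is
#' predicted); recall is pooled true positives over pooled annotations.
#'
#' @param scores Numeric matrix (proteins x terms).
#' @param labels Binary matrix of the same shape.
#' @param t Threshold.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
pooled_pr_rc <- function(scores, labels, t) {
  stopifnot(all(dim(scores) == dim(labels)))
  if (sum(labels) == 0)
    stop("no annotated (protein, term) pairs: recall undefined")
  pred <- scores >= t
  tp <- sum(pred & labels == 1)
  npred <- sum(pred)
  c(precision = if (npred == 0) NA_real_ else tp / npred,
    recall = tp / sum(labels))
}

#' Maximum F-measure over a threshold sweep
#'
#' Sweeps thresholds, computes pooled precision and recall at each, and
#' returns the maximum harmonic mean. Thresholds where nothing is predicted
#' (precision undefined) or where precision + recall = 0 are skipped; if no
#' threshold yields a predictable F, the result is 0 with a warning.
#'
#' @inheritParams pooled_pr_rc
#' @param thresholds Numeric vector of thresholds; the default is the
#'   101-point grid 0, 0.01, ..., 1. Pass `"exact"` to sweep every distinct
#'   score value (the exhaustive sweep a finer grid converges to).
#' @return F-max, with attributes `threshold` (argmax) and `curve` (a data
#'   frame of threshold/precision/recall).
#' @export
fmax <- function(scores, labels, thresholds = seq(0, 1, by = 0.01)) {
  if (identical(thresholds, "exact"))
    thresholds <- sort(unique(as.vector(scores)))
  pr <- vapply(thresholds, function(t) pooled_pr_rc(scores, labels, t),
               numeric(2))
  f <- 2 * pr[1, ] * pr[2, ] / (pr[1, ] + pr[2, ])
  f[is.na(pr[1, ]) | (pr[1, ] + pr[2, ]) == 0] <- NA
  curve <- data.frame(threshold = thresholds,
                      precision = pr[1, ], recall = pr[2, ])
  if (all(is.na(f))) {
    warning("no threshold yields any prediction; F-max = 0")
    return(structure(0, threshold = NA_real_, curve = curve))
  }
  best <- which.max(f)
  structure(max(f, na.rm = TRUE), threshold = thresholds[best], curve = curve)
}

#' Area under the precision-recall curve for one term
#'
#' Step sum `sum_t (rc(t) - rc(t-1)) * pr(t)` with thresholds at the distinct
#' score values in descending order (so recall is non-decreasing along the
#' sweep and every threshold has at least one prediction), starting from
#' recall 0.
#'
#' @param scores Numeric vector of per-protein scores for one term.
#' @param labels Binary vector; must contain at least one positive.
#' @return AUPR in `[0, 1]`.
#' @export
term_aupr <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0)
    stop("term has no positive labels; exclude it from evaluation")
  ts <- sort(unique(scores), decreasing = TRUE)
  rc_prev <- 0
  area <- 0
  for (t in ts) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    pr <- tp / sum(pred)
    rc <- tp / npos
    area <- area + (rc - rc_prev) * pr
    rc_prev <- rc
  }
  area
}

#' Macro- and micro-averaged AUPR
#'
#' Macro: unweighted mean of per-term AUPRs over terms with at least one
#' positive (terms without positives are excluded and the evaluated-term
#' count reduced). Micro: the same step-sum AUPR computed globally, treating
#' every element of the label matrix as one binary decision.
#'
#' @inheritParams pooled_pr_rc
#' @return List with `M_aupr`, `m_aupr`, `per_term_aupr` (named vector) and
#'   `n_terms_evaluated`.
#' @export
macro_micro_aupr <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  has_pos <- colSums(labels == 1) > 0
  if (!any(has_pos)) stop("no term has a positive label")
  per <- vapply(which(has_pos),
                function(j) term_aupr(scores[, j], labels[, j]),
                numeric(1))
  names(per) <- colnames(labels)[has_pos]
  list(M_aupr = mean(per),
       m_aupr = term_aupr(as.vector(scores), as.vector(labels)),
       per_term_aupr = per,
       n_terms_evaluated = sum(has_pos))
}

#' Full evaluation summary for one score matrix
#'
#' @inheritParams fmax
#' @return Object of class `eval_summary`: list with `f_max`,
#'   `f_max_threshold`, `M_aupr`, `m_aupr`, `per_term_aupr`,
#'   `n_terms_evaluated`, `curve`.
#' @export
evaluate_predictions <- function(scores, labels,
                                 thresholds = seq(0, 1, by = 0.01)) {
  fm <- fmax(scores, labels, thresholds)
  au <- macro_micro_aupr(scores, labels)
  structure(
    list(f_max = as.numeric(fm),
         f_max_threshold = attr(fm, "threshold"),
         M_aupr = au$M_aupr, m_aupr = au$m_aupr,
         per_term_aupr = au$per_term_aupr,
         n_terms_evaluated = au$n_terms_evaluated,
         curve = attr(fm, "curve")),
    class = "eval_summary")
}

#' @export
#' @method print eval_summary
print.eval_summary <- function(x, ...) {
  cat(sprintf("F-max  %.3f (at t = %.2f)\n", x$f_max, x$f_max_threshold))
  cat(sprintf("M-AUPR %.3f   m-AUPR %.3f   (%d terms evaluated)\n",
              x$M_aupr, x$m_aupr, x$n_terms_evaluated))
  invisible(x)
}

#' Pooled precision, recall and F1 of binary predictions
#'
#' Micro-averaged over all (protein, term) pairs; used for fixed-threshold
#' comparisons against the homology baseline (which has no scores).
#'
#' @param predictions Binary matrix.
#' @param labels Binary matrix of the same shape.
#' @return Named vector `c(precision, recall, f1)`.
#' @export
fixed_threshold_prf1 <- function(predictions, labels) {
  stopifnot(all(dim(predictions) == dim(labels)))
  tp <- sum(predictions == 1 & labels == 1)
  npred <- sum(predictions == 1)
  npos <- sum(labels == 1)
  if (npred == 0) warning("no positive predictions; precision reported as 0")
  precision <- if (npred == 0) 0 else tp / npred
  recall <- if (npos == 0) 0 else tp / npos
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Best-hit homology annotation transfer
#'
#' For each test protein, finds its best alignment hit among the training
#' proteins (lowest e-value, ties broken by highest bit score, then by
#' lexicographically smallest subject id) and copies that training protein's
#' closed annotation set as binary predictions. Queries with no hit predict
#' nothing.
#'
#' @param hits Data frame with columns `protein1` (query), `protein2`
#'   (subject), `score` (e-value), `bitscore`.
#' @param train_annotations Closed annotation list (from
#'   [propagate_ancestors()]) for the training proteins.
#' @param test_ids Character vector of query protein ids (rows of the
#'   output).
#' @param term_index Character vector of terms (columns of the output).
#' @return Binary matrix `length(test_ids)` x `length(term_index)`.
#' @export
homology_transfer <- function(hits, train_annotations, test_ids, term_index) {
  stopifnot(isTRUE(attr(train_annotations, "closed")))
  h <- hits[hits$protein1 %in% test_ids &
              hits$protein2 %in% names(train_annotations), , drop = FALSE]
  pred <- matrix(0L, length(test_ids), length(term_index),
                 dimnames = list(test_ids, term_index))
  if (nrow(h)) {
    h <- h[order(h$protein1, h$score, -h$bitscore, h$protein2,
                 method = "radix"), ]
    best <- h[!duplicated(h$protein1), ]
    for (k in seq_len(nrow(best))) {
      terms <- intersect(train_annotations[[best$protein2[k]]], term_index)
      pred[best$protein1[k], terms] <- 1L
    }
  }
  pred
}

#' Remove training proteins homologous to the test set
#'
#' Drops every training protein with any alignment hit to any test protein at
#' strictly more than `max_identity` percent identity (either hit
#' orientation), so the baseline and classifier can be evaluated without
#' near-duplicate leakage.
#'
#' @param train_ids,test_ids Character vectors of protein ids.
#' @param hits Data frame with columns `protein1`, `protein2`, `identity`
#'   (percent).
#' @param max_identity Strict threshold; the default 50 removes > 50\%
#'   identity.
#' @return Character vector, the surviving training ids, with attribute
#'   `removed` listing the dropped ones.
#' @export
remove_homologs <- function(train_ids, test_ids, hits, max_identity = 50) {
  close_hit <- hits$identity > max_identity
  bad <- union(
    hits$protein1[close_hit & hits$protein1 %in% train_ids &
                    hits$protein2 %in% test_ids],
    hits$protein2[close_hit & hits$protein2 %in% train_ids &
                    hits$protein1 %in% test_ids])
  keep <- setdiff(train_ids, bad)
  structure(keep, removed = intersect(train_ids, bad))
}
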