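two_by_two <- function() {
  list(scores = matrix(c(0.9, 0.8, 0.1, 0.7), 2,
                       dimnames = list(c("p1", "p2"), c("t1", "t2"))),
       labels = matrix(c(1L, 0L, 0L, 1L), 2,
                       dimnames = list(c("p1", "p2"), c("t1", "t2"))))
}

test_that("pooled precision and recall match hand enumeration", {
  tt <- two_by_two()
  pr <- pooled_pr_rc(tt$scores, tt$labels, 0.5)
  expect_equal(unname(pr["precision"]), 2 / 3)
  expect_equal(unname(pr["recall"]), 1)
  # perfect predictor
  pr <- pooled_pr_rc(tt$labels, tt$labels, 0.5)
  expect_equal(unname(pr), c(1, 1))
  # threshold above every score: no predictions
  pr <- pooled_pr_rc(tt$scores, tt$labels, 0.95)
  expect_true(is.na(pr["precision"]))
  expect_equal(unname(pr["recall"]), 0)
  expect_error(pooled_pr_rc(tt$scores, tt$labels * 0L, 0.5), "no annotated")
})

test_that("F-max attains the hand-computed harmonic mean", {
  tt <- two_by_two()
  fm <- fmax(tt$scores, tt$labels)
  expect_gte(as.numeric(fm), 0.8)  # F1 at t = 0.5 is already 0.8
  expect_equal(as.numeric(fmax(tt$labels, tt$labels)), 1.0)
  expect_warning(fm0 <- fmax(tt$scores * 0, tt$labels, thresholds = 0.5),
                 "no threshold")
  expect_equal(as.numeric(fm0), 0)
  # all-zero scores predict everything at t = 0: F equals prevalence-based F
  fm <- fmax(tt$scores * 0, tt$labels)
  pr <- 2 / 4; rc <- 1
  expect_equal(as.numeric(fm), 2 * pr * rc / (pr + rc))
})

test_that("grid F-max equals the exhaustive sweep when scores lie on it", {
  for (rep in 1:100) {
    inst <- random_instance(n_prot = sample(3:10, 1),
                            n_terms = sample(2:5, 1), seed = 1000 + rep)
    expect_equal(as.numeric(fmax(inst$scores, inst$labels)),
                 oracle_fmax(inst$scores, inst$labels),
                 tolerance = 1e-10)
    expect_equal(as.numeric(fmax(inst$scores, inst$labels, "exact")),
                 oracle_fmax(inst$scores, inst$labels),
                 tolerance = 1e-10)
  }
})

test_that("per-term AUPR matches the sort-and-accumulate oracle", {
  expect_equal(term_aupr(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1.0)
  expect_error(term_aupr(c(0.5, 0.1), c(0, 0)), "no positive")
  for (rep in 1:100) {
    set.seed(2000 + rep)
    n <- sample(5:30, 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # provoke ties
    expect_equal(term_aupr(scores, labels), oracle_aupr(scores, labels),
                 tolerance = 1e-10)
  }
})

test_that("random scores give AUPR near the positive fraction", {
  set.seed(99)
  n <- 20000
  p <- 0.15
  labels <- rbinom(n, 1, p)
  scores <- runif(n)
  # random-classifier baseline: AUPR converges to prevalence
  expect_lt(abs(term_aupr(scores, labels) - p), 3 * sqrt(p * (1 - p) / n) + 0.01)
})

test_that("macro and micro AUPR aggregate per-term areas correctly", {
  tt <- two_by_two()
  au <- macro_micro_aupr(tt$scores, tt$labels)
  expect_equal(au$n_terms_evaluated, 2)
  expect_equal(au$M_aupr, mean(au$per_term_aupr))
  expect_equal(au$M_aupr,
               mean(c(term_aupr(tt$scores[, 1], tt$labels[, 1]),
                      term_aupr(tt$scores[, 2], tt$labels[, 2]))))
  expect_equal(au$m_aupr,
               oracle_aupr(as.vector(tt$scores), as.vector(tt$labels)),
               tolerance = 1e-12)
  # single-term matrix: macro = micro = that term's AUPR
  au1 <- macro_micro_aupr(tt$scores[, 1, drop = FALSE],
                          tt$labels[, 1, drop = FALSE])
  expect_equal(au1$M_aupr, au1$m_aupr)
  # perfect predictor
  aup <- macro_micro_aupr(tt$labels, tt$labels)
  expect_equal(c(aup$M_aupr, aup$m_aupr), c(1, 1))
  # identical columns: macro equals micro
  s <- cbind(tt$scores[, 1], tt$scores[, 1])
  l <- cbind(tt$labels[, 1], tt$labels[, 1])
  au2 <- macro_micro_aupr(s, l)
  expect_equal(au2$M_aupr, au2$m_aupr, tolerance = 1e-12)
  # zero-positive terms are excluded, count reduced
  l3 <- cbind(tt$labels, t3 = c(0L, 0L))
  s3 <- cbind(tt$scores, t3 = c(0.4, 0.2))
  expect_equal(macro_micro_aupr(s3, l3)$n_terms_evaluated, 2)
})

test_that("metrics are invariant to simultaneous row permutation", {
  inst <- random_instance(n_prot = 9, n_terms = 4, seed = 321)
  perm <- sample(9)
  expect_equal(as.numeric(fmax(inst$scores, inst$labels)),
               as.numeric(fmax(inst$scores[perm, ], inst$labels[perm, ])))
  a1 <- macro_micro_aupr(inst$scores, inst$labels)
  a2 <- macro_micro_aupr(inst$scores[perm, ], inst$labels[perm, ])
  expect_equal(a1$M_aupr, a2$M_aupr)
  expect_equal(a1$m_aupr, a2$m_aupr)
})

test_that("fixed-threshold precision/recall/F1 match hand enumeration", {
  tt <- two_by_two()
  pred <- threshold_predictions(tt$scores, 0.5)
  expect_equal(unname(fixed_threshold_prf1(pred, tt$labels)),
               c(2 / 3, 1, 0.8))
  expect_equal(unname(fixed_threshold_prf1(tt$labels, tt$labels)), c(1, 1, 1))
  expect_equal(unname(fixed_threshold_prf1(1L - tt$labels, tt$labels)),
               c(0, 0, 0))
  expect_warning(out <- fixed_threshold_prf1(tt$labels * 0L, tt$labels),
                 "no positive predictions")
  expect_equal(unname(out), c(0, 0, 0))
})

test_that("homology transfer copies the best hit's closed annotations", {
  train_ann <- structure(
    list(s1 = c("GO:1", "GO:2"), s2 = "GO:3"),
    closed = TRUE)
  hit <- function(q, s, e, b) data.frame(protein1 = q, protein2 = s,
                                         score = e, bitscore = b,
                                         stringsAsFactors = FALSE)
  terms <- c("GO:1", "GO:2", "GO:3")
  # single hit: annotations copied verbatim
  pred <- homology_transfer(hit("q1", "s1", 1e-10, 100), train_ann,
                            "q1", terms)
  expect_equal(unname(pred["q1", ]), c(1L, 1L, 0L))
  # lowest e-value wins
  pred <- homology_transfer(
    rbind(hit("q1", "s1", 1e-5, 100), hit("q1", "s2", 1e-10, 50)),
    train_ann, "q1", terms)
  expect_equal(unname(pred["q1", ]), c(0L, 0L, 1L))
  # e-value tie: higher bit score wins
  pred <- homology_transfer(
    rbind(hit("q1", "s1", 1e-8, 200), hit("q1", "s2", 1e-8, 100)),
    train_ann, "q1", terms)
  expect_equal(unname(pred["q1", ]), c(1L, 1L, 0L))
  # full tie: lexicographically smaller subject wins
  pred <- homology_transfer(
    rbind(hit("q1", "s2", 1e-8, 100), hit("q1", "s1", 1e-8, 100)),
    train_ann, "q1", terms)
  expect_equal(unname(pred["q1", ]), c(1L, 1L, 0L))
  # no hit: nothing predicted
  pred <- homology_transfer(hit("other", "s1", 1e-8, 10), train_ann,
                            "q1", terms)
  expect_equal(sum(pred), 0)
})

test_that("homolog removal is strict in percent identity", {
  hits <- data.frame(protein1 = c("a", "b"), protein2 = c("x", "y"),
                     identity = c(50.0, 50.1), stringsAsFactors = FALSE)
  kept <- remove_homologs(c("a", "b", "c"), c("x", "y"), hits)
  expect_true("a" %in% kept)      # exactly 50 is kept
  expect_false("b" %in% kept)     # above 50 is removed
  expect_equal(attr(kept, "removed"), "b")
  # hits in the reverse orientation also count
  hits2 <- data.frame(protein1 = "x", protein2 = "a", identity = 80)
  expect_false("a" %in% remove_homologs(c("a", "b"), "x", hits2))
  # no hits: unchanged
  expect_equal(as.character(remove_homologs(c("a", "b"), "x", hits[0, ])),
               c("a", "b"))
})

test_that("ranking AUC agrees with an established ROC implementation", {
  set.seed(64)
  for (rep in 1:5) {
    pos <- rnorm(40, 1)
    neg <- rnorm(60)
    expect_equal(
      ranking_auc(pos, neg),
      as.numeric(pROC::auc(c(rep(1, 40), rep(0, 60)), c(pos, neg),
                           direction = "<", quiet = TRUE)))
  }
  # ties count one half
  expect_equal(ranking_auc(c(1, 1), c(1, 0)), 0.75)
})
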