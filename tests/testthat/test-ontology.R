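test_that("evidence filtering keeps only experimental codes, case-sensitively", {
  ann <- data.frame(protein = c("p1", "p1", "p2", "p2"),
                    term = c("t1", "t2", "t1", "t3"),
                    evidence = c("IDA", "IEA", "ida", "TAS"),
                    stringsAsFactors = FALSE)
  kept <- filter_evidence(ann)
  expect_equal(kept$term, c("t1", "t3"))
  expect_equal(nrow(filter_evidence(ann[0, ])), 0)
  expect_equal(filter_evidence(ann, unique(ann$evidence)), ann)
})

test_that("ancestor propagation closes annotation sets upward", {
  # chain: c -> b -> a
  chain <- go_dag(data.frame(id = c("a", "b", "c"),
                             namespace = "molecular_function"),
                  list(a = character(0), b = "a", c = "b"))
  closed <- propagate_ancestors(
    data.frame(protein = "p1", term = "c", stringsAsFactors = FALSE), chain)
  expect_equal(closed$p1, c("a", "b", "c"))

  root_only <- propagate_ancestors(
    data.frame(protein = "p1", term = "a", stringsAsFactors = FALSE), chain)
  expect_equal(root_only$p1, "a")

  # diamond: closure picks up both intermediate parents
  closed <- propagate_ancestors(
    data.frame(protein = "p1", term = "GO:c", stringsAsFactors = FALSE),
    diamond_dag())
  expect_equal(closed$p1,
               oracle_closure("GO:c", diamond_dag()$parents))

  expect_warning(
    propagate_ancestors(
      data.frame(protein = "p1", term = c("c", "nope")), chain),
    "not in the DAG")
})

test_that("propagation is idempotent and matches BFS closure on random DAGs", {
  for (rep in 1:10) {
    ra <- random_dag_annotations(seed = 400 + rep)
    closed <- propagate_ancestors(ra$annotations, ra$dag)
    for (p in names(closed)) {
      direct <- unique(ra$annotations$term[ra$annotations$protein == p])
      expect_equal(closed[[p]], oracle_closure(direct, ra$dag$parents))
    }
    again <- propagate_ancestors(
      data.frame(protein = rep(names(closed), lengths(closed)),
                 term = unlist(closed, use.names = FALSE)), ra$dag)
    expect_equal(again[names(closed)], closed[names(closed)],
                 ignore_attr = TRUE)
  }
})

test_that("cycles in the parent relation are detected", {
  expect_error(
    go_dag(data.frame(id = c("a", "b"), namespace = "molecular_function"),
           list(a = "b", b = "a")),
    "cycle")
})

test_that("term selection respects inclusive count bounds per namespace", {
  dag <- go_dag(data.frame(id = c("root", "t1", "t2", "t3"),
                           namespace = c(rep("molecular_function", 3),
                                         "biological_process")),
                list(root = character(0), t1 = "root", t2 = "root",
                     t3 = character(0)))
  mk_closed <- function(counts) {
    prots <- paste0("p", seq_len(max(counts)))
    closed <- lapply(prots, function(p) character(0))
    names(closed) <- prots
    for (term in names(counts))
      for (i in seq_len(counts[[term]]))
        closed[[i]] <- sort(unique(c(closed[[i]], term, "root")))
    attr(closed, "closed") <- TRUE
    closed
  }
  closed <- mk_closed(c(t1 = 30, t2 = 31))
  expect_equal(select_terms(closed, dag, "molecular_function", 11, 30), "t1")
  expect_equal(select_terms(closed, dag, "molecular_function", 11, 100),
               c("t1", "t2"))
  # roots are excluded; namespaces separated
  expect_false("root" %in% select_terms(closed, dag, "molecular_function", 0))
  expect_equal(select_terms(mk_closed(c(t1 = 10)), dag,
                            "molecular_function", 11, 30), character(0))
})

test_that("label matrices satisfy the true-path rule", {
  dag <- diamond_dag()
  closed <- propagate_ancestors(
    data.frame(protein = "p1", term = "GO:c", stringsAsFactors = FALSE), dag)
  y <- build_label_matrix(closed, c("GO:a", "GO:b1", "GO:b2", "GO:c"), "p1")
  expect_equal(unname(y["p1", ]), c(1L, 1L, 1L, 1L))

  empty <- structure(list(), names = character(0), closed = TRUE)
  y0 <- build_label_matrix(empty, c("GO:a"), c("q1", "q2"),
                           allow_unannotated = TRUE)
  expect_equal(sum(y0), 0)
  expect_error(build_label_matrix(empty, "GO:a", "q1"), "without annotation")

  # property: parent column always >= child column after closure
  for (rep in 1:10) {
    ra <- random_dag_annotations(seed = 900 + rep)
    closed <- propagate_ancestors(ra$annotations, ra$dag)
    y <- build_label_matrix(closed, ra$dag$terms$id,
                            sort(unique(ra$annotations$protein)),
                            allow_unannotated = TRUE)
    for (child in ra$dag$terms$id)
      for (parent in ra$dag$parents[[child]])
        expect_true(all(y[, parent] >= y[, child]))
  }
})

test_that("OBO round-trip preserves terms and parent relations", {
  dag <- diamond_dag()
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, path)
  back <- read_obo(path)
  expect_equal(sort(back$terms$id), sort(dag$terms$id))
  for (id in dag$terms$id)
    expect_equal(sort(back$parents[[id]]), sort(dag$parents[[id]]))
  expect_equal(back$terms$namespace[back$terms$id == "GO:a"],
               "molecular_function")
})
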