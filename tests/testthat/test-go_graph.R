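test_that("annotations propagate upward to all ancestors", {
  dag <- load_dag(data.frame(parent = "A", child = "B"),
                  data.frame(gene_id = "g1", term_id = "B"))
  gs <- dag_gene_sets(dag)
  expect_identical(gs$A, "g1")
  expect_identical(gs$B, "g1")

  dag <- load_dag(data.frame(parent = c("A", "A"), child = c("B", "C")),
                  data.frame(gene_id = c("g1", "g2", "g3"),
                             term_id = c("B", "C", "A")))
  gs <- dag_gene_sets(dag)
  expect_setequal(gs$A, c("g1", "g2", "g3"))
  expect_identical(gs$B, "g1")
  expect_identical(gs$C, "g2")
})

test_that("structural defects are rejected and bad annotations skipped", {
  ann <- data.frame(gene_id = "g1", term_id = "B")
  expect_error(load_dag(data.frame(parent = c("A", "B"), child = c("B", "A")), ann),
               class = "hmtree_structural_error")
  # two roots
  expect_error(load_dag(data.frame(parent = c("A", "C"), child = c("B", "B")),
                        data.frame(gene_id = "g1", term_id = "B")),
               class = "hmtree_structural_error")
  # unknown term: warn and skip, keep going
  expect_warning(
    dag <- load_dag(data.frame(parent = "A", child = "B"),
                    data.frame(gene_id = c("g1", "g2"), term_id = c("B", "ZZ"))),
    "unknown term")
  expect_identical(dag_gene_sets(dag)$A, "g1")
  # terms never annotated are dropped
  dag <- load_dag(data.frame(parent = c("A", "A"), child = c("B", "C")),
                  data.frame(gene_id = "g1", term_id = "B"))
  expect_false("C" %in% dag$ids)
})

test_that("transitive reduction removes exactly the shortcut edges", {
  # diamond: the direct root-to-sink edge is redundant
  dag <- diamond_dag()
  red <- transitive_reduce(dag)
  ep <- cbind(red$ids[red$edges[, 1]], red$ids[red$edges[, 2]])
  expect_equal(nrow(ep), 4L)
  expect_false(any(ep[, 1] == "t1" & ep[, 2] == "t4"))
  expect_identical(dag_gene_sets(red), dag_gene_sets(dag))

  # chain with a shortcut
  dag <- load_dag(data.frame(parent = c("A", "B", "A"), child = c("B", "C", "C")),
                  data.frame(gene_id = "g1", term_id = "C"))
  red <- transitive_reduce(dag)
  ep <- cbind(red$ids[red$edges[, 1]], red$ids[red$edges[, 2]])
  expect_setequal(paste(ep[, 1], ep[, 2]), c("A B", "B C"))

  # a tree is unchanged
  dag <- load_dag(data.frame(parent = c("A", "A"), child = c("B", "C")),
                  data.frame(gene_id = c("g1", "g2"), term_id = c("B", "C")))
  expect_identical(transitive_reduce(dag)$edges, dag$edges)
})

test_that("tree transformation reproduces the diamond worked example", {
  tm <- transform_to_tree(diamond_dag())
  expect_identical(tm$tree$ids, c("t1", "t2", "t3", "t4"))
  expect_identical(tm$tree$parent, c(NA_integer_, 1L, 1L, 3L))
  gs <- dag_gene_sets(tm$tree)
  # T_2 = G_2 with node 4's genes removed
  expect_identical(gs$t2, "c")
  expect_setequal(gs$t3, c("a", "b", "d", "e"))
  expect_setequal(gs$t4, c("a", "b"))
  expect_identical(tm$map$gt$t2, c(2L, 4L))
  expect_identical(tm$map$gt$t1, 1:4)
})

test_that("a DAG that is already a tree transforms to itself", {
  dag <- load_dag(
    data.frame(parent = c("A", "A", "B"), child = c("B", "C", "D")),
    data.frame(gene_id = c("g1", "g2", "g3"), term_id = c("C", "D", "B")))
  tm <- transform_to_tree(dag)
  expect_identical(tm$tree$n, dag$n)
  expect_identical(dag_gene_sets(tm$tree), dag_gene_sets(dag))
  # GT_j is exactly the tree subtree of j
  expect_identical(tm$map$gt$B, sort(match(c("B", "D"), tm$tree$ids)))
})

test_that("equal-size parents break ties toward the smaller identifier", {
  # node D has parents B and C with identical gene-set sizes
  dag <- load_dag(
    data.frame(parent = c("A", "A", "B", "C"), child = c("B", "C", "D", "D")),
    data.frame(gene_id = c("g1", "g2", "g3"), term_id = c("D", "B", "C")))
  tm <- transform_to_tree(dag)
  expect_identical(tm$tree$ids[tm$tree$parent[match("D", tm$tree$ids)]], "B")
})

test_that("tree invariants and map monotonicity hold on random DAGs", {
  for (s in 1:100) {
    set.seed(s)
    cfg <- sim_config(sample(10:50, 1), theta = default_theta(), seed = s,
                      multi_parent_fraction = runif(1, 0, 0.6))
    dag <- random_dag(cfg)$dag
    tm <- transform_to_tree(dag)
    tr <- tm$tree
    # nestedness and non-emptiness of carved sets
    expect_true(all(lengths(tr$gene_sets) > 0L))
    for (i in seq_len(tr$n)[-1]) {
      expect_true(all(tr$gene_sets[[i]] %in% tr$gene_sets[[tr$parent[i]]]))
    }
    # GT monotone over sampled DAG edges (G_child subset of G_parent)
    e <- dag$edges[sample.int(nrow(dag$edges), min(10, nrow(dag$edges))), ,
                   drop = FALSE]
    for (r in seq_len(nrow(e))) {
      gtp <- tm$map$gt[[dag$ids[e[r, 1]]]]
      gtc <- tm$map$gt[[dag$ids[e[r, 2]]]]
      expect_true(all(gtc %in% gtp))
    }
  }
})

test_that("transformation is deterministic", {
  cfg <- sim_config(40, theta = default_theta(), seed = 99,
                    multi_parent_fraction = 0.4)
  a <- transform_to_tree(random_dag(cfg)$dag)
  b <- transform_to_tree(random_dag(cfg)$dag)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_tree_tsv(a$tree, f1)
  write_tree_tsv(b$tree, f2)
  expect_identical(readLines(f1), readLines(f2))
})
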